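test_that("VeDBA is zero for constant traces and homogeneous of degree 1", {
  v0 <- compute_vedba(constant_trace(0.2, -0.1, 0.95, n = 500))
  expect_true(all(abs(v0$vedba) < 1e-9))

  sim <- quick_sim(seconds = 400, n_dives = 1, seed = 6)
  v1 <- compute_vedba(sim$trace)
  # doubling dynamic amplitudes about any baseline doubles every value
  st <- running_stats(sim$trace, 2)
  doubled <- sim$trace
  doubled$ax <- st$mean_x + 2 * (sim$trace$ax - st$mean_x)
  doubled$ay <- st$mean_y + 2 * (sim$trace$ay - st$mean_y)
  doubled$az <- st$mean_z + 2 * (sim$trace$az - st$mean_z)
  v2 <- compute_vedba(doubled)
  # the running mean of the doubled trace shifts slightly, so compare with
  # a small relative tolerance
  expect_equal(v2$vedba, 2 * v1$vedba, tolerance = 0.02)

  # brute-force per-second oracle: recompute directly from dynamic norms
  rate <- trace_rate(sim$trace)
  dyn <- sqrt((sim$trace$ax - st$mean_x)^2 + (sim$trace$ay - st$mean_y)^2 +
                (sim$trace$az - st$mean_z)^2)
  oracle <- tapply(dyn, floor(sim$trace$t - sim$trace$t[1]), sum) / rate
  expect_equal(unname(v1$vedba), unname(as.numeric(oracle)),
               tolerance = 1e-9)
})

test_that("allometric BMR and FMR follow their stated forms", {
  p <- list(bmr = list(a = 1, b = 1), fmr = list(b0 = 0, b1 = 1, b2 = 0))
  expect_equal(bmr_allometric(2.7, p), 2.7)
  expect_equal(fmr_allometric(2.0, 52, p), 2000)
  expect_error(bmr_allometric(-1, p), "positive")

  d <- allometric_defaults()
  masses <- seq(2, 3.5, by = 0.1)
  expect_true(all(diff(bmr_allometric(masses, d)) > 0))
  expect_true(all(fmr_allometric(masses, 52, d) > bmr_allometric(masses, d)))
  # latitude coefficient > 0 implies FMR increases with |latitude|
  expect_gt(fmr_allometric(2.7, 60, d), fmr_allometric(2.7, 40, d))
  # arithmetic oracle on the default coefficients
  expect_equal(bmr_allometric(2.7, d), d$bmr$a * 2.7^d$bmr$b)
  expect_equal(fmr_allometric(2.7, 52, d),
               10^(d$fmr$b0 + d$fmr$b1 * log10(2700) + d$fmr$b2 * 52))
})

test_that("the k calibration is a line through the origin", {
  p <- list(bmr = list(a = 1600, b = 0), fmr = list(b0 = log10(4000), b1 = 0,
                                                    b2 = 0))
  prof <- calibrate_k("b", 2.8, daily_vedba = c(600000, 600000), params = p)
  expect_equal(prof$k, 0.004)
  # predicting AEE back from the mean VeDBA24 recovers FMR - BMR exactly
  expect_lt(abs(prof$k * prof$vedba24_mean - prof$aee_kj_day) /
              prof$aee_kj_day, 1e-12)
  # halving all VeDBA doubles k and leaves predicted kJ unchanged
  prof2 <- calibrate_k("b", 2.8, daily_vedba = c(300000, 300000), params = p)
  expect_equal(prof2$k, 2 * prof$k)
  expect_equal(prof2$k * 300000, prof$k * 600000)
  # zero complete days: excluded with a warning
  expect_warning(prof3 <- calibrate_k("b", 2.8, daily_vedba = numeric(0)),
                 "no complete")
  expect_true(prof3$excluded)
  expect_true(is.na(prof3$k))
})

test_that("event costs sum VeDBA over dive plus linked take-off", {
  vs <- tibble::tibble(bird_id = "b", t = 0:99,
                       vedba = rep(16, 100), n_samples = 50)
  prof <- tibble::tibble(bird_id = "b", k = 0.004, bmr_kj_day = 800)
  ev <- tibble::tibble(
    bird_id = "b", event_id = c("d1", "t1"), kind = c("dive", "takeoff"),
    start_s = c(10, 13), end_s = c(13, 40), duration_s = c(3, 27),
    dive_type = c("plunge", "n/a"), linked_id = c("t1", "d1"),
    no_takeoff = FALSE, flagged = FALSE
  )
  cost <- event_cost(ev, vs, prof)
  # half-open span [10, 40) covers the 30 seconds 10..39
  expect_equal(cost$summed_vedba, 16 * 30)
  expect_equal(cost$cost_kj, 0.004 * 16 * 30)
  expect_false(cost$partial)
  # arithmetic example: 480 g-seconds at k = 0.004 costs 1.92 kJ
  expect_equal(0.004 * 480, 1.92)
  # a dive with no take-off is costed over the dive alone and flagged
  ev2 <- ev[1, ]
  ev2$linked_id <- NA_character_
  cost2 <- event_cost(ev2, vs, prof)
  expect_true(cost2$no_takeoff)
  expect_lt(cost2$summed_vedba, cost$summed_vedba)
})

test_that("trip expenditure adds prorated BMR and is additive", {
  vs <- tibble::tibble(bird_id = "b", t = 0:86399,
                       vedba = rep(0, 86400), n_samples = 50)
  prof <- tibble::tibble(bird_id = "b", k = 0.004, bmr_kj_day = 800)
  te <- trip_expenditure(vs, prof)
  expect_equal(te$expenditure_kj, 800)  # a resting bird spends its BMR

  vs$vedba <- runif(86400)
  whole <- trip_expenditure(vs, prof, c(0, 86400))
  a <- trip_expenditure(vs, prof, c(0, 40000))
  b <- trip_expenditure(vs, prof, c(40000, 86400))
  expect_equal(a$movement_kj + b$movement_kj, whole$movement_kj,
               tolerance = 1e-9)
  expect_error(trip_expenditure(vs, prof, c(0, 2 * 86400)), "coverage")
})

test_that("TED applies the sex-specific chick share", {
  d <- demand_defaults()
  f <- total_energetic_demand(0, "female", 1)
  expect_equal(f$ted_kj, 0.6 * 1397.14)
  # a tracked male over 4.91 days lands on the printed Table value within
  # rounding of the day length
  m <- total_energetic_demand(17024, "male", 4.91)
  expect_lt(abs(m$ted_kj - 19763), 15)
  # female and male TED over equal expenditure differ by exactly the share
  # gap times the chick demand
  fm <- total_energetic_demand(c(5000, 5000), c("female", "male"),
                               c(3, 3))
  expect_equal(fm$ted_kj[1] - fm$ted_kj[2], 0.2 * 1397.14 * 3)
  expect_equal(fm$ted_per_day_kj[1] - fm$ted_per_day_kj[2], 0.2 * 1397.14)
  expect_warning(u <- total_energetic_demand(5000, "unknown", 3), "unknown")
  expect_true(is.na(u$ted_kj))
})

test_that("daily period sums keep only complete aligned periods", {
  vs <- tibble::tibble(bird_id = "b", t = 0:249, vedba = rep(1, 250),
                       n_samples = 50)
  s <- vedba_period_sums(vs, period_s = 100)
  expect_equal(s$period, c(0, 1))
  expect_equal(s$vedba_sum, c(100, 100))
  # a missing second invalidates its period
  vs$vedba[50] <- NA
  s2 <- vedba_period_sums(vs, period_s = 100)
  expect_equal(s2$period, 1)
})
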