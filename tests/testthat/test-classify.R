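test_that("running statistics match a brute-force window recomputation", {
  tr <- constant_trace(0.1, -0.2, 0.9, n = 300)
  st <- running_stats(tr, 2)
  expect_equal(st$mean_x, rep(0.1, 300), tolerance = 1e-12)
  # the end samples have a one-point window, so their SD is undefined
  expect_true(all(is.na(st$sd_x[c(1, 300)])))
  expect_equal(st$sd_x[2:299], rep(0, 298), tolerance = 1e-7)

  # alternating +/-1 g square wave: mean ~ 0, SD ~ 1 away from edges
  n <- 400
  sq <- accel_trace(
    tibble::tibble(t = (seq_len(n) - 1) / 50, ax = rep(c(1, -1), n / 2),
                   ay = 0, az = 1),
    rate_hz = 50
  )
  st_sq <- running_stats(sq, 2)
  mid <- 100:300
  expect_true(all(abs(st_sq$mean_x[mid]) < 0.02))
  expect_true(all(abs(st_sq$sd_x[mid] - 1) < 0.02))

  # random trace against direct per-window recomputation
  set.seed(42)
  m <- 200
  rnd <- accel_trace(
    tibble::tibble(t = (seq_len(m) - 1) / 50, ax = rnorm(m), ay = rnorm(m),
                   az = rnorm(m) + 1),
    rate_hz = 50
  )
  st_r <- running_stats(rnd, 2)
  half <- 50
  for (i in c(60, 100, 141)) {
    w <- (i - half):(i + half)
    expect_equal(st_r$mean_x[i], mean(rnd$ax[w]), tolerance = 1e-9)
    expect_equal(st_r$sd_x[i], sd(rnd$ax[w]), tolerance = 1e-9)
    expect_equal(st_r$sd_z[i], sd(rnd$az[w]), tolerance = 1e-9)
  }
  # edge samples shrink symmetrically: first interior estimate uses i-1 pts
  expect_equal(st_r$mean_x[3], mean(rnd$ax[1:5]), tolerance = 1e-12)

  # a segment shorter than the window is unusable
  short <- accel_trace(
    tibble::tibble(t = c(0:10 / 50, 10 + 0:5 / 50), ax = 0, ay = 0, az = 1),
    rate_hz = 50
  )
  st_s <- running_stats(short, 2)
  expect_true(all(!st_s$usable))
})

test_that("pitch matches closed-form angles for static orientations", {
  p0 <- compute_pitch(constant_trace(0, 0, 1))
  expect_equal(p0, rep(0, 500), tolerance = 1e-9)
  p90 <- compute_pitch(constant_trace(1, 0, 0))
  expect_equal(p90, rep(90, 500), tolerance = 1e-9)
  p30 <- compute_pitch(constant_trace(0.5, 0, 0.866))
  expect_equal(p30, rep(30, 500), tolerance = 0.01)
})

test_that("dive detection triggers on the mean/SD thresholds only", {
  # flat rest: no dives
  rest <- quick_sim(seconds = 300, n_dives = 0, seed = 2)
  expect_equal(nrow(detect_dives(rest$trace)), 0)

  # region with running mean -0.2 g and running SD 1.6 g triggers a dive
  n <- 3000; rate <- 50
  t <- (seq_len(n) - 1) / rate
  ax <- rep(0, n)
  dive_idx <- t >= 30 & t < 40
  ax[dive_idx] <- -0.2 + 1.6 * sqrt(2) * sin(2 * pi * 8 * t[dive_idx])
  tr <- accel_trace(tibble::tibble(t = t, ax = ax, ay = 0, az = 1),
                    rate_hz = rate)
  dv <- detect_dives(tr)
  expect_equal(nrow(dv), 1)
  expect_lt(abs(dv$start_s[1] - 30), 1.5)

  # below either threshold nothing triggers
  ax2 <- rep(0, n)
  ax2[dive_idx] <- -0.2 + 1.2 * sqrt(2) * sin(2 * pi * 8 * t[dive_idx])
  tr2 <- accel_trace(tibble::tibble(t = t, ax = ax2, ay = 0, az = 1),
                     rate_hz = rate)
  expect_equal(nrow(detect_dives(tr2)), 0)
})

test_that("synthetic dives are recovered with starts within 1 s of truth", {
  sim <- quick_sim(seconds = 1500, n_dives = 10, seed = 42)
  ev <- classify_behaviour(sim$trace)
  det <- ev[ev$kind == "dive", ]
  truth <- sim$events[sim$events$kind == "dive", ]
  expect_equal(nrow(det), 10)
  offs <- det$start_s - truth$start_s
  expect_true(all(abs(offs) < 1))
  # every take-off starts at or after its dive's end
  to <- ev[ev$kind == "takeoff", ]
  expect_equal(nrow(to), 10)
  expect_true(all(to$start_s >= det$end_s - 1e-9))
  # type counts partition the total
  expect_equal(sum(det$dive_type == "plunge") +
                 sum(det$dive_type == "pursuit"), nrow(det))
})

test_that("classification is invariant to uniform time translation", {
  sim <- quick_sim(seconds = 600, n_dives = 4, seed = 9)
  ev <- classify_behaviour(sim$trace)
  shifted <- sim$trace
  shifted$t <- shifted$t + 1000
  ev_s <- classify_behaviour(shifted)
  expect_equal(ev_s$start_s, ev$start_s + 1000, tolerance = 1e-9)
  expect_equal(ev_s$end_s, ev$end_s + 1000, tolerance = 1e-9)
  expect_equal(ev_s$dive_type, ev$dive_type)
})

test_that("dive types split at 5 s with the boundary in pursuit", {
  expect_equal(classify_dive_type(4.0), "plunge")
  expect_equal(classify_dive_type(5.0), "pursuit")
  expect_equal(classify_dive_type(6.0), "pursuit")
  expect_error(classify_dive_type(0))
})

test_that("TDR matching is one-to-one within tolerance", {
  mk_events <- function(starts) {
    tibble::tibble(bird_id = "x", event_id = paste0("d", seq_along(starts)),
                   kind = "dive", start_s = starts, end_s = starts + 2,
                   duration_s = 2, dive_type = "plunge",
                   linked_id = NA_character_, no_takeoff = TRUE,
                   flagged = FALSE)
  }
  mk_depth <- function(starts, T_end = 400) {
    t <- seq(0, T_end, by = 0.25)
    depth <- rep(0, length(t))
    for (s in starts) depth[t >= s & t <= s + 2] <- 2
    depth_trace(tibble::tibble(t = t, depth_m = depth), rate_hz = 4,
                trigger_threshold_m = 0.5)
  }
  starts <- c(50, 150, 250)
  # identical times: all matched, zero offsets
  v <- validate_against_tdr(mk_events(starts), mk_depth(starts))
  expect_equal(v$n_matched, 3)
  expect_equal(v$match_rate_pct, 100)
  expect_equal(v$matches$offset_s, rep(0, 3))
  # accel shifted +2 s: all matched with mean offset 2
  v2 <- validate_against_tdr(mk_events(starts + 2), mk_depth(starts))
  expect_equal(v2$n_matched, 3)
  expect_equal(mean(v2$matches$offset_s), 2)
  # one accel dive with no TDR dive within 5 s stays unmatched
  v3 <- validate_against_tdr(mk_events(c(starts, 350)), mk_depth(starts))
  expect_equal(v3$n_matched, 3)
  expect_equal(v3$n_accel_only, 1)
  expect_lt(v3$match_rate_pct, 100)
  # empty TDR trace: zero matches with a warning
  empty <- depth_trace(tibble::tibble(t = seq(0, 10, 0.25), depth_m = 0),
                       rate_hz = 4, trigger_threshold_m = 0.5)
  expect_warning(v4 <- validate_against_tdr(mk_events(starts), empty),
                 "empty TDR")
  expect_equal(v4$n_matched, 0)
})
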