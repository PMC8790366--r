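# independent grid-integration oracle for the two-source, one-group model:
# integrates the posterior over p1 and the two residual SDs on a grid and
# returns the posterior mean of p1
grid_posterior_mean_p1 <- function(consumers, sources, tdf) {
  p1 <- seq(0.0005, 0.9995, length.out = 200)
  xi <- seq(0.005, 4, length.out = 60)
  lam <- c(d13C = tdf$d13C_mean, d15N = tdf$d15N_mean)
  tau <- c(d13C = tdf$d13C_sd, d15N = tdf$d15N_sd)
  iso_marg <- function(iso) {
    mu_s <- sources[[paste0(iso, "_mean")]] + lam[iso]
    var_s <- sources[[paste0(iso, "_sd")]]^2 + tau[iso]^2
    x <- consumers[[iso]]
    ll <- outer(seq_along(p1), seq_along(xi), function(i, j) {
      mu <- p1[i] * mu_s[1] + (1 - p1[i]) * mu_s[2]
      v <- p1[i]^2 * var_s[1] + (1 - p1[i])^2 * var_s[2] + xi[j]^2
      -length(x) / 2 * log(2 * pi * v) - (sum(x^2) - 2 * mu * sum(x) +
                                            length(x) * mu^2) / (2 * v)
    })
    pr <- -xi^2 / 50  # half-normal(5) prior on xi
    mx <- max(ll)
    log(rowSums(exp(sweep(ll - mx, 2, -pr, "-") * 1))) + mx  # per p1
  }
  # joint factorises over isotopes given p1
  lp <- iso_marg("d13C") + iso_marg("d15N")
  w <- exp(lp - max(lp))
  sum(p1 * w) / sum(w)
}

test_that("lipid correction is configurable, monotone and exact", {
  # zeroed parameters: identity
  p0 <- list(b0 = 0, b1 = 0, cn_threshold = 3.5)
  expect_equal(lipid_correct(-18, 45, 10, p0), -18)
  # below the lipid-free threshold: identity under any parameters
  expect_equal(lipid_correct(-18, 10.5, 3.5), -18)
  # correction increases with C:N when b1 > 0
  p <- list(b0 = -2.06, b1 = 1.91, cn_threshold = 3.5)
  cn <- c(4, 6, 9)
  out <- lipid_correct(rep(-18, 3), cn * 10, rep(10, 3), p)
  expect_true(all(diff(out) > 0))
  # hand-computed arithmetic on one row
  expect_equal(lipid_correct(-18.4, 48, 10, p),
               -18.4 - 2.06 + 1.91 * log(4.8), tolerance = 1e-9)
  expect_error(lipid_correct(-18, 45, 0, p), "positive")
})

test_that("sources are filtered strictly above the 3% rule", {
  src <- tibble::tibble(species = c("a", "b", "c"),
                        d13C_mean = 0, d13C_sd = 0.1,
                        d15N_mean = 0, d15N_sd = 0.1,
                        diet_pct = c(2.9, 3.1, 50))
  kept <- filter_sources(src)
  expect_equal(kept$species, c("b", "c"))
  src_hi <- dplyr::mutate(src, diet_pct = c(10, 20, 30))
  expect_equal(filter_sources(src_hi), src_hi)
  src_lo <- dplyr::mutate(src, diet_pct = c(1, 2, 3))
  expect_error(filter_sources(src_lo), "fewer than 2")
})

test_that("Gelman-Rubin behaves at its reference points", {
  set.seed(1)
  x <- rnorm(1000)
  expect_equal(gelman_rubin(cbind(x, x, x)), 1, tolerance = 1e-2)
  disjoint <- cbind(rnorm(500, 0, 0.1), rnorm(500, 10, 0.1))
  expect_gt(gelman_rubin(disjoint), 5)
  white <- matrix(rnorm(3000), ncol = 3)
  expect_lt(gelman_rubin(white), 1.05)
  expect_warning(r1 <- gelman_rubin(matrix(rnorm(100), ncol = 1)),
                 "2 chains")
  expect_true(is.na(r1))
})

test_that("posterior proportions recover known mixtures", {
  src <- two_sources()
  sim <- simulate_isotopes(list(all = c(A = 0.7, B = 0.3)), sources = src,
                           n_per_group = 30, seed = 7)
  fit <- fit_mixing_model(sim$consumers, src, settings = quick_mcmc(7))
  td <- tidy(fit)
  pA <- td[td$source == "A", ]
  # draws live on the simplex
  sums <- tidyr::pivot_wider(fit$draws, names_from = "source",
                             values_from = "p")
  expect_true(all(abs(sums$A + sums$B - 1) < 1e-9))
  expect_true(all(fit$draws$p >= 0))
  # cross-check against the independent grid-integration oracle
  oracle <- grid_posterior_mean_p1(sim$consumers, src,
                                   discrimination_defaults())
  expect_lt(abs(pA$mean - oracle), 0.03)
  expect_lt(abs(pA$mean - 0.7), 3 * pA$sd + 0.05)
  expect_true(all(td$rhat < 1.05))

  # symmetric cloud midway between symmetric sources: p ~ (0.5, 0.5)
  sim_s <- simulate_isotopes(list(all = c(A = 0.5, B = 0.5)), sources = src,
                             n_per_group = 30, seed = 8)
  fit_s <- fit_mixing_model(sim_s$consumers, src, settings = quick_mcmc(8))
  td_s <- tidy(fit_s)
  expect_lt(abs(td_s$mean[td_s$source == "A"] - 0.5),
            2 * td_s$sd[td_s$source == "A"] + 0.05)

  # identical sources: unidentifiable, posterior reverts to the prior mean
  src_id <- src
  src_id$d13C_mean <- -17; src_id$d15N_mean <- 12
  sim_i <- simulate_isotopes(list(all = c(A = 0.5, B = 0.5)),
                             sources = src_id, n_per_group = 20, seed = 9)
  fit_i <- fit_mixing_model(sim_i$consumers, src_id,
                            settings = quick_mcmc(9))
  td_i <- tidy(fit_i)
  expect_lt(abs(td_i$mean[td_i$source == "A"] - 0.5), 0.12)

  expect_error(fit_mixing_model(sim$consumers, src[1, ]), "2 sources")
})

test_that("model comparison weights and guards behave", {
  src <- two_sources()
  sim <- simulate_isotopes(list(all = c(A = 0.6, B = 0.4)), sources = src,
                           n_per_group = 15, seed = 5)
  f1 <- fit_mixing_model(sim$consumers, src, settings = quick_mcmc(5),
                         label = "Null")
  # a single model takes all the weight
  expect_equal(compare_models(list(f1))$weight, 1)
  # refitting the same structure gives near-equal criteria, weights sum to 1
  f2 <- fit_mixing_model(sim$consumers, src, settings = quick_mcmc(6),
                         label = "Null2")
  cmp <- compare_models(list(f1, f2))
  expect_equal(sum(cmp$weight), 1)
  expect_lt(abs(cmp$weight[1] - 0.5), 0.25)
  # different consumer data is rejected
  sim_b <- simulate_isotopes(list(all = c(A = 0.6, B = 0.4)), sources = src,
                             n_per_group = 15, seed = 99)
  f3 <- fit_mixing_model(sim_b$consumers, src, settings = quick_mcmc(5))
  expect_error(compare_models(list(f1, f3)), "identical consumer data")
})

test_that("KIV is the proportion-weighted assimilable energy", {
  en <- tibble::tibble(species = c("A", "B"), gross_kj = c(1000, 2000))
  expect_equal(kiv(c(A = 1, B = 0), en), 761)
  expect_equal(kiv(c(A = 0.5, B = 0.5), en, assimilation_efficiency = 1),
               1500)
  # linear in proportions, invariant to source ordering
  expect_equal(kiv(c(B = 0.5, A = 0.5), en, 1),
               kiv(c(A = 0.5, B = 0.5), en, 1))
  p <- c(A = 0.3, B = 0.7)
  expect_equal(kiv(p, en), 0.761 * sum(p * c(1000, 2000)))
  # tibble input is accepted
  expect_equal(kiv(tibble::tibble(species = "A", p = 1), en), 761)
  expect_error(kiv(c(A = 0.5, C = 0.5), en), "no energy value")
  expect_error(kiv(c(A = 0.9, B = 0.2), en), "simplex")
})
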