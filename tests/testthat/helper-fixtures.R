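# short deployments and small mixing problems used across test files

quick_sim <- function(seconds = 1500, n_dives = 10, bird_index = 1,
                      seed = 1, ...) {
  cfg <- sim_config(deployment_days = seconds / 86400, n_dives = n_dives,
                    ...)
  simulate_deployment(cfg, bird_index = bird_index, seed = seed)
}

# two well-separated sources (>= 4 combined SDs apart on both isotopes)
two_sources <- function() {
  tibble::tibble(
    species = c("A", "B"),
    d13C_mean = c(-19, -15), d13C_sd = c(0.4, 0.4),
    d15N_mean = c(10, 14), d15N_sd = c(0.4, 0.4),
    diet_pct = c(50, 50)
  )
}

quick_mcmc <- function(seed = 1) {
  mcmc_settings(chains = 3, iter = 6000, burn_in = 2000, thin = 4,
                seed = seed)
}

# brute-force two-sided permutation p for the rank test, computed from raw
# values (pair counting), independently of the package's rank-based path
brute_rank_p <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  Ufun <- function(av, bv) {
    sum(outer(av, bv, ">")) + 0.5 * sum(outer(av, bv, "=="))
  }
  U_obs <- Ufun(a, b)
  E <- na * length(b) / 2
  combos <- utils::combn(length(pooled), na)
  Us <- apply(combos, 2, function(ix) Ufun(pooled[ix], pooled[-ix]))
  mean(abs(Us - E) >= abs(U_obs - E) - 1e-9)
}

# greedy one-to-one matching of detected dive starts to truth starts
match_events <- function(det, truth, tol = 2.5) {
  used <- logical(length(truth))
  match_idx <- rep(NA_integer_, length(det))
  for (i in order(det)) {
    d <- abs(truth - det[i])
    d[used] <- Inf
    j <- which.min(d)
    if (length(j) == 1 && d[j] <= tol) {
      match_idx[i] <- j
      used[j] <- TRUE
    }
  }
  match_idx
}

# constant-signal trace helper: static orientation (x, y, z) held for n
# samples at a given rate
constant_trace <- function(x, y, z, n = 500, rate = 50) {
  accel_trace(
    tibble::tibble(bird_id = "const", t = (seq_len(n) - 1) / rate,
                   ax = rep(x, n), ay = rep(y, n), az = rep(z, n)),
    rate_hz = rate
  )
}
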