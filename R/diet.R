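#' Lipid correction of d13C from the C:N ratio
#'
#' Normalises bulk d13C for tissue lipid content using elemental C and N:
#' above a lipid-free C:N threshold the corrected value is
#' `d13C + b0 + b1 * log(C:N)`; at or below the threshold the value is
#' returned unchanged. Coefficients are fully configurable; the defaults are
#' of the published linear-log family for fish muscle and should be replaced
#' with the variant appropriate to the tissue at hand.
#'
#' @param d13C Bulk d13C (permil).
#' @param pctC,pctN Elemental percentages; `pctN` must be positive.
#' @param params List with `b0`, `b1` and `cn_threshold`.
#' @return Corrected d13C (permil).
#' @export
lipid_correct <- function(d13C, pctC, pctN,
                          params = list(b0 = -2.06, b1 = 1.91,
                                        cn_threshold = 3.5)) {
  if (any(is.na(pctC) | is.na(pctN))) {
    warn("samples with missing %C or %N are excluded (NA returned)")
  }
  if (any(pctN <= 0, na.rm = TRUE)) abort("pctN must be positive")
  cn <- pctC / pctN
  ifelse(cn <= params$cn_threshold, d13C,
         d13C + params$b0 + params$b1 * log(cn))
}

#' Filter prey sources by historical diet fraction
#'
#' Retains only species previously recorded in more than `threshold_pct` of
#' the diet (strictly greater), preserving order. Fewer than two survivors
#' make the mixing model unidentifiable and raise an error.
#'
#' @param sources Sources tibble with a `diet_pct` column.
#' @param threshold_pct Percentage threshold (default 3).
#' @return The reduced sources tibble.
#' @export
filter_sources <- function(sources, threshold_pct = 3) {
  if (!("diet_pct" %in% names(sources))) {
    abort("sources table has no diet_pct column")
  }
  out <- sources[sources$diet_pct > threshold_pct, ]
  if (nrow(out) < 2) {
    abort("fewer than 2 sources survive the diet-fraction filter")
  }
  out
}

#' MCMC settings for the mixing model
#'
#' Desk-scale defaults (3 chains of 20,000 iterations, 5,000 burn-in,
#' thinning 10). Hours-scale settings equivalent to published "long" runs
#' can be supplied by overriding `iter`/`burn_in`/`thin`.
#'
#' @param chains Number of chains (>= 2 for convergence diagnostics).
#' @param iter Total iterations per chain (including burn-in).
#' @param burn_in Iterations discarded per chain.
#' @param thin Keep every `thin`-th post-burn-in draw.
#' @param seed Optional integer seed.
#' @return A named list.
#' @export
mcmc_settings <- function(chains = 3, iter = 20000, burn_in = 5000,
                          thin = 10, seed = NULL) {
  stopifnot(chains >= 1, iter > burn_in, thin >= 1)
  list(chains = chains, iter = iter, burn_in = burn_in, thin = thin,
       seed = seed)
}

# softmax with a fixed last logit of 0
.softmax0 <- function(z) {
  e <- exp(c(z, 0) - max(c(z, 0), 0))
  e / sum(e)
}

#' Fit the Bayesian stable-isotope mixing model
#'
#' Estimates diet proportions per group from consumer d13C/d15N values and
#' source distributions, propagating discrimination-factor uncertainty.
#' For each group g and isotope j the likelihood is
#' `x ~ Normal(sum_i p_gi (mu_ij + lambda_j),
#' sqrt(sum_i p_gi^2 (sigma_ij^2 + tau_j^2) + xi_j^2))` with a flat
#' Dirichlet(1) prior on each proportion vector and half-normal priors on
#' the residual SDs `xi_j` (shared across groups). Sampling is by adaptive
#' random-walk Metropolis on softmax-transformed proportions; convergence is
#' summarised by the Gelman-Rubin statistic per reported parameter, and the
#' fit is flagged non-converged when any R-hat exceeds 1.05.
#'
#' @param consumers Tibble with columns `d13C`, `d15N` and any grouping
#'   columns.
#' @param sources Sources tibble (`species`, `d13C_mean`, `d13C_sd`,
#'   `d15N_mean`, `d15N_sd`); at least two species.
#' @param tdf [discrimination_defaults()].
#' @param grouping Character vector of consumer columns defining fixed
#'   groups (e.g. `"sex"`, `c("sex", "year")`); `NULL` fits one population.
#' @param settings [mcmc_settings()].
#' @param residual `"residual"` (default) includes the additive residual
#'   error term; `"process_only"` fixes `xi = 0`.
#' @param label Model label used in comparison tables.
#' @return An object of class `diet_mix`: posterior draws of proportions per
#'   group, residual SD draws, R-hat per parameter, pointwise log-likelihood
#'   (for information criteria) and a convergence flag. Summarise with
#'   [tidy()], [glance()] or [autoplot.diet_mix()].
#' @export
fit_mixing_model <- function(consumers, sources,
                             tdf = discrimination_defaults(),
                             grouping = NULL,
                             settings = mcmc_settings(),
                             residual = c("residual", "process_only"),
                             label = NULL) {
  residual <- match.arg(residual)
  if (nrow(sources) < 2) abort("mixing model needs at least 2 sources")
  if (nrow(consumers) < 1) abort("no consumers")
  if (!all(c("d13C", "d15N") %in% names(consumers))) {
    abort("consumers need d13C and d15N columns")
  }
  label <- label %||%
    if (is.null(grouping)) "Null" else paste(grouping, collapse = " + ")
  grp <- if (is.null(grouping)) rep("all", nrow(consumers)) else
    interaction(consumers[grouping], drop = TRUE, sep = ".")
  grp <- as.character(grp)
  groups <- unique(grp)
  G <- length(groups)
  K <- nrow(sources)
  lam <- c(d13C = tdf$d13C_mean, d15N = tdf$d15N_mean)
  tau <- c(d13C = tdf$d13C_sd, d15N = tdf$d15N_sd)
  smu <- cbind(d13C = sources$d13C_mean, d15N = sources$d15N_mean)
  svar <- cbind(d13C = sources$d13C_sd^2 + tau["d13C"]^2,
                d15N = sources$d15N_sd^2 + tau["d15N"]^2)
  xs <- lapply(groups, function(g) {
    cbind(d13C = consumers$d13C[grp == g], d15N = consumers$d15N[grp == g])
  })
  use_xi <- residual == "residual"
  d_p <- G * (K - 1)
  d <- d_p + if (use_xi) 2L else 0L

  # per-group log density: likelihood of group g's consumers plus the
  # Dirichlet(1) prior expressed through the softmax Jacobian
  group_logdens <- function(z, g, xi2) {
    p <- .softmax0(z)
    if (any(p < 1e-300)) return(-Inf)
    lp <- sum(log(p))
    for (j in 1:2) {
      mu <- sum(p * (smu[, j] + lam[j]))
      v <- sum(p^2 * svar[, j]) + xi2[j]
      lp <- lp + sum(dnorm(xs[[g]][, j], mu, sqrt(v), log = TRUE))
    }
    lp
  }
  eta_logprior <- function(eta) {
    xi <- exp(eta)
    sum(-xi^2 / 50 + log(xi))  # half-normal(5) + log Jacobian
  }

  if (!is.null(settings$seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(settings$seed)
  }
  kept <- floor((settings$iter - settings$burn_in) / settings$thin)
  chains <- vector("list", settings$chains)
  for (ch in seq_len(settings$chains)) {
    # blockwise adaptive random-walk Metropolis: one block per group's
    # softmax coordinates plus one for the residual-SD pair
    z <- lapply(seq_len(G), function(g) rnorm(K - 1, 0, 0.5))
    eta <- if (use_xi) rnorm(2, log(0.5), 0.3) else NULL
    xi2 <- if (use_xi) exp(2 * eta) else c(0, 0)
    ld_g <- vapply(seq_len(G), function(g) group_logdens(z[[g]], g, xi2),
                   numeric(1))
    scales <- rep(0.6, G + use_xi)
    accs <- integer(G + use_xi)
    draws <- matrix(NA_real_, kept, d)
    kidx <- 0L
    for (it in seq_len(settings$iter)) {
      for (g in seq_len(G)) {
        zp <- z[[g]] + rnorm(K - 1, 0, scales[g])
        ldp <- group_logdens(zp, g, xi2)
        if (is.finite(ldp) && log(runif(1)) < ldp - ld_g[g]) {
          z[[g]] <- zp; ld_g[g] <- ldp; accs[g] <- accs[g] + 1L
        }
      }
      if (use_xi) {
        ep <- eta + rnorm(2, 0, scales[G + 1])
        xi2p <- exp(2 * ep)
        ldp_g <- vapply(seq_len(G),
                        function(g) group_logdens(z[[g]], g, xi2p),
                        numeric(1))
        if (log(runif(1)) < sum(ldp_g) + eta_logprior(ep) -
            sum(ld_g) - eta_logprior(eta)) {
          eta <- ep; xi2 <- xi2p; ld_g <- ldp_g
          accs[G + 1] <- accs[G + 1] + 1L
        }
      }
      if (it <= settings$burn_in && it %% 100 == 0) {
        scales <- scales * exp(0.5 * (accs / 100 - 0.3))
        accs[] <- 0L
      }
      if (it > settings$burn_in &&
          (it - settings$burn_in) %% settings$thin == 0) {
        kidx <- kidx + 1L
        if (kidx <= kept) draws[kidx, ] <- c(unlist(z), eta)
      }
    }
    chains[[ch]] <- draws
  }

  # transform kept draws to proportions / residual SDs
  p_names <- as.vector(outer(sources$species, groups,
                             function(s, g) paste(g, s, sep = ":")))
  to_p <- function(mat) {
    out <- matrix(NA_real_, nrow(mat), G * K)
    for (g in seq_len(G)) {
      z <- mat[, ((g - 1) * (K - 1) + 1):(g * (K - 1)), drop = FALSE]
      out[, ((g - 1) * K + 1):(g * K)] <-
        t(apply(z, 1, .softmax0))
    }
    colnames(out) <- p_names
    out
  }
  p_chains <- lapply(chains, to_p)
  xi_chains <- if (use_xi) {
    lapply(chains, function(m) {
      out <- exp(m[, d_p + 1:2, drop = FALSE])
      colnames(out) <- c("xi_d13C", "xi_d15N")
      out
    })
  } else NULL

  par_chains <- if (use_xi) {
    purrr::map2(p_chains, xi_chains, cbind)
  } else p_chains
  rhat <- vapply(seq_len(ncol(par_chains[[1]])), function(jc) {
    gelman_rubin(sapply(par_chains, function(m) m[, jc]))
  }, numeric(1))
  names(rhat) <- colnames(par_chains[[1]])

  p_draws <- do.call(rbind, p_chains)
  xi_draws <- if (use_xi) do.call(rbind, xi_chains) else
    matrix(0, nrow(p_draws), 2, dimnames = list(NULL, c("xi_d13C", "xi_d15N")))

  # pointwise log-likelihood per consumer (summed over isotopes) per draw
  n_draw <- nrow(p_draws)
  ll <- matrix(NA_real_, n_draw, nrow(consumers))
  for (g in seq_len(G)) {
    pg <- p_draws[, ((g - 1) * K + 1):(g * K), drop = FALSE]
    ci <- which(grp == groups[g])
    for (j in 1:2) {
      mu <- pg %*% (smu[, j] + lam[j])
      v <- pg^2 %*% svar[, j] + xi_draws[, j]^2
      lj <- -0.5 * log(2 * pi * as.vector(v)) -
        outer(as.vector(mu), xs[[g]][, j], "-")^2 / (2 * as.vector(v))
      ll[, ci] <- if (j == 1) lj else ll[, ci] + lj
    }
  }

  draws_tbl <- tibble::as_tibble(p_draws) |>
    dplyr::mutate(.chain = rep(seq_len(settings$chains), each = kept),
                  .draw = rep(seq_len(kept), settings$chains)) |>
    tidyr::pivot_longer(-c(".chain", ".draw"),
                        names_to = c("group", "source"), names_sep = ":",
                        values_to = "p")

  converged <- all(rhat <= 1.05, na.rm = TRUE)
  if (!converged) {
    warn(paste0("mixing model '", label, "' has R-hat > 1.05; ",
                "treat the posterior with caution"))
  }
  structure(
    list(label = label, draws = draws_tbl, p_draws = p_draws,
         xi_draws = xi_draws, rhat = rhat, converged = converged,
         loglik_pointwise = ll, groups = groups, sources = sources$species,
         grouping = grouping, n_consumers = nrow(consumers),
         settings = settings,
         data_fingerprint = c(n = nrow(consumers),
                              s13 = sum(consumers$d13C),
                              s15 = sum(consumers$d15N))),
    class = "diet_mix"
  )
}

#' @export
print.diet_mix <- function(x, ...) {
  cat("Bayesian isotope mixing model '", x$label, "': ",
      length(x$sources), " sources x ", length(x$groups), " group(s), ",
      nrow(x$p_draws), " posterior draws; max R-hat ",
      sprintf("%.3f", max(x$rhat, na.rm = TRUE)),
      if (x$converged) " (converged)\n" else " (NOT converged)\n", sep = "")
  print(tidy(x))
  invisible(x)
}

#' Gelman-Rubin potential scale reduction
#'
#' Standard between/within-chain variance ratio,
#' `sqrt(((n-1)/n * W + B/n) / W)`. Values near 1 indicate convergence;
#' fits are flagged above 1.05.
#'
#' @param chains Matrix (iterations x chains) or list of equal-length
#'   numeric vectors, one per chain.
#' @return R-hat (NA with a warning for a single chain).
#' @export
gelman_rubin <- function(chains) {
  if (is.list(chains)) chains <- do.call(cbind, chains)
  chains <- as.matrix(chains)
  m <- ncol(chains); n <- nrow(chains)
  if (m < 2) {
    warn("Gelman-Rubin diagnostic needs >= 2 chains")
    return(NA_real_)
  }
  mu <- colMeans(chains)
  W <- mean(apply(chains, 2, var))
  B <- n * var(mu)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# stable log of column means of exp(ll)
.log_col_mean_exp <- function(ll) {
  mx <- apply(ll, 2, max)
  mx + log(colMeans(exp(sweep(ll, 2, mx))))
}

#' WAIC from a fitted mixing model
#'
#' Widely applicable information criterion computed from the pointwise
#' log-likelihood, used here as the leave-one-out surrogate for ranking
#' covariate structures.
#'
#' @param fit A `diet_mix` object.
#' @return List with `waic`, `se`, `p_waic`, `lppd` and the per-consumer
#'   contributions.
#' @export
waic <- function(fit) {
  ll <- fit$loglik_pointwise
  lppd_i <- .log_col_mean_exp(ll)
  p_i <- apply(ll, 2, var)
  contrib <- -2 * (lppd_i - p_i)
  list(waic = sum(contrib), se = sqrt(length(contrib) * var(contrib)),
       p_waic = sum(p_i), lppd = sum(lppd_i), pointwise = contrib)
}

#' Compare mixing-model covariate structures
#'
#' Ranks fitted models by WAIC (a leave-one-out surrogate computed from the
#' pointwise log-likelihood) and converts differences to Akaike-type
#' weights, `w ~ exp(-delta/2)` normalised over the candidate set. All
#' models must be fitted to identical consumer data.
#'
#' @param fits List of `diet_mix` objects (named or labelled).
#' @return Tibble sorted by criterion: `model`, `waic`, `se_waic`, `delta`,
#'   `se_delta`, `weight`.
#' @export
compare_models <- function(fits) {
  if (inherits(fits, "diet_mix")) fits <- list(fits)
  fps <- lapply(fits, function(f) f$data_fingerprint)
  if (length(unique(lapply(fps, round, 6))) != 1) {
    abort("models were not fitted to identical consumer data")
  }
  ws <- lapply(fits, waic)
  tab <- tibble::tibble(
    model = vapply(fits, function(f) f$label, character(1)),
    waic = vapply(ws, function(w) w$waic, numeric(1)),
    se_waic = vapply(ws, function(w) w$se, numeric(1))
  )
  best <- which.min(tab$waic)
  tab$delta <- tab$waic - tab$waic[best]
  tab$se_delta <- vapply(seq_along(ws), function(i) {
    if (i == best) return(NA_real_)
    dd <- ws[[i]]$pointwise - ws[[best]]$pointwise
    sqrt(length(dd) * var(dd))
  }, numeric(1))
  w <- exp(-tab$delta / 2)
  tab$weight <- w / sum(w)
  dplyr::arrange(tab, .data$waic)
}

#' Kilojoule intake value of a successful dive
#'
#' The diet-proportion-weighted mean assimilable energy of one prey item:
#' each species' gross energy content is discounted by the assimilation
#' efficiency and weighted by its posterior diet proportion, assuming a
#' successful dive captures exactly one prey item.
#'
#' @param proportions Named numeric vector of diet proportions (summing to
#'   1), or a tibble with columns `species` and `p`.
#' @param energy Energy tibble with columns `species` and `gross_kj`.
#' @param assimilation_efficiency Fraction of gross energy assimilated
#'   (default 0.761).
#' @return KIV in kJ per successful dive.
#' @export
kiv <- function(proportions, energy, assimilation_efficiency = 0.761) {
  stopifnot(assimilation_efficiency > 0, assimilation_efficiency <= 1)
  if (is.data.frame(proportions)) {
    p <- setNames(proportions$p, proportions$species)
  } else {
    p <- proportions
  }
  if (any(p < -1e-9) || abs(sum(p) - 1) > 1e-6) {
    abort("proportions must lie on the simplex")
  }
  idx <- match(names(p), energy$species)
  if (any(is.na(idx))) {
    abort(paste0("no energy value for species: ",
                 paste(names(p)[is.na(idx)], collapse = ", ")))
  }
  sum(p * energy$gross_kj[idx] * assimilation_efficiency)
}
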