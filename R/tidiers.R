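#' Tidy a fitted mixing model
#'
#' Posterior summary per group and source: mean, SD, central quantiles and
#' the Gelman-Rubin statistic.
#'
#' @param x A `diet_mix` object.
#' @param ... Unused.
#' @return A tibble with one row per group x source.
#' @method tidy diet_mix
#' @export
tidy.diet_mix <- function(x, ...) {
  out <- x$draws |>
    dplyr::group_by(.data$group, .data$source) |>
    dplyr::summarise(mean = mean(.data$p), sd = sd(.data$p),
                     q2.5 = quantile(.data$p, 0.025),
                     q50 = quantile(.data$p, 0.5),
                     q97.5 = quantile(.data$p, 0.975),
                     .groups = "drop")
  out$rhat <- unname(x$rhat[paste(out$group, out$source, sep = ":")])
  out
}

#' One-line summary of a fitted mixing model
#'
#' @param x A `diet_mix` object.
#' @param ... Unused.
#' @return A one-row tibble: WAIC, its SE, effective parameter count, the
#'   maximum R-hat, convergence flag, draw and consumer counts.
#' @method glance diet_mix
#' @export
glance.diet_mix <- function(x, ...) {
  w <- waic(x)
  tibble::tibble(model = x$label, waic = w$waic, se_waic = w$se,
                 p_waic = w$p_waic, max_rhat = max(x$rhat, na.rm = TRUE),
                 converged = x$converged, n_draws = nrow(x$p_draws),
                 n_consumers = x$n_consumers)
}

#' Tidy an averaged dive-cost model
#'
#' @param x An `averaged_model` object.
#' @param ... Unused.
#' @return Tibble of conditionally averaged coefficients with plain and
#'   adjusted standard errors, z and p values.
#' @method tidy averaged_model
#' @export
tidy.averaged_model <- function(x, ...) {
  dplyr::rename(x$coefs, std.error = "se", adj.std.error = "adj_se",
                statistic = "z")
}

#' One-line summary of an averaged model
#'
#' @param x An `averaged_model` object.
#' @param ... Unused.
#' @return One-row tibble: candidate and retained counts, AIC window, best
#'   AIC.
#' @method glance averaged_model
#' @export
glance.averaged_model <- function(x, ...) {
  tibble::tibble(n_candidates = x$n_candidates,
                 n_retained = nrow(x$retained), window = x$window,
                 best_aic = min(x$retained$aic))
}

#' Tidy a single dive-cost candidate fit
#'
#' @param x A `cost_fit` object.
#' @param ... Unused.
#' @return Tibble of fixed-effect estimates and standard errors.
#' @method tidy cost_fit
#' @export
tidy.cost_fit <- function(x, ...) {
  dplyr::rename(x$coefs, std.error = "se")
}

#' One-line summary of a dive-cost candidate fit
#'
#' @param x A `cost_fit` object.
#' @param ... Unused.
#' @return One-row tibble with AIC, log-likelihood and the singularity flag.
#' @method glance cost_fit
#' @export
glance.cost_fit <- function(x, ...) {
  tibble::tibble(aic = x$aic, logLik = as.numeric(logLik(x$fit)),
                 singular = x$singular, label = x$label)
}

#' Tidy a rank test
#'
#' @param x A `rank_test` object.
#' @param ... Unused.
#' @return One-row tibble: U, p, rank-biserial r, method.
#' @method tidy rank_test
#' @export
tidy.rank_test <- function(x, ...) {
  tibble::tibble(statistic = unname(x$statistic), p.value = x$p.value,
                 effect_r = x$effect_r, method = x$method)
}
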