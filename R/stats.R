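#' Mann-Whitney-Wilcoxon rank test
#'
#' Two-sided rank-sum test with an exact permutation p-value when the
#' smaller sample has at most `exact_max` observations (full enumeration of
#' group assignments, valid under ties), and a tie-corrected normal
#' approximation otherwise. The effect size is the rank-biserial
#' correlation `r = 2U/(n_a n_b) - 1`.
#'
#' @param a,b Numeric samples (n >= 1 each).
#' @param exact_max Largest min(n_a, n_b) for which the exact enumeration is
#'   used (default 8).
#' @return List of class `rank_test`: `statistic` (U of sample `a`),
#'   `p.value`, `effect_r`, `method`.
#' @export
rank_test <- function(a, b, exact_max = 8) {
  if (length(a) < 1 || length(b) < 1) abort("both samples must be non-empty")
  na <- length(a); nb <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  U_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  EU <- na * nb / 2
  if (min(na, nb) <= exact_max) {
    # enumerate every assignment of na pooled ranks to group a
    combos <- combn(na + nb, na)
    Us <- colSums(matrix(r[combos], nrow = na)) - na * (na + 1) / 2
    p <- mean(abs(Us - EU) >= abs(U_obs - EU) - 1e-9)
    method <- "exact"
  } else {
    ties <- table(r)
    sigma2 <- na * nb / 12 *
      (na + nb + 1 - sum(ties^3 - ties) / ((na + nb) * (na + nb - 1)))
    z <- (U_obs - EU) / sqrt(sigma2)
    p <- 2 * pnorm(-abs(z))
    method <- "normal approximation"
  }
  structure(list(statistic = c(U = U_obs), p.value = min(p, 1),
                 effect_r = 2 * U_obs / (na * nb) - 1, method = method,
                 n = c(na = na, nb = nb)),
            class = c("rank_test", "list"))
}

#' @export
print.rank_test <- function(x, ...) {
  cat("Mann-Whitney-Wilcoxon (", x$method, "): U = ", x$statistic,
      ", p = ", signif(x$p.value, 3), ", rank-biserial r = ",
      signif(x$effect_r, 3), "\n", sep = "")
  invisible(x)
}

#' Welch two-sample t-test
#'
#' @param a,b Numeric samples (n >= 2 each).
#' @return List with `statistic` (t), `df` (Welch-Satterthwaite), `p.value`.
#' @export
two_sample_t <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) {
    abort("both samples need at least 2 observations")
  }
  ht <- t.test(a, b, var.equal = FALSE)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p.value = ht$p.value)
}

#' Fit one candidate dive-cost mixed model
#'
#' Linear mixed model for the energetic cost of a prey-capture attempt with
#' a random intercept per bird (repeated measures), fitted by maximum
#' likelihood so AICs are comparable across fixed-effect structures.
#'
#' @param data Data frame with the response, covariates and a `bird_id`
#'   column.
#' @param terms Character vector of fixed-effect terms (e.g.
#'   `c("dive_type", "year", "sex:dive_type")`); empty for intercept-only.
#' @param response Response column name (default `"cost_kj"`).
#' @param random Random-intercept grouping column (default `"bird_id"`).
#' @return Object of class `cost_fit`: the `lmerMod` fit, `aic`, `coefs`
#'   tibble (`term`, `estimate`, `se`), `terms` and a `singular` flag.
#' @export
fit_dive_cost_model <- function(data, terms = character(),
                                response = "cost_kj", random = "bird_id") {
  if (length(unique(data[[random]])) < 2) {
    abort("need at least 2 birds for a random intercept")
  }
  rhs <- if (length(terms) == 0) "1" else paste(terms, collapse = " + ")
  fml <- as.formula(paste0(response, " ~ ", rhs, " + (1 | ", random, ")"))
  fit <- suppressMessages(lme4::lmer(fml, data = data, REML = FALSE))
  singular <- lme4::isSingular(fit, tol = 1e-5)
  if (singular) {
    warn("singular random-effect fit; model retained")
  }
  fe <- lme4::fixef(fit)
  # fully degenerate fits (zero variance) can break vcov; keep estimates
  se <- tryCatch(coef(summary(fit))[, "Std. Error"],
                 error = function(e) rep(NA_real_, length(fe)))
  structure(
    list(fit = fit, aic = AIC(fit),
         coefs = tibble::tibble(term = names(fe), estimate = unname(fe),
                                se = unname(se)),
         terms = terms, label = rhs, singular = singular),
    class = c("cost_fit", "list")
  )
}

# all fixed-effect subsets of the full model respecting marginality:
# an interaction enters only when both its main effects are present
.candidate_term_sets <- function(full_terms) {
  mains <- full_terms[!grepl(":", full_terms)]
  inters <- full_terms[grepl(":", full_terms)]
  sets <- list(character())
  for (k in seq_along(mains)) {
    sets <- c(sets, combn(mains, k, simplify = FALSE))
  }
  out <- sets
  for (int in inters) {
    parts <- strsplit(int, ":")[[1]]
    for (s in sets) {
      if (all(parts %in% s)) out <- c(out, list(c(s, int)))
    }
  }
  out
}

#' Enumerate and fit all dive-cost candidate models
#'
#' All-subsets enumeration of the full fixed-effect specification
#' (marginality respected), each fitted by [fit_dive_cost_model()].
#'
#' @inheritParams fit_dive_cost_model
#' @param full_terms Full fixed-effect set; default
#'   `c("dive_type", "sex", "year", "mass_kg", "sex:dive_type")`.
#' @return List of `cost_fit` objects.
#' @export
dredge_cost_models <- function(data,
                               full_terms = c("dive_type", "sex", "year",
                                              "mass_kg", "sex:dive_type"),
                               response = "cost_kj", random = "bird_id") {
  purrr::map(.candidate_term_sets(full_terms),
             ~ fit_dive_cost_model(data, .x, response, random))
}

#' AIC-window model averaging
#'
#' Retains every candidate within `window` AIC units of the best model,
#' weights them by `exp(-delta/2)` (normalised over the retained set) and
#' averages coefficients conditionally (the "natural" average over the
#' models that contain each term). Reported uncertainty follows the
#' model-averaging literature: `se` is the square root of the weighted
#' average of `se_m^2 + (b_m - b_bar)^2`, and `adjusted se` the weighted
#' average of the square roots; z and p derive from the adjusted SE.
#'
#' @param fits List of candidate fits: `cost_fit` objects, or any list with
#'   elements `aic` and `coefs` (tibble of `term`, `estimate`, `se`).
#' @param window AIC window (default 6).
#' @return Object of class `averaged_model` with the coefficient table and
#'   the retained-model table.
#' @export
aic_model_average <- function(fits, window = 6) {
  if (inherits(fits, "cost_fit")) fits <- list(fits)
  aics <- vapply(fits, function(f) f$aic, numeric(1))
  delta <- aics - min(aics)
  keep <- which(delta <= window)
  w <- exp(-delta[keep] / 2)
  w <- w / sum(w)
  retained <- tibble::tibble(
    model = vapply(fits[keep], function(f)
      f$label %||% paste(f$coefs$term, collapse = "+"), character(1)),
    aic = aics[keep], delta = delta[keep], weight = w
  )
  all_terms <- unique(unlist(lapply(fits[keep], function(f) f$coefs$term)))
  coefs <- purrr::map_dfr(all_terms, function(tm) {
    has <- vapply(fits[keep], function(f) tm %in% f$coefs$term, logical(1))
    wi <- w[has] / sum(w[has])
    est <- vapply(fits[keep][has], function(f)
      f$coefs$estimate[f$coefs$term == tm], numeric(1))
    se <- vapply(fits[keep][has], function(f)
      f$coefs$se[f$coefs$term == tm], numeric(1))
    b <- sum(wi * est)
    se_u <- sqrt(sum(wi * (se^2 + (est - b)^2)))
    se_a <- sum(wi * sqrt(se^2 + (est - b)^2))
    z <- b / se_a
    tibble::tibble(term = tm, estimate = b, se = se_u, adj_se = se_a,
                   z = z, p.value = 2 * pnorm(-abs(z)),
                   weight_sum = sum(w[has]))
  })
  structure(list(coefs = coefs, retained = retained, window = window,
                 n_candidates = length(fits)),
            class = c("averaged_model", "list"))
}

#' @export
print.averaged_model <- function(x, ...) {
  cat("Model-averaged coefficients (", nrow(x$retained), " of ",
      x$n_candidates, " candidates within ", x$window, " AIC)\n", sep = "")
  print(x$coefs)
  invisible(x)
}

#' Sex effect on daily dive rate
#'
#' One-way linear model F-test of sex on per-bird dive rate (dives per
#' day).
#'
#' @param data Data frame with one row per bird.
#' @param rate Column with the dive rate (default `"dives_per_day"`).
#' @param sex Sex column (default `"sex"`); unknown-sex birds are dropped.
#' @return List: `F`, `df` (c(num, den)), `p.value`, per-sex means, and the
#'   underlying `lm` fit.
#' @export
dive_rate_model <- function(data, rate = "dives_per_day", sex = "sex") {
  d <- data[data[[sex]] %in% c("female", "male"), ]
  counts <- table(d[[sex]])
  if (length(counts) < 2 || any(counts < 2)) {
    abort("each sex needs at least 2 birds")
  }
  fit <- lm(reformulate(sex, rate), data = d)
  an <- anova(fit)
  list(F = an$`F value`[1], df = c(an$Df[1], an$Df[2]),
       p.value = an$`Pr(>F)`[1],
       means = tapply(d[[rate]], d[[sex]], mean), fit = fit)
}
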