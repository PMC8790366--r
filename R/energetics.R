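#' Allometric metabolic-rate coefficients
#'
#' Coefficients for the basal (BMR) and field (FMR) metabolic-rate
#' allometries used to anchor the VeDBA-to-kilojoule calibration:
#' `BMR (kJ/day) = a * mass_kg^b` and
#' `log10 FMR (kJ/day) = b0 + b1 * log10(mass_g) + b2 * |latitude|`.
#' The defaults follow the functional forms of published seabird allometries
#' (an all-seabird BMR power law and a mass-and-latitude FMR regression) and
#' give realistic magnitudes for a 2.7-3.0 kg gannet at 52 degrees N
#' (BMR ~ 780 kJ/day, FMR ~ 3200-3500 kJ/day). They are configuration, not
#' ground truth: substitute coefficients transcribed from your preferred
#' source for other species or colonies.
#'
#' @param bmr List with elements `a`, `b` (and a free-text `note`).
#' @param fmr List with elements `b0`, `b1`, `b2` (and `note`).
#' @return A list with elements `bmr` and `fmr`. Construction fails unless
#'   predicted FMR exceeds BMR across 2-3.5 kg at latitude 52.
#' @export
allometric_defaults <- function(
    bmr = list(a = 381.8, b = 0.721,
               note = "all-seabird BMR power law, mass in kg"),
    fmr = list(b0 = 1.02, b1 = 0.65, b2 = 0.0049,
               note = "seabird FMR regression on log10 mass (g) and |latitude|")) {
  params <- list(bmr = bmr, fmr = fmr)
  m <- seq(2, 3.5, by = 0.25)
  if (!all(fmr_allometric(m, 52, params) > bmr_allometric(m, params))) {
    abort("allometric coefficients imply FMR <= BMR for study-range masses")
  }
  params
}

#' Basal metabolic rate from mass
#'
#' @param mass_kg Body mass in kilograms (> 0).
#' @param params Coefficients from [allometric_defaults()].
#' @return BMR in kJ/day.
#' @export
bmr_allometric <- function(mass_kg, params = allometric_defaults()) {
  if (any(mass_kg <= 0)) abort("mass must be positive")
  params$bmr$a * mass_kg^params$bmr$b
}

#' Field metabolic rate from mass and colony latitude
#'
#' @param mass_kg Body mass in kilograms (> 0).
#' @param latitude_deg Colony latitude in degrees (absolute value is used;
#'   default 52, the study colony).
#' @param params Coefficients from [allometric_defaults()].
#' @return FMR in kJ/day.
#' @export
fmr_allometric <- function(mass_kg, latitude_deg = 52,
                           params = allometric_defaults()) {
  if (any(mass_kg <= 0)) abort("mass must be positive")
  f <- params$fmr
  10^(f$b0 + f$b1 * log10(1000 * mass_kg) + f$b2 * abs(latitude_deg))
}

#' Chick-provisioning demand split
#'
#' Daily energetic demand of a four-week-old chick and its division between
#' the parents: females carry 60% of provisioning, males 40%.
#'
#' @param chick_demand_kj_day Chick demand in kJ/day (default 1397.14).
#' @param female_share,male_share Fractions summing to 1.
#' @return A named list.
#' @export
demand_defaults <- function(chick_demand_kj_day = 1397.14,
                            female_share = 0.60, male_share = 0.40) {
  stopifnot(chick_demand_kj_day > 0,
            abs(female_share + male_share - 1) < 1e-12)
  list(chick_demand_kj_day = chick_demand_kj_day,
       female_share = female_share, male_share = male_share)
}

#' Per-second VeDBA from a trace
#'
#' Vectorial dynamic body acceleration: the dynamic component of each axis is
#' the raw signal minus its running mean over `static_window_s`; per-sample
#' VeDBA is the Euclidean norm of the three dynamic components; the
#' per-second value is the per-sample sum divided by the sampling rate
#' (units: g-seconds per second). Seconds covered by fewer than half the
#' nominal samples are returned as `NA` and excluded from daily sums.
#'
#' @param trace An [accel_trace()].
#' @param static_window_s Running-mean window (s) used as the gravity
#'   estimate (default 2).
#' @return A tibble with columns `bird_id`, `t` (start of each 1 s bin),
#'   `vedba` (g-seconds, `NA` when coverage < 50%), `n_samples`.
#' @export
compute_vedba <- function(trace, static_window_s = 2) {
  rate <- trace_rate(trace)
  stats <- running_stats(trace, static_window_s)
  dx <- trace$ax - stats$mean_x
  dy <- trace$ay - stats$mean_y
  dz <- trace$az - stats$mean_z
  v <- sqrt(dx^2 + dy^2 + dz^2)
  # unusable (short-segment) samples carry no VeDBA
  v[!stats$usable] <- NA_real_
  sec <- floor(trace$t - trace$t[1])
  ok <- !is.na(v)
  per <- tibble::tibble(sec = sec, v = v, ok = ok) |>
    dplyr::group_by(.data$sec) |>
    dplyr::summarise(vedba = sum(.data$v[.data$ok]) / rate,
                     n_samples = sum(.data$ok), .groups = "drop")
  low <- per$n_samples < rate / 2
  if (any(low)) {
    warn(paste0(sum(low), " second(s) with < 50% sample coverage set to NA"))
    per$vedba[low] <- NA_real_
  }
  tibble::tibble(bird_id = trace$bird_id[1], t = trace$t[1] + per$sec,
                 vedba = per$vedba, n_samples = per$n_samples)
}

#' Daily VeDBA sums over complete periods
#'
#' Sums a 1 Hz VeDBA series over complete periods (default 24 h) aligned to
#' the start of the series. Incomplete trailing periods, and periods
#' containing missing seconds, are dropped.
#'
#' @param vedba Tibble from [compute_vedba()] (columns `t`, `vedba`).
#' @param period_s Period length in seconds (default 86400).
#' @param require_complete Drop periods with any missing second (default
#'   TRUE).
#' @return Tibble with columns `period` and `vedba_sum` (g-seconds).
#' @export
vedba_period_sums <- function(vedba, period_s = 86400,
                              require_complete = TRUE) {
  stopifnot(period_s > 0)
  rel <- vedba$t - vedba$t[1]
  per <- floor(rel / period_s)
  n_full <- floor((max(rel) + 1) / period_s)
  out <- tibble::tibble(period = per, vedba = vedba$vedba) |>
    dplyr::filter(.data$period < n_full) |>
    dplyr::group_by(.data$period) |>
    dplyr::summarise(vedba_sum = sum(.data$vedba),
                     n = dplyr::n(), .groups = "drop")
  if (require_complete) {
    keep <- !is.na(out$vedba_sum) & out$n >= period_s
    out <- out[keep, ]
  }
  out[, c("period", "vedba_sum")]
}

#' Calibrate the individual VeDBA-to-kilojoule gradient
#'
#' The activity energy budget AEE = FMR - BMR for a 24 h period is assumed
#' to be spent on movement alone, and zero VeDBA must cost zero kJ, so the
#' line through the origin and (mean VeDBA24, AEE) converts accumulated
#' VeDBA to kilojoules with gradient `k = AEE / mean(VeDBA24)`.
#'
#' @param bird_id Identifier.
#' @param mass_kg Body mass (kg).
#' @param daily_vedba Numeric vector of complete-period VeDBA sums
#'   (g-seconds), e.g. `vedba_period_sums(...)$vedba_sum`.
#' @param latitude_deg Colony latitude (default 52).
#' @param params [allometric_defaults()].
#' @return One-row tibble (a bird energy profile): `bird_id`, `mass_kg`,
#'   `bmr_kj_day`, `fmr_kj_day`, `aee_kj_day`, `vedba24_mean`,
#'   `n_complete_days`, `k` (kJ per g-second), `excluded`.
#' @export
calibrate_k <- function(bird_id, mass_kg, daily_vedba, latitude_deg = 52,
                        params = allometric_defaults()) {
  bmr <- bmr_allometric(mass_kg, params)
  fmr <- fmr_allometric(mass_kg, latitude_deg, params)
  daily_vedba <- daily_vedba[!is.na(daily_vedba)]
  excluded <- length(daily_vedba) == 0
  if (excluded) {
    warn(paste0(bird_id, ": no complete 24 h period; ",
                "excluded from energy analyses"))
  }
  v24 <- if (excluded) NA_real_ else mean(daily_vedba)
  tibble::tibble(
    bird_id = bird_id, mass_kg = mass_kg,
    bmr_kj_day = bmr, fmr_kj_day = fmr, aee_kj_day = fmr - bmr,
    vedba24_mean = v24, n_complete_days = length(daily_vedba),
    k = if (excluded) NA_real_ else (fmr - bmr) / v24,
    excluded = excluded
  )
}

# sum a 1 Hz VeDBA series over the half-open span [from, to): a second's
# bin [t, t+1) counts when it overlaps. Half-open so sums are additive over
# a partition of an interval. Returns sum and a partial-coverage flag.
.sum_vedba_span <- function(vedba, from, to) {
  inside <- vedba$t + 1 > from & vedba$t < to
  vals <- vedba$vedba[inside]
  list(sum = sum(vals, na.rm = TRUE),
       partial = length(vals) == 0 || any(is.na(vals)))
}

#' Energetic cost of each prey-capture attempt
#'
#' VeDBA is summed from the initiation of a dive to the completion of its
#' linked take-off and multiplied by the bird's gradient `k`. Dives with no
#' detected take-off are costed over the dive alone and flagged; coverage
#' gaps inside the span flag the cost as partial.
#'
#' @param events Event tibble from [classify_behaviour()].
#' @param vedba 1 Hz VeDBA series from [compute_vedba()].
#' @param profile One-row profile from [calibrate_k()].
#' @return Tibble with one row per dive: `bird_id`, `event_id`, `dive_type`,
#'   `start_s`, `end_s` (take-off completion), `summed_vedba`, `cost_kj`,
#'   `no_takeoff`, `partial`.
#' @export
event_cost <- function(events, vedba, profile) {
  dives <- events[events$kind == "dive", ]
  takeoffs <- events[events$kind == "takeoff", ]
  if (nrow(dives) == 0) {
    return(tibble::tibble(bird_id = character(), event_id = character(),
                          dive_type = character(), start_s = numeric(),
                          end_s = numeric(), summed_vedba = numeric(),
                          cost_kj = numeric(), no_takeoff = logical(),
                          partial = logical()))
  }
  to_end <- takeoffs$end_s[match(dives$linked_id, takeoffs$event_id)]
  span_end <- ifelse(is.na(to_end), dives$end_s, to_end)
  res <- purrr::map2(dives$start_s, span_end,
                     ~ .sum_vedba_span(vedba, .x, .y))
  sums <- purrr::map_dbl(res, "sum")
  tibble::tibble(
    bird_id = dives$bird_id, event_id = dives$event_id,
    dive_type = dives$dive_type, start_s = dives$start_s, end_s = span_end,
    summed_vedba = sums, cost_kj = profile$k * sums,
    no_takeoff = is.na(to_end), partial = purrr::map_lgl(res, "partial")
  )
}

#' Total energetic expenditure over a tracking interval
#'
#' Movement energy is `k` times the VeDBA accumulated over the interval;
#' basal maintenance is added as BMR prorated over the (possibly fractional)
#' interval length, giving the total expenditure from colony departure to
#' recapture.
#'
#' @param vedba 1 Hz VeDBA series from [compute_vedba()].
#' @param profile One-row profile from [calibrate_k()].
#' @param interval Numeric length-2 vector `c(from, to)` in trace seconds;
#'   defaults to full coverage.
#' @return One-row tibble: `bird_id`, `interval_days`, `movement_kj`,
#'   `bmr_kj`, `expenditure_kj`.
#' @export
trip_expenditure <- function(vedba, profile, interval = NULL) {
  cov <- range(vedba$t)
  interval <- interval %||% c(cov[1], cov[2] + 1)
  if (interval[1] < cov[1] - 1 || interval[2] > cov[2] + 1 + 1e-9) {
    abort("interval extends outside VeDBA coverage")
  }
  days <- (interval[2] - interval[1]) / 86400
  movement <- profile$k * .sum_vedba_span(vedba, interval[1], interval[2])$sum
  bmr <- profile$bmr_kj_day * days
  tibble::tibble(bird_id = profile$bird_id, interval_days = days,
                 movement_kj = movement, bmr_kj = bmr,
                 expenditure_kj = movement + bmr)
}

#' Total energetic demand including chick provisioning
#'
#' Adds the bird's sex-specific share of the daily chick demand, multiplied
#' by the tracking length, to its expenditure: females carry 60% and males
#' 40% of the 1397.14 kJ/day a four-week-old chick requires. Unknown-sex
#' birds get `NA` with a warning.
#'
#' @param expenditure_kj Tracking-period expenditure (kJ).
#' @param sex `"female"`, `"male"` or `"unknown"` (vectorised).
#' @param days Tracking length in days (> 0).
#' @param demand [demand_defaults()].
#' @return Tibble with columns `ted_kj` and `ted_per_day_kj`.
#' @export
total_energetic_demand <- function(expenditure_kj, sex, days,
                                   demand = demand_defaults()) {
  stopifnot(all(days > 0))
  share <- dplyr::case_match(sex, "female" ~ demand$female_share,
                             "male" ~ demand$male_share,
                             .default = NA_real_)
  if (any(is.na(share))) {
    warn("unknown sex: chick share undefined, TED set to NA")
  }
  ted <- expenditure_kj + share * demand$chick_demand_kj_day * days
  tibble::tibble(ted_kj = ted, ted_per_day_kj = ted / days)
}
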