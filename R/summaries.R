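#' Successful dives needed to meet demand
#'
#' Total energetic demand divided by the kilojoule intake value of one
#' successful dive: the (fractional) number of dives that must capture prey
#' for the bird to meet its demand.
#'
#' @param ted_kj Total energetic demand over the tracking period (kJ).
#' @param kiv_kj Assimilable energy per successful dive (kJ, > 0).
#' @return Fractional dive count.
#' @export
successful_dives_needed <- function(ted_kj, kiv_kj) {
  if (any(kiv_kj <= 0, na.rm = TRUE)) abort("KIV must be positive")
  ted_kj / kiv_kj
}

#' Minimum dive-success percentage
#'
#' The successful dives needed, as a percentage of the dives actually
#' undertaken: a lower bound on the realised capture success rate. The
#' fractional count is deliberately not rounded up first.
#'
#' @param needed Successful dives needed (fractional).
#' @param n_dives Number of dives undertaken (> 0).
#' @return Percentage (0-100+, `NA` with a warning when `n_dives` is 0).
#' @export
min_success_rate <- function(needed, n_dives) {
  bad <- n_dives <= 0
  if (any(bad, na.rm = TRUE)) {
    warn("birds with zero dives have undefined success rates (NA)")
  }
  ifelse(bad, NA_real_, 100 * needed / n_dives)
}

#' Complete a per-bird trip table
#'
#' Given the per-bird input columns (tracking days, dive count, expenditure,
#' TED, KIV), recomputes the derived columns: dives per day, TED per day
#' (kept as supplied when already present, since printed per-day values can
#' carry more precise day lengths than the rounded `tracking_days`),
#' successful dives needed, and the minimum success percentage.
#'
#' @param trips Tibble with columns `bird_id`, `sex`, `year`,
#'   `tracking_days`, `n_dives`, `expenditure_kj`, `ted_kj`, `kiv_kj` and
#'   optionally `ted_per_day_kj`.
#' @return The tibble with columns `dives_per_day`, `ted_per_day_kj`,
#'   `dives_needed`, `pct_success_min` recomputed/added.
#' @export
reconstruct_trip_table <- function(trips) {
  out <- dplyr::mutate(
    trips,
    dives_per_day = .data$n_dives / .data$tracking_days,
    dives_needed = successful_dives_needed(.data$ted_kj, .data$kiv_kj),
    pct_success_min = min_success_rate(.data$dives_needed, .data$n_dives)
  )
  if (!("ted_per_day_kj" %in% names(trips)) ||
      all(is.na(trips$ted_per_day_kj))) {
    out$ted_per_day_kj <- out$ted_kj / out$tracking_days
  }
  out
}

#' Assemble a trip summary from pipeline components
#'
#' One Table-style row per bird from its metadata, classified events,
#' expenditure, TED and KIV.
#'
#' @param metadata One-row metadata tibble (`bird_id`, `sex`, `year`,
#'   `deployment_days`).
#' @param events Event tibble from [classify_behaviour()].
#' @param expenditure One-row tibble from [trip_expenditure()].
#' @param kiv_kj KIV for the bird's sex-year diet (kJ).
#' @param demand [demand_defaults()].
#' @return One-row trip-summary tibble.
#' @export
trip_summary <- function(metadata, events, expenditure, kiv_kj,
                         demand = demand_defaults()) {
  n_dives <- sum(events$kind == "dive")
  ted <- total_energetic_demand(expenditure$expenditure_kj, metadata$sex,
                                metadata$deployment_days, demand)
  reconstruct_trip_table(tibble::tibble(
    bird_id = metadata$bird_id, sex = metadata$sex, year = metadata$year,
    tracking_days = metadata$deployment_days, n_dives = n_dives,
    expenditure_kj = expenditure$expenditure_kj, ted_kj = ted$ted_kj,
    ted_per_day_kj = ted$ted_per_day_kj, kiv_kj = kiv_kj
  ))
}

#' Sex-level summary of trip statistics
#'
#' Unweighted per-bird means and SDs of dive rate, per-day TED and minimum
#' success percentage, plus the percent by which female mean per-day TED
#' exceeds the male mean. Unknown-sex birds are excluded.
#'
#' @param trips Trip-summary tibble (see [reconstruct_trip_table()]).
#' @return List with `by_sex` (tibble, one row per sex) and
#'   `ted_excess_pct`.
#' @export
summarize_by_sex <- function(trips) {
  known <- trips[trips$sex %in% c("female", "male"), ]
  if (nrow(known) == 0) abort("no birds of known sex")
  if (length(unique(known$sex)) < 2) {
    warn("only one sex present: partial summary")
  }
  by_sex <- known |>
    dplyr::group_by(.data$sex) |>
    dplyr::summarise(
      n = dplyr::n(),
      dives_per_day_mean = mean(.data$dives_per_day),
      dives_per_day_sd = sd(.data$dives_per_day),
      ted_per_day_mean = mean(.data$ted_per_day_kj),
      ted_per_day_sd = sd(.data$ted_per_day_kj),
      pct_success_mean = mean(.data$pct_success_min),
      pct_success_sd = sd(.data$pct_success_min),
      .groups = "drop"
    )
  f <- by_sex[by_sex$sex == "female", ]
  m <- by_sex[by_sex$sex == "male", ]
  excess <- if (nrow(f) == 1 && nrow(m) == 1) {
    100 * (f$ted_per_day_mean - m$ted_per_day_mean) / m$ted_per_day_mean
  } else NA_real_
  list(by_sex = by_sex, ted_excess_pct = excess)
}

#' Published per-bird trip table for tracked gannets
#'
#' The printed per-bird summary of the 14 tracked gannets (2017-2018):
#' tracking duration, dive counts and rates, tracking expenditure, TED,
#' per-day TED, modelled KIV, successful dives needed and the minimum
#' success percentage. Ships as a plain-text fixture; derived columns can be
#' recomputed from the input columns with [reconstruct_trip_table()].
#'
#' @return A trip-table tibble (one row per bird; the unknown-sex bird has
#'   `NA` demand columns).
#' @export
gannet_trips <- function() {
  path <- system.file("extdata", "gannet_trips_table4.csv",
                      package = "divebudget", mustWork = TRUE)
  read_table(path, "trip_table")
}
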