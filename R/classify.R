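#' Classifier thresholds and windows
#'
#' Threshold parameters for dive and take-off detection from tri-axial
#' accelerometry. Defaults implement the published thresholding scheme for
#' plunge-diving gannets: a dive starts when the 2 s running mean of the
#' surge (X) axis drops below 0 g while its running SD exceeds 1.4 g; the
#' dive ends at the 1 s lagged maximum of pitch change within 60 s; a
#' take-off is active while SD(Z) > 1.8 g and SD(X) > 1 g and ends once both
#' SDs fall below 1.4 g; dives shorter than 5 s are plunge dives, the rest
#' pursuit dives.
#'
#' @param mean_window_s,sd_window_s Running mean / SD window (s).
#' @param dive_mean_x_max Running-mean X threshold (g) below which a dive can
#'   start.
#' @param dive_sd_x_min Running-SD X threshold (g) above which a dive can
#'   start.
#' @param dive_end_search_s Window (s) after the dive start searched for the
#'   pitch-change maximum.
#' @param dive_end_lag_s Lag (s) added to the pitch-change argmax.
#' @param dive_end_mode `"offset"` adds the lag to the argmax time;
#'   `"lagged_series"` takes the argmax over the pitch-change series lagged
#'   by `dive_end_lag_s` before maximising.
#' @param takeoff_sd_z_min,takeoff_sd_x_min SD thresholds (g) that start a
#'   take-off.
#' @param takeoff_end_sd_z_max,takeoff_end_sd_x_max SD thresholds (g) below
#'   which a take-off has resolved to normal flight.
#' @param takeoff_horizon_s Maximum time (s) after a dive end searched for
#'   its take-off.
#' @param dive_type_split_s Duration (s) splitting plunge from pursuit dives.
#' @param tdr_match_tol_s Tolerance (s) for matching accelerometer dives to
#'   TDR dives.
#' @return A named list of class `classifier_params`.
#' @export
classifier_params <- function(mean_window_s = 2, sd_window_s = 2,
                              dive_mean_x_max = 0, dive_sd_x_min = 1.4,
                              dive_end_search_s = 60, dive_end_lag_s = 1,
                              dive_end_mode = c("offset", "lagged_series"),
                              takeoff_sd_z_min = 1.8, takeoff_sd_x_min = 1.0,
                              takeoff_end_sd_z_max = 1.4,
                              takeoff_end_sd_x_max = 1.4,
                              takeoff_horizon_s = 120,
                              dive_type_split_s = 5, tdr_match_tol_s = 5) {
  stopifnot(mean_window_s > 0, sd_window_s > 0, dive_end_search_s > 0,
            takeoff_horizon_s > 0, dive_type_split_s > 0,
            tdr_match_tol_s > 0,
            takeoff_end_sd_z_max < takeoff_sd_z_min)
  p <- list(mean_window_s = mean_window_s, sd_window_s = sd_window_s,
            dive_mean_x_max = dive_mean_x_max, dive_sd_x_min = dive_sd_x_min,
            dive_end_search_s = dive_end_search_s,
            dive_end_lag_s = dive_end_lag_s,
            dive_end_mode = match.arg(dive_end_mode),
            takeoff_sd_z_min = takeoff_sd_z_min,
            takeoff_sd_x_min = takeoff_sd_x_min,
            takeoff_end_sd_z_max = takeoff_end_sd_z_max,
            takeoff_end_sd_x_max = takeoff_end_sd_x_max,
            takeoff_horizon_s = takeoff_horizon_s,
            dive_type_split_s = dive_type_split_s,
            tdr_match_tol_s = tdr_match_tol_s)
  class(p) <- c("classifier_params", "list")
  p
}

# centred running mean / sample SD of one vector via cumulative sums;
# edges shrink to the largest symmetric window (SD needs >= 2 samples).
.run_mean_sd <- function(x, half_width) {
  n <- length(x)
  i <- seq_len(n)
  h <- pmin(half_width, i - 1L, n - i)
  cs <- c(0, cumsum(x))
  cs2 <- c(0, cumsum(x^2))
  m <- 2 * h + 1
  s <- cs[i + h + 1L] - cs[i - h]
  s2 <- cs2[i + h + 1L] - cs2[i - h]
  mu <- s / m
  v <- (s2 - m * mu^2) / (m - 1)
  v[m < 2] <- NA_real_
  list(mean = mu, sd = sqrt(pmax(v, 0)))
}

#' Per-sample running mean and SD of each axis
#'
#' Centred running statistics computed within dropout segments only; a
#' segment shorter than the window is flagged unusable (`usable = FALSE`,
#' statistics `NA`). Edge samples use the largest available symmetric
#' window.
#'
#' @param trace An [accel_trace()].
#' @param window_s Window length in seconds (default 2). Must span at least
#'   2 samples.
#' @return A tibble with columns `t`, `segment`, `usable`, and
#'   `mean_x/y/z`, `sd_x/y/z`.
#' @export
running_stats <- function(trace, window_s = 2) {
  rate <- trace_rate(trace)
  win <- round(window_s * rate)
  if (win < 2) abort("running-stats window spans fewer than 2 samples")
  half <- max(1L, round(win / 2))
  out <- tibble::tibble(
    t = trace$t, segment = trace$segment, usable = TRUE,
    mean_x = NA_real_, mean_y = NA_real_, mean_z = NA_real_,
    sd_x = NA_real_, sd_y = NA_real_, sd_z = NA_real_
  )
  for (seg in split(seq_len(nrow(trace)), trace$segment)) {
    if (length(seg) < win) {
      out$usable[seg] <- FALSE
      next
    }
    for (ax in c("x", "y", "z")) {
      ms <- .run_mean_sd(trace[[paste0("a", ax)]][seg], half)
      out[[paste0("mean_", ax)]][seg] <- ms$mean
      out[[paste0("sd_", ax)]][seg] <- ms$sd
    }
  }
  out
}

.fill_forward <- function(x) {
  ok <- !is.na(x)
  c(NA_real_, x[ok])[cumsum(ok) + 1L]
}

#' Per-sample pitch angle from static acceleration
#'
#' Pitch is the inclination of the surge (X) axis relative to horizontal,
#' computed as `asin(static_x / ||static vector||)` in degrees, where the
#' static vector is the running mean of the three axes over
#' `params$mean_window_s`. Samples with a zero-magnitude static vector are
#' undefined and carry the previous pitch forward.
#'
#' @param trace An [accel_trace()].
#' @param params [classifier_params()].
#' @param stats Optional precomputed [running_stats()] (at the mean window).
#' @return Numeric vector of pitch angles (degrees), one per sample.
#' @export
compute_pitch <- function(trace, params = classifier_params(), stats = NULL) {
  stats <- stats %||% running_stats(trace, params$mean_window_s)
  norm <- sqrt(stats$mean_x^2 + stats$mean_y^2 + stats$mean_z^2)
  ratio <- ifelse(norm > 0, pmin(pmax(stats$mean_x / norm, -1), 1), NA_real_)
  pitch <- asin(ratio) * 180 / pi
  .fill_forward(pitch)
}

# pitch change over a 1 s spacing, computed within segments
.pitch_change <- function(pitch, segment, rate) {
  lag_n <- max(1L, round(rate))
  n <- length(pitch)
  dp <- rep(NA_real_, n)
  idx <- (lag_n + 1L):n
  dp[idx] <- pitch[idx] - pitch[idx - lag_n]
  same_seg <- c(rep(FALSE, lag_n), segment[idx] == segment[idx - lag_n])
  dp[!same_seg] <- NA_real_
  dp
}

#' Detect dives from running statistics
#'
#' A dive starts at the first sample whose running-mean X is below
#' `dive_mean_x_max` and running-SD X above `dive_sd_x_min`. Its end is the
#' lagged maximum of absolute pitch change within `dive_end_search_s` of the
#' start; if no pitch extremum is available the dive is closed at the search
#' horizon and flagged. Candidate starts inside an open dive are ignored.
#'
#' @inheritParams compute_pitch
#' @param stats Optional precomputed [running_stats()].
#' @return Tibble with columns `start_s`, `end_s`, `duration_s`,
#'   `end_flagged`.
#' @export
detect_dives <- function(trace, params = classifier_params(), stats = NULL) {
  rate <- trace_rate(trace)
  stats <- stats %||% running_stats(trace, params$mean_window_s)
  sd_stats <- if (params$sd_window_s == params$mean_window_s) stats else
    running_stats(trace, params$sd_window_s)
  pitch <- compute_pitch(trace, params, stats = stats)
  dp <- .pitch_change(pitch, trace$segment, rate)

  cand <- stats$usable & sd_stats$usable &
    stats$mean_x < params$dive_mean_x_max &
    sd_stats$sd_x > params$dive_sd_x_min
  cand[is.na(cand)] <- FALSE
  t <- trace$t
  n <- length(t)
  starts <- numeric(0); ends <- numeric(0); flagged <- logical(0)
  cand_idx <- which(cand)
  cursor_t <- -Inf
  for (i in cand_idx) {
    if (t[i] < cursor_t) next
    t0 <- t[i]
    win <- which(t > t0 & t <= t0 + params$dive_end_search_s &
                   trace$segment == trace$segment[i])
    end_t <- t0 + params$dive_end_search_s
    flag <- TRUE
    if (length(win) > 0) {
      dpw <- abs(dp[win])
      if (params$dive_end_mode == "lagged_series") {
        # maximise the pitch-change series lagged by dive_end_lag_s
        lag_n <- round(params$dive_end_lag_s * rate)
        win_l <- win[win - lag_n >= 1]
        dpw_l <- abs(dp[pmax(win_l - lag_n, 1L)])
        if (any(is.finite(dpw_l))) {
          end_t <- t[win_l[which.max(dpw_l)]]
          flag <- FALSE
        }
      } else if (any(is.finite(dpw))) {
        end_t <- t[win[which.max(dpw)]] + params$dive_end_lag_s
        flag <- FALSE
      }
    }
    starts <- c(starts, t0); ends <- c(ends, end_t); flagged <- c(flagged, flag)
    cursor_t <- end_t
  }
  tibble::tibble(start_s = starts, end_s = ends,
                 duration_s = ends - starts, end_flagged = flagged)
}

# take-off search from one dive end; returns c(start, end) or NULL,
# with attribute "end_flagged" when the end threshold was never met
.find_takeoff <- function(t, sd_x, sd_z, usable, from_t, params) {
  horizon <- from_t + params$takeoff_horizon_s
  on <- usable & sd_z > params$takeoff_sd_z_min &
    sd_x > params$takeoff_sd_x_min
  on[is.na(on)] <- FALSE
  i0 <- which(on & t >= from_t & t <= horizon)
  if (length(i0) == 0) return(NULL)
  i0 <- i0[1]
  off <- usable & sd_z < params$takeoff_end_sd_z_max &
    sd_x < params$takeoff_end_sd_x_max
  off[is.na(off)] <- FALSE
  i1 <- which(off & t > t[i0])
  if (length(i1) == 0) {
    res <- c(t[i0], t[length(t)])
    attr(res, "end_flagged") <- TRUE
    return(res)
  }
  res <- c(t[i0], t[i1[1]])
  attr(res, "end_flagged") <- FALSE
  res
}

#' Detect take-offs following dives
#'
#' Starting from each dive end, a take-off begins at the first sample where
#' SD(Z) exceeds `takeoff_sd_z_min` and SD(X) exceeds `takeoff_sd_x_min`,
#' and ends at the first later sample where both SDs have resolved below the
#' end thresholds. A dive with no take-off within `takeoff_horizon_s` is
#' flagged, and its cost is later computed over the dive alone.
#'
#' @inheritParams detect_dives
#' @param dives Tibble from [detect_dives()].
#' @return Tibble with one row per dive: `dive_start_s`, `takeoff_start_s`,
#'   `takeoff_end_s` (NA when none found), `no_takeoff`, `end_flagged`.
#' @export
detect_takeoffs <- function(trace, dives, params = classifier_params(),
                            stats = NULL) {
  sd_stats <- stats %||% running_stats(trace, params$sd_window_s)
  out <- tibble::tibble(dive_start_s = dives$start_s,
                        takeoff_start_s = NA_real_,
                        takeoff_end_s = NA_real_,
                        no_takeoff = TRUE, end_flagged = FALSE)
  for (k in seq_len(nrow(dives))) {
    res <- .find_takeoff(trace$t, sd_stats$sd_x, sd_stats$sd_z,
                         sd_stats$usable, dives$end_s[k], params)
    if (!is.null(res)) {
      out$takeoff_start_s[k] <- res[1]
      out$takeoff_end_s[k] <- res[2]
      out$no_takeoff[k] <- FALSE
      out$end_flagged[k] <- attr(res, "end_flagged")
    }
  }
  out
}

#' Assign plunge vs pursuit from dive duration
#'
#' Dive durations are bimodal with a trough at 5 s: dives shorter than the
#' split are plunge dives (immediate surfacing), the rest pursuit dives
#' (underwater chase). The boundary itself is assigned to pursuit.
#'
#' @param duration_s Dive duration(s) in seconds.
#' @param params [classifier_params()].
#' @return Character vector, `"plunge"` or `"pursuit"`.
#' @export
classify_dive_type <- function(duration_s, params = classifier_params()) {
  stopifnot(all(duration_s > 0))
  ifelse(duration_s < params$dive_type_split_s, "plunge", "pursuit")
}

#' Classify dives and take-offs in one pass
#'
#' Runs [detect_dives()] and [detect_takeoffs()], applies the refractory
#' rule (a new dive cannot start before the previous dive's take-off has
#' ended, or its search horizon lapsed), labels dive types, and returns a
#' linked event table.
#'
#' @inheritParams detect_dives
#' @return Tibble with columns `bird_id`, `event_id`, `kind`
#'   (`dive`/`takeoff`), `start_s`, `end_s`, `duration_s`, `dive_type`
#'   (`plunge`/`pursuit`/`n/a`), `linked_id`, `no_takeoff`, `flagged`.
#' @export
classify_behaviour <- function(trace, params = classifier_params()) {
  stats <- running_stats(trace, params$mean_window_s)
  sd_stats <- if (params$sd_window_s == params$mean_window_s) stats else
    running_stats(trace, params$sd_window_s)
  dives <- detect_dives(trace, params, stats = stats)
  bird <- trace$bird_id[1]
  if (nrow(dives) == 0) {
    return(tibble::tibble(bird_id = character(), event_id = character(),
                          kind = character(), start_s = numeric(),
                          end_s = numeric(), duration_s = numeric(),
                          dive_type = character(), linked_id = character(),
                          no_takeoff = logical(), flagged = logical()))
  }
  rows <- list()
  blocked_until <- -Inf
  k <- 0L
  for (d in seq_len(nrow(dives))) {
    if (dives$start_s[d] < blocked_until) next
    k <- k + 1L
    res <- .find_takeoff(trace$t, sd_stats$sd_x, sd_stats$sd_z,
                         sd_stats$usable, dives$end_s[d], params)
    dive_id <- sprintf("%s-d%04d", bird, k)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      bird_id = bird, event_id = dive_id, kind = "dive",
      start_s = dives$start_s[d], end_s = dives$end_s[d],
      duration_s = dives$duration_s[d],
      dive_type = classify_dive_type(dives$duration_s[d], params),
      linked_id = if (is.null(res)) NA_character_ else
        sprintf("%s-t%04d", bird, k),
      no_takeoff = is.null(res), flagged = dives$end_flagged[d]
    )
    if (is.null(res)) {
      blocked_until <- dives$end_s[d] + params$takeoff_horizon_s
    } else {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        bird_id = bird, event_id = sprintf("%s-t%04d", bird, k),
        kind = "takeoff", start_s = res[1], end_s = res[2],
        duration_s = res[2] - res[1], dive_type = "n/a",
        linked_id = dive_id, no_takeoff = FALSE,
        flagged = attr(res, "end_flagged")
      )
      blocked_until <- res[2]
    }
  }
  dplyr::arrange(dplyr::bind_rows(rows), .data$start_s)
}

#' Dive start times from a TDR trace
#'
#' A TDR dive starts where depth first exceeds the trigger threshold on a
#' rising edge.
#'
#' @param depth A [depth_trace()].
#' @param trigger_threshold_m Threshold (m); defaults to the trace attribute.
#' @return Numeric vector of dive start times (s).
#' @export
tdr_dive_starts <- function(depth, trigger_threshold_m = NULL) {
  thr <- trigger_threshold_m %||% attr(depth, "trigger_threshold_m") %||% 0.5
  above <- depth$depth_m > thr
  rising <- above & !c(FALSE, above[-length(above)])
  depth$t[rising]
}

#' Validate accelerometer dives against TDR dives
#'
#' Greedy nearest-neighbour one-to-one matching of accelerometer dive starts
#' to TDR dive starts within `tdr_match_tol_s`, automating the visual
#' timestamp comparison used with twin-tagged birds.
#'
#' @param events Event tibble from [classify_behaviour()].
#' @param depth A [depth_trace()].
#' @param params [classifier_params()].
#' @return A list of class `tdr_validation`: `matches` (tibble of
#'   `accel_start_s`, `tdr_start_s`, `offset_s`), counts of unmatched events
#'   on each side, and `match_rate_pct` (100 only when both sides match
#'   perfectly).
#' @export
validate_against_tdr <- function(events, depth,
                                 params = classifier_params()) {
  accel <- sort(events$start_s[events$kind == "dive"])
  tdr <- sort(tdr_dive_starts(depth, NULL))
  if (length(tdr) == 0) {
    warn("empty TDR trace: no dives to match")
  }
  pairs <- NULL
  if (length(accel) > 0 && length(tdr) > 0) {
    grid <- expand.grid(a = seq_along(accel), d = seq_along(tdr))
    grid$dist <- abs(accel[grid$a] - tdr[grid$d])
    grid <- grid[grid$dist <= params$tdr_match_tol_s, , drop = FALSE]
    grid <- grid[order(grid$dist), , drop = FALSE]
    used_a <- logical(length(accel)); used_d <- logical(length(tdr))
    keep <- logical(nrow(grid))
    for (r in seq_len(nrow(grid))) {
      if (!used_a[grid$a[r]] && !used_d[grid$d[r]]) {
        keep[r] <- TRUE
        used_a[grid$a[r]] <- TRUE
        used_d[grid$d[r]] <- TRUE
      }
    }
    pairs <- grid[keep, , drop = FALSE]
  }
  matches <- if (is.null(pairs) || nrow(pairs) == 0) {
    tibble::tibble(accel_start_s = numeric(), tdr_start_s = numeric(),
                   offset_s = numeric())
  } else {
    tibble::tibble(accel_start_s = accel[pairs$a], tdr_start_s = tdr[pairs$d],
                   offset_s = accel[pairs$a] - tdr[pairs$d]) |>
      dplyr::arrange(.data$accel_start_s)
  }
  n_m <- nrow(matches)
  out <- list(matches = matches, n_matched = n_m,
              n_accel_only = length(accel) - n_m,
              n_tdr_only = length(tdr) - n_m,
              match_rate_pct = if (max(length(accel), length(tdr)) == 0)
                NA_real_ else 100 * n_m / max(length(accel), length(tdr)))
  class(out) <- c("tdr_validation", "list")
  out
}

#' @export
print.tdr_validation <- function(x, ...) {
  cat("TDR validation: ", x$n_matched, " matched, ",
      x$n_accel_only, " accel-only, ", x$n_tdr_only, " TDR-only (",
      sprintf("%.1f%%", x$match_rate_pct), " matched)\n", sep = "")
  invisible(x)
}
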