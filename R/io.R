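#' Read a tri-axial accelerometer trace
#'
#' Reads a delimited text file with columns `time`, `ax`, `ay`, `az` (time in
#' seconds since deployment start, accelerations in units of g) and returns a
#' validated trace tibble. Time must be strictly increasing; any step larger
#' than twice the nominal sampling interval starts a new segment, so that
#' running statistics never bridge logger dropouts.
#'
#' @param path Path to a delimited text file with a header row.
#' @param rate_hz Nominal sampling rate in Hz (default 50).
#' @param bird_id Identifier attached to every row; defaults to the file name
#'   without extension.
#' @param time_offset_s Per-bird clock offset (seconds) added to `time`, for
#'   aligning the accelerometer clock with a TDR clock. Default 0.
#'
#' @return A tibble of class `accel_trace` with columns `bird_id`, `t`, `ax`,
#'   `ay`, `az`, `segment` and attribute `rate_hz`.
#' @export
read_accel <- function(path, rate_hz = 50, bird_id = NULL,
                       time_offset_s = 0) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("time", "ax", "ay", "az")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("accelerometer file is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(raw) == 0) abort("accelerometer file is empty")
  bird_id <- bird_id %||% sub("\\.[^.]*$", "", basename(path))
  accel_trace(
    tibble::tibble(
      bird_id = bird_id,
      t = as.numeric(raw$time) + time_offset_s,
      ax = as.numeric(raw$ax),
      ay = as.numeric(raw$ay),
      az = as.numeric(raw$az)
    ),
    rate_hz = rate_hz
  )
}

#' Construct an accelerometer trace from a data frame
#'
#' Validates monotone time and finite g-values, assigns dropout segments by
#' the gap rule (a step greater than `2 / rate_hz` opens a new segment), and
#' attaches the sampling rate as an attribute.
#'
#' @param df Data frame with columns `t`, `ax`, `ay`, `az` and optionally
#'   `bird_id`.
#' @param rate_hz Sampling rate in Hz.
#' @return A tibble of class `accel_trace`.
#' @export
accel_trace <- function(df, rate_hz = 50) {
  stopifnot(rate_hz > 0)
  df <- tibble::as_tibble(df)
  need <- c("t", "ax", "ay", "az")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("trace is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!("bird_id" %in% names(df))) df$bird_id <- "unknown"
  if (any(!is.finite(df$t))) abort("non-finite time values in trace")
  dt <- diff(df$t)
  if (any(dt <= 0)) {
    abort(paste0("time is not strictly increasing at row ",
                 which(dt <= 0)[1] + 1L))
  }
  if (any(!is.finite(df$ax) | !is.finite(df$ay) | !is.finite(df$az))) {
    abort("non-finite acceleration values in trace")
  }
  df$segment <- c(1L, 1L + cumsum(dt > 2 / rate_hz))
  df <- df[, c("bird_id", "t", "ax", "ay", "az", "segment")]
  attr(df, "rate_hz") <- rate_hz
  class(df) <- c("accel_trace", class(df))
  df
}

#' Sampling rate of a trace
#'
#' @param trace An `accel_trace` or depth-trace tibble.
#' @return Sampling rate in Hz (from the `rate_hz` attribute, or the median
#'   time step when absent).
#' @export
trace_rate <- function(trace) {
  r <- attr(trace, "rate_hz")
  if (!is.null(r)) return(r)
  1 / median(diff(trace$t))
}

# Column schemas for the tabular inputs. Each entry: required columns and the
# prototype used for type coercion.
.table_schemas <- list(
  metadata = list(
    required = c("bird_id", "sex", "mass_kg", "year", "deployment_days"),
    optional = c("n_complete_days", "colony_latitude_deg"),
    numeric = c("mass_kg", "year", "deployment_days", "n_complete_days",
                "colony_latitude_deg")
  ),
  isotopes = list(
    required = c("bird_id", "sex", "year", "d13C", "d15N", "pctC", "pctN"),
    optional = character(),
    numeric = c("year", "d13C", "d15N", "pctC", "pctN")
  ),
  sources = list(
    required = c("species", "d13C_mean", "d13C_sd", "d15N_mean", "d15N_sd",
                 "diet_pct"),
    optional = c("pctC", "pctN"),
    numeric = c("d13C_mean", "d13C_sd", "d15N_mean", "d15N_sd", "diet_pct",
                "pctC", "pctN")
  ),
  energy = list(
    required = c("species", "gross_kj"),
    optional = character(),
    numeric = "gross_kj"
  ),
  events = list(
    required = c("bird_id", "kind", "start_s", "end_s"),
    optional = c("duration_s", "dive_type", "linked_id"),
    numeric = c("start_s", "end_s", "duration_s")
  ),
  trip_table = list(
    required = c("bird_id", "sex", "year", "tracking_days", "n_dives",
                 "expenditure_kj", "ted_kj", "kiv_kj"),
    optional = c("dives_per_day", "ted_per_day_kj", "dives_needed",
                 "pct_success_min"),
    numeric = c("year", "tracking_days", "n_dives", "dives_per_day",
                "expenditure_kj", "ted_kj", "ted_per_day_kj", "kiv_kj",
                "dives_needed", "pct_success_min")
  )
)

#' Read a typed pipeline table
#'
#' Reads one of the pipeline's delimited tables against a named schema and
#' validates required columns and numeric types row by row. Rows with sex
#' `unknown` are retained but flagged `exclude_sex_contrast`, mirroring the
#' treatment of birds whose molecular sexing was inconclusive.
#'
#' @param path Path to a delimited text file with a header row.
#' @param schema One of `"metadata"`, `"isotopes"`, `"sources"`, `"energy"`,
#'   `"events"`, `"trip_table"`.
#' @return A tibble with schema-typed columns.
#' @export
read_table <- function(path, schema = c("metadata", "isotopes", "sources",
                                        "energy", "events", "trip_table")) {
  schema <- match.arg(schema)
  sch <- .table_schemas[[schema]]
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = "c"))
  if (nrow(raw) == 0) abort(paste0("empty ", schema, " table: ", path))
  missing_cols <- setdiff(sch$required, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0(schema, " table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  out <- raw[, intersect(c(sch$required, sch$optional), names(raw))]
  for (col in intersect(sch$numeric, names(out))) {
    vals <- suppressWarnings(as.numeric(out[[col]]))
    bad <- which(!is.na(out[[col]]) & out[[col]] != "NA" & is.na(vals))
    if (length(bad) > 0) {
      abort(paste0(schema, " table column '", col,
                   "' is not numeric at row ", bad[1]))
    }
    out[[col]] <- vals
  }
  if ("sex" %in% names(out)) {
    out$sex <- tolower(out$sex)
    ok <- out$sex %in% c("female", "male", "unknown")
    if (!all(ok)) {
      abort(paste0(schema, " table has invalid sex at row ", which(!ok)[1]))
    }
    out$exclude_sex_contrast <- out$sex == "unknown"
  }
  if (schema == "metadata" && any(out$mass_kg <= 0)) {
    abort("metadata table has non-positive mass")
  }
  tibble::as_tibble(out)
}

#' Write a trace or table to CSV
#'
#' Thin wrapper over [readr::write_csv()] so write/read round trips are
#' value-identical for every pipeline table.
#'
#' @param x Data frame to write. An `accel_trace` is written with its `t`
#'   column renamed back to `time`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path) {
  if (inherits(x, "accel_trace")) {
    x <- dplyr::rename(tibble::as_tibble(x)[, c("t", "ax", "ay", "az")],
                       time = "t")
  }
  readr::write_csv(x, path, progress = FALSE)
  invisible(path)
}

#' Read a time-depth-recorder trace
#'
#' @param path Delimited file with columns `time` (s) and `depth_m`.
#' @param rate_hz Sampling rate in Hz (default 4).
#' @param trigger_threshold_m Depth threshold (m) that arms the recorder,
#'   0.5 or 1.0 depending on tag set-up.
#' @param bird_id Identifier; defaults to the file name.
#' @return A tibble of class `depth_trace` with attributes `rate_hz` and
#'   `trigger_threshold_m`.
#' @export
read_depth <- function(path, rate_hz = 4, trigger_threshold_m = 0.5,
                       bird_id = NULL) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("time", "depth_m")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("depth file is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  bird_id <- bird_id %||% sub("\\.[^.]*$", "", basename(path))
  depth_trace(
    tibble::tibble(bird_id = bird_id, t = as.numeric(raw$time),
                   depth_m = as.numeric(raw$depth_m)),
    rate_hz = rate_hz, trigger_threshold_m = trigger_threshold_m
  )
}

#' Construct a depth trace from a data frame
#'
#' @param df Data frame with columns `t` and `depth_m` (and optionally
#'   `bird_id`).
#' @inheritParams read_depth
#' @return A tibble of class `depth_trace`.
#' @export
depth_trace <- function(df, rate_hz = 4, trigger_threshold_m = 0.5) {
  stopifnot(rate_hz > 0, trigger_threshold_m > 0)
  df <- tibble::as_tibble(df)
  if (!("bird_id" %in% names(df))) df$bird_id <- "unknown"
  if (any(df$depth_m < 0)) abort("negative depth in depth trace")
  if (any(diff(df$t) <= 0)) abort("time is not strictly increasing in depth trace")
  df <- df[, c("bird_id", "t", "depth_m")]
  attr(df, "rate_hz") <- rate_hz
  attr(df, "trigger_threshold_m") <- trigger_threshold_m
  class(df) <- c("depth_trace", class(df))
  df
}

#' Default run configuration
#'
#' Bundles the classifier thresholds, allometric coefficients, chick-demand
#' split, mixing-model settings and assimilation efficiency into one list, so
#' a whole analysis can be driven from a single object.
#'
#' @param ... Named overrides for any top-level entry.
#' @return A named list.
#' @export
run_config <- function(...) {
  cfg <- list(
    classifier = classifier_params(),
    allometry = allometric_defaults(),
    demand = demand_defaults(),
    mcmc = mcmc_settings(),
    assimilation_efficiency = 0.761
  )
  dots <- list(...)
  for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]
  stopifnot(cfg$assimilation_efficiency > 0, cfg$assimilation_efficiency <= 1)
  cfg
}
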