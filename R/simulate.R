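#' Trophic discrimination factors
#'
#' Mean and SD of the diet-to-tissue isotopic enrichment added to source
#' values in the mixing model. Defaults are averages for piscivorous birds:
#' 2.25 +/- 0.61 permil for d15N and 0.24 +/- 0.79 permil for d13C.
#'
#' @param d15N_mean,d15N_sd,d13C_mean,d13C_sd Values in permil.
#' @return A named list.
#' @export
discrimination_defaults <- function(d15N_mean = 2.25, d15N_sd = 0.61,
                                    d13C_mean = 0.24, d13C_sd = 0.79) {
  stopifnot(d15N_sd >= 0, d13C_sd >= 0)
  list(d15N_mean = d15N_mean, d15N_sd = d15N_sd,
       d13C_mean = d13C_mean, d13C_sd = d13C_sd)
}

#' Synthetic prey source table
#'
#' A small synthetic source table with isotope distributions in the range of
#' Celtic Sea forage fish, used as the generator default. Values are
#' invented for testing, not measurements.
#'
#' @return A sources tibble (`species`, `d13C_mean`, `d13C_sd`, `d15N_mean`,
#'   `d15N_sd`, `diet_pct`).
#' @export
synthetic_sources <- function() {
  tibble::tribble(
    ~species,   ~d13C_mean, ~d13C_sd, ~d15N_mean, ~d15N_sd, ~diet_pct,
    "mackerel",      -17.2,      0.5,       12.2,      0.6,        45,
    "sprat",         -18.6,      0.4,       10.6,      0.5,        15,
    "sandeel",       -16.0,      0.4,       11.0,      0.5,        12,
    "herring",       -18.0,      0.5,       11.8,      0.6,         8
  )
}

#' Simulation configuration
#'
#' Defaults encode the study conditions: 14 birds (5 female, 8 male, 1
#' unknown), female mass 2.99 +/- 0.15 kg and male 2.70 +/- 0.19 kg,
#' deployments averaging 3.7 days, dive rates of ~26/day (females) and
#' ~17/day (males), 24% pursuit dives, dive-duration modes of 2 s (plunge)
#' and 8 s (pursuit) straddling the 5 s split, 50 Hz accelerometry and 4 Hz
#' depth with a 0.5 m trigger. Regime amplitudes are synthetic: they are
#' calibrated only to realise the classifier's threshold contrasts
#' (documented in the methods vignette), not to any published amplitude
#' statistics.
#'
#' @param ... Named overrides of any default.
#' @return A named list of class `sim_config`.
#' @export
sim_config <- function(...) {
  cfg <- list(
    n_birds = 14,
    sex_counts = c(female = 5, male = 8, unknown = 1),
    mass = list(female = c(mean = 2.99, sd = 0.15),
                male = c(mean = 2.70, sd = 0.19),
                unknown = c(mean = 2.85, sd = 0.20)),
    deployment_days = 3.70,
    dives_per_day = c(female = 26, male = 17, unknown = 20),
    dive_count_dist = "poisson",  # or "fixed"
    n_dives = NULL,               # explicit override of the dive count
    pursuit_fraction = 0.24,
    dive_meanlog = c(plunge = log(2.0), pursuit = log(8.0)),
    dive_sdlog = c(plunge = 0.25, pursuit = 0.20),
    max_dive_s = 45,
    takeoff_range_s = c(2.5, 4),
    min_dive_gap_s = 90,
    rate_hz = 50, depth_rate_hz = 4, trigger_threshold_m = 0.5,
    depth_max_m = list(plunge = c(1.5, 4), pursuit = c(3, 10)),
    # regime signal parameters (static level, oscillation amp/freq, noise SD)
    regimes = list(
      rest = list(x = c(0, 0, 0, 0.05), y = c(0, 0, 0, 0.05),
                  z = c(1, 0, 0, 0.05)),
      flight = list(x = c(0, 0, 0, 0.15), y = c(0, 0, 0, 0.15),
                    z = c(1, 0.5, 4, 0.10)),
      dive = list(x = c(-0.8, 2.2, 8, 0.30), y = c(0, 0.8, 8, 0.30),
                  z = c(0.5, 1.2, 8, 0.30)),
      takeoff = list(x = c(0.3, 1.6, 6, 0.30), y = c(0, 0.8, 6, 0.30),
                     z = c(1.0, 3.2, 6, 0.40))
    ),
    years = c(2017, 2018),
    colony_latitude_deg = 52,
    isotopes = list(
      sources = synthetic_sources(),
      true_p = list(
        female = c(mackerel = 0.45, sprat = 0.25, sandeel = 0.15,
                   herring = 0.15),
        male = c(mackerel = 0.55, sprat = 0.15, sandeel = 0.15,
                 herring = 0.15)
      ),
      tdf = discrimination_defaults(),
      residual_sd = c(d13C = 0.3, d15N = 0.3),
      n_per_group = 20
    )
  )
  dots <- list(...)
  for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]
  stopifnot(cfg$deployment_days > 0, cfg$pursuit_fraction >= 0,
            cfg$pursuit_fraction <= 1, cfg$min_dive_gap_s > 0)
  class(cfg) <- c("sim_config", "list")
  cfg
}

# deterministic per-bird seed from the global seed and the bird id,
# independent of bird order
.bird_seed <- function(seed, bird_id) {
  h <- 0
  for (ch in utf8ToInt(bird_id)) h <- (h * 31 + ch) %% 2147480009
  as.integer(((seed %% 65521) * 32749 + h) %% 2147483629)
}

# fill regime signal into axis vectors over sample index slice
.regime_signal <- function(n, t, rp) {
  vapply(c("x", "y", "z"), function(ax) {
    p <- rp[[ax]]
    p[1] + p[2] * sin(2 * pi * p[3] * t) + rnorm(n, 0, p[4])
  }, numeric(n))
}

#' Simulate one tagged deployment
#'
#' Generates a regime-structured 50 Hz tri-axial trace (rest, flapping
#' flight, dive, take-off), the matching 4 Hz depth trace, the ground-truth
#' event log and the bird's metadata row. Each dive is followed by exactly
#' one take-off; depth exceeds the trigger threshold only during dives.
#'
#' @param config [sim_config()].
#' @param bird_index Integer index (1..n_birds) selecting sex, year and the
#'   bird id.
#' @param seed Global integer seed; the bird's substream is derived by a
#'   stable hash of its id so results do not depend on simulation order.
#' @return A list with elements `trace` ([accel_trace()]), `depth`
#'   ([depth_trace()]), `events` (ground-truth log: `bird_id`, `kind`,
#'   `start_s`, `end_s`, `dive_type`) and `metadata` (one-row tibble).
#' @export
simulate_deployment <- function(config = sim_config(), bird_index = 1,
                                seed = 1) {
  stopifnot(bird_index >= 1, bird_index <= config$n_birds)
  sexes <- rep(names(config$sex_counts), config$sex_counts)
  sex <- sexes[bird_index]
  bird_id <- sprintf("SIM%02d", bird_index)
  year <- config$years[(bird_index - 1) %% length(config$years) + 1]
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(.bird_seed(seed, bird_id))

  rate <- config$rate_hz
  T_s <- config$deployment_days * 86400
  n <- round(T_s * rate)
  t <- (seq_len(n) - 1) / rate

  m <- config$mass[[sex]]
  mass_kg <- max(1.5, rnorm(1, m["mean"], m["sd"]))

  # dive schedule: uniform starts with a minimum gap inside safety margins
  n_dives <- config$n_dives %||% {
    lam <- config$dives_per_day[[sex]] * config$deployment_days
    if (identical(config$dive_count_dist, "fixed")) round(lam)
    else stats::rpois(1, lam)
  }
  margin_lead <- 60; margin_tail <- 130
  avail <- T_s - margin_lead - margin_tail -
    n_dives * config$min_dive_gap_s
  if (n_dives > 0 && avail < 0) {
    abort("infeasible config: requested dives do not fit the deployment")
  }
  starts <- if (n_dives > 0) {
    margin_lead + sort(runif(n_dives, 0, avail)) +
      (seq_len(n_dives) - 1) * config$min_dive_gap_s
  } else numeric(0)
  is_pursuit <- runif(n_dives) < config$pursuit_fraction
  comp <- rep("plunge", n_dives)
  comp[is_pursuit] <- "pursuit"
  durs <- pmin(rlnorm(n_dives, config$dive_meanlog[comp],
                      config$dive_sdlog[comp]), config$max_dive_s)
  to_durs <- runif(n_dives, config$takeoff_range_s[1],
                   config$takeoff_range_s[2])

  # base flight everywhere, rest in the middle of long inter-dive gaps
  acc <- .regime_signal(n, t, config$regimes$flight)
  gap_bounds <- cbind(c(0, starts + durs + to_durs), c(starts, T_s))
  for (g in seq_len(nrow(gap_bounds))) {
    lo <- gap_bounds[g, 1]; hi <- gap_bounds[g, 2]
    if (hi - lo > 180) {
      idx <- which(t >= lo + 60 & t < hi - 60)
      acc[idx, ] <- .regime_signal(length(idx), t[idx], config$regimes$rest)
    }
  }
  for (d in seq_len(n_dives)) {
    di <- which(t >= starts[d] & t < starts[d] + durs[d])
    acc[di, ] <- .regime_signal(length(di), t[di], config$regimes$dive)
    ti <- which(t >= starts[d] + durs[d] &
                  t < starts[d] + durs[d] + to_durs[d])
    acc[ti, ] <- .regime_signal(length(ti), t[ti], config$regimes$takeoff)
  }

  trace <- accel_trace(
    tibble::tibble(bird_id = bird_id, t = t, ax = acc[, 1], ay = acc[, 2],
                   az = acc[, 3]),
    rate_hz = rate
  )

  # depth: quiet surface, sinusoidal excursion during each dive
  td <- seq(0, T_s - 1 / config$depth_rate_hz, by = 1 / config$depth_rate_hz)
  depth <- pmax(rnorm(length(td), 0, 0.02), 0)
  for (d in seq_len(n_dives)) {
    rng <- config$depth_max_m[[comp[d]]]
    maxd <- runif(1, rng[1], rng[2])
    di <- which(td >= starts[d] & td <= starts[d] + durs[d])
    frac <- (td[di] - starts[d]) / durs[d]
    depth[di] <- maxd * sin(pi * frac)
  }
  depth_tr <- depth_trace(
    tibble::tibble(bird_id = bird_id, t = td, depth_m = depth),
    rate_hz = config$depth_rate_hz,
    trigger_threshold_m = config$trigger_threshold_m
  )

  events <- dplyr::bind_rows(
    tibble::tibble(bird_id = bird_id, kind = "dive", start_s = starts,
                   end_s = starts + durs, dive_type = comp),
    tibble::tibble(bird_id = bird_id, kind = "takeoff",
                   start_s = starts + durs,
                   end_s = starts + durs + to_durs, dive_type = "n/a")
  ) |> dplyr::arrange(.data$start_s, .data$kind)

  metadata <- tibble::tibble(
    bird_id = bird_id, sex = sex, mass_kg = mass_kg, year = year,
    deployment_days = config$deployment_days,
    n_complete_days = floor(config$deployment_days),
    colony_latitude_deg = config$colony_latitude_deg
  )
  list(trace = trace, depth = depth_tr, events = events, metadata = metadata)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Simulate consumer and source isotope tables with known mixing
#'
#' Consumers in each group are drawn from the mixing model's own likelihood:
#' per isotope, `Normal(sum_i p_i (mu_i + lambda), sqrt(sum_i p_i^2
#' (sigma_i^2 + tau_i^2) + xi^2))`, where `lambda, tau` are the
#' discrimination mean/SD and `xi` the residual SD. True proportions are
#' known, so posterior recovery can be scored exactly.
#'
#' @param true_p Named list: group label -> named proportion vector over
#'   `sources$species` (each summing to 1).
#' @param sources Sources tibble (see [synthetic_sources()]); at least one
#'   species.
#' @param n_per_group Consumers per group.
#' @param tdf [discrimination_defaults()].
#' @param residual_sd Named vector with elements `d13C`, `d15N`.
#' @param group_var Name of the grouping column on the consumer table
#'   (default `"group"`).
#' @param seed Integer seed.
#' @return List with `consumers` and `sources` tibbles.
#' @export
simulate_isotopes <- function(true_p, sources = synthetic_sources(),
                              n_per_group = 20,
                              tdf = discrimination_defaults(),
                              residual_sd = c(d13C = 0.3, d15N = 0.3),
                              group_var = "group", seed = 1) {
  if (nrow(sources) < 1) abort("at least one source is required")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  lam <- c(d13C = tdf$d13C_mean, d15N = tdf$d15N_mean)
  tau <- c(d13C = tdf$d13C_sd, d15N = tdf$d15N_sd)
  consumers <- purrr::imap(true_p, function(p, grp) {
    p <- p[sources$species]
    if (any(is.na(p)) || abs(sum(p) - 1) > 1e-8) {
      abort("true proportions must cover every source and sum to 1")
    }
    draw_iso <- function(iso) {
      mu <- sum(p * (sources[[paste0(iso, "_mean")]] + lam[iso]))
      s <- sqrt(sum(p^2 * (sources[[paste0(iso, "_sd")]]^2 + tau[iso]^2)) +
                  residual_sd[iso]^2)
      rnorm(n_per_group, mu, s)
    }
    out <- tibble::tibble(
      bird_id = sprintf("%s%02d", toupper(substr(grp, 1, 1)),
                        seq_len(n_per_group)),
      d13C = draw_iso("d13C"), d15N = draw_iso("d15N"),
      pctC = 45, pctN = 13
    )
    out[[group_var]] <- grp
    out
  }) |> dplyr::bind_rows()
  list(consumers = consumers, sources = sources)
}
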