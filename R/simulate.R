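#' Synthetic study scenario
#'
#' Describes a simulated two-carnivore study: how many wolves and coyotes (and
#' optionally deer) are collared, per-state Brownian motion variances, the
#' crepuscular activity schedule (a two-peak von Mises mixture over the
#' 24-hr clock), species diet profiles per period, scat diameter
#' distributions, and measurement error. Defaults mirror the field study the
#' package emulates: 11 wolves and 13 coyotes with usable collar data, 15-min
#' GPS fixes, 5-min accelerometer summaries, dawn/dusk activity peaks, and
#' scat diameters averaging 25.2 mm (SD 4.4) for coyotes and 33.3 mm (SD 6.1)
#' for wolves.
#'
#' @param n_wolves,n_coyotes,n_deer Numbers of simulated individuals.
#' @param sigma_active,sigma_inactive Brownian motion variance by behavioral
#'   state, m^2 per minute.
#' @param activity_peaks Hours of the two circular activity peaks (dawn, dusk).
#' @param activity_concentration Von Mises concentration of each peak.
#' @param prop_active Long-run mean proportion of 5-min intervals active.
#' @param gps_error_sd GPS location error SD, meters.
#' @param vhf_error_sd VHF triangulation error SD, meters (deer).
#' @param diet Named list `species -> period -> named probability vector` over
#'   the seven prey items; each vector sums to 1.
#' @param scat_diameter Named list `species -> c(mean, sd)` in mm.
#' @param dirichlet_concentration Concentration of the per-scat Dirichlet
#'   around the diet vector; larger = less scat-to-scat variability.
#' @param track_confirmed_frac Fraction of scats with confirmed tracks.
#' @param ruf_effects Named list `species -> named coefficient vector` of true
#'   standardized resource-selection effects, used to construct synthetic
#'   occurrence surfaces for recovery experiments.
#' @param year Calendar year stamped on simulated dates.
#' @param rng_seed Integer seed.
#' @return A `synthetic_scenario` object (a named list).
#' @export
synthetic_scenario <- function(n_wolves = 11L, n_coyotes = 13L, n_deer = 0L,
                               sigma_active = 8, sigma_inactive = 0.5,
                               activity_peaks = c(5.5, 20.5),
                               activity_concentration = c(3, 3),
                               prop_active = 0.35,
                               gps_error_sd = 10,
                               vhf_error_sd = 100,
                               diet = default_diet_profiles(),
                               scat_diameter = list(
                                 coyote = c(mean = 25.2, sd = 4.4),
                                 wolf = c(mean = 33.3, sd = 6.1)
                               ),
                               dirichlet_concentration = 10,
                               track_confirmed_frac = 0.3,
                               ruf_effects = list(
                                 wolf = c(dist_edge = -0.4, hare_density = 0.3,
                                          deer_adult_occ = 0.3),
                                 coyote = c(dist_road = -0.3,
                                            grouse_density = 0.2,
                                            wolf_occ = -0.2)
                               ),
                               year = 2014L,
                               rng_seed = 1L) {
  stopifnot(sigma_active >= 0, sigma_inactive >= 0,
            all(activity_concentration >= 0),
            prop_active > 0, prop_active < 1)
  for (sp in names(diet)) {
    for (pd in names(diet[[sp]])) {
      if (abs(sum(diet[[sp]][[pd]]) - 1) > 1e-6) {
        stop("diet vector for ", sp, "/", pd, " does not sum to 1")
      }
    }
  }
  structure(
    list(
      n_wolves = as.integer(n_wolves), n_coyotes = as.integer(n_coyotes),
      n_deer = as.integer(n_deer),
      sigma_active = sigma_active, sigma_inactive = sigma_inactive,
      activity_peaks = activity_peaks,
      activity_concentration = activity_concentration,
      prop_active = prop_active,
      gps_error_sd = gps_error_sd, vhf_error_sd = vhf_error_sd,
      diet = diet, scat_diameter = scat_diameter,
      dirichlet_concentration = dirichlet_concentration,
      track_confirmed_frac = track_confirmed_frac,
      ruf_effects = ruf_effects,
      year = as.integer(year),
      rng_seed = as.integer(rng_seed)
    ),
    class = "synthetic_scenario"
  )
}

prey_items <- function() {
  c("deer_adult", "deer_fawn", "hare", "grouse", "rodent", "seeds", "other")
}

#' Default simulated diet profiles
#'
#' Per species and period probability vectors over the seven prey items. The
#' wolf is an ungulate specialist (deer-heavy, narrowing onto fawns during the
#' limited-mobility period); the coyote is a generalist with more rodents,
#' hare, and seeds and a broader spread. No fawns occur before parturition
#' (PPP).
#'
#' @return Named list `species -> period -> probability vector`.
#' @export
default_diet_profiles <- function() {
  v <- function(...) {
    p <- c(...)
    names(p) <- prey_items()
    stopifnot(abs(sum(p) - 1) < 1e-9)
    p
  }
  list(
    wolf = list(
      PPP = v(0.45, 0.00, 0.08, 0.05, 0.18, 0.09, 0.15),
      LMP = v(0.20, 0.50, 0.03, 0.02, 0.10, 0.05, 0.10),
      SMP = v(0.45, 0.20, 0.04, 0.03, 0.10, 0.06, 0.12)
    ),
    coyote = list(
      PPP = v(0.30, 0.00, 0.10, 0.05, 0.25, 0.12, 0.18),
      LMP = v(0.15, 0.35, 0.07, 0.04, 0.20, 0.07, 0.12),
      SMP = v(0.35, 0.20, 0.08, 0.04, 0.22, 0.05, 0.06)
    )
  )
}

# Unnormalized two-peak von Mises mixture on clock hours.
activity_schedule_density <- function(hours, scenario) {
  th <- hours / 24 * 2 * pi
  mu <- scenario$activity_peaks / 24 * 2 * pi
  k <- scenario$activity_concentration
  d <- 0
  for (j in seq_along(mu)) {
    d <- d + 0.5 * exp(k[j] * (cos(th - mu[j]) - 1)) /
      (2 * pi * besselI(k[j], 0, expon.scaled = TRUE))
  }
  d
}

# Probability a 5-min interval starting at clock hour h is active, scaled so
# the daily mean equals prop_active.
activity_probability <- function(hours, scenario) {
  grid <- seq(0, 24, length.out = 577L)[-577L]
  f <- activity_schedule_density(grid, scenario)
  p <- activity_schedule_density(hours, scenario) * scenario$prop_active / mean(f)
  pmin(p, 1)
}

#' Simulate an accelerometer activity series
#'
#' Draws true active/inactive states for consecutive 5-min intervals from the
#' scenario's crepuscular schedule, then draws summed accelerometer readings:
#' active intervals at or above the activity threshold, inactive intervals
#' below it.
#'
#' @param scenario A [synthetic_scenario()].
#' @param id,species Individual labels.
#' @param start POSIXct start of the first interval.
#' @param n_intervals Number of 5-min intervals.
#' @param threshold Activity threshold separating the two reading regimes.
#' @param interval Interval length, minutes.
#' @param seed Integer seed.
#' @return Tibble `id, species, interval_start, summed_accel, true_state`.
#' @export
simulate_activity <- function(scenario, id, species, start,
                              n_intervals, threshold = 30.7, interval = 5,
                              seed = scenario$rng_seed) {
  set.seed(seed)
  t0 <- as.POSIXct(start, tz = "UTC")
  starts <- t0 + (seq_len(n_intervals) - 1L) * interval * 60
  hours <- clock_hours(starts)
  p <- activity_probability(hours, scenario)
  active <- stats::runif(n_intervals) < p
  accel <- numeric(n_intervals)
  accel[active] <- threshold + stats::rgamma(sum(active), shape = 2, scale = 25)
  accel[!active] <- stats::runif(sum(!active), 0, threshold * 0.999)
  tibble::tibble(
    id = id, species = species, interval_start = starts,
    summed_accel = accel,
    true_state = ifelse(active, "active", "inactive")
  )
}

clock_hours <- function(times) {
  as.numeric(times - trunc(times, "days"), units = "hours") %% 24
}

#' Simulate a GPS (or VHF) track
#'
#' A two-state Brownian walk: the behavioral state of each inter-fix segment
#' sets its motion variance, per-axis displacement over a segment of duration
#' `dt` minutes is Normal(0, sigma_m^2 * dt), and each observed fix is the
#' true position plus isotropic Gaussian measurement error. States are taken
#' from `states` when supplied (e.g. derived from a simulated activity
#' series), otherwise drawn independently per fix from the scenario's diel
#' schedule.
#'
#' @param scenario A [synthetic_scenario()].
#' @param id,species Individual labels.
#' @param start POSIXct time of the first fix.
#' @param n_fixes Number of fixes.
#' @param fix_interval Minutes between fixes.
#' @param error_sd Location error SD, meters; default the scenario's GPS error.
#' @param states Optional character vector of per-fix true states.
#' @param origin Numeric length-2 start position, meters.
#' @param seed Integer seed.
#' @return List with `track` (tibble `id, species, timestamp, x, y, error_sd`)
#'   and `truth` (tibble with true positions and states, for recovery tests
#'   only — the analysis pipeline never reads it).
#' @export
simulate_track <- function(scenario, id, species, start, n_fixes,
                           fix_interval = 15,
                           error_sd = scenario$gps_error_sd,
                           states = NULL, origin = c(0, 0),
                           seed = scenario$rng_seed) {
  set.seed(seed)
  t0 <- as.POSIXct(start, tz = "UTC")
  ts <- t0 + (seq_len(n_fixes) - 1L) * fix_interval * 60
  if (is.null(states)) {
    p <- activity_probability(clock_hours(ts), scenario)
    states <- ifelse(stats::runif(n_fixes) < p, "active", "inactive")
  }
  stopifnot(length(states) == n_fixes)
  sig <- ifelse(states == "active", scenario$sigma_active,
                scenario$sigma_inactive)
  # segment variance governed by the state at the segment's start fix
  seg_sd <- sqrt(sig[-n_fixes] * fix_interval)
  x <- origin[1] + cumsum(c(0, stats::rnorm(n_fixes - 1L, 0, seg_sd)))
  y <- origin[2] + cumsum(c(0, stats::rnorm(n_fixes - 1L, 0, seg_sd)))
  obs_x <- x + stats::rnorm(n_fixes, 0, error_sd)
  obs_y <- y + stats::rnorm(n_fixes, 0, error_sd)
  list(
    track = tibble::tibble(
      id = id, species = species, timestamp = ts,
      x = obs_x, y = obs_y, error_sd = error_sd
    ),
    truth = tibble::tibble(
      timestamp = ts, true_x = x, true_y = y, true_state = states
    )
  )
}

#' Simulate scat records
#'
#' Per-scat prey-item volume fractions are Dirichlet-distributed around the
#' scenario's species/period diet vector; diameters are normal with the
#' species mean and SD (truncated positive); a configured fraction of scats
#' carries confirmed tracks, the rest are identified by diameter alone.
#'
#' @param scenario A [synthetic_scenario()].
#' @param species `"wolf"` or `"coyote"`.
#' @param period `"PPP"`, `"LMP"`, or `"SMP"`.
#' @param n Number of scats, > 0.
#' @param seed Integer seed.
#' @return Long tibble `id, date, diameter_mm, track_species, item,
#'   volume_fraction` (seven rows per scat).
#' @export
simulate_scats <- function(scenario, species, period, n,
                           seed = scenario$rng_seed) {
  if (n <= 0) stop("`n` must be positive")
  p <- scenario$diet[[species]][[period]]
  if (is.null(p)) stop("no diet profile for ", species, "/", period)
  set.seed(seed)
  items <- prey_items()
  alpha <- scenario$dirichlet_concentration * p
  # Dirichlet via normalized gammas; zero-alpha items stay exactly zero
  g <- matrix(0, n, length(items))
  pos <- alpha > 0
  g[, pos] <- matrix(
    stats::rgamma(n * sum(pos), shape = rep(alpha[pos], each = n)),
    n, sum(pos)
  )
  fr <- g / rowSums(g)
  dm <- scenario$scat_diameter[[species]]
  diam <- abs(stats::rnorm(n, dm["mean"], dm["sd"]))
  tracked <- stats::runif(n) < scenario$track_confirmed_frac
  dates <- random_period_dates(period, n, scenario$year)
  ids <- sprintf("%s_%s_%03d", species, period, seq_len(n))
  tibble::tibble(
    id = rep(ids, each = length(items)),
    date = rep(dates, each = length(items)),
    diameter_mm = rep(diam, each = length(items)),
    track_species = rep(ifelse(tracked, species, "none"), each = length(items)),
    item = rep(items, times = n),
    volume_fraction = as.vector(t(fr))
  )
}

random_period_dates <- function(period, n, year) {
  pt <- period_table()
  i <- match(period, pt$label)
  if (is.na(i)) stop("unknown period: ", period)
  from <- as.Date(sprintf("%d-%02d-%02d", year, pt$start_month[i], pt$start_day[i]))
  to <- as.Date(sprintf("%d-%02d-%02d", year, pt$end_month[i], pt$end_day[i]))
  from + sample.int(as.integer(to - from) + 1L, n, replace = TRUE) - 1L
}

#' Simulate a full study scenario
#'
#' Generates everything the pipeline consumes: a landscape stack, per-
#' individual accelerometer series and GPS tracks (track states derived from
#' the simulated activity series so movement and activity agree), and scat
#' tables for both species and all three periods.
#'
#' @param scenario A [synthetic_scenario()].
#' @param geom A [grid_geometry()] for the landscape.
#' @param n_fixes Fixes per individual.
#' @param scats_per_cell Scats per species x period.
#' @param start Start timestamp of collar deployment.
#' @return List with `landscape`, `tracks`, `activity`, `truth`, `scats`.
#' @export
simulate_scenario <- function(scenario = synthetic_scenario(),
                              geom = grid_geometry(n_rows = 40L, n_cols = 40L),
                              n_fixes = 400L, scats_per_cell = 60L,
                              start = paste0(scenario$year, "-05-01 00:00:00")) {
  landscape <- generate_landscape(geom, seed = scenario$rng_seed)
  span_x <- geom$n_cols * geom$cell
  span_y <- geom$n_rows * geom$cell
  ids <- c(
    if (scenario$n_wolves > 0) sprintf("W%02d", seq_len(scenario$n_wolves)),
    if (scenario$n_coyotes > 0) sprintf("C%02d", seq_len(scenario$n_coyotes))
  )
  species <- c(
    rep("wolf", scenario$n_wolves), rep("coyote", scenario$n_coyotes)
  )
  n_act <- ceiling(n_fixes * 15 / 5) + 1L
  sims <- purrr::map(seq_along(ids), function(i) {
    s <- scenario$rng_seed + i * 101L
    act <- simulate_activity(scenario, ids[i], species[i], start, n_act,
                             seed = s)
    # per-fix state = state of containing 5-min interval
    fix_times <- as.POSIXct(start, tz = "UTC") + (seq_len(n_fixes) - 1L) * 15 * 60
    idx <- pmin(
      floor(as.numeric(fix_times - act$interval_start[1], units = "mins") / 5) + 1L,
      n_act
    )
    st <- act$true_state[idx]
    origin <- c(
      landscape$geom$origin_x + stats::runif(1, 0.25, 0.75) * span_x,
      landscape$geom$origin_y + stats::runif(1, 0.25, 0.75) * span_y
    )
    tr <- simulate_track(scenario, ids[i], species[i], start, n_fixes,
                         states = st, origin = origin, seed = s + 1L)
    list(activity = act, track = tr$track, truth = tr$truth)
  })
  scats <- purrr::map2_dfr(
    rep(c("wolf", "coyote"), each = 3L),
    rep(c("PPP", "LMP", "SMP"), times = 2L),
    function(sp, pd) {
      simulate_scats(scenario, sp, pd, scats_per_cell,
                     seed = scenario$rng_seed + match(pd, c("PPP", "LMP", "SMP")) +
                       10L * (sp == "wolf"))
    }
  )
  list(
    landscape = landscape,
    tracks = purrr::map_dfr(sims, "track"),
    activity = purrr::map_dfr(sims, "activity") |>
      dplyr::select(-"true_state"),
    truth = purrr::map_dfr(seq_along(sims), function(i) {
      dplyr::mutate(sims[[i]]$truth, id = ids[i], .before = 1)
    }),
    scats = scats
  )
}
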