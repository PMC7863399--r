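#' Study configuration
#'
#' Bundles every scalar setting of the analysis: the accelerometer activity
#' threshold, collar fix and activity-interval cadences, the analysis grid
#' resolution, occurrence-distribution contour level, dynamic Brownian bridge
#' window and margin, the VHF maximum time lag, the covariate-screening
#' correlation cutoff, cross-validation bin count, significance level, and the
#' minimum location counts for adult and fawn deer.
#'
#' Defaults are the study settings: individuals are considered active when the
#' summed accelerometer reading over a 5-min interval is at least 30.7
#' (unitless gravitational acceleration); GPS fixes every 15 min; a 30 x 30 m
#' grid; the 99% occurrence distribution as the availability boundary; a
#' dynamic Brownian bridge window of 23 locations with a margin of 5; a 48-hr
#' maximum lag for VHF motion-variance estimation; covariate pairs with
#' |r| > 0.7 screened; eight cross-validation bins; alpha = 0.05; adult deer
#' retained with >= 20 locations and fawns with >= 5.
#'
#' @param activity_threshold Summed acceleration at or above which a 5-min
#'   interval counts as active (unitless).
#' @param fix_interval GPS fix cadence, minutes.
#' @param activity_interval Accelerometer summary cadence, minutes.
#' @param grid_cell Analysis grid cell side, meters.
#' @param od_level Occurrence-distribution contour level, fraction in (0, 1).
#' @param dbbmm_window Sliding-window length for dynamic motion-variance
#'   estimation, in fixes (odd).
#' @param dbbmm_margin Minimum distance of a candidate breakpoint from either
#'   window edge, in fixes.
#' @param vhf_max_lag Maximum time between successive VHF fixes for a segment
#'   to inform motion variance or the occurrence distribution, hours.
#' @param correlation_cutoff Absolute Pearson correlation above which one of a
#'   covariate pair is dropped.
#' @param cv_bins Number of equal-count bins in cross-validation, >= 2.
#' @param alpha Significance level for population-level inference.
#' @param min_locs_adult,min_locs_fawn Minimum location counts for adult and
#'   fawn deer inclusion.
#' @param covariate_priority Character vector of covariate names ordered from
#'   most to least ecologically relevant, used to resolve screening conflicts.
#' @param quadrature_steps Time steps per segment when integrating the bridge
#'   density.
#' @param rng_seed Integer seed echoed into outputs.
#'
#' @return A `study_config` object (a named list).
#' @export
#' @examples
#' cfg <- study_config()
#' cfg$activity_threshold
study_config <- function(activity_threshold = 30.7,
                         fix_interval = 15,
                         activity_interval = 5,
                         grid_cell = 30,
                         od_level = 0.99,
                         dbbmm_window = 23,
                         dbbmm_margin = 5,
                         vhf_max_lag = 48,
                         correlation_cutoff = 0.7,
                         cv_bins = 8,
                         alpha = 0.05,
                         min_locs_adult = 20,
                         min_locs_fawn = 5,
                         covariate_priority = c(
                           "deer_adult_occ", "deer_fawn_occ", "hare_density",
                           "grouse_density", "wolf_occ", "dist_road",
                           "dist_water", "dist_edge", "patch_size"
                         ),
                         quadrature_steps = 10,
                         rng_seed = 1L) {
  cfg <- list(
    activity_threshold = activity_threshold,
    fix_interval = fix_interval,
    activity_interval = activity_interval,
    grid_cell = grid_cell,
    od_level = od_level,
    dbbmm_window = as.integer(dbbmm_window),
    dbbmm_margin = as.integer(dbbmm_margin),
    vhf_max_lag = vhf_max_lag,
    correlation_cutoff = correlation_cutoff,
    cv_bins = as.integer(cv_bins),
    alpha = alpha,
    min_locs_adult = as.integer(min_locs_adult),
    min_locs_fawn = as.integer(min_locs_fawn),
    covariate_priority = covariate_priority,
    quadrature_steps = as.integer(quadrature_steps),
    rng_seed = as.integer(rng_seed)
  )
  class(cfg) <- "study_config"
  validate_study_config(cfg)
}

validate_study_config <- function(cfg) {
  pos <- c(
    "activity_threshold", "fix_interval", "activity_interval", "grid_cell",
    "vhf_max_lag", "correlation_cutoff", "alpha", "min_locs_adult",
    "min_locs_fawn", "quadrature_steps"
  )
  for (nm in pos) {
    if (!is.numeric(cfg[[nm]]) || length(cfg[[nm]]) != 1L || cfg[[nm]] <= 0) {
      stop("`", nm, "` must be a single positive number", call. = FALSE)
    }
  }
  if (cfg$od_level <= 0 || cfg$od_level >= 1) {
    stop("`od_level` must lie strictly between 0 and 1", call. = FALSE)
  }
  if (cfg$dbbmm_margin >= cfg$dbbmm_window) {
    stop("`dbbmm_margin` must be smaller than `dbbmm_window`", call. = FALSE)
  }
  if (cfg$dbbmm_window < 2L * cfg$dbbmm_margin + 3L) {
    stop("`dbbmm_window` must be at least 2 * dbbmm_margin + 3", call. = FALSE)
  }
  if (cfg$cv_bins < 2L) stop("`cv_bins` must be >= 2", call. = FALSE)
  cfg
}

#' @export
print.study_config <- function(x, ...) {
  cat("<study_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-20s %s\n", nm, paste(format(x[[nm]]), collapse = ", ")))
  }
  invisible(x)
}

# Study-period calendar (inclusive month-day bounds, year ignored).
period_table <- function() {
  tibble::tibble(
    label = c("PPP", "LMP", "SMP"),
    start_month = c(5L, 5L, 7L), start_day = c(1L, 27L, 1L),
    end_month = c(5L, 6L, 8L), end_day = c(26L, 30L, 31L)
  )
}

#' Assign study periods to dates
#'
#' Maps calendar dates to the three fawn-availability periods: the deer
#' preparturition period (PPP, May 1 - May 26), the fawn limited-mobility
#' period (LMP, May 27 - June 30), and the fawn social-mobility period
#' (SMP, July 1 - August 31). Both boundaries are inclusive; the year is
#' ignored. Dates outside May 1 - August 31 map to `NA`.
#'
#' @param date A `Date` vector, or anything `as.Date()` accepts.
#' @return A character vector of `"PPP"`, `"LMP"`, `"SMP"`, or `NA`.
#' @export
#' @examples
#' assign_period(as.Date(c("2014-05-26", "2014-05-27", "2014-09-01")))
assign_period <- function(date) {
  date <- tryCatch(as.Date(date), error = function(e) {
    stop("`date` could not be parsed as a calendar date", call. = FALSE)
  })
  if (anyNA(date) && !all(is.na(date))) {
    # propagate NA dates as NA periods, parse failures already errored
  }
  md <- as.integer(format(date, "%m")) * 100L + as.integer(format(date, "%d"))
  out <- rep(NA_character_, length(date))
  out[md >= 501L & md <= 526L] <- "PPP"
  out[md >= 527L & md <= 630L] <- "LMP"
  out[md >= 701L & md <= 831L] <- "SMP"
  out
}

#' Apply location-count inclusion filters
#'
#' Deer are retained only with enough locations: adults need at least
#' `min_locs_adult` fixes and fawns at least `min_locs_fawn` (fawns face
#' higher early mortality, so requiring adult-level counts would bias the
#' population average toward survivors). Wolves and coyotes are never
#' count-filtered; their inclusion is driven by collar data recovery.
#'
#' @param tracks A tibble of fixes with at least `id` and `species` columns
#'   (`species` in `wolf`, `coyote`, `deer_adult`, `deer_fawn`).
#' @param config A [study_config()].
#' @return The filtered tibble, same columns.
#' @export
filter_individuals <- function(tracks, config = study_config()) {
  stopifnot(is.data.frame(tracks))
  if (nrow(tracks) == 0L) return(dplyr::as_tibble(tracks))
  tracks |>
    dplyr::group_by(.data$id, .data$species) |>
    dplyr::filter(
      (.data$species[1] == "deer_adult" && dplyr::n() >= config$min_locs_adult) ||
        (.data$species[1] == "deer_fawn" && dplyr::n() >= config$min_locs_fawn) ||
        .data$species[1] %in% c("wolf", "coyote")
    ) |>
    dplyr::ungroup()
}
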