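#' @section Brownian bridge movement models:
#' The occurrence distribution (OD) of a tracked animal conditions a Brownian
#' motion on the observed fixes: between consecutive fixes z0 (time t0) and z1
#' (time t1) the animal's position at fractional time `a` is bivariate normal
#' with mean `z0 + a (z1 - z0)` and per-axis variance
#' `T a (1 - a) sigma_m^2 + ((1 - a) d0)^2 + (a d1)^2`, where `T = t1 - t0`,
#' `sigma_m^2` is the Brownian motion variance (m^2/min) and d0, d1 are the
#' fixes' location-error SDs. The motion variance is estimated by maximizing
#' the leave-one-out likelihood of each interior fix under the bridge spanned
#' by its neighbors; the dynamic model lets `sigma_m^2` vary along the path
#' via windowed breakpoint detection.
#' @name movement-models
#' @keywords internal
NULL

# Per-triple quantities for the leave-one-out Brownian bridge likelihood.
# Each interior fix z_i is predicted from its neighbors: mean
# z_{i-1} + a (z_{i+1} - z_{i-1}), per-axis variance
# T a(1-a) sigma + (1-a)^2 d0^2 + a^2 d1^2 + dm^2
# (bridge diffusion, endpoint location errors, and the observed middle fix's
# own location error; omitting dm^2 inflates sigma by dm^2 / (T a(1-a))).
loo_triples <- function(track, max_lag_min = Inf) {
  n <- nrow(track)
  if (n < 3L) stop("need at least 3 fixes to estimate motion variance")
  t_min <- as.numeric(track$timestamp, units = "secs") / 60
  if (any(diff(t_min) <= 0)) stop("timestamps must be strictly increasing")
  # alternate interior fixes only, so triples share no fixes and the
  # leave-one-out residuals are independent (a correlated all-fixes scheme
  # badly miscalibrates the windowed model comparison)
  i <- seq(2L, n - 1L, by = 2L)
  T_span <- t_min[i + 1L] - t_min[i - 1L]
  a <- (t_min[i] - t_min[i - 1L]) / T_span
  keep <- T_span <= max_lag_min
  if (!any(keep)) stop("all fix triples exceed max_lag; cannot estimate motion variance")
  d0 <- track$error_sd[i - 1L]
  dm <- track$error_sd[i]
  d1 <- track$error_sd[i + 1L]
  rx <- track$x[i] - (track$x[i - 1L] + a * (track$x[i + 1L] - track$x[i - 1L]))
  ry <- track$y[i] - (track$y[i - 1L] + a * (track$y[i + 1L] - track$y[i - 1L]))
  tibble::tibble(
    mid = i,
    Ta = (T_span * a * (1 - a))[seq_along(i)],
    err = ((1 - a)^2 * d0^2 + a^2 * d1^2 + dm^2),
    r2 = rx^2 + ry^2
  )[keep, ]
}

# Negative log-likelihood of sigma_m^2 over prepared triples (both axes).
bb_negloglik <- function(sigma, triples) {
  s <- triples$Ta * sigma + triples$err
  if (any(s <= 0)) return(Inf)
  sum(log(2 * pi * s) + triples$r2 / (2 * s))
}

sigma_bounds <- function() c(1e-6, 1e3)

fit_sigma_triples <- function(triples) {
  b <- sigma_bounds()
  opt <- stats::optimize(
    function(ls) bb_negloglik(exp(ls), triples),
    interval = log(b), tol = 1e-8
  )
  exp(opt$minimum)
}

#' Estimate static Brownian motion variance
#'
#' Maximizes the leave-one-out Brownian bridge likelihood: each interior fix
#' is treated as an observation of the bridge spanned by its two neighbors,
#' and the motion variance sigma_m^2 (m^2/min) maximizing the joint normal
#' likelihood is found by bounded one-dimensional optimization. Triples whose
#' time span exceeds `max_lag` are excluded so that only related movements
#' inform the estimate.
#'
#' @param track Tibble with `timestamp` (POSIXct, strictly increasing),
#'   `x`, `y` (projected meters), and `error_sd` (meters).
#' @param max_lag Maximum triple time span, hours.
#' @return Motion variance, m^2 per minute.
#' @export
fit_motion_variance <- function(track, max_lag = Inf) {
  tr <- loo_triples(track, max_lag_min = max_lag * 60)
  fit_sigma_triples(tr)
}

#' Estimate a dynamic motion-variance profile
#'
#' Slides a window of `window` fixes along the track one fix at a time. Within
#' each window a no-break model (one sigma_m^2) is compared against
#' single-break models at every interior position at least `margin` fixes from
#' either edge, using BIC on the window's leave-one-out likelihood. Each
#' inter-fix segment's motion variance is the mean of the estimates from all
#' windows covering it. Tracks shorter than the window fall back to the
#' static fit with a warning.
#'
#' @inheritParams fit_motion_variance
#' @param window Window length in fixes (odd, >= 2 * margin + 3).
#' @param margin Minimum distance of a break from either window edge, fixes.
#' @return A `motion_variance_profile`: tibble of per-segment sigma_m^2
#'   (length `n_fixes - 1`) with selected per-window breakpoints as a
#'   diagnostic attribute.
#' @export
fit_dynamic_motion_variance <- function(track, window = 23L, margin = 5L,
                                        max_lag = Inf) {
  window <- as.integer(window); margin <- as.integer(margin)
  if (window < 2L * margin + 3L) {
    stop("`window` must be at least 2 * margin + 3")
  }
  n <- nrow(track)
  t_min <- as.numeric(track$timestamp, units = "secs") / 60
  if (n < window) {
    warning("track shorter than window (", n, " < ", window,
            "); falling back to static motion variance")
    sig <- fit_motion_variance(track, max_lag)
    return(new_mv_profile(rep(sig, n - 1L), t_min, integer(0)))
  }
  triples <- loo_triples(track, max_lag_min = max_lag * 60)
  seg_sum <- numeric(n - 1L)
  seg_n <- numeric(n - 1L)
  breakpoints <- integer(0)
  for (s in seq_len(n - window + 1L)) {
    hi <- s + window - 1L
    w <- triples[triples$mid > s & triples$mid < hi, ]
    if (nrow(w) < 3L) next
    m_obs <- 2L * nrow(w)  # two axes per triple
    # estimates are trusted only for segments >= margin fixes from the
    # window edges; both fixes of segment j are interior when
    # s + margin <= j and j + 1 <= hi - margin
    idx <- (s + margin):(hi - margin - 1L)
    sig0 <- fit_sigma_triples(w)
    # no-break model: one parameter (sigma); break model: three (two sigmas
    # and the estimated break position)
    bic0 <- 2 * bb_negloglik(sig0, w) + log(m_obs)
    best <- list(bic = bic0, brk = NA_integer_, sig = rep(sig0, length(idx)))
    cand <- (s + margin):(hi - margin)
    for (b in cand) {
      left <- w[w$mid < b, ]
      right <- w[w$mid >= b, ]
      if (nrow(left) < 2L || nrow(right) < 2L) next
      sl <- fit_sigma_triples(left)
      sr <- fit_sigma_triples(right)
      bic <- 2 * (bb_negloglik(sl, left) + bb_negloglik(sr, right)) +
        3 * log(m_obs)
      if (bic < best$bic) {
        best <- list(bic = bic, brk = b, sig = ifelse(idx < b, sl, sr))
      }
    }
    if (!is.na(best$brk)) breakpoints <- c(breakpoints, best$brk)
    seg_sum[idx] <- seg_sum[idx] + best$sig
    seg_n[idx] <- seg_n[idx] + 1
  }
  if (all(seg_n == 0)) {
    sig <- fit_motion_variance(track, max_lag)
    return(new_mv_profile(rep(sig, n - 1L), t_min, integer(0)))
  }
  # segments never covered (possible only at extreme ends) take the nearest
  # covered estimate
  prof <- seg_sum / pmax(seg_n, 1)
  if (any(seg_n == 0)) {
    covered <- which(seg_n > 0)
    for (i in which(seg_n == 0)) {
      prof[i] <- prof[covered[which.min(abs(covered - i))]]
    }
  }
  new_mv_profile(prof, t_min, breakpoints)
}

new_mv_profile <- function(sigma, t_min, breakpoints) {
  structure(
    tibble::tibble(
      segment = seq_along(sigma),
      t_start = t_min[seq_along(sigma)],
      t_end = t_min[seq_along(sigma) + 1L],
      sigma_m2 = sigma
    ),
    breakpoints = breakpoints,
    class = c("motion_variance_profile", class(tibble::tibble()))
  )
}

#' Locate the dominant behavioral breakpoint of a dynamic profile
#'
#' Returns `NA` when no sliding window preferred a break model. Otherwise the
#' break position is estimated from the profile by a rank-CUSUM changepoint:
#' per-segment variances are rank-transformed (individual estimates are
#' heavy-tailed, especially where measurement error dominates the diffusion
#' signal) and the break is placed where the cumulative sum of centered ranks
#' peaks — the least-squares single-changepoint estimator on ranks. The raw
#' per-window break positions remain available as the profile's
#' `breakpoints` attribute.
#'
#' @param profile A `motion_variance_profile`.
#' @return Fix index (numeric) or `NA`.
#' @export
profile_breakpoint <- function(profile) {
  bp <- attr(profile, "breakpoints")
  if (length(bp) == 0L) return(NA_real_)
  r <- rank(profile$sigma_m2)
  cs <- cumsum(r - mean(r))
  # |CUSUM| peaks at the last segment of the first regime; the change takes
  # effect at the following fix
  which.max(abs(cs)) + 1L
}

# Gauss-Legendre nodes and weights on [0, 1] (Golub-Welsch on the Jacobi
# matrix); the bridge cell-mass integrand is smooth in fractional time, so a
# handful of nodes integrates it essentially exactly.
gauss_legendre_01 <- function(n) {
  if (n == 1L) return(list(nodes = 0.5, weights = 1))
  i <- seq_len(n - 1L)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1L)] <- b
  J[cbind(i + 1L, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(
    nodes = (e$values[ord] + 1) / 2,
    weights = (2 * e$vectors[1, ord]^2) / 2
  )
}

# Accumulate the time-integrated bridge density of one segment onto the grid.
# Separable over axes: the probability mass falling in each cell is the
# product of 1-D normal CDF differences across the cell edges.
accumulate_segment <- function(height_mat, geom, z0, z1, T_min, sigma,
                               d0, d1, n_steps, method) {
  gl <- gauss_legendre_01(n_steps)
  a <- gl$nodes
  w <- T_min * gl$weights
  xs <- geom$origin_x + geom$cell * (0:geom$n_cols)
  ys <- geom$origin_y + geom$cell * (0:geom$n_rows)
  for (k in seq_len(n_steps)) {
    mu_x <- z0[1] + a[k] * (z1[1] - z0[1])
    mu_y <- z0[2] + a[k] * (z1[2] - z0[2])
    v <- T_min * a[k] * (1 - a[k]) * sigma +
      ((1 - a[k]) * d0)^2 + (a[k] * d1)^2
    sd <- sqrt(v)
    if (sd < 1e-9) {
      ci <- min(max(floor((mu_x - geom$origin_x) / geom$cell) + 1L, 1L),
                geom$n_cols)
      ri <- min(max(floor((mu_y - geom$origin_y) / geom$cell) + 1L, 1L),
                geom$n_rows)
      height_mat[ri, ci] <- height_mat[ri, ci] + w[k]
      next
    }
    # restrict to cells within 6 SD of the mean
    lo_c <- max(1L, floor((mu_x - 6 * sd - geom$origin_x) / geom$cell) + 1L)
    hi_c <- min(geom$n_cols, ceiling((mu_x + 6 * sd - geom$origin_x) / geom$cell))
    lo_r <- max(1L, floor((mu_y - 6 * sd - geom$origin_y) / geom$cell) + 1L)
    hi_r <- min(geom$n_rows, ceiling((mu_y + 6 * sd - geom$origin_y) / geom$cell))
    if (lo_c > hi_c || lo_r > hi_r) next
    if (method == "integrate") {
      px <- diff(stats::pnorm(xs[lo_c:(hi_c + 1L)], mu_x, sd))
      py <- diff(stats::pnorm(ys[lo_r:(hi_r + 1L)], mu_y, sd))
    } else {
      cx <- geom$origin_x + (lo_c:hi_c - 0.5) * geom$cell
      cy <- geom$origin_y + (lo_r:hi_r - 0.5) * geom$cell
      px <- stats::dnorm(cx, mu_x, sd) * geom$cell
      py <- stats::dnorm(cy, mu_y, sd) * geom$cell
    }
    height_mat[lo_r:hi_r, lo_c:hi_c] <-
      height_mat[lo_r:hi_r, lo_c:hi_c] + w[k] * (py %o% px)
  }
  height_mat
}

#' Gridded occurrence distribution from a fitted bridge model
#'
#' Accumulates the time-integrated Brownian bridge density of every retained
#' segment onto the analysis grid and normalizes heights to sum to one. When
#' an activity-state filter is requested, a segment is retained only if both
#' endpoint fixes carry that state (mixed segments are dropped). Each
#' segment's bridge is integrated over fractional time by Gauss-Legendre
#' quadrature with `quadrature_steps` nodes; cell masses are exact normal-CDF
#' integrals over cell rectangles by default.
#'
#' @param track Fix tibble (`timestamp, x, y, error_sd`, optionally `state`).
#' @param profile A `motion_variance_profile` aligned to the track, or a
#'   single motion variance recycled over segments.
#' @param geom A [grid_geometry()] covering the track (see [od_grid()]).
#' @param state Optional `"active"` or `"inactive"` segment filter.
#' @param level Contour level for the availability mask.
#' @param quadrature_steps Time steps per segment.
#' @param max_lag Segments longer than this many hours are skipped.
#' @param method `"integrate"` (cell-integrated normal mass, default) or
#'   `"center"` (density at the cell center times cell area).
#' @param meta Named list stored on the result (individual, species, period,
#'   state).
#' @return An `occurrence_dist`: grid geometry, per-cell `height` summing to
#'   1, and the `level`-contour `mask`.
#' @export
occurrence_distribution <- function(track, profile, geom, state = NULL,
                                    level = 0.99, quadrature_steps = 10L,
                                    max_lag = Inf, method = c("integrate", "center"),
                                    meta = list()) {
  method <- match.arg(method)
  n <- nrow(track)
  sigma <- if (inherits(profile, "motion_variance_profile")) {
    stopifnot(nrow(profile) == n - 1L)
    profile$sigma_m2
  } else {
    rep(profile, n - 1L)
  }
  t_min <- as.numeric(track$timestamp, units = "secs") / 60
  keep <- rep(TRUE, n - 1L)
  if (!is.null(state)) {
    if (!"state" %in% names(track)) {
      stop("track has no `state` column to filter on")
    }
    keep <- track$state[-n] == state & track$state[-1L] == state
  }
  keep <- keep & (diff(t_min) <= max_lag * 60)
  if (!any(keep)) {
    stop(
      "no segments retained",
      if (length(meta)) paste0(
        " for ", paste(unlist(meta), collapse = "/")
      ) else "",
      if (!is.null(state)) paste0(" in state '", state, "'") else ""
    )
  }
  h <- matrix(0, geom$n_rows, geom$n_cols)
  for (i in which(keep)) {
    h <- accumulate_segment(
      h, geom,
      z0 = c(track$x[i], track$y[i]), z1 = c(track$x[i + 1L], track$y[i + 1L]),
      T_min = t_min[i + 1L] - t_min[i], sigma = sigma[i],
      d0 = track$error_sd[i], d1 = track$error_sd[i + 1L],
      n_steps = quadrature_steps, method = method
    )
  }
  height <- as.vector(h) / sum(h)
  od <- structure(
    list(geom = geom, height = height, mask = NULL, level = level, meta = meta),
    class = "occurrence_dist"
  )
  od$mask <- od_contour(od, level)
  od
}

#' Contour mask of an occurrence distribution
#'
#' The smallest set of cells whose summed height reaches `level`: cells are
#' sorted by height descending and included until the cumulative height is at
#' least `level`; all cells tied with the threshold height are included.
#'
#' @param od An `occurrence_dist`.
#' @param level Fraction in (0, 1].
#' @return Logical vector, one element per cell.
#' @export
od_contour <- function(od, level = od$level) {
  h <- od$height
  ord <- order(h, decreasing = TRUE)
  cum <- cumsum(h[ord])
  k <- which(cum >= level - 1e-12)[1]
  if (is.na(k)) k <- length(h)
  thr <- h[ord[k]]
  h >= thr & h > 0
}

#' VHF occurrence distribution (static Brownian bridge)
#'
#' For sparse triangulated relocations: a single motion variance is estimated
#' from the whole track (triples spanning more than `max_lag` hours excluded),
#' and segments longer than `max_lag` contribute nothing to the occurrence
#' distribution. No activity-state filtering is applied.
#'
#' @inheritParams occurrence_distribution
#' @param max_lag Maximum segment (and triple) span, hours; default 48.
#' @return An `occurrence_dist`.
#' @export
fit_vhf_od <- function(track, geom, max_lag = 48, level = 0.99,
                       quadrature_steps = 10L, meta = list()) {
  sigma <- fit_motion_variance(track, max_lag = max_lag)
  occurrence_distribution(
    track, sigma, geom,
    state = NULL, level = level, quadrature_steps = quadrature_steps,
    max_lag = max_lag, meta = meta
  )
}

#' Analysis grid for a track
#'
#' A grid aligned to `cell` covering the track's bounding box plus a buffer of
#' three times the 99th percentile of the bridge SD (so that effectively all
#' occurrence mass falls inside).
#'
#' @param track Fix tibble.
#' @param profile Motion-variance profile or scalar, m^2/min.
#' @param cell Cell size, meters.
#' @return A [grid_geometry()].
#' @export
od_grid <- function(track, profile, cell = 30) {
  n <- nrow(track)
  sigma <- if (inherits(profile, "motion_variance_profile")) {
    profile$sigma_m2
  } else {
    rep(profile, max(n - 1L, 1L))
  }
  t_min <- as.numeric(track$timestamp, units = "secs") / 60
  T_seg <- diff(t_min)
  sd_mid <- sqrt(T_seg * 0.25 * sigma +
                   0.5 * (track$error_sd[-n]^2 + track$error_sd[-1L]^2))
  buffer <- 3 * stats::quantile(sd_mid, 0.99, names = FALSE) + cell
  x0 <- floor((min(track$x) - buffer) / cell) * cell
  y0 <- floor((min(track$y) - buffer) / cell) * cell
  x1 <- ceiling((max(track$x) + buffer) / cell) * cell
  y1 <- ceiling((max(track$y) + buffer) / cell) * cell
  grid_geometry(
    origin_x = x0, origin_y = y0, cell = cell,
    n_rows = round((y1 - y0) / cell), n_cols = round((x1 - x0) / cell)
  )
}

#' @export
print.occurrence_dist <- function(x, ...) {
  cat(sprintf(
    "<occurrence_dist> %d x %d cells of %g m; %.0f%% mask: %d cells",
    x$geom$n_rows, x$geom$n_cols, x$geom$cell, 100 * x$level, sum(x$mask)
  ))
  if (length(x$meta)) {
    cat(" [", paste(names(x$meta), unlist(x$meta), sep = "=", collapse = ", "),
        "]", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' @rdname tidy_sympatric
#' @export
tidy.occurrence_dist <- function(x, ...) {
  cells <- grid_cells(x$geom)
  cells$height <- x$height
  cells$in_mask <- x$mask
  cells
}
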