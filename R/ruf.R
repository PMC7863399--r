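#' Screen correlated covariates
#'
#' Computes Pearson correlations between all continuous covariate pairs (over
#' masked cells when a mask is given) and, for every pair with |r| strictly
#' above the cutoff, drops the covariate lower in the priority order.
#' Categorical land cover is always retained.
#'
#' @param stack A `landscape_stack`.
#' @param cutoff Absolute correlation cutoff (pairs at exactly the cutoff are
#'   both kept).
#' @param priority Covariate names ordered from most to least ecologically
#'   relevant.
#' @param covariates Continuous covariates to consider; defaults to all
#'   continuous layers present in the stack.
#' @param mask Optional logical per-cell vector restricting the correlation
#'   computation.
#' @return Character vector of retained continuous covariates (priority
#'   order preserved as in `covariates`).
#' @export
screen_covariates <- function(stack, cutoff = 0.7,
                              priority = study_config()$covariate_priority,
                              covariates = NULL, mask = NULL) {
  cells <- stack$cells
  if (!is.null(mask)) cells <- cells[mask, , drop = FALSE]
  if (is.null(covariates)) {
    covariates <- intersect(continuous_layers(), names(cells))
  }
  if (length(covariates) < 2L) return(covariates)
  retained <- covariates
  repeat {
    cm <- stats::cor(as.matrix(cells[retained]))
    diag(cm) <- 0
    cm[is.na(cm)] <- 0
    worst <- which(abs(cm) == max(abs(cm)), arr.ind = TRUE)[1, ]
    # strict inequality at the cutoff, with an epsilon so that a pair whose
    # correlation is exactly the cutoff up to floating point is kept
    if (max(abs(cm)) <= cutoff + 1e-9) break
    pair <- retained[worst]
    ranks <- match(pair, priority)
    if (anyNA(ranks)) {
      stop("covariate(s) ", paste(pair[is.na(ranks)], collapse = ", "),
           " involved in a correlation conflict but missing from the ",
           "priority order")
    }
    drop <- pair[which.max(ranks)]
    retained <- setdiff(retained, drop)
    if (length(retained) < 2L) break
  }
  retained
}

# Design matrix for a RUF: z-scored continuous covariates over the used cells
# plus land-cover dummies with deciduous as the reference. Returns the matrix
# and the scaling used (for unstandardizing coefficients).
ruf_design <- function(cells, covariates, reference = "deciduous") {
  keep <- covariates
  mu <- vapply(keep, function(v) mean(cells[[v]]), numeric(1))
  sd <- vapply(keep, function(v) stats::sd(cells[[v]]), numeric(1))
  const <- keep[sd == 0 | is.na(sd)]
  if (length(const)) {
    warning("dropping constant covariate(s): ", paste(const, collapse = ", "))
    keep <- setdiff(keep, const)
  }
  X <- vapply(keep, function(v) (cells[[v]] - mu[v]) / sd[v],
              numeric(nrow(cells)))
  X <- matrix(X, nrow = nrow(cells), dimnames = list(NULL, keep))
  dummies <- NULL
  if ("land_cover" %in% names(cells)) {
    lv <- setdiff(intersect(land_cover_classes(), unique(cells$land_cover)),
                  reference)
    if (length(lv)) {
      dummies <- vapply(lv, function(cl) as.numeric(cells$land_cover == cl),
                        numeric(nrow(cells)))
      dummies <- matrix(dummies, nrow = nrow(cells),
                        dimnames = list(NULL, paste0("land_cover_", lv)))
    }
  }
  list(X = cbind(X, dummies), mu = mu[keep], sd = sd[keep],
       continuous = keep,
       dummies = if (is.null(dummies)) character(0) else colnames(dummies))
}

#' Fit an individual resource utilization function
#'
#' Ordinary least squares of occurrence-distribution height on landscape and
#' prey covariates over the cells inside the OD's availability contour.
#' Continuous covariates are z-scored over those cells (so standardized
#' coefficients are comparable across individuals before population
#' averaging); land cover is dummy-coded against a deciduous reference.
#' Rank-deficient dummies are dropped with a warning.
#'
#' @param od An `occurrence_dist` sharing the stack's grid.
#' @param stack A `landscape_stack` with all covariate layers.
#' @param covariates Retained continuous covariate names (see
#'   [screen_covariates()]).
#' @param reference Land-cover reference class.
#' @return A `ruf_fit`: coefficient tibble (`term`, standardized and
#'   unstandardized `estimate`/`std.error`) plus metadata (`meta`,
#'   `n_cells`, scaling).
#' @export
fit_individual_ruf <- function(od, stack, covariates,
                               reference = "deciduous") {
  stopifnot(inherits(od, "occurrence_dist"),
            inherits(stack, "landscape_stack"))
  if (length(od$height) != nrow(stack$cells)) {
    stop("occurrence distribution and landscape stack grids differ")
  }
  use <- od$mask
  cells <- stack$cells[use, , drop = FALSE]
  des <- ruf_design(cells, covariates, reference)
  if (nrow(cells) <= ncol(des$X) + 1L) {
    stop("fewer in-mask cells than model parameters")
  }
  y <- od$height[use]
  df <- data.frame(.y = y, des$X, check.names = FALSE)
  fit <- stats::lm(.y ~ ., data = df)
  cf <- stats::coef(fit)
  dropped <- names(cf)[is.na(cf)]
  if (length(dropped)) {
    warning("dropping rank-deficient term(s): ",
            paste(gsub("`", "", dropped), collapse = ", "))
  }
  sm <- summary(fit)$coefficients
  terms <- gsub("`", "", rownames(sm))
  terms[terms == "(Intercept)"] <- "intercept"
  est <- sm[, 1]; se <- sm[, 2]
  # back-transform to the raw covariate scale: beta_raw = beta_std / sd(x),
  # intercept_raw = b0 - sum(beta_std * mu / sd)
  est_raw <- est; se_raw <- se
  for (v in des$continuous) {
    j <- which(terms == v)
    if (length(j)) {
      est_raw[j] <- est[j] / des$sd[v]
      se_raw[j] <- se[j] / des$sd[v]
    }
  }
  j0 <- which(terms == "intercept")
  present <- intersect(des$continuous, terms)
  est_raw[j0] <- est[j0] -
    sum(est[match(present, terms)] * des$mu[present] / des$sd[present])
  structure(
    list(
      coefficients = tibble::tibble(
        term = terms,
        estimate_std = unname(est), std_error_std = unname(se),
        estimate_raw = unname(est_raw), std_error_raw = unname(se_raw)
      ),
      n_cells = nrow(cells),
      covariates = covariates,
      dummies = des$dummies,
      r_squared = summary(fit)$r.squared,
      meta = od$meta
    ),
    class = "ruf_fit"
  )
}

#' @export
print.ruf_fit <- function(x, ...) {
  cat("<ruf_fit>", if (length(x$meta)) paste(unlist(x$meta), collapse = "/"),
      sprintf("(%d cells, R^2 = %.3f)\n", x$n_cells, x$r_squared))
  print(x$coefficients)
  invisible(x)
}

#' @rdname tidy_sympatric
#' @export
tidy.ruf_fit <- function(x, scale = c("standardized", "raw"), ...) {
  scale <- match.arg(scale)
  cf <- x$coefficients
  out <- if (scale == "standardized") {
    dplyr::transmute(cf, term = .data$term, estimate = .data$estimate_std,
                     std.error = .data$std_error_std)
  } else {
    dplyr::transmute(cf, term = .data$term, estimate = .data$estimate_raw,
                     std.error = .data$std_error_raw)
  }
  for (nm in names(x$meta)) out[[nm]] <- x$meta[[nm]]
  out
}

#' @rdname glance_sympatric
#' @export
glance.ruf_fit <- function(x, ...) {
  tibble::tibble(n_cells = x$n_cells, r_squared = x$r_squared,
                 n_terms = nrow(x$coefficients))
}

#' Population-level resource utilization function
#'
#' Averages individual RUF coefficients: the population coefficient is the
#' mean over individuals, and its variance is the between-individual sample
#' variance (denominator n - 1), capturing both intra- and inter-individual
#' variation. Confidence intervals and p-values use the t distribution with
#' n - 1 degrees of freedom.
#'
#' @param fits List of `ruf_fit` objects (>= 2) sharing a covariate set.
#' @param alpha Significance level for the confidence intervals.
#' @param meta Named list describing species/period/state.
#' @return A `population_ruf` with a coefficient tibble (`term`, `mean_std`,
#'   `var_std`, `conf_low`, `conf_high`, `p_value`, and raw-scale means) and
#'   `n` individuals.
#' @export
population_ruf <- function(fits, alpha = 0.05, meta = list()) {
  n <- length(fits)
  if (n < 2L) stop("population averaging needs at least 2 individual fits")
  terms <- Reduce(intersect, lapply(fits, function(f) f$coefficients$term))
  if (length(terms) == 0L) stop("no common coefficients across fits")
  get <- function(f, col) {
    cf <- f$coefficients
    cf[[col]][match(terms, cf$term)]
  }
  B_std <- vapply(fits, get, numeric(length(terms)), col = "estimate_std")
  B_raw <- vapply(fits, get, numeric(length(terms)), col = "estimate_raw")
  B_std <- matrix(B_std, nrow = length(terms))
  B_raw <- matrix(B_raw, nrow = length(terms))
  mean_std <- rowMeans(B_std)
  var_std <- apply(B_std, 1, stats::var)
  se_mean <- sqrt(var_std / n)
  tq <- stats::qt(1 - alpha / 2, df = n - 1L)
  tstat <- ifelse(se_mean > 0, mean_std / se_mean, NA_real_)
  structure(
    list(
      coefficients = tibble::tibble(
        term = terms,
        mean_std = mean_std,
        var_std = var_std,
        se_mean = se_mean,
        conf_low = mean_std - tq * se_mean,
        conf_high = mean_std + tq * se_mean,
        statistic = tstat,
        p_value = 2 * stats::pt(-abs(tstat), df = n - 1L),
        mean_raw = rowMeans(B_raw)
      ),
      n = n, alpha = alpha, meta = meta
    ),
    class = "population_ruf"
  )
}

#' @export
print.population_ruf <- function(x, ...) {
  cat("<population_ruf>",
      if (length(x$meta)) paste(unlist(x$meta), collapse = "/"),
      sprintf("(n = %d, alpha = %g)\n", x$n, x$alpha))
  print(x$coefficients)
  invisible(x)
}

#' @rdname tidy_sympatric
#' @export
tidy.population_ruf <- function(x, ...) {
  out <- dplyr::transmute(
    x$coefficients,
    term = .data$term, estimate = .data$mean_std,
    std.error = .data$se_mean, statistic = .data$statistic,
    p.value = .data$p_value,
    conf.low = .data$conf_low, conf.high = .data$conf_high
  )
  for (nm in names(x$meta)) out[[nm]] <- x$meta[[nm]]
  out
}

#' @rdname glance_sympatric
#' @export
glance.population_ruf <- function(x, ...) {
  tibble::tibble(n = x$n, alpha = x$alpha, n_terms = nrow(x$coefficients))
}

#' Predict a relative-use surface from a population RUF
#'
#' Evaluates the linear predictor per grid cell from the unstandardized
#' population-mean coefficients, then min-max rescales to \[0, 1\] as a
#' relative probability of use. The wolf surface produced this way enters
#' coyote RUFs as an avoidance covariate.
#'
#' @param popruf A `population_ruf`.
#' @param stack A `landscape_stack` with every model covariate layer.
#' @param reference Land-cover reference class.
#' @return Numeric vector of relative use, one value per cell, in \[0, 1\].
#' @export
predict_surface <- function(popruf, stack, reference = "deciduous") {
  cf <- popruf$coefficients
  cells <- stack$cells
  pred <- rep(0, nrow(cells))
  j0 <- cf$term == "intercept"
  if (any(j0)) pred <- pred + cf$mean_raw[j0]
  for (i in which(!j0)) {
    term <- cf$term[i]
    if (startsWith(term, "land_cover_")) {
      cl <- sub("^land_cover_", "", term)
      pred <- pred + cf$mean_raw[i] * (cells$land_cover == cl)
    } else {
      if (is.null(cells[[term]])) {
        stop("stack is missing model covariate layer '", term, "'")
      }
      pred <- pred + cf$mean_raw[i] * cells[[term]]
    }
  }
  rng <- range(pred)
  if (rng[1] == rng[2]) return(rep(0.5, length(pred)))
  (pred - rng[1]) / (rng[2] - rng[1])
}

#' Leave-one-individual-out cross-validation of population RUFs
#'
#' For each fold, one individual is withheld and the population RUF is rebuilt
#' from the rest; the rebuilt model predicts relative use over the grid; the
#' withheld individual's OD heights are paired with predictions on its in-mask
#' cells, sorted by predicted value, and split into `bins` groups of equal
#' cell counts (remainder cells to the last bin). Per bin, OD heights and
#' predictions are summed and the bin sums regressed on each other; the fold's
#' slope and R-squared are recorded and finally averaged. A positive average
#' slope with high R-squared indicates good predictive fit.
#'
#' @param ods Named list of `occurrence_dist` (one per individual) on the
#'   stack's grid.
#' @param stack A `landscape_stack`.
#' @param covariates Retained continuous covariates.
#' @param bins Number of equal-count bins (default 8).
#' @param fits Optional precomputed list of `ruf_fit` matching `ods`.
#' @param reference Land-cover reference class.
#' @return A `cv_result`: per-fold tibble (`id, slope, r_squared, n_cells`)
#'   and averaged `mean_slope`, `mean_r_squared`.
#' @export
loio_cv <- function(ods, stack, covariates, bins = 8L, fits = NULL,
                    reference = "deciduous") {
  if (length(ods) < 3L) stop("leave-one-out CV needs at least 3 individuals")
  if (is.null(fits)) {
    fits <- purrr::map(ods, fit_individual_ruf, stack = stack,
                       covariates = covariates, reference = reference)
  }
  folds <- purrr::imap_dfr(ods, function(od, id) {
    pop <- population_ruf(fits[names(ods) != id])
    pred <- predict_surface(pop, stack, reference)
    use <- od$mask
    if (sum(use) < bins) {
      warning("fold '", id, "' skipped: fewer than ", bins,
              " overlapping cells")
      return(tibble::tibble(id = id, slope = NA_real_,
                            r_squared = NA_real_, n_cells = sum(use)))
    }
    d <- tibble::tibble(pred = pred[use], od = od$height[use]) |>
      dplyr::arrange(.data$pred)
    n <- nrow(d)
    base <- n %/% bins
    sizes <- rep(base, bins)
    sizes[bins] <- sizes[bins] + n - base * bins
    d$bin <- rep(seq_len(bins), times = sizes)
    bs <- d |>
      dplyr::group_by(.data$bin) |>
      dplyr::summarise(sum_od = sum(.data$od), sum_pred = sum(.data$pred),
                       .groups = "drop")
    fit <- stats::lm(sum_od ~ sum_pred, data = bs)
    tibble::tibble(
      id = id,
      slope = unname(stats::coef(fit)[2]),
      r_squared = summary(fit)$r.squared,
      n_cells = n
    )
  })
  structure(
    list(
      folds = folds,
      mean_slope = mean(folds$slope, na.rm = TRUE),
      mean_r_squared = mean(folds$r_squared, na.rm = TRUE),
      bins = as.integer(bins)
    ),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf(
    "<cv_result> %d folds, %d bins: mean slope %.3f, mean R^2 %.3f\n",
    nrow(x$folds), x$bins, x$mean_slope, x$mean_r_squared
  ))
  invisible(x)
}

#' @rdname tidy_sympatric
#' @export
tidy.cv_result <- function(x, ...) x$folds

#' @rdname glance_sympatric
#' @export
glance.cv_result <- function(x, ...) {
  tibble::tibble(
    mean_slope = x$mean_slope, mean_r_squared = x$mean_r_squared,
    bins = x$bins, n_folds = nrow(x$folds)
  )
}

#' Construct a synthetic occurrence distribution from known effects
#'
#' Builds an OD whose height is a linear function of z-scored covariates (plus
#' optional Gaussian noise), clamped positive and normalized. Used to validate
#' coefficient recovery and cross-validation behavior against known truth.
#'
#' @param stack A `landscape_stack`.
#' @param effects Named standardized coefficient vector (continuous layers or
#'   `land_cover_<class>` dummies).
#' @param noise_sd SD of additive Gaussian noise (on the standardized linear-
#'   predictor scale).
#' @param level Contour level of the availability mask.
#' @param intercept Baseline added before clamping.
#' @param meta Metadata list.
#' @return An `occurrence_dist`.
#' @export
synthetic_od <- function(stack, effects, noise_sd = 0, level = 0.99,
                         intercept = NULL, meta = list()) {
  cells <- stack$cells
  lp <- rep(0, nrow(cells))
  for (term in names(effects)) {
    xv <- if (startsWith(term, "land_cover_")) {
      as.numeric(cells$land_cover == sub("^land_cover_", "", term))
    } else {
      z <- cells[[term]]
      if (is.null(z)) stop("no layer '", term, "' in stack")
      if (stats::sd(z) > 0) (z - mean(z)) / stats::sd(z) else z * 0
    }
    lp <- lp + effects[[term]] * xv
  }
  if (noise_sd > 0) lp <- lp + stats::rnorm(length(lp), 0, noise_sd)
  if (is.null(intercept)) intercept <- -min(lp) + 0.1 * (max(lp) - min(lp)) + 1e-9
  h <- pmax(lp + intercept, 0)
  h <- h / sum(h)
  od <- structure(
    list(geom = stack$geom, height = h, mask = NULL, level = level,
         meta = meta),
    class = "occurrence_dist"
  )
  od$mask <- od_contour(od, level)
  od
}
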