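# Shared fixtures, built in code at test time.

# Sample from a von Mises distribution by inversion on a fine grid.
vm_sample <- function(n, mu, kappa) {
  g <- seq(0, 2 * pi, length.out = 1e5 + 1)[seq_len(1e5)]
  p <- exp(kappa * (cos(g - mu) - 1))
  sample(g, n, replace = TRUE, prob = p / sum(p))
}

# Von Mises density (per radian).
vm_density <- function(theta, mu, kappa) {
  exp(kappa * (cos(theta - mu) - 1)) /
    (2 * pi * besselI(kappa, 0, expon.scaled = TRUE))
}

# Analytic von Mises activity density tibble on the package's 24-h grid.
vm_density_tbl <- function(mu_hours, kappa, n_grid = 512L) {
  grid <- seq(0, 2 * pi, length.out = n_grid + 1L)[seq_len(n_grid)]
  tibble::tibble(
    time = grid / (2 * pi) * 24,
    density = vm_density(grid, mu_hours / 24 * 2 * pi, kappa) * 2 * pi / 24
  )
}

# Minimal track tibble from coordinate vectors (minutes since start).
make_track <- function(x, y, minutes = seq_along(x) * 15, error_sd = 0,
                       id = "A1", species = "wolf", state = NULL) {
  tr <- tibble::tibble(
    id = id, species = species,
    timestamp = as.POSIXct("2014-05-01 00:00:00", tz = "UTC") + minutes * 60,
    x = x, y = y,
    error_sd = rep_len(error_sd, length(x))
  )
  if (!is.null(state)) tr$state <- rep_len(state, length(x))
  tr
}

# A two-phase Brownian track with a motion-variance change at `change_at`.
two_phase_track <- function(n = 600L, change_at = 300L, sigma1 = 0.5,
                            sigma2 = 8, dt = 15, error_sd = 2, seed = 1) {
  set.seed(seed)
  sig <- c(rep(sigma1, change_at - 1L), rep(sigma2, n - change_at))
  steps_x <- stats::rnorm(n - 1L, 0, sqrt(sig * dt))
  steps_y <- stats::rnorm(n - 1L, 0, sqrt(sig * dt))
  make_track(
    x = cumsum(c(0, steps_x)) + stats::rnorm(n, 0, error_sd),
    y = cumsum(c(0, steps_y)) + stats::rnorm(n, 0, error_sd),
    minutes = seq_len(n) * dt, error_sd = error_sd
  )
}

# Small landscape reused across RUF tests.
test_stack <- function(n = 25L, seed = 9L) {
  generate_landscape(grid_geometry(n_rows = n, n_cols = n), seed = seed)
}

# Fake individual RUF fit carrying given standardized coefficients, for
# exercising the population-averaging machinery directly.
fake_ruf_fit <- function(betas) {
  structure(
    list(
      coefficients = tibble::tibble(
        term = names(betas),
        estimate_std = unname(betas), std_error_std = 0,
        estimate_raw = unname(betas), std_error_raw = 0
      ),
      n_cells = 100L, covariates = names(betas), dummies = character(0),
      r_squared = 1, meta = list()
    ),
    class = "ruf_fit"
  )
}
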