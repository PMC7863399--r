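#' Analysis grid geometry
#'
#' Defines the projected 30 x 30 m (by default) analysis grid shared by all
#' raster layers and occurrence distributions: an origin (lower-left corner),
#' a square cell size in meters, and row/column counts. Rows count upward from
#' the origin.
#'
#' @param origin_x,origin_y Projected coordinates of the grid's lower-left
#'   corner, meters.
#' @param cell Cell side, meters.
#' @param n_rows,n_cols Grid dimensions.
#' @return A `grid_geometry` object.
#' @export
grid_geometry <- function(origin_x = 0, origin_y = 0, cell = 30,
                          n_rows = 50L, n_cols = 50L) {
  stopifnot(cell > 0, n_rows >= 1, n_cols >= 1)
  structure(
    list(
      origin_x = origin_x, origin_y = origin_y, cell = cell,
      n_rows = as.integer(n_rows), n_cols = as.integer(n_cols)
    ),
    class = "grid_geometry"
  )
}

#' @export
print.grid_geometry <- function(x, ...) {
  cat(sprintf(
    "<grid_geometry> %d x %d cells of %g m, origin (%g, %g)\n",
    x$n_rows, x$n_cols, x$cell, x$origin_x, x$origin_y
  ))
  invisible(x)
}

# Tibble of cell centers for a geometry; `cell` indexes column-major
# (row fastest), rows increasing with y.
grid_cells <- function(geom) {
  row <- rep(seq_len(geom$n_rows), times = geom$n_cols)
  col <- rep(seq_len(geom$n_cols), each = geom$n_rows)
  tibble::tibble(
    cell = seq_len(geom$n_rows * geom$n_cols),
    row = row,
    col = col,
    x = geom$origin_x + (col - 0.5) * geom$cell,
    y = geom$origin_y + (row - 0.5) * geom$cell
  )
}

land_cover_classes <- function() {
  c(
    "deciduous", "mixed", "evergreen", "woody_wetland",
    "open_water", "grassland_shrub", "developed"
  )
}

continuous_layers <- function() {
  c(
    "patch_size", "dist_road", "dist_water", "dist_edge",
    "hare_density", "grouse_density", "deer_adult_occ", "deer_fawn_occ",
    "wolf_occ"
  )
}

new_landscape_stack <- function(geom, cells, lines = list()) {
  structure(list(geom = geom, cells = cells, lines = lines),
            class = "landscape_stack")
}

#' @export
print.landscape_stack <- function(x, ...) {
  lay <- setdiff(names(x$cells), c("cell", "row", "col", "x", "y"))
  cat(sprintf(
    "<landscape_stack> %d x %d cells of %g m; layers: %s\n",
    x$geom$n_rows, x$geom$n_cols, x$geom$cell, paste(lay, collapse = ", ")
  ))
  invisible(x)
}

#' @rdname tidy_sympatric
#' @export
tidy.landscape_stack <- function(x, ...) x$cells

# Extract one layer as an n_rows x n_cols matrix (row i = grid row i).
layer_matrix <- function(stack, layer) {
  matrix(stack$cells[[layer]], nrow = stack$geom$n_rows)
}

# Minimum Euclidean distance from points to a set of segments
# (segments: matrix with columns x0, y0, x1, y1).
dist_to_segments <- function(x, y, segments) {
  if (is.null(segments) || nrow(segments) == 0L) {
    return(rep(Inf, length(x)))
  }
  d <- rep(Inf, length(x))
  for (i in seq_len(nrow(segments))) {
    x0 <- segments[i, 1]; y0 <- segments[i, 2]
    x1 <- segments[i, 3]; y1 <- segments[i, 4]
    dx <- x1 - x0; dy <- y1 - y0
    len2 <- dx * dx + dy * dy
    t <- if (len2 == 0) rep(0, length(x)) else
      pmin(1, pmax(0, ((x - x0) * dx + (y - y0) * dy) / len2))
    di <- sqrt((x - (x0 + t * dx))^2 + (y - (y0 + t * dy))^2)
    d <- pmin(d, di)
  }
  d
}

# Exact Euclidean distance transform of a logical matrix (TRUE = source),
# Felzenszwalb & Huttenlocher two-pass algorithm on squared distances.
# Returns distances in cell units.
distance_transform <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  INF <- (nr + nc + 1)^2
  f <- matrix(INF, nr, nc)
  f[mask] <- 0
  dt1d <- function(f) {
    n <- length(f)
    d <- numeric(n)
    v <- integer(n); z <- numeric(n + 1L)
    k <- 1L; v[1L] <- 1L; z[1L] <- -Inf; z[2L] <- Inf
    for (q in 2:n) {
      repeat {
        s <- ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2 * q - 2 * v[k])
        if (s <= z[k]) { k <- k - 1L } else break
      }
      k <- k + 1L
      v[k] <- q; z[k] <- s; z[k + 1L] <- Inf
    }
    k <- 1L
    for (q in 1:n) {
      while (z[k + 1L] < q) k <- k + 1L
      d[q] <- (q - v[k])^2 + f[v[k]]
    }
    d
  }
  g <- apply(f, 2, dt1d)          # along rows (each column vector)
  d2 <- t(apply(g, 1, dt1d))      # along columns
  sqrt(d2)
}

# Connected components of a categorical matrix under rook adjacency.
# Returns an integer matrix of component labels.
connected_components <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  queue <- integer(nr * nc)
  for (start in seq_len(nr * nc)) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    lab[start] <- nxt
    queue[1L] <- start
    head <- 1L; tail <- 1L
    val <- m[start]
    while (head <= tail) {
      cur <- queue[head]; head <- head + 1L
      r <- ((cur - 1L) %% nr) + 1L
      cl <- ((cur - 1L) %/% nr) + 1L
      for (nb in c(
        if (r > 1L) cur - 1L,
        if (r < nr) cur + 1L,
        if (cl > 1L) cur - nr,
        if (cl < nc) cur + nr
      )) {
        if (lab[nb] == 0L && m[nb] == val) {
          lab[nb] <- nxt
          tail <- tail + 1L
          queue[tail] <- nb
        }
      }
    }
  }
  lab
}

# Smooth positive field: positive baseline plus Gaussian bumps.
smooth_field <- function(cells, geom, n_bumps = 4L, base = 0.2, amp = 1) {
  span_x <- geom$n_cols * geom$cell
  span_y <- geom$n_rows * geom$cell
  z <- rep(base, nrow(cells))
  for (b in seq_len(n_bumps)) {
    cx <- geom$origin_x + stats::runif(1) * span_x
    cy <- geom$origin_y + stats::runif(1) * span_y
    s <- stats::runif(1, 0.1, 0.3) * min(span_x, span_y)
    a <- stats::runif(1, 0.3, 1) * amp
    z <- z + a * exp(-((cells$x - cx)^2 + (cells$y - cy)^2) / (2 * s^2))
  }
  z
}

random_polyline <- function(geom, n_vertices = 4L) {
  span_x <- geom$n_cols * geom$cell
  span_y <- geom$n_rows * geom$cell
  # a meandering line crossing the grid
  xs <- geom$origin_x + seq(0, 1, length.out = n_vertices) * span_x
  ys <- geom$origin_y + stats::runif(n_vertices) * span_y
  if (stats::runif(1) < 0.5) { tmp <- xs; xs <- ys; ys <- tmp }
  cbind(xs[-n_vertices], ys[-n_vertices], xs[-1], ys[-1])
}

#' Generate a synthetic landscape covariate stack
#'
#' Draws a categorical land-cover raster as Voronoi patches around
#' class-weighted seed points, random road and water polylines with exact
#' Euclidean distance-to-feature layers, patch size from rook-adjacency
#' connected components, distance to land-cover edge via an exact distance
#' transform, and smooth positive prey surfaces (hare and grouse densities,
#' adult and fawn deer occurrence).
#'
#' @param geom A [grid_geometry()].
#' @param class_weights Named nonnegative weights over the seven land-cover
#'   classes; at least one positive. Seed-point counts are proportional.
#' @param n_seeds Total Voronoi seed points controlling patch graininess.
#' @param n_roads,n_water Number of road / water polylines.
#' @param seed Integer RNG seed.
#' @return A `landscape_stack`: grid geometry plus a tibble of cells with
#'   layers `land_cover`, `patch_size` (ha), `dist_road`, `dist_water`,
#'   `dist_edge` (m), `hare_density`, `grouse_density`, `deer_adult_occ`,
#'   `deer_fawn_occ`.
#' @export
generate_landscape <- function(geom = grid_geometry(),
                               class_weights = c(
                                 deciduous = 0.40, mixed = 0.15,
                                 evergreen = 0.10, woody_wetland = 0.20,
                                 open_water = 0.05, grassland_shrub = 0.07,
                                 developed = 0.03
                               ),
                               n_seeds = 40L, n_roads = 2L, n_water = 2L,
                               seed = 1L) {
  if (geom$n_rows < 1L || geom$n_cols < 1L) stop("non-positive grid")
  classes <- land_cover_classes()
  w <- class_weights[classes]
  names(w) <- classes
  w[is.na(w)] <- 0
  if (any(w < 0) || !any(w > 0)) {
    stop("class weights must be nonnegative with at least one positive")
  }
  set.seed(seed)
  cells <- grid_cells(geom)
  span_x <- geom$n_cols * geom$cell
  span_y <- geom$n_rows * geom$cell

  # land cover: nearest class-labelled seed point
  seed_class <- sample(classes, n_seeds, replace = TRUE, prob = w / sum(w))
  sx <- geom$origin_x + stats::runif(n_seeds) * span_x
  sy <- geom$origin_y + stats::runif(n_seeds) * span_y
  d2 <- outer(cells$x, sx, "-")^2 + outer(cells$y, sy, "-")^2
  cells$land_cover <- seed_class[max.col(-d2)]

  # linear features and exact distances
  roads <- do.call(rbind, lapply(seq_len(n_roads), function(i) random_polyline(geom)))
  water <- do.call(rbind, lapply(seq_len(n_water), function(i) random_polyline(geom)))
  cells$dist_road <- dist_to_segments(cells$x, cells$y, roads)
  cells$dist_water <- dist_to_segments(cells$x, cells$y, water)

  # patch size (ha) from rook components of land cover
  lc_mat <- matrix(cells$land_cover, nrow = geom$n_rows)
  comp <- connected_components(lc_mat)
  sizes <- tabulate(comp)
  cells$patch_size <- sizes[as.vector(comp)] * geom$cell^2 / 1e4

  # distance to land-cover edge: sources are cells rook-adjacent to a
  # different class (distance 0 at the edge cells themselves)
  edge <- matrix(FALSE, geom$n_rows, geom$n_cols)
  nr <- geom$n_rows; nc <- geom$n_cols
  if (nr > 1L) {
    diffv <- lc_mat[-1, , drop = FALSE] != lc_mat[-nr, , drop = FALSE]
    edge[-1, ] <- edge[-1, ] | diffv
    edge[-nr, ] <- edge[-nr, ] | diffv
  }
  if (nc > 1L) {
    diffh <- lc_mat[, -1, drop = FALSE] != lc_mat[, -nc, drop = FALSE]
    edge[, -1] <- edge[, -1] | diffh
    edge[, -nc] <- edge[, -nc] | diffh
  }
  cells$dist_edge <- if (any(edge)) {
    as.vector(distance_transform(edge)) * geom$cell
  } else {
    rep(0, nrow(cells))  # uniform landscape: no edges anywhere
  }

  # prey and deer-occurrence surfaces
  cells$hare_density <- smooth_field(cells, geom, n_bumps = 4L, base = 0.3)
  cells$grouse_density <- smooth_field(cells, geom, n_bumps = 4L, base = 0.2)
  occ <- smooth_field(cells, geom, n_bumps = 3L, base = 0.1)
  cells$deer_adult_occ <- occ / sum(occ)
  occ_f <- smooth_field(cells, geom, n_bumps = 3L, base = 0.1)
  cells$deer_fawn_occ <- occ_f / sum(occ_f)

  new_landscape_stack(geom, cells, lines = list(roads = roads, water = water))
}

#' Add or replace a layer in a landscape stack
#'
#' @param stack A `landscape_stack`.
#' @param name Layer name.
#' @param values Numeric vector, one value per cell (grid order).
#' @return The modified stack.
#' @export
set_layer <- function(stack, name, values) {
  stopifnot(inherits(stack, "landscape_stack"),
            length(values) == nrow(stack$cells))
  stack$cells[[name]] <- values
  stack
}

#' Read and write landscape stacks as CSV
#'
#' The on-disk form is a plain CSV of the cell tibble (cell, row, col, x, y
#' and one column per layer); grid geometry is recovered from the coordinate
#' columns.
#'
#' @param stack A `landscape_stack`.
#' @param path File path.
#' @return `write_landscape()` returns `path` invisibly; `read_landscape()`
#'   returns a `landscape_stack`.
#' @export
write_landscape <- function(stack, path) {
  utils::write.csv(stack$cells, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_landscape
#' @export
read_landscape <- function(path) {
  cells <- dplyr::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  n_rows <- max(cells$row); n_cols <- max(cells$col)
  cell <- diff(sort(unique(cells$y)))[1]
  if (is.na(cell)) cell <- diff(sort(unique(cells$x)))[1]
  geom <- grid_geometry(
    origin_x = min(cells$x) - cell / 2, origin_y = min(cells$y) - cell / 2,
    cell = cell, n_rows = n_rows, n_cols = n_cols
  )
  cells <- dplyr::arrange(cells, .data$col, .data$row)
  cells$cell <- seq_len(nrow(cells))
  new_landscape_stack(geom, cells)
}
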