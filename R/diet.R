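#' Assign scats to species
#'
#' Track-confirmed scats take the track's species. Scats without tracks are
#' assigned by diameter: at most 28.1 mm is a coyote, at least 29.0 mm a wolf,
#' and the band strictly between (above the coyote third quartile and below
#' the wolf first quartile) cannot be identified and is excluded.
#'
#' @param scats Tibble with one or more rows per scat, including `id`,
#'   `diameter_mm`, and `track_species` (`"wolf"`, `"coyote"`, or `"none"`).
#' @param coyote_max Largest track-free diameter still assigned to coyote, mm.
#' @param wolf_min Smallest track-free diameter assigned to wolf, mm.
#' @return The tibble with an `assigned_species` column
#'   (`"wolf"`/`"coyote"`/`"excluded"`).
#' @export
assign_scat_species <- function(scats, coyote_max = 28.1, wolf_min = 29.0) {
  stopifnot(is.data.frame(scats))
  if (any(scats$diameter_mm <= 0, na.rm = TRUE)) {
    stop("scat diameters must be positive")
  }
  dplyr::mutate(
    dplyr::as_tibble(scats),
    assigned_species = dplyr::case_when(
      .data$track_species %in% c("wolf", "coyote") ~ .data$track_species,
      .data$diameter_mm <= coyote_max ~ "coyote",
      .data$diameter_mm >= wolf_min ~ "wolf",
      TRUE ~ "excluded"
    )
  )
}

#' Diet proportions for a species and period
#'
#' The proportion of prey item i in the diet is the mean over scats of the
#' per-scat volume fraction of item i, renormalized to sum to one. Scats must
#' already carry `assigned_species` (see [assign_scat_species()]); the period
#' is derived from the collection date.
#'
#' @param scats Long scat tibble (`id, date, item, volume_fraction`,
#'   `assigned_species`).
#' @param species `"wolf"` or `"coyote"`.
#' @param period `"PPP"`, `"LMP"`, or `"SMP"`; `NULL` pools all periods.
#' @return A `diet_summary` tibble: one row per prey item with `proportion`,
#'   plus attributes `species`, `period`, `n_scats`.
#' @export
diet_proportions <- function(scats, species, period = NULL) {
  s <- dplyr::as_tibble(scats)
  if (!"assigned_species" %in% names(s)) s <- assign_scat_species(s)
  s <- dplyr::filter(s, .data$assigned_species == species)
  if (!is.null(period)) {
    s <- dplyr::filter(s, assign_period(.data$date) == period)
  }
  if (nrow(s) == 0L) {
    stop("no assigned scats for ", species, "/",
         if (is.null(period)) "all periods" else period)
  }
  n_scats <- dplyr::n_distinct(s$id)
  # mean over scats of the per-scat fraction of each item; scats lacking an
  # item contribute zero, so the mean is just sum / n_scats
  sums <- s |>
    dplyr::group_by(.data$item) |>
    dplyr::summarise(total = sum(.data$volume_fraction), .groups = "drop")
  items <- union(prey_items(), sums$item)
  prop <- stats::setNames(rep(0, length(items)), items)
  prop[sums$item] <- sums$total / n_scats
  out <- tibble::tibble(item = items, proportion = unname(prop)) |>
    dplyr::mutate(proportion = .data$proportion / sum(.data$proportion))
  structure(out,
            species = species, period = period, n_scats = n_scats,
            class = c("diet_summary", class(out)))
}

check_proportions <- function(p, tol = 1e-6) {
  if (!is.numeric(p) || any(p < 0) || abs(sum(p) - 1) > tol) {
    stop("proportions must be nonnegative and sum to 1")
  }
  invisible(p)
}

#' Dietary breadth
#'
#' Levins-style dietary breadth `B = 1 / sum(p_i^2)`: 1 for a single-item
#' diet, the number of items for a uniform diet.
#'
#' @param p Proportion vector (nonnegative, sums to 1).
#' @return Breadth `B` in \[1, length(p)\].
#' @export
#' @examples
#' dietary_breadth(c(0.5, 0.25, 0.25))
dietary_breadth <- function(p) {
  if (inherits(p, "diet_summary")) p <- p$proportion
  check_proportions(p)
  1 / sum(p^2)
}

#' Pianka's food-niche overlap
#'
#' The symmetric overlap `alpha = sum(p_i q_i) / sqrt(sum(p_i^2) sum(q_i^2))`
#' between the diet proportion vectors of two predators: 0 for disjoint diets,
#' 1 for identical ones.
#'
#' @param p,q Proportion vectors over the same (named) item set.
#' @return Overlap alpha in \[0, 1\].
#' @export
#' @examples
#' food_niche_overlap(c(1, 0), c(0.5, 0.5))
food_niche_overlap <- function(p, q) {
  if (inherits(p, "diet_summary")) { names_p <- p$item; p <- stats::setNames(p$proportion, names_p) }
  if (inherits(q, "diet_summary")) { names_q <- q$item; q <- stats::setNames(q$proportion, names_q) }
  if (length(p) != length(q)) stop("item sets differ in length")
  if (!is.null(names(p)) && !is.null(names(q))) {
    if (!setequal(names(p), names(q))) stop("item sets differ")
    q <- q[names(p)]
  }
  check_proportions(p)
  check_proportions(q)
  sum(p * q) / sqrt(sum(p^2) * sum(q^2))
}

#' Compare per-item scat volumes between species
#'
#' One-way ANOVA per prey item on per-scat volume fractions (wolf vs coyote),
#' reporting species means (as percent) and SDs, the F statistic and p-value,
#' and the coyote:wolf ratio of means.
#'
#' @param scats Long scat tibble with `assigned_species`, `id`, `item`,
#'   `volume_fraction`.
#' @return Tibble, one row per prey item.
#' @export
compare_item_volumes <- function(scats) {
  s <- dplyr::as_tibble(scats)
  if (!"assigned_species" %in% names(s)) s <- assign_scat_species(s)
  s <- dplyr::filter(s, .data$assigned_species %in% c("wolf", "coyote"))
  counts <- s |>
    dplyr::distinct(.data$id, .data$assigned_species) |>
    dplyr::count(.data$assigned_species)
  if (nrow(counts) < 2L || any(counts$n < 2L)) {
    stop("need at least 2 scats per species for the volume comparison")
  }
  per <- s |>
    dplyr::group_by(.data$assigned_species, .data$id, .data$item) |>
    dplyr::summarise(v = sum(.data$volume_fraction), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "item", values_from = "v",
                       values_fill = 0) |>
    tidyr::pivot_longer(cols = -c("assigned_species", "id"),
                        names_to = "item", values_to = "v")
  per |>
    dplyr::group_by(.data$item) |>
    dplyr::group_modify(function(d, key) {
      fit <- stats::lm(v ~ assigned_species, data = d)
      an <- stats::anova(fit)
      msb <- an$`Mean Sq`[1]
      fv <- if (msb == 0) 0 else an$`F value`[1]
      pv <- if (msb == 0) 1 else an$`Pr(>F)`[1]
      mw <- mean(d$v[d$assigned_species == "wolf"])
      mc <- mean(d$v[d$assigned_species == "coyote"])
      tibble::tibble(
        mean_wolf_pct = 100 * mw,
        sd_wolf_pct = 100 * stats::sd(d$v[d$assigned_species == "wolf"]),
        mean_coyote_pct = 100 * mc,
        sd_coyote_pct = 100 * stats::sd(d$v[d$assigned_species == "coyote"]),
        f_statistic = fv,
        df1 = an$Df[1], df2 = an$Df[2],
        p_value = pv,
        ratio_coyote_wolf = if (mw == 0 && mc == 0) NA_real_ else mc / mw
      )
    }) |>
    dplyr::ungroup()
}

#' Diet breadth and overlap table by period
#'
#' Computes per species x period diet proportions, dietary breadth, and the
#' between-species food-niche overlap, mirroring the study's diet summary row.
#'
#' @param scats Long scat tibble (assigned or raw).
#' @param periods Period labels to tabulate.
#' @return Tibble `period, n_wolf, n_coyote, B_wolf, B_coyote, alpha`.
#' @export
diet_overlap_table <- function(scats, periods = c("PPP", "LMP", "SMP")) {
  s <- dplyr::as_tibble(scats)
  if (!"assigned_species" %in% names(s)) s <- assign_scat_species(s)
  purrr::map_dfr(periods, function(pd) {
    pw <- diet_proportions(s, "wolf", pd)
    pc <- diet_proportions(s, "coyote", pd)
    tibble::tibble(
      period = pd,
      n_wolf = attr(pw, "n_scats"), n_coyote = attr(pc, "n_scats"),
      B_wolf = dietary_breadth(pw), B_coyote = dietary_breadth(pc),
      alpha = food_niche_overlap(pw, pc)
    )
  })
}
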