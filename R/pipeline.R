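run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full niche-overlap analysis
#'
#' Executes every stage of the analysis in order on one coherent set of
#' inputs: accelerometer classification and fix labelling; per-individual,
#' per-period, per-state dynamic Brownian bridge occurrence distributions on
#' the landscape grid; covariate screening; wolf resource utilization
#' functions, their population average, and the predicted wolf surface; coyote
#' RUFs with the wolf surface as an avoidance covariate (coyote fits refuse to
#' run without it); population RUFs; leave-one-individual-out cross-validation;
#' diet proportions, breadth, and overlap; and circular activity overlap.
#' Writes result tables and a run log into `out_dir`.
#'
#' Inputs may be supplied as tibbles (`inputs = list(tracks=, activity=,
#' scats=, landscape=)`); by default they are simulated from `scenario`.
#'
#' @param out_dir Output directory (created if needed).
#' @param scenario A [synthetic_scenario()] used when `inputs` is `NULL`.
#' @param config A [study_config()].
#' @param geom Landscape/OD grid geometry for simulation.
#' @param n_fixes Fixes per simulated individual.
#' @param scats_per_cell Simulated scats per species x period.
#' @param inputs Optional list of input tibbles, bypassing simulation.
#' @return Invisibly, a list of all in-memory results.
#' @export
run_full_analysis <- function(out_dir,
                              scenario = synthetic_scenario(),
                              config = study_config(),
                              geom = grid_geometry(n_rows = 40L, n_cols = 40L),
                              n_fixes = 300L,
                              scats_per_cell = 60L,
                              inputs = NULL) {
  config <- validate_study_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c(
    sprintf("run started (seed %d)", config$rng_seed),
    paste0("config: ", paste(names(unclass(config)),
                             vapply(unclass(config), function(v)
                               paste(format(v), collapse = "|"), ""),
                             sep = "=", collapse = "; "))
  )
  set.seed(config$rng_seed)

  data <- run_stage("inputs", {
    if (is.null(inputs)) {
      simulate_scenario(scenario, geom = geom, n_fixes = n_fixes,
                        scats_per_cell = scats_per_cell)
    } else {
      inputs
    }
  })
  stack <- data$landscape
  if (!all(c("wolf", "coyote") %in% data$tracks$species)) {
    stop("stage 'inputs' failed: both wolf and coyote tracks are required")
  }

  # --- activity classification and fix labelling -------------------------
  series <- run_stage("activity", {
    classify_activity(data$activity, config$activity_threshold)
  })
  tracks <- run_stage("activity", {
    data$tracks |>
      dplyr::group_by(.data$id) |>
      dplyr::group_modify(function(tr, key) {
        s <- dplyr::filter(series, .data$id == key$id)
        assign_activity_to_fixes(tr, s, config$fix_interval,
                                 config$activity_interval) |>
          dplyr::select(-dplyr::any_of("id"))
      }) |>
      dplyr::ungroup()
  })

  # --- occurrence distributions ------------------------------------------
  ods <- run_stage("odf", {
    combos <- tracks |>
      dplyr::mutate(period = assign_period(as.Date(.data$timestamp))) |>
      dplyr::filter(!is.na(.data$period))
    out <- list()
    for (id in unique(combos$id)) {
      for (pd in unique(combos$period[combos$id == id])) {
        tr <- dplyr::filter(combos, .data$id == .env$id, .data$period == .env$pd)
        if (nrow(tr) < 10L) next
        prof <- suppressWarnings(fit_dynamic_motion_variance(
          tr, window = config$dbbmm_window, margin = config$dbbmm_margin
        ))
        for (st in c("active", "inactive")) {
          od <- tryCatch(
            occurrence_distribution(
              tr, prof, stack$geom, state = st, level = config$od_level,
              quadrature_steps = config$quadrature_steps,
              meta = list(id = id, species = tr$species[1],
                          period = pd, state = st)
            ),
            error = function(e) NULL
          )
          if (!is.null(od)) out[[paste(id, pd, st, sep = ".")]] <- od
        }
      }
    }
    if (length(out) == 0L) stop("no occurrence distributions could be built")
    out
  })

  # --- covariate screening ------------------------------------------------
  covs_wolf <- run_stage("ruf", {
    screen_covariates(
      stack, cutoff = config$correlation_cutoff,
      priority = config$covariate_priority,
      covariates = setdiff(intersect(continuous_layers(), names(stack$cells)),
                           "wolf_occ")
    )
  })

  od_meta <- purrr::map_dfr(ods, function(od) {
    tibble::as_tibble(od$meta[c("id", "species", "period", "state")])
  })
  od_meta$key <- names(ods)

  # --- wolf RUFs, population average, predicted surface -------------------
  ruf_results <- run_stage("ruf", {
    fits <- list(); pops <- list(); cvs <- list()
    stack_coyote <- stack
    # individuals whose OD offers too few available cells are skipped, not
    # fatal: the population is averaged over the fittable individuals
    fit_set <- function(keys, stk, covs) {
      f <- purrr::map(ods[keys], function(od) {
        tryCatch(fit_individual_ruf(od, stk, covs), error = function(e) {
          warning("skipping RUF for ",
                  paste(unlist(od$meta), collapse = "/"), ": ",
                  conditionMessage(e))
          NULL
        })
      })
      purrr::compact(f)
    }
    for (pd in unique(od_meta$period)) {
      for (st in c("active", "inactive")) {
        sel_w <- od_meta$key[od_meta$species == "wolf" &
                               od_meta$period == pd & od_meta$state == st]
        f <- fit_set(sel_w, stack, covs_wolf)
        if (length(f) >= 2L) {
          fits <- c(fits, f)
          pops[[paste("wolf", pd, st, sep = ".")]] <-
            population_ruf(f, alpha = config$alpha,
                           meta = list(species = "wolf", period = pd,
                                       state = st))
          if (length(f) >= 3L) {
            cvs[[paste("wolf", pd, st, sep = ".")]] <-
              loio_cv(ods[names(f)], stack, covs_wolf, bins = config$cv_bins,
                      fits = f)
          }
        }
      }
      # wolf surface for the period: all wolf fits of the period pooled
      sel_all <- od_meta$key[od_meta$species == "wolf" & od_meta$period == pd]
      pool <- fit_set(sel_all, stack, covs_wolf)
      if (length(pool) >= 2L) {
        wolf_pop <- population_ruf(pool, alpha = config$alpha,
                                   meta = list(species = "wolf", period = pd,
                                               state = "all"))
        stack_coyote <- set_layer(stack_coyote, "wolf_occ",
                                  predict_surface(wolf_pop, stack))
      }
    }
    # coyote RUFs need the wolf surface in the stack
    if (!"wolf_occ" %in% names(stack_coyote$cells)) {
      stop("coyote RUFs require a wolf prediction surface in the stack")
    }
    covs_coyote <- screen_covariates(
      stack_coyote, cutoff = config$correlation_cutoff,
      priority = config$covariate_priority
    )
    for (pd in unique(od_meta$period)) {
      for (st in c("active", "inactive")) {
        sel_c <- od_meta$key[od_meta$species == "coyote" &
                               od_meta$period == pd & od_meta$state == st]
        f <- fit_set(sel_c, stack_coyote, covs_coyote)
        if (length(f) >= 2L) {
          fits <- c(fits, f)
          pops[[paste("coyote", pd, st, sep = ".")]] <-
            population_ruf(f, alpha = config$alpha,
                           meta = list(species = "coyote", period = pd,
                                       state = st))
          if (length(f) >= 3L) {
            cvs[[paste("coyote", pd, st, sep = ".")]] <-
              loio_cv(ods[names(f)], stack_coyote, covs_coyote,
                      bins = config$cv_bins, fits = f)
          }
        }
      }
    }
    list(fits = fits, populations = pops, cv = cvs,
         stack_coyote = stack_coyote, covs_wolf = covs_wolf,
         covs_coyote = covs_coyote)
  })

  # --- diet ----------------------------------------------------------------
  diet_results <- run_stage("diet", {
    assigned <- assign_scat_species(data$scats)
    list(
      assigned = assigned,
      table = diet_overlap_table(assigned),
      volumes = compare_item_volumes(assigned)
    )
  })

  # --- activity overlap ----------------------------------------------------
  overlap_results <- run_stage("overlap", {
    periods <- unique(assign_period(as.Date(series$interval_start)))
    periods <- periods[!is.na(periods)]
    res <- purrr::map(periods, function(pd) {
      ov <- activity_overlap(series, period = pd)
      pt <- proportion_active_test(series, period = pd)
      list(period = pd, overlap = ov, proportions = pt)
    })
    stats::setNames(res, periods)
  })

  # --- outputs --------------------------------------------------------------
  run_stage("write", {
    writeLines(log_lines, file.path(out_dir, "run_log.txt"))
    pop_tbl <- purrr::map_dfr(ruf_results$populations, tidy)
    utils::write.csv(pop_tbl, file.path(out_dir, "population_ruf.csv"),
                     row.names = FALSE)
    ind_tbl <- purrr::map_dfr(ruf_results$fits, tidy)
    utils::write.csv(ind_tbl, file.path(out_dir, "individual_ruf.csv"),
                     row.names = FALSE)
    if (length(ruf_results$cv)) {
      cv_tbl <- purrr::imap_dfr(ruf_results$cv, function(cv, key) {
        dplyr::mutate(tidy(cv), model = key, .before = 1)
      })
      utils::write.csv(cv_tbl, file.path(out_dir, "cv_folds.csv"),
                       row.names = FALSE)
    }
    utils::write.csv(diet_results$table, file.path(out_dir, "diet_overlap.csv"),
                     row.names = FALSE)
    utils::write.csv(diet_results$volumes,
                     file.path(out_dir, "diet_item_volumes.csv"),
                     row.names = FALSE)
    ov_tbl <- purrr::map_dfr(overlap_results, function(r) {
      tibble::tibble(period = r$period, delta = r$overlap$delta)
    })
    utils::write.csv(ov_tbl, file.path(out_dir, "activity_overlap.csv"),
                     row.names = FALSE)
    prop_tbl <- purrr::map_dfr(overlap_results, function(r) {
      dplyr::mutate(r$proportions$summary, period = r$period, .before = 1)
    })
    utils::write.csv(prop_tbl, file.path(out_dir, "activity_proportions.csv"),
                     row.names = FALSE)
    if ("wolf_occ" %in% names(ruf_results$stack_coyote$cells)) {
      utils::write.csv(
        ruf_results$stack_coyote$cells[c("cell", "row", "col", "x", "y",
                                         "wolf_occ")],
        file.path(out_dir, "wolf_surface.csv"), row.names = FALSE
      )
    }
  })

  invisible(list(
    config = config, tracks = tracks, series = series, ods = ods,
    ruf = ruf_results, diet = diet_results, overlap = overlap_results,
    out_dir = out_dir
  ))
}
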