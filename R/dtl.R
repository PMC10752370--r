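#' Classify species behavior across a cycle's design conditions
#'
#' Species without predictive regression models are steered heuristically,
#' based on how they behaved across the cycle: a species whose mean relative
#' abundance across the design conditions is below `low_threshold`
#' undergrew; above `high_threshold` it overgrew (saturated dominance);
#' otherwise it is labeled ok.
#'
#' @param compositions Wide composition tibble for the cycle.
#' @param species Species columns; default autodetected.
#' @param low_threshold Undergrowth cutoff on mean relative abundance
#'   (default 0.025).
#' @param high_threshold Overgrowth cutoff (default 0.25).
#' @return Tibble: species, mean_rel_abundance, behavior.
#' @export
classify_behavior <- function(compositions, species = NULL,
                              low_threshold = 0.025, high_threshold = 0.25) {
  if (is.null(species)) species <- species_of(compositions)
  tibble::tibble(
    species = species,
    mean_rel_abundance = purrr::map_dbl(species, ~ mean(compositions[[.x]]))
  ) |>
    dplyr::mutate(behavior = dplyr::case_when(
      .data$mean_rel_abundance < low_threshold ~ "undergrew",
      .data$mean_rel_abundance > high_threshold ~ "overgrew",
      TRUE ~ "ok"
    ))
}

#' Frameshift center-point update for non-predictive species
#'
#' Moves the center point to an extremum of the previous design space: a
#' species that overgrew gets the previous low level as its new center; one
#' that undergrew gets the previous high level. Species with predictive
#' models (behavior `"predictive"`) and well-behaved species keep their
#' center.
#'
#' @param levels Tibble with `species`, `low`, `center`, `high` from the
#'   previous cycle.
#' @param behavior Named character vector (`"overgrew"`, `"undergrew"`,
#'   `"ok"`, `"predictive"`) covering every species in `levels`.
#' @return Named vector of updated center points.
#' @export
frameshift_update <- function(levels, behavior) {
  miss <- setdiff(levels$species, names(behavior))
  if (length(miss))
    stop("no behavior label for species: ", paste(miss, collapse = ", "))
  centers <- setNames(levels$center, levels$species)
  for (sp in levels$species) {
    b <- behavior[[sp]]
    row <- levels[levels$species == sp, ]
    if (b == "overgrew") centers[sp] <- row$low
    else if (b == "undergrew") centers[sp] <- row$high
  }
  centers
}

#' Set log-symmetric design levels for a cycle
#'
#' High and low levels bracket the center geometrically
#' (`high = center * fold`, `low = center / fold`). Cycle 2 keeps the
#' previous fold but caps the total high/low range at two orders of
#' magnitude (`fold <= 10`); cycle 3 fixes the fold at 2 (robustness check
#' around a trusted center rather than exploration).
#'
#' @param center Named vector of center-point inoculum densities.
#' @param cycle Cycle index (2 or 3 apply the built-in rules; otherwise
#'   `fold` is used as given).
#' @param fold Per-species or scalar fold factor carried from the previous
#'   cycle.
#' @param range_cap Maximum total high/low range (default 100).
#' @return Tibble: species, low, center, high, fold.
#' @export
set_cycle_levels <- function(center, cycle, fold, range_cap = 100) {
  if (any(center <= 0)) stop("center points must be positive")
  fold <- rep_len(fold, length(center))
  if (cycle >= 3) fold <- rep_len(2, length(center))
  else if (cycle == 2) fold <- pmin(fold, sqrt(range_cap))
  tibble::tibble(species = names(center), low = unname(center / fold),
                 center = unname(center), high = unname(center * fold),
                 fold = fold)
}

#' Run a closed-loop design-test-learn campaign against a synthetic world
#'
#' Orchestrates the full inoculum-optimization loop offline, with the
#' synthetic world standing in for the wet-lab "test" step:
#' \enumerate{
#'   \item Cycle 1: infer a constrained-logistic model from the world's
#'     monoculture curves, optimize the inoculum for steady-state diversity
#'     (the first center point), calibrate design levels by the steady-state
#'     fold-change rule, run a definitive screening design.
#'   \item Learn: fit one elastic-net ensemble per species (log10 inoculum
#'     features, endpoint absolute abundance response) on all accumulated
#'     replicate-averaged conditions minus a held-out validation set; a
#'     species' model is predictive when its out-of-fold Pearson correlation
#'     reaches `predictive_threshold`.
#'   \item Cycles 2-3: predictive species get model-guided center points
#'     (matching the even-composition target); the rest are frameshifted.
#'     Cycle 2 reuses a definitive screening design with the range cap;
#'     cycle 3 switches to a Plackett-Burman design at two-fold levels.
#' }
#'
#' @param world A `synthetic_world` (the ground truth being probed).
#' @param n_cycles Cycles to run (default 3).
#' @param pinned Named vector of fixed inoculum densities (at most a few
#'   species), or `NULL`.
#' @param predictive_threshold Out-of-fold Pearson cutoff (default 0.7).
#' @param replicates Replicates per condition in the simulated test step.
#' @param n_holdout Conditions withheld from ensemble training for held-out
#'   validation (default 5).
#' @param alpha_grid,lambda_grid Hyperparameter grids for [fit_ensemble()].
#' @param center_move_min_gain Hysteresis on model-guided center updates:
#'   the optimized center replaces the current one only when the refit
#'   models predict at least this relative reduction in the distance to the
#'   target composition (default 0.1). Re-centering a design is an
#'   experimental cost, so marginal predicted gains do not move it.
#' @param ensemble_thresh,ensemble_maxit Convergence controls for
#'   [fit_ensemble()]; the loop's wide exploration designs produce badly
#'   scaled features, where a looser tolerance avoids pathological
#'   coordinate-descent paths.
#' @param total_cap,free_cap Inoculum caps for the cycle-1 optimization.
#' @param min_level,max_level Practical inoculation-density window (OD600)
#'   bounding every design level.
#' @param seed Seed for all stochastic steps.
#' @return List of per-cycle records (center, levels, runs, compositions,
#'   model stats) plus `summary`: a tibble with, per cycle, the center-point
#'   endpoint diversity and the median endpoint diversity across the cycle's
#'   design conditions, both under the noiseless world dynamics.
#' @export
run_dtl <- function(world, n_cycles = 3, pinned = NULL,
                    predictive_threshold = 0.7, replicates = 3,
                    n_holdout = 5,
                    alpha_grid = seq(0.1, 1, by = 0.1),
                    lambda_grid = 10^seq(-6, 2, length.out = 50),
                    center_move_min_gain = 0.1,
                    ensemble_thresh = 1e-5, ensemble_maxit = 2e4,
                    total_cap = 0.02, free_cap = 0.01,
                    min_level = 1e-7, max_level = 0.05, seed = 1) {
  species <- world$species
  free <- setdiff(species, names(pinned))

  # world monocultures -> constrained-logistic model for cycle 1
  mono <- synthesize_monocultures(world, seed = seed + 100)
  mono <- blank_growth_curves(mono)
  even_x0 <- setNames(rep(0.001, length(species)), species)
  comm_endpoint <- sum(glv_endpoint(world$glv, even_x0))
  csle <- infer_csle(mono, route = "empirical",
                     community_endpoint = comm_endpoint)
  copt <- optimize_inoculum_csle(csle, total_cap = total_cap,
                                 free_cap = free_cap, pinned = pinned,
                                 seed = seed)
  center <- copt$x0
  calib <- calibrate_levels_csle(csle, center, species = free, fold = 3.3,
                                 search_upper = max_level)
  # exploration cycle: levels straight from the steady-state fold-change
  # calibration, with the fold shrunk where needed so both levels stay inside
  # the practical density window (keeping them log-symmetric)
  fold1 <- pmin(unname(calib$high / calib$center),
                max_level / unname(calib$center),
                unname(calib$center) / min_level)
  fold1 <- pmax(fold1, 1)
  levels <- tibble::tibble(
    species = calib$species,
    low = unname(calib$center) / fold1,
    center = unname(calib$center),
    high = unname(calib$center) * fold1,
    fold = fold1
  )

  cycles <- list()
  runs_all <- NULL
  comps_all <- NULL
  status <- setNames(rep("frameshift", length(free)), free)
  models <- NULL

  for (cy in seq_len(n_cycles)) {
    if (cy > 1) {
      # center update: model-guided for predictive species, frameshift else
      behavior <- classify_behavior(cycles[[cy - 1]]$compositions,
                                    species = species)
      blab <- setNames(behavior$behavior, behavior$species)
      predictive <- names(status)[status == "predictive"]
      new_center <- setNames(levels$center, levels$species)
      if (length(predictive)) {
        mean_od <- mean(comps_all$total_od600)
        target <- even_target(mean_od, species)[predictive]
        obs_bounds <- tibble::tibble(
          name = species,
          lower = purrr::map_dbl(species, ~ min(runs_all[[.x]])),
          upper = purrr::map_dbl(species, ~ max(runs_all[[.x]])))
        iopt <- optimize_inoculum(models[predictive], target, obs_bounds,
                                  pinned = pinned, seed = seed + cy)
        # hysteresis: moving the center costs an experiment, so adopt the
        # model-guided point only when the refit models predict a
        # substantially better match to the target than the current center
        cur <- c(new_center, pinned)[species]
        cur_run <- matrix(cur, nrow = 1, dimnames = list(NULL, species))
        sse_cur <- sum((target - purrr::map_dbl(models[predictive],
                                                ~ predict(.x, cur_run)))^2)
        if (iopt$objective < (1 - center_move_min_gain) * sse_cur)
          new_center[free] <- iopt$profile[free]
        # otherwise hold: predictive species keep their current center
      }
      blab[predictive] <- "predictive"
      fs_center <- frameshift_update(levels, blab[levels$species])
      nonpred <- setdiff(free, predictive)
      new_center[nonpred] <- fs_center[nonpred]
      levels <- set_cycle_levels(new_center[free], cycle = cy,
                                 fold = levels$fold)
    }

    kind <- if (cy >= 3) "plackett_burman" else "dsd"
    design <- generate_design(kind, n_factors = length(free),
                              center_point = TRUE, factor_names = free)
    spec <- factor_spec(levels$species, center = levels$center,
                        high = levels$high, low = levels$low,
                        scale = "log10")
    runs <- scale_design(design, spec)
    runs$run_id <- paste0("c", cy, "_", runs$run_id)
    if (length(pinned)) for (sp in names(pinned)) runs[[sp]] <- pinned[[sp]]
    runs <- runs[c("run_id", species)]

    comps <- synthesize_communities(world, runs, replicates = replicates,
                                    seed = seed + 10 * cy)
    runs_all <- dplyr::bind_rows(runs_all, runs)
    comps_all <- dplyr::bind_rows(comps_all, comps)

    # learn: replicate-average, hold out validation conditions, fit ensembles
    avg <- comps_all |>
      dplyr::group_by(.data$condition_id) |>
      dplyr::summarise(dplyr::across(dplyr::all_of(c(species, "total_od600")),
                                     mean), .groups = "drop")
    hold_n <- min(n_holdout, max(0, nrow(avg) - 8))
    held <- local({ set.seed(seed + 1000 + cy)
                    sample(avg$condition_id, hold_n) })
    train <- avg[!avg$condition_id %in% held, ]
    test <- avg[avg$condition_id %in% held, ]
    xtrain <- runs_all[match(train$condition_id, runs_all$run_id), species]
    feats <- build_features(xtrain, log10_transform = TRUE)
    models <- purrr::map(setNames(free, free), function(sp) {
      fit_ensemble(feats, train[[sp]] * train$total_od600,
                   alpha_grid = alpha_grid, lambda_grid = lambda_grid,
                   thresh = ensemble_thresh, glm_maxit = ensemble_maxit)
    })
    stats <- purrr::imap_dfr(models, function(m, sp) {
      g <- glance(m)
      held_r <- NA_real_
      if (nrow(test) >= 3) {
        xt <- runs_all[match(test$condition_id, runs_all$run_id), species]
        held_r <- suppressWarnings(
          cor(predict(m, xt), test[[sp]] * test$total_od600))
      }
      dplyr::mutate(g, species = sp, heldout_pearson = held_r, .before = 1)
    })
    status <- setNames(ifelse(!is.na(stats$oof_pearson) &
                                stats$oof_pearson >= predictive_threshold,
                              "predictive", "frameshift"), stats$species)

    center_vec <- setNames(unname(levels$center), levels$species)
    if (length(pinned)) center_vec <- c(center_vec, pinned)
    cycles[[cy]] <- list(cycle = cy, center = center_vec[species],
      levels = levels, design_kind = kind, runs = runs,
      compositions = comps, model_stats = stats, status = status,
      held_out = held)
  }

  summary <- purrr::map_dfr(cycles, function(c) {
    xe <- glv_endpoint(world$glv, c$center)
    # median simulated (noise-free) endpoint diversity across the cycle's
    # design conditions — the cycle-level improvement readout
    med <- median(vapply(seq_len(nrow(c$runs)), function(r) {
      xe <- glv_endpoint(world$glv, as.numeric(c$runs[r, species]))
      shannon_diversity(to_relative(xe), tol = 1e-3)
    }, numeric(1)))
    tibble::tibble(cycle = c$cycle,
                   n_runs = nrow(c$runs),
                   n_predictive = sum(c$status == "predictive"),
                   center_total_od = sum(xe),
                   center_diversity = shannon_diversity(to_relative(xe),
                                                        tol = 1e-3),
                   median_condition_diversity = med)
  })
  list(cycles = cycles, summary = summary, csle = csle,
       first_center = center)
}
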