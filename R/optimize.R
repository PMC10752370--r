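#' Media profile maximizing predicted monoculture diversity
#'
#' Given one fitted response ensemble per species (predicting that species'
#' carrying capacity from media-component levels), searches the bounded
#' factor space for the profile maximizing the Shannon diversity of the
#' normalized predicted capacities. Negative predictions are clipped at zero
#' before normalization. Bounded multi-start local search (L-BFGS-B).
#'
#' @param ensembles Named list of `response_ensemble` objects (one per
#'   species), sharing one factor space.
#' @param bounds Tibble or list with `name`, `lower`, `upper` per factor, in
#'   the ensembles' factor order.
#' @param n_starts Random multi-starts (default 20).
#' @param seed Seed for the starts.
#' @return List: `profile` (named optimal levels), `diversity` (predicted
#'   monoculture diversity), `K_hat` (predicted capacities).
#' @export
optimize_media <- function(ensembles, bounds, n_starts = 20, seed = 1) {
  bounds <- tibble::as_tibble(bounds)
  lo <- bounds$lower; hi <- bounds$upper
  nm <- bounds$name
  objective <- function(p) {
    run <- matrix(p, nrow = 1, dimnames = list(NULL, nm))
    Kh <- purrr::map_dbl(ensembles, ~ predict(.x, run))
    tot <- sum(Kh)
    if (tot <= 0) return(1e6)
    -shannon_diversity(Kh / tot, tol = 1e-9)
  }
  starts <- local({
    set.seed(seed)
    c(list((lo + hi) / 2),
      purrr::map(seq_len(n_starts - 1), ~ lo + runif(length(lo)) * (hi - lo)))
  })
  best <- NULL
  for (s in starts) {
    fit <- try(optim(s, objective, method = "L-BFGS-B", lower = lo, upper = hi,
                     control = list(factr = 1e7)), silent = TRUE)
    if (inherits(fit, "try-error") || !is.finite(fit$value)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("media optimization failed: all-zero predicted capacities at every start")
  run <- matrix(best$par, nrow = 1, dimnames = list(NULL, nm))
  Kh <- purrr::map_dbl(ensembles, ~ predict(.x, run))
  list(profile = setNames(best$par, nm), diversity = -best$value,
       K_hat = Kh)
}

#' Inoculum profile matching a target endpoint composition
#'
#' Minimizes the squared error between target per-species endpoint
#' abundances and ensemble predictions, over the (log10) inoculum levels of
#' the free species. Pinned species are held fixed. The search is bounded by
#' the observed design-level ranges so the regression models never
#' extrapolate. The even-composition target used for diversity maximization
#' is `rep(mean_total_od / S, S)` (see [even_target()]).
#'
#' @param ensembles Named list of `response_ensemble` objects, one per free
#'   species, each predicting that species' endpoint abundance from the full
#'   inoculum profile (log10-transforming feature map).
#' @param target Named numeric vector of target endpoint abundances for the
#'   modeled species.
#' @param bounds Tibble with `name`, `lower`, `upper`: absolute inoculum
#'   bounds per factor (all species entering the feature map).
#' @param pinned Named vector of fixed inoculum densities.
#' @param n_starts,seed Multi-start controls.
#' @return List: `profile` (named absolute inoculum levels, pinned included),
#'   `objective` (residual sum of squares), `predicted` (per-species
#'   predictions at the optimum).
#' @export
optimize_inoculum <- function(ensembles, target, bounds, pinned = NULL,
                              n_starts = 20, seed = 1) {
  if (!length(ensembles)) stop("no predictive models supplied")
  bounds <- tibble::as_tibble(bounds)
  nm <- bounds$name
  # zero-width bounds cannot be searched; hold those factors fixed
  degenerate <- bounds$name[bounds$upper <= bounds$lower * (1 + 1e-12)]
  fixed <- c(pinned, setNames(bounds$lower[match(setdiff(degenerate,
                                                         names(pinned)),
                                                 bounds$name)],
                              setdiff(degenerate, names(pinned))))
  free <- setdiff(nm, names(fixed))
  if (!length(free)) stop("no free factors to optimize")
  li <- log10(bounds$lower[match(free, bounds$name)])
  ui <- log10(bounds$upper[match(free, bounds$name)])
  pinned <- fixed
  target <- target[names(ensembles)]
  if (any(!is.finite(target))) stop("targets must be finite for every modeled species")
  assemble <- function(lf) {
    p <- setNames(numeric(length(nm)), nm)
    p[free] <- 10^lf
    if (length(pinned)) p[names(pinned)] <- pinned
    p
  }
  objective <- function(lf) {
    run <- matrix(assemble(lf), nrow = 1, dimnames = list(NULL, nm))
    pred <- purrr::map_dbl(ensembles, ~ predict(.x, run))
    sum((target - pred)^2)
  }
  starts <- local({
    set.seed(seed)
    c(list((li + ui) / 2),
      purrr::map(seq_len(n_starts - 1), ~ li + runif(length(li)) * (ui - li)))
  })
  best <- NULL
  for (s in starts) {
    fit <- try(optim(s, objective, method = "L-BFGS-B", lower = li, upper = ui,
                     control = list(factr = 1e7)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("inoculum optimization failed from every start")
  prof <- assemble(best$par)
  run <- matrix(prof, nrow = 1, dimnames = list(NULL, nm))
  list(profile = prof, objective = best$value,
       predicted = purrr::map_dbl(ensembles, ~ predict(.x, run)))
}

#' Even-composition endpoint target
#'
#' The diversity-maximizing target used in the design-test-learn loop: each
#' species targeted at (average community OD600) / (number of species),
#' where the average is taken over the previous experiment's endpoints.
#'
#' @param mean_total_od Average endpoint community OD600.
#' @param species Species labels.
#' @return Named target vector.
#' @export
even_target <- function(mean_total_od, species) {
  setNames(rep(mean_total_od / length(species), length(species)), species)
}
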