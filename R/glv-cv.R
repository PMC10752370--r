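#' Train/test split of community conditions
#'
#' Reproducibly withholds a fraction of the community (and passage)
#' conditions as a test set. Monoculture time series never enter the test
#' set: they are dense in time and would not probe community prediction.
#'
#' @param data Training tibble from [glv_training()].
#' @param test_frac Fraction withheld (default 0.10).
#' @param seed Seed.
#' @return List of two training tibbles: `train`, `test`.
#' @export
split_train_test <- function(data, test_frac = 0.10, seed = 1) {
  species <- attr(data, "species")
  comm <- which(data$type != "monoculture")
  if (length(comm) < 10) stop("need at least 10 community conditions to split")
  n_test <- max(1, round(test_frac * length(comm)))
  test_idx <- local({ set.seed(seed); sample(comm, n_test) })
  out <- list(train = data[-test_idx, ], test = data[test_idx, ])
  attr(out$train, "species") <- species
  attr(out$test, "species") <- species
  out
}

#' Select the L1 penalty by k-fold cross validation
#'
#' Scans penalty strengths in two passes: a coarse logarithmic scan (10
#' values, 1e-8..10), then a refined scan of 13 log-spaced values spanning
#' one decade either side of the coarse optimum. For each penalty, community
#' conditions are partitioned into `k` folds; the model is fit on the
#' remaining conditions (plus all monocultures) and out-of-fold endpoint
#' compositions are scored by pooled Pearson correlation on relative
#' abundances. The best penalty maximizes the mean out-of-fold correlation.
#' The full curve is returned: on well-determined data it is flat over a
#' wide penalty range, while under-sampled data produce a peaked curve —
#' a useful overfitting diagnostic.
#'
#' @param data Training tibble.
#' @param k Folds (default 5).
#' @param coarse_grid Coarse penalty grid.
#' @param refine Run the refined scan? (default `TRUE`)
#' @param seed Seed for fold assignment.
#' @param ... Passed to [fit_glv()] (e.g. `maxit`, `dt`, `n_starts`).
#' @return List: `best_lambda`, `curve` (tibble: lambda, stage,
#'   mean_oof_pearson, mean_oof_sse).
#' @export
select_regularization <- function(data, k = 5,
                                  coarse_grid = 10^seq(-8, 1, length.out = 10),
                                  refine = TRUE, seed = 1, ...) {
  species <- attr(data, "species")
  comm <- which(data$type != "monoculture")
  if (length(comm) < k) stop("need at least k community conditions")
  foldid <- local({
    set.seed(seed)
    sample(rep(seq_len(k), length.out = length(comm)))
  })
  scan <- function(grid, stage) {
    purrr::map_dfr(grid, function(lam) {
      scores <- purrr::map_dfr(seq_len(k), function(f) {
        hold <- comm[foldid == f]
        train <- data[-hold, ]; test <- data[hold, ]
        attr(train, "species") <- species; attr(test, "species") <- species
        fit <- fit_glv(train, lambda = lam, ...)
        sc <- score_glv(fit, test)
        tibble::tibble(pearson = sc$pearson,
                       sse = sum((sc$table$observed - sc$table$predicted)^2))
      })
      tibble::tibble(lambda = lam, stage = stage,
                     mean_oof_pearson = mean(scores$pearson, na.rm = TRUE),
                     mean_oof_sse = mean(scores$sse))
    })
  }
  curve <- scan(coarse_grid, "coarse")
  best <- curve$lambda[which.max(curve$mean_oof_pearson)]
  if (refine) {
    fine_grid <- 10^seq(log10(best) - 1, log10(best) + 1, length.out = 13)
    fine <- scan(fine_grid, "refined")
    curve <- dplyr::bind_rows(curve, fine)
    best <- fine$lambda[which.max(fine$mean_oof_pearson)]
  }
  list(best_lambda = best, curve = curve)
}

#' Bootstrap ensemble of gLV fits
#'
#' Resamples community conditions with replacement (`B` times, same size as
#' the original), refits the model on each resample, and summarizes
#' per-parameter uncertainty. Monoculture series stay in every resample —
#' they anchor the within-species kinetics. Individual fit failures are
#' dropped (tolerated up to 10% of `B`, then an error).
#'
#' @param data Training tibble.
#' @param B Bootstrap replicates (default 100).
#' @param lambda L1 penalty.
#' @param seed Seed.
#' @param ... Passed to [fit_glv()].
#' @return List: `fits` (list of `glv_params`), `summary` (tibble with
#'   per-parameter median and interquartile range), `n_failed`.
#' @export
bootstrap_glv <- function(data, B = 100, lambda = 0.1, seed = 1, ...) {
  species <- attr(data, "species")
  comm <- which(data$type != "monoculture")
  mono <- setdiff(seq_len(nrow(data)), comm)
  draws <- local({
    set.seed(seed)
    purrr::map(seq_len(B), ~ sample(comm, length(comm), replace = TRUE))
  })
  fits <- purrr::map(draws, function(idx) {
    d <- data[c(mono, idx), ]
    attr(d, "species") <- species
    try(fit_glv(d, lambda = lambda, ...), silent = TRUE)
  })
  failed <- purrr::map_lgl(fits, inherits, "try-error")
  if (mean(failed) > 0.10)
    stop(sum(failed), " of ", B, " bootstrap fits failed (> 10%)")
  fits <- fits[!failed]
  par_mat <- do.call(rbind, purrr::map(fits, ~ glv_pack(unname(.x$mu), .x$A)))
  S <- length(species)
  labels <- c(paste0("mu_", species),
              as.vector(outer(species, species, function(i, j) paste0("a_", i, "_", j))))
  summ <- tibble::tibble(
    parameter = labels,
    median = apply(par_mat, 2, median),
    q25 = apply(par_mat, 2, quantile, 0.25),
    q75 = apply(par_mat, 2, quantile, 0.75)
  ) |> dplyr::mutate(iqr = .data$q75 - .data$q25)
  list(fits = fits, summary = summ, n_failed = sum(failed))
}

#' Endpoint-composition distribution under a bootstrap ensemble
#'
#' @param fits List of `glv_params` (e.g. from [bootstrap_glv()]).
#' @param x0 Initial abundances.
#' @param t_end Horizon (hours).
#' @return Tibble: draw, species, abundance, rel_abundance.
#' @export
bootstrap_predict <- function(fits, x0, t_end = 28) {
  purrr::imap_dfr(fits, function(f, i) {
    xe <- glv_endpoint(f, x0, t_end)
    tibble::tibble(draw = i, species = names(xe), abundance = unname(xe),
                   rel_abundance = unname(to_relative(xe)))
  })
}

#' Shuffled-interaction null ensemble (derangements only)
#'
#' Permutes the off-diagonal interaction terms of a gLV matrix uniformly at
#' random, `n` times, and keeps only permutations in which every off-diagonal
#' entry lands in a new position (derangements); growth rates and diagonal
#' terms are untouched. A uniform permutation of the 90 off-diagonal cells of
#' a 10x10 matrix is a derangement with probability about 1/e, so roughly 37
#' of 100 shuffles survive the filter.
#'
#' @param params A `glv_params` object (>= 3 species).
#' @param n Shuffles attempted (default 100).
#' @param seed Seed.
#' @return List: `accepted` (list of `glv_params`), `n_accepted`, `n`.
#' @export
shuffle_null <- function(params, n = 100, seed = 1) {
  S <- length(params$mu)
  if (S < 3) stop("need at least 3 species")
  off <- which(row(params$A) != col(params$A))
  set.seed(seed)
  accepted <- list()
  for (i in seq_len(n)) {
    perm <- sample(length(off))
    if (any(perm == seq_along(perm))) next
    A2 <- params$A
    A2[off] <- params$A[off][perm]
    accepted[[length(accepted) + 1]] <-
      glv_params(unname(params$mu), A2, params$species)
  }
  list(accepted = accepted, n_accepted = length(accepted), n = n)
}
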