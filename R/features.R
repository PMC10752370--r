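#' Polynomial feature matrix for response-surface regression
#'
#' Expands factor levels into main effects, quadratics, unique pairwise
#' interactions (l < m) and optionally unique three-way interactions
#' (l < m < n), in that deterministic order. Four factors with three-way
#' terms give 4 + 4 + 6 + 4 = 18 features (the media response surface); ten
#' factors without give 10 + 10 + 45 = 65 (the inoculum surface). When
#' `log10_transform` is set the inputs are log10-transformed first, as
#' inoculum densities spanning orders of magnitude require.
#'
#' @param runs Matrix or tibble of factor levels (runs x factors).
#' @param include_three_way Include three-way interaction terms?
#' @param log10_transform Log10-transform inputs before expansion?
#' @return Numeric matrix with named feature columns; attribute
#'   `feature_map` records the construction.
#' @export
build_features <- function(runs, include_three_way = FALSE,
                           log10_transform = FALSE) {
  X <- if (is.matrix(runs)) runs
       else as.matrix(dplyr::select(tibble::as_tibble(runs),
                                    -dplyr::any_of("run_id")))
  storage.mode(X) <- "double"
  if (ncol(X) < 2) stop("need at least 2 factors")
  if (any(!is.finite(X))) stop("non-finite factor levels")
  if (log10_transform) {
    if (any(X <= 0)) stop("log10 transform requires positive levels")
    X <- log10(X)
  }
  m <- ncol(X)
  nm <- colnames(X)
  if (is.null(nm)) nm <- paste0("x", seq_len(m))
  cols <- list()
  for (l in seq_len(m)) cols[[nm[l]]] <- X[, l]
  for (l in seq_len(m)) cols[[paste0(nm[l], "^2")]] <- X[, l]^2
  if (m >= 2)
    for (l in seq_len(m - 1)) for (mm in (l + 1):m)
      cols[[paste0(nm[l], ":", nm[mm])]] <- X[, l] * X[, mm]
  if (include_three_way && m >= 3)
    for (l in seq_len(m - 2)) for (mm in (l + 1):(m - 1)) for (n in (mm + 1):m)
      cols[[paste0(nm[l], ":", nm[mm], ":", nm[n])]] <- X[, l] * X[, mm] * X[, n]
  F <- do.call(cbind, cols)
  rownames(F) <- NULL
  attr(F, "feature_map") <- list(factors = nm,
                                 include_three_way = include_three_way,
                                 log10_transform = log10_transform)
  F
}
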