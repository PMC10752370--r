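#' Shannon diversity of a community composition
#'
#' Computes `-sum(x * log(x))` in natural-log units (nats) over a vector of
#' relative abundances, with the continuity convention `0 * log(0) = 0`.
#' For an even S-species community the maximum is `log(S)`; for ten species
#' that is 2.30.
#'
#' @param x Numeric vector of relative abundances. Must be non-negative and
#'   sum to 1 (within `tol`).
#' @param tol Tolerance on the simplex-sum check.
#' @return Shannon diversity in nats, in `[0, log(length(x))]`.
#' @examples
#' shannon_diversity(rep(0.1, 10)) # log(10) = 2.30
#' @export
shannon_diversity <- function(x, tol = 1e-6) {
  check_composition(x, tol)
  x <- x[x > 1e-12]
  -sum(x * log(x))
}

#' Inverse Simpson diversity
#'
#' `1 / sum(x^2)` over relative abundances; equals S for an even S-species
#' community and 1 for a monoculture.
#'
#' @inheritParams shannon_diversity
#' @return Scalar in `[1, length(x)]`.
#' @export
inverse_simpson <- function(x, tol = 1e-6) {
  check_composition(x, tol)
  if (all(x <= 0)) stop("inverse Simpson undefined for an all-zero composition")
  1 / sum(x^2)
}

check_composition <- function(x, tol = 1e-6) {
  if (!is.numeric(x) || length(x) < 1) stop("composition must be numeric")
  if (any(!is.finite(x))) stop("composition contains non-finite values")
  if (any(x < 0)) stop("relative abundances must be non-negative")
  s <- sum(x)
  if (s > 0 && abs(s - 1) > tol)
    stop("relative abundances must sum to 1 (got ", format(s), ")")
  invisible(x)
}

#' Monoculture diversity from per-species carrying capacities
#'
#' The media-optimization objective: normalizes single-species carrying
#' capacities onto the simplex and takes their Shannon diversity. High values
#' mean the medium supports all species to similar maximum densities.
#'
#' @param K Numeric vector of carrying capacities (OD600), non-negative with
#'   at least one positive entry.
#' @return Shannon diversity of the normalized capacities, in nats.
#' @examples
#' monoculture_diversity(c(1, 1, 2))
#' @export
monoculture_diversity <- function(K) {
  if (any(!is.finite(K)) || any(K < 0)) stop("carrying capacities must be finite and >= 0")
  tot <- sum(K)
  if (tot <= 0) stop("all carrying capacities are zero")
  shannon_diversity(K / tot)
}

#' Euclidean distance between two compositions
#'
#' @param a,b Numeric composition vectors over the same species set (same
#'   length and order).
#' @return `sqrt(sum((a - b)^2))`.
#' @export
composition_distance <- function(a, b) {
  if (length(a) != length(b)) stop("compositions are over different species sets")
  na <- names(a); nb <- names(b)
  if (!is.null(na) && !is.null(nb) && !identical(na, nb))
    stop("species order differs between compositions: ",
         paste(nb[na != nb], collapse = ", "))
  sqrt(sum((a - b)^2))
}

#' Coefficient of variation of a species across passages
#'
#' `100 * sd(x) / mean(x)` with the sample (n-1) standard deviation, applied
#' to one species' relative abundances across serial-passage endpoints. A
#' species holding (0.2, 0.1, 0.1, 0.1) across four passages has CV 40%.
#'
#' @param x Numeric vector of per-passage relative abundances (length >= 2).
#' @return CV in percent, or `NA` (with a warning) when the mean is zero.
#' @export
cv_across_passages <- function(x) {
  if (length(x) < 2) stop("need at least two passages for a CV")
  m <- mean(x)
  if (m == 0) {
    warning("zero mean abundance; CV undefined")
    return(NA_real_)
  }
  100 * sd(x) / m
}

#' Per-species passage CVs for a passage series table
#'
#' @param series Tibble with columns `passage` and one column per species
#'   (relative abundances), e.g. from [simulate_passages()] or
#'   [read_compositions()].
#' @param species Character vector naming the species columns; defaults to
#'   every column except the bookkeeping ones.
#' @return Tibble with columns `species`, `cv_pct`, `flag_zero_mean`.
#' @export
passage_cv <- function(series, species = NULL) {
  if (is.null(species))
    species <- setdiff(names(series),
                       c("passage", "condition_id", "replicate", "total_od600"))
  purrr::map_dfr(species, function(sp) {
    x <- series[[sp]]
    zero <- mean(x) == 0
    tibble::tibble(
      species = sp,
      cv_pct = if (zero) NA_real_ else suppressWarnings(cv_across_passages(x)),
      flag_zero_mean = zero
    )
  })
}
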