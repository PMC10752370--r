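#' Convert between absolute and relative abundance
#'
#' Relative abundances scale to absolute ones by multiplying with a community
#' total (endpoint OD600 or total CFU/mL); absolute abundances normalize to
#' the simplex by dividing by their sum. The two directions are exact inverses
#' up to floating point. An all-zero absolute vector marks a failed culture:
#' it is returned as all zeros with attribute `failed_culture = TRUE` rather
#' than silently producing NaN, so replicate-exclusion logic stays auditable.
#'
#' @param x Numeric vector; relative abundances for `to_absolute()`, absolute
#'   abundances for `to_relative()`.
#' @param total Positive scalar total (OD600 or CFU/mL).
#' @return Numeric vector of the other representation.
#' @examples
#' to_absolute(c(0.5, 0.5), total = 0.8)
#' to_relative(c(0.2, 0.2, 0.6))
#' @export
to_absolute <- function(x, total) {
  if (!is.numeric(total) || length(total) != 1 || total <= 0)
    stop("`total` must be a positive scalar")
  if (any(x < 0)) stop("relative abundances must be non-negative")
  x * total
}

#' @rdname to_absolute
#' @export
to_relative <- function(x) {
  if (any(x < 0)) stop("absolute abundances must be non-negative")
  s <- sum(x)
  if (s == 0) {
    out <- x
    attr(out, "failed_culture") <- TRUE
    return(out)
  }
  x / s
}

#' Is a composition a flagged failed culture?
#' @param x Vector returned by [to_relative()].
#' @return `TRUE` if the all-zero failed-culture sentinel flag is set.
#' @export
is_failed_culture <- function(x) isTRUE(attr(x, "failed_culture"))
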