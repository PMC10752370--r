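#' Read and validate growth-curve tables
#'
#' Growth curves travel as long-format CSV with one OD600 reading per row.
#' Required columns: `species`, `condition_id`, `replicate`, `time_h`,
#' `od600`, `inoc_density`. Malformed rows (non-finite OD, negative time) are
#' rejected with row-numbered diagnostics.
#'
#' @param path CSV file path.
#' @return Tibble of growth-curve readings, ordered by curve and time.
#' @export
read_growth_curves <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  validate_growth_curves(df, where = path)
}

#' @rdname read_growth_curves
#' @param df In-memory growth-curve tibble to validate.
#' @param where Label used in error messages.
#' @export
validate_growth_curves <- function(df, where = "growth curves") {
  need <- c("species", "condition_id", "replicate", "time_h", "od600", "inoc_density")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(where, ": missing required column(s): ", paste(miss, collapse = ", "))
  bad <- which(!is.finite(df$od600) | !is.finite(df$time_h) | df$time_h < 0)
  if (length(bad))
    stop(where, ": malformed rows (non-finite od600/time or negative time): ",
         paste(head(bad, 5), collapse = ", "))
  dplyr::arrange(tibble::as_tibble(df), .data$species, .data$condition_id,
                 .data$replicate, .data$time_h)
}

#' Read and validate wide composition tables
#'
#' Endpoint compositions travel as wide CSV: `condition_id`, `replicate`,
#' `passage`, `total_od600`, then one relative-abundance column per species.
#' When `species` is supplied the species columns must match it exactly, in
#' order; a shuffled or missing column is reported by name.
#'
#' @param path CSV file path.
#' @param species Optional character vector fixing the species order.
#' @return Tibble with attribute `species` carrying the species order.
#' @export
read_compositions <- function(path, species = NULL) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  validate_compositions(df, species = species, where = path)
}

#' @rdname read_compositions
#' @param df In-memory composition tibble to validate.
#' @param where Label used in error messages.
#' @export
validate_compositions <- function(df, species = NULL, where = "compositions") {
  meta <- c("condition_id", "replicate", "passage", "total_od600")
  miss <- setdiff(meta, names(df))
  if (length(miss))
    stop(where, ": missing required column(s): ", paste(miss, collapse = ", "))
  sp_cols <- setdiff(names(df), meta)
  if (!is.null(species)) {
    if (!identical(sp_cols, species)) {
      off <- c(setdiff(species, sp_cols), sp_cols[sp_cols != species[seq_along(sp_cols)]])
      stop(where, ": species columns do not match the declared species order; ",
           "offending column(s): ", paste(unique(off), collapse = ", "))
    }
  }
  if (anyDuplicated(df[c("condition_id", "replicate", "passage")]))
    stop(where, ": duplicate (condition_id, replicate, passage) rows")
  fr <- as.matrix(df[sp_cols])
  if (any(!is.finite(fr)) || any(fr < 0))
    stop(where, ": non-finite or negative relative abundances")
  sums <- rowSums(fr)
  bad <- which(sums > 0 & abs(sums - 1) > 1e-6)
  if (length(bad))
    stop(where, ": rows not on the unit simplex: ", paste(head(bad, 5), collapse = ", "))
  out <- tibble::as_tibble(df)
  attr(out, "species") <- sp_cols
  out
}

#' Write pipeline tables at full double precision
#'
#' @param df Tibble to write.
#' @param path Destination CSV path.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(df, path) {
  df <- dplyr::mutate(df, dplyr::across(dplyr::where(is.numeric),
                                        ~ format(.x, digits = 17, trim = TRUE)))
  readr::write_csv(df, path)
  invisible(path)
}

#' Species columns of a composition table
#' @param df Composition tibble (wide).
#' @return Character vector of species column names.
#' @export
species_of <- function(df) {
  sp <- attr(df, "species")
  if (!is.null(sp)) return(sp)
  setdiff(names(df), c("condition_id", "replicate", "passage", "total_od600"))
}

#' Read and write gLV parameters as JSON
#'
#' Serializes the species order, growth rates and the interaction matrix
#' (row-major) at full double precision; the reader reconstructs a validated
#' [glv_params()] object.
#'
#' @param params A `glv_params` object.
#' @param path JSON file path.
#' @return `write_glv_json()` returns `path` invisibly; `read_glv_json()`
#'   returns a `glv_params` object.
#' @export
write_glv_json <- function(params, path) {
  jsonlite::write_json(
    list(species = params$species, mu = unname(params$mu),
         A_rowmajor = as.vector(t(params$A))),
    path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_glv_json
#' @export
read_glv_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  S <- length(x$species)
  glv_params(x$mu, matrix(x$A_rowmajor, S, S, byrow = TRUE), x$species)
}
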