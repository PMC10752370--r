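#' Generate a coded design-of-experiments matrix
#'
#' Screening-design families used across the pipeline:
#' \describe{
#'   \item{`full_factorial`}{All \eqn{2^k} two-level runs; no aliasing, so
#'     every polynomial term up to the k-way interaction is estimable.}
#'   \item{`half_factorial`}{Resolution-IV \eqn{2^{k-1}} fraction (highest
#'     factor aliased with the product of the others); 8 runs for 4 factors,
#'     9 with the center point.}
#'   \item{`dsd`}{Definitive screening design from a conference matrix C:
#'     `rbind(C, -C, 0)`, three levels per factor, `2m + 1` runs for even
#'     factor counts. Odd counts use the next even construction with one
#'     column dropped (`2m + 3` runs).}
#'   \item{`plackett_burman`}{Hadamard-derived 12-run two-level array for up
#'     to 11 factors, 13 runs with the center point.}
#' }
#'
#' @param kind One of `"full_factorial"`, `"half_factorial"`, `"dsd"`,
#'   `"plackett_burman"`.
#' @param n_factors Number of factors (>= 2).
#' @param center_point Append one all-zero center row? (default `TRUE`)
#' @param factor_names Optional factor column names.
#' @return Tibble with `run_id` plus one coded column per factor (values in
#'   -1/0/+1), classed `cs_design` with attributes `kind` and `center_point`.
#' @examples
#' generate_design("half_factorial", 4) # 9 runs
#' @export
generate_design <- function(kind = c("half_factorial", "full_factorial", "dsd",
                                     "plackett_burman"),
                            n_factors, center_point = TRUE,
                            factor_names = NULL) {
  kind <- match.arg(kind)
  if (n_factors < 2) stop("need at least 2 factors")
  m <- switch(kind,
    full_factorial = as.matrix(expand.grid(rep(list(c(-1, 1)), n_factors))),
    half_factorial = {
      if (n_factors < 3) stop("half factorial supported for 3 or more factors")
      base <- as.matrix(expand.grid(rep(list(c(-1, 1)), n_factors - 1)))
      cbind(base, apply(base, 1, prod))
    },
    dsd = {
      use <- if (n_factors %% 2 == 0) n_factors else n_factors + 1
      key <- as.character(use)
      if (!key %in% names(conference_matrices))
        stop("dsd supported for factor counts 3-14 (conference matrix orders ",
             paste(names(conference_matrices), collapse = ", "), ")")
      C <- conference_matrices[[key]][, seq_len(n_factors), drop = FALSE]
      # the center row is part of the construction (2m + 1 runs); the
      # center_point flag therefore adds nothing for this family
      center_point <- FALSE
      rbind(C, -C, 0)
    },
    plackett_burman = {
      if (n_factors > 11)
        stop("12-run Plackett-Burman supports at most 11 factors")
      rows <- purrr::map(0:10, function(s) {
        idx <- ((seq_len(11) - 1 + s) %% 11) + 1
        pb12_first_row[idx]
      })
      m <- do.call(rbind, c(rows, list(rep(-1, 11))))
      m[, seq_len(n_factors), drop = FALSE]
    }
  )
  if (center_point) m <- rbind(m, rep(0, n_factors))
  if (is.null(factor_names)) factor_names <- paste0("x", seq_len(n_factors))
  colnames(m) <- factor_names
  out <- tibble::as_tibble(m)
  out <- dplyr::mutate(out, run_id = sprintf("run%02d", dplyr::row_number()),
                       .before = 1)
  structure(out, kind = kind, center_point = center_point,
            class = c("cs_design", class(out)))
}

#' Factor specification table
#'
#' Declares the mapping from coded design levels to absolute values. On a
#' `log10` scale, levels are symmetric in log space: high = center * fold,
#' low = center / fold, so center = sqrt(high * low).
#'
#' @param name Factor names.
#' @param center,high,low Absolute values per factor. `high`/`low` may be
#'   omitted when `fold` is given (log10 scale only).
#' @param scale `"linear"` or `"log10"` per factor.
#' @param fold Optional fold-factor defining high/low around the center on
#'   the log10 scale.
#' @return Tibble of factor specs.
#' @export
factor_spec <- function(name, center, high = NULL, low = NULL,
                        scale = "log10", fold = NULL) {
  scale <- rep_len(scale, length(name))
  if (any(scale == "log10" & center <= 0))
    stop("log10-scaled factors require positive levels")
  if (is.null(high)) {
    if (is.null(fold)) stop("supply high/low or a fold factor")
    fold <- rep_len(fold, length(name))
    high <- center * fold
    low <- center / fold
  }
  spec <- tibble::tibble(name = name, low = low, center = center, high = high,
                         scale = scale)
  bad <- spec$low > spec$center | spec$center > spec$high
  if (any(bad)) stop("need low <= center <= high for factor(s): ",
                     paste(spec$name[bad], collapse = ", "))
  if (any(spec$scale == "log10" & spec$low <= 0))
    stop("log10-scaled factors require positive levels")
  spec
}

#' Map a coded design to absolute run levels
#'
#' Coded -1/0/+1 map to the declared low/center/high of each factor.
#' Intermediate coded values interpolate arithmetically on a linear scale and
#' geometrically on a log10 scale.
#'
#' @param design A `cs_design` tibble from [generate_design()].
#' @param spec Factor-spec tibble from [factor_spec()]; must cover every
#'   factor column.
#' @return Tibble of absolute-valued runs (same shape as `design`).
#' @export
scale_design <- function(design, spec) {
  factors <- setdiff(names(design), "run_id")
  miss <- setdiff(factors, spec$name)
  if (length(miss)) stop("no factor spec for: ", paste(miss, collapse = ", "))
  out <- design
  for (f in factors) {
    s <- spec[spec$name == f, ]
    coded <- design[[f]]
    out[[f]] <- if (s$scale == "log10") {
      ifelse(coded >= 0,
             s$center * (s$high / s$center)^coded,
             s$center * (s$center / s$low)^coded)
    } else {
      ifelse(coded >= 0,
             s$center + coded * (s$high - s$center),
             s$center + coded * (s$center - s$low))
    }
  }
  class(out) <- setdiff(class(out), "cs_design")
  out
}

#' Recover coded levels from an absolute run table
#'
#' Inverse of [scale_design()] for the three coded levels; used to audit
#' user-supplied absolute designs.
#'
#' @inheritParams scale_design
#' @param runs Absolute-valued run tibble.
#' @return Coded tibble.
#' @export
unscale_design <- function(runs, spec) {
  factors <- intersect(names(runs), spec$name)
  out <- runs
  for (f in factors) {
    s <- spec[spec$name == f, ]
    v <- runs[[f]]
    out[[f]] <- if (s$scale == "log10") {
      ifelse(v >= s$center,
             log(v / s$center) / log(s$high / s$center),
             -log(s$center / v) / log(s$center / s$low))
    } else {
      ifelse(v >= s$center,
             (v - s$center) / (s$high - s$center),
             (v - s$center) / (s$center - s$low))
    }
  }
  out
}

#' Liquid-handler inoculation plan for one species
#'
#' Given a preculture density and a target inoculation density, selects the
#' ten-fold serial dilution of the preculture from which the aspiration
#' volume `target * culture_volume / source_od` is the smallest volume
#' strictly greater than `min_volume_uL` (volumes below that cannot be
#' pipetted accurately; larger ones accumulate across species).
#'
#' @param preculture_od Preculture density (OD600).
#' @param target_density Target inoculation density (OD600), less than
#'   `preculture_od`.
#' @param culture_volume_uL Culture volume being inoculated.
#' @param min_volume_uL Minimum pipettable volume (default 7).
#' @param dilution_step Fold dilution between source wells (default 10).
#' @param max_dilutions Deepest dilution well available.
#' @return Tibble: dilution_factor, source_od, volume_uL.
#' @examples
#' inoculation_plan(0.2, 1e-4, 700) # 35 uL from the 100-fold well
#' @export
inoculation_plan <- function(preculture_od, target_density, culture_volume_uL,
                             min_volume_uL = 7, dilution_step = 10,
                             max_dilutions = 12) {
  if (target_density > preculture_od)
    stop("target density exceeds the preculture density")
  d <- 0:max_dilutions
  source_od <- preculture_od / dilution_step^d
  vol <- target_density * culture_volume_uL / source_od
  ok <- vol > min_volume_uL & vol <= culture_volume_uL
  if (target_density == preculture_od) {
    # degenerate: aspirate the full volume undiluted
    return(tibble::tibble(dilution_factor = 1, source_od = preculture_od,
                          volume_uL = culture_volume_uL))
  }
  if (!any(ok))
    stop("no feasible dilution: every candidate volume is below ",
         min_volume_uL, " uL or above the culture volume")
  i <- which(ok)[which.min(vol[ok])]
  tibble::tibble(dilution_factor = dilution_step^d[i],
                 source_od = source_od[i], volume_uL = vol[i])
}

#' Inoculation plans for a whole run table
#'
#' @param runs Absolute-valued run tibble (species columns are target
#'   densities, OD600).
#' @param preculture_od Named vector of preculture densities per species.
#' @param culture_volume_uL Culture volume.
#' @param ... Passed to [inoculation_plan()].
#' @return Tibble: run_id, species, dilution_factor, source_od, volume_uL.
#' @export
inoculation_plan_table <- function(runs, preculture_od, culture_volume_uL = 700,
                                   ...) {
  species <- intersect(names(runs), names(preculture_od))
  purrr::map_dfr(seq_len(nrow(runs)), function(r) {
    purrr::map_dfr(species, function(sp) {
      p <- inoculation_plan(preculture_od[[sp]], runs[[sp]][r],
                            culture_volume_uL, ...)
      dplyr::mutate(p, run_id = runs$run_id[r], species = sp, .before = 1)
    })
  })
}
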