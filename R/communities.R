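#' Enumerate subset communities
#'
#' All subsets of the species set with the given sizes, in deterministic
#' order (by size, then lexicographic). For 10 species and sizes 2..9 this
#' is `sum(choose(10, 2:9))` = 1012 subsets.
#'
#' @param species Species labels (or an integer count).
#' @param sizes Subset sizes (default 2 to S-1).
#' @return List of character vectors.
#' @export
enumerate_subcommunities <- function(species, sizes = NULL) {
  if (is.numeric(species) && length(species) == 1)
    species <- sprintf("sp%02d", seq_len(species))
  S <- length(species)
  if (is.null(sizes)) sizes <- 2:(S - 1)
  if (any(sizes < 2) || any(sizes > S - 1))
    stop("subset sizes must lie in [2, S-1]")
  purrr::flatten(purrr::map(sizes, function(k)
    purrr::array_branch(combn(species, k), 2)))
}

#' Simulate serial passages under a gLV model
#'
#' Chains `n_passages` initial-value problems: each passage integrates
#' `t_per_passage` hours, and the next starts from the endpoint divided by
#' the dilution factor (25-fold by default, the volumetric transfer used in
#' batch passaging). Returns the stationary-phase composition per passage.
#'
#' @param params A `glv_params` object.
#' @param x0 Initial abundances at passage 1.
#' @param n_passages Passages (default 4).
#' @param dilution Fold dilution between passages (default 25).
#' @param t_per_passage Hours per passage (default 28).
#' @return Tibble: passage, total_od600, one column per species (relative
#'   abundance).
#' @export
simulate_passages <- function(params, x0, n_passages = 4, dilution = 25,
                              t_per_passage = 28) {
  x0 <- align_x0(x0, params$species)
  chain <- cpp_glv_passages(unname(params$mu), params$A, x0, n_passages,
                            dilution, t_per_passage)
  if (chain$diverged) stop("divergent trajectory during passage simulation")
  purrr::map_dfr(seq_len(n_passages), function(p) {
    abs <- chain$endpoints[p, ]
    tot <- sum(abs)
    out <- tibble::tibble(passage = p, total_od600 = tot)
    out[params$species] <- as.list(if (tot > 0) abs / tot else abs)
    out
  })
}

#' Temporal-variability objective of a passage series
#'
#' Per-passage Shannon diversities `Sd_p` (p = 1..4) and between-passage
#' Euclidean displacements `Eu_p` (p = 2..4) combine into:
#' \describe{
#'   \item{`low`}{`sum(Sd) / max(sum(Eu), eps)` — rewarding diverse AND
#'     stable series; a perfectly constant series is capped at
#'     `sum(Sd) / eps`.}
#'   \item{`high`}{`sum(Sd) * sum(Eu)` — rewarding diverse and mobile
#'     series; zero for a constant series.}
#' }
#'
#' @param series Passage tibble from [simulate_passages()] (columns
#'   `passage` + species).
#' @param mode `"low"` or `"high"` variability objective.
#' @param eps Denominator floor for the low mode (default 1e-6).
#' @param species Species columns; default all non-bookkeeping columns.
#' @return Scalar objective.
#' @export
variability_score <- function(series, mode = c("low", "high"), eps = 1e-6,
                              species = NULL) {
  mode <- match.arg(mode)
  if (is.null(species))
    species <- setdiff(names(series), c("passage", "total_od600",
                                        "condition_id", "replicate"))
  M <- as.matrix(series[order(series$passage), species])
  if (nrow(M) < 2) stop("need at least 2 passages")
  sd_sum <- sum(apply(M, 1, function(x) {
    x <- x[x > 0]
    if (!length(x)) 0 else -sum(x / sum(x) * log(x / sum(x)))
  }))
  eu_sum <- sum(sqrt(rowSums((M[-1, , drop = FALSE] -
                                M[-nrow(M), , drop = FALSE])^2)))
  if (mode == "low") sd_sum / max(eu_sum, eps) else sd_sum * eu_sum
}

#' Design subset communities with prescribed temporal variability
#'
#' For each candidate subset, searches the inoculum space of the present
#' species (absent species clamped to zero) for the initial densities
#' maximizing the low- or high-variability objective over four simulated
#' passages. Endpoint compositions are deduplicated within a per-species
#' tolerance, and the surviving designs are ranked by objective.
#'
#' @param params A fitted `glv_params` object.
#' @param subsets List of species subsets ([enumerate_subcommunities()]).
#' @param mode `"low"` or `"high"`.
#' @param dedup_tol Per-species tolerance for collapsing equivalent designs
#'   (default 0.05).
#' @param x0_bounds Inoculum bounds for present species (OD600).
#' @param n_starts Multi-starts per subset.
#' @param n_passages,dilution,t_per_passage Passage-simulation settings.
#' @param eps Low-mode denominator floor.
#' @param seed Seed.
#' @return Tibble of designs ranked by objective: members, size, `x0`
#'   (list), `objective`, `series` (list of passage tibbles), `dedup_group`.
#' @export
design_communities <- function(params, subsets, mode = c("low", "high"),
                               dedup_tol = 0.05,
                               x0_bounds = c(1e-6, 0.01), n_starts = 5,
                               n_passages = 4, dilution = 25,
                               t_per_passage = 28, eps = 1e-6, seed = 1) {
  mode <- match.arg(mode)
  species <- params$species
  S <- length(species)
  lb <- log10(x0_bounds[1]); ub <- log10(x0_bounds[2])
  designs <- purrr::imap(subsets, function(members, si) {
    idx <- match(members, species)
    k <- length(idx)
    obj <- function(lx) {
      x0 <- numeric(S); x0[idx] <- 10^lx
      ch <- cpp_glv_passages(unname(params$mu), params$A, x0, n_passages,
                             dilution, t_per_passage)
      if (ch$diverged) return(1e8)
      M <- ch$endpoints
      tot <- rowSums(M)
      if (any(tot <= 0)) return(1e8)
      Mfr <- M / tot
      sd_sum <- sum(apply(Mfr, 1, function(x) {
        x <- x[x > 0]; if (!length(x)) 0 else -sum(x * log(x))
      }))
      eu_sum <- sum(sqrt(rowSums((Mfr[-1, , drop = FALSE] -
                                    Mfr[-nrow(Mfr), , drop = FALSE])^2)))
      if (mode == "low") -sd_sum / max(eu_sum, eps) else -sd_sum * eu_sum
    }
    starts <- local({
      set.seed(seed + si)
      c(list(rep((lb + ub) / 2, k)),
        purrr::map(seq_len(n_starts - 1), ~ runif(k, lb, ub)))
    })
    best <- NULL
    for (s in starts) {
      fit <- try(optim(s, obj, method = "L-BFGS-B", lower = rep(lb, k),
                       upper = rep(ub, k), control = list(factr = 1e8)),
                 silent = TRUE)
      if (inherits(fit, "try-error") || !is.finite(fit$value)) next
      if (is.null(best) || fit$value < best$value) best <- fit
    }
    if (is.null(best)) return(NULL)
    x0 <- setNames(numeric(S), species); x0[idx] <- 10^best$par
    series <- simulate_passages(params, x0, n_passages, dilution, t_per_passage)
    tibble::tibble(members = list(members), size = k, x0 = list(x0),
                   objective = -best$value, series = list(series))
  })
  out <- dplyr::bind_rows(purrr::compact(designs))
  if (!nrow(out)) stop("no subset optimization succeeded")
  out <- dplyr::arrange(out, dplyr::desc(.data$objective))
  # dedup by final-passage composition within per-species tolerance
  finals <- do.call(rbind, purrr::map(out$series, function(s)
    as.numeric(s[s$passage == max(s$passage), species])))
  group <- integer(nrow(out))
  reps <- list()
  for (i in seq_len(nrow(out))) {
    hit <- purrr::detect_index(reps, ~ all(abs(finals[i, ] - .x) < dedup_tol))
    if (hit == 0) {
      reps[[length(reps) + 1]] <- finals[i, ]
      hit <- length(reps)
    }
    group[i] <- hit
  }
  out$dedup_group <- group
  out$is_unique <- !duplicated(group)
  out
}

#' Greedy cover of species by ranked designs
#'
#' Walks the ranked design list and keeps a design whenever it contains a
#' species not yet covered `min_times` times; used to choose a minimal
#' validation set in which every species appears at least twice.
#'
#' @param designs Ranked design tibble from [design_communities()].
#' @param species Full species set to cover.
#' @param min_times Required coverage per species (default 2).
#' @return Subset of `designs`.
#' @export
select_validation_designs <- function(designs, species, min_times = 2) {
  counts <- setNames(rep(0L, length(species)), species)
  keep <- logical(nrow(designs))
  for (i in seq_len(nrow(designs))) {
    if (!designs$is_unique[i]) next
    mem <- designs$members[[i]]
    if (any(counts[mem] < min_times)) {
      keep[i] <- TRUE
      counts[mem] <- counts[mem] + 1L
    }
    if (all(counts >= min_times)) break
  }
  designs[keep, ]
}

#' Evaluate measured designs: passage CVs and group comparison
#'
#' Computes the per-species coefficient of variation across passages for
#' each measured community, then compares the low- and high-variability
#' groups with a two-sided Mann-Whitney (Wilcoxon rank-sum) test.
#'
#' @param measured Tibble of passage series: columns `community`, `group`
#'   (`"low"`/`"high"`), `passage`, species columns (mean relative
#'   abundances across replicates).
#' @param species Species columns; default autodetected.
#' @return List: `cv` (tibble community, group, species, cv_pct), `test`
#'   (`htest` from [wilcox.test()]).
#' @export
evaluate_design <- function(measured, species = NULL) {
  if (is.null(species))
    species <- setdiff(names(measured),
                       c("community", "group", "passage", "total_od600",
                         "replicate", "condition_id"))
  cv <- measured |>
    dplyr::group_by(.data$community, .data$group) |>
    dplyr::group_modify(function(g, k) {
      present <- species[colSums(as.matrix(g[species])) > 0]
      passage_cv(g, species = present)
    }) |>
    dplyr::ungroup() |>
    dplyr::filter(!.data$flag_zero_mean)
  groups <- unique(cv$group)
  if (length(groups) < 2) stop("need both a low and a high variability group")
  test <- wilcox.test(cv_pct ~ group, data = cv, exact = FALSE)
  list(cv = cv, test = test)
}
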