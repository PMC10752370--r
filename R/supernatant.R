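#' Area under a growth curve
#'
#' Trapezoidal integral of OD600 over time up to `t_max` hours; the summary
#' statistic for conditioned-media growth assays.
#'
#' @param times,od Numeric vectors (hours ascending, OD600).
#' @param t_max Integration horizon (default 40 h).
#' @return Area in OD600 * h.
#' @export
auc_growth <- function(times, od, t_max = 40) {
  if (length(times) < 2) stop("need at least 2 timepoints")
  if (is.unsorted(times, strictly = TRUE)) stop("times must be strictly increasing")
  keep <- times <= t_max
  t <- times[keep]; y <- od[keep]
  sum(diff(t) * (head(y, -1) + y[-1]) / 2)
}

#' Pairwise supernatant growth effects
#'
#' For every recipient/donor pair, the effect is the median area under the
#' recipient's growth curve on the donor's spent supernatant minus the
#' median area on fresh media. Self pairs are omitted.
#'
#' @param panel Long tibble with columns `recipient`, `donor` (including
#'   `"fresh"` reference rows), `replicate`, `time_h`, `od600`.
#' @param t_max AUC horizon (hours).
#' @return Matrix (recipient rows x donor columns) of effects in OD600 * h,
#'   diagonal `NA`.
#' @export
supernatant_effects <- function(panel, t_max = 40) {
  aucs <- panel |>
    dplyr::group_by(.data$recipient, .data$donor, .data$replicate) |>
    dplyr::summarise(auc = auc_growth(.data$time_h, .data$od600, t_max),
                     .groups = "drop") |>
    dplyr::group_by(.data$recipient, .data$donor) |>
    dplyr::summarise(auc = median(.data$auc), .groups = "drop")
  species <- sort(unique(aucs$recipient))
  fresh <- dplyr::filter(aucs, .data$donor == "fresh")
  if (nrow(fresh) < length(species))
    stop("missing fresh-media reference for recipient(s): ",
         paste(setdiff(species, fresh$recipient), collapse = ", "))
  E <- matrix(NA_real_, length(species), length(species),
              dimnames = list(species, species))
  for (r in seq_len(nrow(aucs))) {
    don <- aucs$donor[r]
    if (don == "fresh" || don == aucs$recipient[r]) next
    E[aucs$recipient[r], don] <-
      aucs$auc[r] - fresh$auc[fresh$recipient == aucs$recipient[r]]
  }
  E
}

#' Sign consistency between supernatant effects and gLV interactions
#'
#' Both matrices are normalized by their own maximum absolute value, then
#' each off-diagonal entry is categorized positive (> `threshold_frac`),
#' negative (< `-threshold_frac`) or zero (strict inequalities, so a value
#' exactly at the threshold counts as zero — the threshold exists to treat
#' L1-shrunken near-zero parameters as zero). Consistency is the percentage
#' of pairs with matching categories; a Spearman rank correlation over the
#' off-diagonal pairs is reported with its two-sided p-value.
#'
#' @param effects Effect matrix from [supernatant_effects()] (recipient rows,
#'   donor columns).
#' @param glv A `glv_params` object over the same species.
#' @param threshold_frac Zero-band half width after normalization
#'   (default 0.05).
#' @return List: `percent_consistent`, `spearman_rho`, `spearman_p`,
#'   `table` (per-pair tibble).
#' @export
sign_consistency <- function(effects, glv, threshold_frac = 0.05) {
  species <- rownames(effects)
  if (!identical(sort(species), sort(glv$species)))
    stop("species sets differ between effects and gLV parameters")
  A <- glv$A[species, species]
  off <- row(A) != col(A)
  norm <- function(M) {
    m <- max(abs(M[off]), na.rm = TRUE)
    if (m == 0) stop("all-zero matrix cannot be normalized")
    M / m
  }
  En <- norm(effects); An <- norm(A)
  cat3 <- function(v) ifelse(v > threshold_frac, 1L,
                             ifelse(v < -threshold_frac, -1L, 0L))
  keep <- off & !is.na(En)
  tab <- tibble::tibble(
    recipient = rownames(A)[row(A)[keep]],
    donor = colnames(A)[col(A)[keep]],
    effect_norm = En[keep], interaction_norm = An[keep],
    effect_cat = cat3(En[keep]), interaction_cat = cat3(An[keep])
  )
  ct <- suppressWarnings(cor.test(tab$effect_norm, tab$interaction_norm,
                                  method = "spearman", exact = FALSE))
  list(percent_consistent = 100 * mean(tab$effect_cat == tab$interaction_cat),
       spearman_rho = unname(ct$estimate), spearman_p = ct$p.value,
       table = tab)
}
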