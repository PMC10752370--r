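#' Generate a ground-truth synthetic world
#'
#' A world bundles a gLV truth (growth rates, interaction matrix), a
#' media-response truth (sparse per-species polynomial coefficients over four
#' media factors), and a noise model, all reproducible from one seed. The
#' interaction structure mirrors a competitively dominated gut community:
#' off-diagonal terms are sparse and mostly negative, self-interactions are
#' `-mu_i / K_i` with capacities drawn so that the summed capacity exceeds a
#' realistic community total. Noise defaults: multiplicative log-normal on
#' abundances (sdlog 0.1, the scale of replicate compositional scatter) plus
#' additive Gaussian OD600 noise (sd 0.005, plate-reader scale).
#'
#' @param n_species Community size (default 10).
#' @param seed Seed.
#' @param neg_fraction Fraction of non-zero inter-species interactions that
#'   are negative (default 0.8).
#' @param sparsity Fraction of inter-species pairs with a non-zero
#'   interaction (default 0.5).
#' @param noise_sdlog Multiplicative log-normal noise SD on abundances.
#' @param noise_od Additive OD600 noise SD.
#' @return A `synthetic_world` object containing `glv` ([glv_params()]),
#'   `K` (per-species capacities), `media_truth`, `noise`, `seed`.
#' @export
make_world <- function(n_species = 10, seed = 1, neg_fraction = 0.8,
                       sparsity = 0.5, noise_sdlog = 0.1, noise_od = 0.005) {
  set.seed(seed)
  species <- sprintf("sp%02d", seq_len(n_species))
  mu <- runif(n_species, 0.2, 1.0)
  K <- runif(n_species, 0.3, 1.2)
  aii <- -mu / K
  A <- matrix(0, n_species, n_species)
  diag(A) <- aii
  off <- which(row(A) != col(A))
  nz <- off[runif(length(off)) < sparsity]
  sgn <- ifelse(runif(length(nz)) < neg_fraction, -1, 1)
  mag <- runif(length(nz), 0.05, 0.5) * mean(abs(aii)) * 0.5
  A[nz] <- sgn * mag
  glv <- glv_params(mu, A, species)
  # media truth: sparse main effects on 4 coded factors + baseline capacity
  media_truth <- purrr::map(seq_len(n_species), function(i) {
    beta <- numeric(4)
    active <- sample(4, sample(2:3, 1))
    beta[active] <- runif(length(active), -0.25, 0.25)
    list(intercept = runif(1, 0.4, 1.0), main = beta)
  })
  names(media_truth) <- species
  structure(list(glv = glv, K = setNames(K, species),
                 media_truth = media_truth,
                 noise = list(sdlog = noise_sdlog, od = noise_od),
                 species = species, seed = seed),
            class = "synthetic_world")
}

#' @exportS3Method
print.synthetic_world <- function(x, ...) {
  cat("synthetic world:", length(x$species), "species, seed", x$seed, "\n")
  print(x$glv)
  invisible(x)
}

#' Synthesize monoculture OD600 growth curves
#'
#' Logistic trajectories from each species' (mu, K) truth, sampled every
#' `sample_every` hours to `t_end` (the plate-reader cadence: 2 h to 60 h,
#' 31 timepoints), with additive OD noise, optional 10-fold dilution series
#' and optional injected flat "failed" replicates for outlier-detection
#' tests.
#'
#' @param world A `synthetic_world`.
#' @param inoc_density Base inoculation density (OD600).
#' @param dilutions Ten-fold dilution exponents of the base density
#'   (0 = undiluted).
#' @param sample_every,t_end Sampling grid (hours).
#' @param replicates Replicates per condition (default 4).
#' @param failed_replicates Tibble with `species`, `replicate` naming
#'   replicates to replace by flat no-growth curves, or `NULL`.
#' @param noise Apply the world's OD noise? (default `TRUE`)
#' @param seed Seed for the noise.
#' @return Long growth-curve tibble (see [read_growth_curves()]).
#' @export
synthesize_monocultures <- function(world, inoc_density = 0.01, dilutions = 0,
                                    sample_every = 2, t_end = 60,
                                    replicates = 4, failed_replicates = NULL,
                                    noise = TRUE, seed = world$seed + 1) {
  set.seed(seed)
  times <- seq(0, t_end, by = sample_every)
  grid <- tidyr::expand_grid(species = world$species, dil = dilutions,
                             replicate = seq_len(replicates))
  purrr::pmap_dfr(grid, function(species, dil, replicate) {
    i <- match(species, world$species)
    x0 <- inoc_density / 10^dil
    od <- logistic_simulate(world$glv$mu[i], world$K[i], x0, times)
    failed <- !is.null(failed_replicates) &&
      nrow(dplyr::filter(failed_replicates, .data$species == !!species,
                         .data$replicate == !!replicate)) > 0
    if (failed) od <- rep(x0, length(times))
    if (noise) od <- pmax(od + rnorm(length(times), 0, world$noise$od), 0)
    tibble::tibble(species = species,
                   condition_id = sprintf("dil%d", dil),
                   replicate = replicate, time_h = times, od600 = od,
                   inoc_density = x0)
  })
}

#' Synthesize designed community endpoint compositions
#'
#' Simulates the world's gLV dynamics from each designed inoculum to
#' `t_end`, applies multiplicative replicate noise, and reports the
#' measurements a 16S + OD600 readout would give: relative abundances plus
#' total OD600. Passage chains (fixed-fold dilution of the previous
#' endpoint) are generated when `n_passages > 1`.
#'
#' @param world A `synthetic_world`.
#' @param runs Absolute-valued run table: `run_id` plus one column per
#'   species (initial densities, OD600).
#' @param t_end Endpoint time (hours, default 28).
#' @param replicates Biological replicates (default 3).
#' @param n_passages Passages to chain (default 1).
#' @param dilution Passage dilution factor (default 25).
#' @param noise Apply multiplicative noise? (default `TRUE`)
#' @param seed Seed.
#' @return Wide composition tibble (see [read_compositions()]).
#' @export
synthesize_communities <- function(world, runs, t_end = 28, replicates = 3,
                                   n_passages = 1, dilution = 25,
                                   noise = TRUE, seed = world$seed + 2) {
  set.seed(seed)
  species <- world$species
  S <- length(species)
  purrr::map_dfr(seq_len(nrow(runs)), function(r) {
    x0 <- as.numeric(runs[r, species])
    chain <- cpp_glv_passages(unname(world$glv$mu), world$glv$A, x0,
                              n_passages, dilution, t_end)
    purrr::map_dfr(seq_len(n_passages), function(p) {
      true_abs <- chain$endpoints[p, ]
      purrr::map_dfr(seq_len(replicates), function(rep) {
        meas <- true_abs
        if (noise)
          meas <- meas * rlnorm(S, 0, world$noise$sdlog)
        tot <- sum(meas)
        fr <- if (tot > 0) meas / tot else meas
        out <- tibble::tibble(condition_id = runs$run_id[r], replicate = rep,
                              passage = p, total_od600 = tot)
        out[species] <- as.list(fr)
        out
      })
    })
  })
}

#' Synthesize a media-screen carrying-capacity response
#'
#' Evaluates each species' ground-truth response polynomial (intercept +
#' sparse main effects on the coded factors) at every design run, adds
#' Gaussian noise and floors at zero.
#'
#' @param world A `synthetic_world`.
#' @param design Coded design tibble ([generate_design()], 4 factors).
#' @param noise_sd Gaussian noise SD on K (default the world's OD noise).
#' @param seed Seed.
#' @return Tibble: run_id, species, K.
#' @export
synthesize_media_screen <- function(world, design, noise_sd = world$noise$od,
                                    seed = world$seed + 3) {
  set.seed(seed)
  X <- as.matrix(dplyr::select(design, -"run_id"))
  purrr::imap_dfr(world$media_truth, function(tr, sp) {
    K <- tr$intercept + as.numeric(X %*% tr$main) +
      rnorm(nrow(X), 0, noise_sd)
    tibble::tibble(run_id = design$run_id, species = sp, K = pmax(K, 0))
  })
}

#' Synthesize a supernatant growth panel
#'
#' Recipient-on-donor-supernatant growth curves whose area-under-curve
#' shifts are proportional to the world's interaction terms: the recipient's
#' fresh-media logistic curve is scaled by
#' `1 + gain * a_ij / max|a_offdiag|`, so the sign of every supernatant
#' effect matches the sign of the corresponding interaction by
#' construction.
#'
#' @param world A `synthetic_world`.
#' @param gain Relative AUC shift at the largest interaction (default 0.4).
#' @param t_end,sample_every Curve sampling (hours).
#' @param replicates Replicates per cell (default 4).
#' @param noise Apply OD noise? (default `TRUE`)
#' @param seed Seed.
#' @return Long tibble: recipient, donor (`"fresh"` for the reference),
#'   replicate, time_h, od600.
#' @export
synthesize_supernatant_panel <- function(world, gain = 0.4, t_end = 40,
                                         sample_every = 2, replicates = 4,
                                         noise = TRUE, seed = world$seed + 4) {
  set.seed(seed)
  species <- world$species
  times <- seq(0, t_end, by = sample_every)
  A <- world$glv$A
  off <- A[row(A) != col(A)]
  amax <- max(abs(off), 1e-12)
  donors <- c("fresh", species)
  purrr::map_dfr(species, function(rec) {
    i <- match(rec, species)
    base <- logistic_simulate(world$glv$mu[i], world$K[i], 0.01, times)
    purrr::map_dfr(donors, function(don) {
      if (don == rec) return(NULL)
      fac <- if (don == "fresh") 1 else 1 + gain * A[i, match(don, species)] / amax
      purrr::map_dfr(seq_len(replicates), function(rep) {
        od <- base * max(fac, 0.05)
        if (noise) od <- pmax(od + rnorm(length(od), 0, world$noise$od), 0)
        tibble::tibble(recipient = rec, donor = don, replicate = rep,
                       time_h = times, od600 = od)
      })
    })
  })
}
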