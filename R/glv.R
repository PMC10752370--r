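#' Generalized Lotka-Volterra parameter bundle
#'
#' \deqn{dx_i/dt = (\mu_i + \sum_j a_{ij} x_j) x_i}
#' with basal growth rates mu and pairwise interaction matrix A. Diagonal
#' entries are self-limitation terms (`a_ii = -mu_i / K_i` recovers an
#' independent logistic with capacity `K_i`); off-diagonal entries are
#' inter-species interactions. Biological bounds: mu in [0, 3] 1/h, a_ii in
#' [-10, 0], a_ij in [-10, 10] 1/(OD600 h) — non-positive self-interactions
#' and non-negative growth rates keep trajectories bounded and
#' interpretable.
#'
#' @param mu Per-species growth rates.
#' @param A Interaction matrix (S x S).
#' @param species Optional labels.
#' @return A `glv_params` object.
#' @export
glv_params <- function(mu, A, species = NULL) {
  S <- length(mu)
  A <- as.matrix(A)
  if (!all(dim(A) == S)) stop("A must be ", S, " x ", S)
  if (any(mu < 0 - 1e-12) || any(mu > 3 + 1e-12))
    stop("growth rates must lie in [0, 3] 1/h")
  if (any(diag(A) > 1e-12)) stop("self-interaction terms must be <= 0")
  if (any(abs(A) > 10 + 1e-9)) stop("interaction terms must lie in [-10, 10]")
  if (is.null(species)) species <- paste0("sp", seq_len(S))
  dimnames(A) <- list(species, species)
  structure(list(mu = setNames(as.numeric(mu), species), A = A,
                 species = species),
            class = "glv_params")
}

#' @exportS3Method
print.glv_params <- function(x, ...) {
  off <- x$A[row(x$A) != col(x$A)]
  cat(sprintf("gLV parameters: %d species, %d non-zero interactions (%.0f%% negative)\n",
              length(x$mu), sum(off != 0),
              if (any(off != 0)) 100 * mean(off[off != 0] < 0) else 0))
  invisible(x)
}

#' @export
tidy.glv_params <- function(x, ...) {
  expand.grid(target = x$species, source = x$species,
              stringsAsFactors = FALSE) |>
    tibble::as_tibble() |>
    dplyr::mutate(weight = as.vector(x$A),
                  sign = sign(.data$weight)) |>
    dplyr::select("source", "target", "weight", "sign")
}

#' Simulate generalized Lotka-Volterra dynamics
#'
#' @param params A [glv_params()] object.
#' @param x0 Initial abundances (>= 0); zero stays zero.
#' @param t_end Horizon (hours).
#' @param times Optional explicit record times.
#' @param dt Integrator step.
#' @return Tidy tibble: time_h, species, abundance.
#' @export
simulate_glv <- function(params, x0, t_end = 28, times = NULL, dt = 0.05) {
  if (is.null(times)) times <- seq(0, t_end, by = max(dt, t_end / 200))
  x0 <- align_x0(x0, params$species)
  sim <- cpp_glv_simulate(unname(params$mu), params$A, x0, times, dt)
  if (sim$diverged)
    stop("gLV trajectory diverged (unbounded growth); check that self-",
         "interaction terms are negative where growth rates are positive")
  states_to_tidy(sim$states, times, params$species)
}

#' Endpoint abundances of a gLV community at a fixed time
#'
#' @inheritParams simulate_glv
#' @return Named abundance vector at `t_end`.
#' @export
glv_endpoint <- function(params, x0, t_end = 28, dt = 0.05) {
  x0 <- align_x0(x0, params$species)
  sim <- cpp_glv_simulate(unname(params$mu), params$A, x0, t_end, dt)
  if (sim$diverged) stop("gLV trajectory diverged")
  setNames(sim$states[1, ], params$species)
}

#' Assemble a gLV training dataset
#'
#' Uniform container for heterogeneous observations: monoculture time series
#' (dense OD600 curves), community endpoints (relative abundance times total
#' OD600 at a recorded time), and passage observations (chained by a fixed
#' dilution of the previous endpoint). One row per condition, with list
#' columns for the initial state, observation times and observation matrix
#' (times x species, `NA` for unobserved species).
#'
#' @param species Species labels fixing order.
#' @return Empty training tibble; add rows with [add_monocultures()] /
#'   [add_communities()].
#' @export
glv_training <- function(species) {
  out <- tibble::tibble(condition_id = character(), type = character(),
                        x0 = list(), times = list(), obs = list())
  attr(out, "species") <- species
  out
}

#' @rdname glv_training
#' @param data Training tibble.
#' @param curves Long growth-curve tibble (blanked monocultures).
#' @export
add_monocultures <- function(data, curves) {
  species <- attr(data, "species")
  S <- length(species)
  rows <- curves |>
    dplyr::group_by(.data$species, .data$condition_id, .data$replicate) |>
    dplyr::group_split() |>
    purrr::map_dfr(function(cu) {
      i <- match(cu$species[1], species)
      x0 <- numeric(S); x0[i] <- cu$inoc_density[1]
      obs <- matrix(NA_real_, nrow(cu), S)
      obs[, i] <- cu$od600
      tibble::tibble(
        condition_id = paste("mono", cu$species[1], cu$condition_id[1],
                             cu$replicate[1], sep = "_"),
        type = "monoculture",
        x0 = list(x0), times = list(cu$time_h), obs = list(obs))
    })
  out <- dplyr::bind_rows(data, rows)
  attr(out, "species") <- species
  out
}

#' @rdname glv_training
#' @param compositions Wide composition tibble (relative abundances +
#'   `total_od600`), replicate-averaged; passages > 1 are chained from the
#'   previous passage's endpoint divided by `dilution`.
#' @param inoculum Run table of designed initial densities with `condition_id`
#'   and species columns (passage-1 conditions).
#' @param t_obs Observation time (hours) per endpoint.
#' @param dilution Passage dilution factor (default 25).
#' @export
add_communities <- function(data, compositions, inoculum, t_obs = 28,
                            dilution = 25) {
  species <- attr(data, "species")
  rows <- compositions |>
    dplyr::group_by(.data$condition_id) |>
    dplyr::arrange(.data$passage, .by_group = TRUE) |>
    dplyr::group_split() |>
    purrr::map_dfr(function(g) {
      abs_prev <- NULL
      purrr::map_dfr(seq_len(nrow(g)), function(p) {
        abs_now <- as.numeric(g[p, species]) * g$total_od600[p]
        x0 <- if (g$passage[p] == 1 || is.null(abs_prev)) {
          ir <- inoculum[inoculum$condition_id == g$condition_id[p], species]
          if (!nrow(ir)) stop("no inoculum row for condition ", g$condition_id[p])
          as.numeric(ir[1, ])
        } else {
          abs_prev / dilution
        }
        abs_prev <<- abs_now
        tibble::tibble(
          condition_id = paste0(g$condition_id[p], "_p", g$passage[p]),
          type = if (g$passage[p] == 1) "community" else "passage",
          x0 = list(x0), times = list(t_obs),
          obs = list(matrix(abs_now, 1, length(species))))
      })
    })
  out <- dplyr::bind_rows(data, rows)
  attr(out, "species") <- species
  out
}

glv_pack <- function(mu, A) c(mu, as.vector(A))

glv_bounds <- function(S) {
  lower_A <- matrix(-10, S, S)
  upper_A <- matrix(10, S, S); diag(upper_A) <- 0
  list(lower = c(rep(0, S), as.vector(lower_A)),
       upper = c(rep(3, S), as.vector(upper_A)))
}

#' Fit a generalized Lotka-Volterra model by L1-penalized least squares
#'
#' Minimizes the sum of squared errors between simulated and observed
#' abundances over every training condition, plus `lambda` times the L1 norm
#' of the inter-species interaction terms, under the biological bounds of
#' [glv_params()]. Growth rates and self-interactions are initialized from
#' monoculture logistic fits; inter-species terms start at zero (the value
#' the penalty shrinks poorly constrained parameters toward). Bounded
#' quasi-Newton search with a small deterministic multi-start.
#'
#' @param data Training tibble from [glv_training()].
#' @param lambda L1 penalty weight.
#' @param init Optional `glv_params` initial guess (overrides the
#'   monoculture-derived default).
#' @param penalize_diag Also penalize self-interaction terms? (default off)
#' @param n_starts Multi-starts (default 3; the extra starts jitter the
#'   initialization).
#' @param maxit Iteration cap per optimization stage and start.
#' @param dt Integrator step for the objective (hours).
#' @param seed Seed for the start jitter.
#'
#' @details The search runs in two stages per start. Monoculture data carry
#' no information about inter-species terms (absent species never enter the
#' dynamics), so the first stage holds the monoculture-informed growth rates
#' and self-interactions fixed and optimizes only the inter-species terms —
#' a far better-conditioned subproblem — and the second stage polishes all
#' parameters jointly.
#'
#' @return A `glv_params` object with attributes `objective` and
#'   `convergence`.
#' @export
fit_glv <- function(data, lambda = 0.1, init = NULL, penalize_diag = FALSE,
                    n_starts = 3, maxit = 300, dt = 0.15, seed = 1) {
  species <- attr(data, "species")
  S <- length(species)
  if (!nrow(data)) stop("empty training dataset")
  x0s <- do.call(rbind, data$x0)
  b <- glv_bounds(S)
  par0 <- if (!is.null(init)) {
    glv_pack(unname(init$mu), init$A)
  } else {
    mono_init_glv(data, species)
  }
  par0 <- pmin(pmax(par0, b$lower), b$upper)
  obj <- function(p) cpp_glv_objective(p, S, x0s, data$times, data$obs,
                                       lambda, penalize_diag, dt)
  off_idx <- S + which(as.vector(row(diag(S)) != col(diag(S)))) # off-diagonal A
  grad_all <- function(p) cpp_glv_gradient(p, S, x0s, data$times, data$obs,
                                           lambda, penalize_diag, dt)
  # conditions with >= 2 species present; the only ones informing stage 1
  multi <- which(purrr::map_lgl(data$x0, ~ sum(.x > 0) >= 2))
  x0s_m <- x0s[multi, , drop = FALSE]
  times_m <- data$times[multi]; obs_m <- data$obs[multi]
  jitters <- local({
    set.seed(seed)
    purrr::map(seq_len(max(0, n_starts - 1)),
               ~ rnorm(length(par0), sd = 0.05))
  })
  starts <- c(list(par0),
              purrr::map(jitters, ~ pmin(pmax(par0 + .x, b$lower), b$upper)))
  best <- NULL
  for (s in starts) {
    # stage 1: inter-species terms only, kinetic parameters fixed,
    # multi-species conditions only (monocultures are constant here)
    obj_off <- function(po) {
      p <- s; p[off_idx] <- po
      cpp_glv_objective(p, S, x0s_m, times_m, obs_m, lambda, penalize_diag, dt)
    }
    grad_off <- function(po) {
      p <- s; p[off_idx] <- po
      cpp_glv_gradient(p, S, x0s_m, times_m, obs_m, lambda,
                       penalize_diag, dt, idx = off_idx - 1L)[off_idx]
    }
    st1 <- if (length(multi)) {
      try(stats::nlminb(s[off_idx], obj_off, grad_off,
                        lower = b$lower[off_idx], upper = b$upper[off_idx],
                        control = list(iter.max = maxit,
                                       eval.max = 2 * maxit)),
          silent = TRUE)
    } else structure("no multi-species conditions", class = "try-error")
    s2 <- s
    if (!inherits(st1, "try-error")) s2[off_idx] <- st1$par
    # stage 2: joint polish of all parameters on the full dataset
    fit <- try(stats::nlminb(s2, obj, grad_all, lower = b$lower,
                             upper = b$upper,
                             control = list(iter.max = max(50, maxit %/% 3),
                                            eval.max = maxit)),
               silent = TRUE)
    if (inherits(fit, "try-error")) {
      if (inherits(st1, "try-error")) next
      fit <- list(par = s2, objective = obj(s2), convergence = 52L)
    }
    fit$value <- fit$objective
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best))
    stop("gLV fit failed to converge from any start")
  out <- glv_params(best$par[seq_len(S)],
                    matrix(best$par[-seq_len(S)], S, S), species)
  attr(out, "objective") <- best$value
  attr(out, "convergence") <- best$convergence
  out
}

# initial parameter guess: logistic fit per monoculture species, zeros for
# inter-species terms
mono_init_glv <- function(data, species) {
  S <- length(species)
  mu0 <- rep(0.5, S)
  aii <- rep(-1, S)
  mono <- data[data$type == "monoculture", ]
  if (nrow(mono)) {
    for (i in seq_len(S)) {
      rows <- which(purrr::map_lgl(mono$x0, ~ which.max(.x) == i & sum(.x > 0) == 1))
      if (!length(rows)) next
      r <- rows[[1]]
      tm <- mono$times[[r]]; ob <- mono$obs[[r]][, i]
      f <- try(fit_logistic(tm, ob, mono$x0[[r]][i],
                            truncate_h = max(tm)), silent = TRUE)
      if (!inherits(f, "try-error")) {
        mu0[i] <- min(f$mu, 3)
        aii[i] <- max(-f$mu / f$K, -10)
      }
    }
  }
  A0 <- matrix(0, S, S); diag(A0) <- aii
  glv_pack(mu0, A0)
}

#' Predict community observations and score against data
#'
#' Simulates every condition of a training tibble under `params` and pairs
#' predictions with observations. Both are normalized to relative abundance
#' before the correlation statistic, so the score is invariant to
#' per-condition rescaling of absolute abundances.
#'
#' @param params A `glv_params` object.
#' @param data Training tibble (typically a held-out subset).
#' @param dt Integrator step.
#' @return List: `table` (tibble of condition, species, observed, predicted,
#'   relative versions), `pearson` (pooled correlation over relative
#'   abundances).
#' @export
score_glv <- function(params, data, dt = 0.05) {
  species <- attr(data, "species")
  tab <- purrr::map_dfr(seq_len(nrow(data)), function(r) {
    sim <- cpp_glv_simulate(unname(params$mu), params$A, data$x0[[r]],
                            data$times[[r]], dt)
    obs <- data$obs[[r]]
    purrr::map_dfr(seq_along(data$times[[r]]), function(t) {
      o <- obs[t, ]; p <- sim$states[t, ]
      keep <- !is.na(o)
      ofr <- if (sum(o[keep]) > 0) o / sum(o[keep]) else o
      pfr <- if (sum(p[keep]) > 0) p / sum(p[keep]) else p
      tibble::tibble(condition_id = data$condition_id[r],
                     time_h = data$times[[r]][t],
                     species = species[keep],
                     observed = o[keep], predicted = p[keep],
                     observed_rel = ofr[keep], predicted_rel = pfr[keep])
    })
  })
  r <- suppressWarnings(cor(tab$observed_rel, tab$predicted_rel))
  list(table = tab, pearson = r)
}
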