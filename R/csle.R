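#' Constrained-system-of-logistic-equations parameter bundle
#'
#' Independent logistic models coupled by one shared total-growth constraint:
#' \deqn{dx_i/dt = \mu_i (1 - x_i/K_i) (1 - \sum_j x_j / K_{comm}) x_i}
#' Each species grows logistically toward its own capacity `K_i` until the
#' community total approaches the community carrying capacity `K_comm`,
#' which freezes the race: when `sum(K) > K_comm` the endpoint composition
#' depends on the inoculum.
#'
#' @param mu Per-species growth rates (1/h), >= 0.
#' @param K Per-species carrying capacities (OD600), > 0.
#' @param K_comm Community carrying capacity (OD600), > 0.
#' @param species Optional species labels.
#' @return A `csle_params` object.
#' @export
csle_params <- function(mu, K, K_comm, species = NULL) {
  if (length(mu) != length(K)) stop("mu and K differ in length")
  if (any(mu < 0) || any(K <= 0) || K_comm <= 0)
    stop("need mu >= 0, K > 0, K_comm > 0")
  if (is.null(species)) species <- paste0("sp", seq_along(mu))
  structure(list(mu = setNames(as.numeric(mu), species),
                 K = setNames(as.numeric(K), species),
                 K_comm = K_comm, species = species),
            class = "csle_params")
}

#' @exportS3Method
print.csle_params <- function(x, ...) {
  cat("CSLE parameters for", length(x$mu), "species; K_comm =",
      format(x$K_comm), "OD600\n")
  invisible(x)
}

#' @export
tidy.csle_params <- function(x, ...) {
  tibble::tibble(species = x$species, mu = unname(x$mu), K = unname(x$K))
}

#' Simulate community assembly under the constrained logistic system
#'
#' @param params A [csle_params()] object.
#' @param x0 Named or ordered initial abundances (OD600), >= 0. Species
#'   starting at zero stay at zero.
#' @param t_end Horizon in hours.
#' @param times Optional explicit record times (overrides `t_end`).
#' @param dt Integrator step (hours).
#' @return Tidy tibble: time_h, species, abundance.
#' @export
simulate_csle <- function(params, x0, t_end = 28, times = NULL, dt = 0.05) {
  if (is.null(times)) times <- seq(0, t_end, by = max(dt, t_end / 200))
  x0 <- align_x0(x0, params$species)
  sim <- cpp_csle_simulate(unname(params$mu), unname(params$K), params$K_comm,
                           x0, times, dt)
  if (sim$diverged) stop("CSLE integration diverged; state: ",
                         paste(format(x0), collapse = ", "))
  states_to_tidy(sim$states, times, params$species)
}

#' Endpoint of the constrained logistic system at steady state
#'
#' Integrates until `max(|dx/dt|) < dtol` or `t_max`, whichever first.
#'
#' @inheritParams simulate_csle
#' @param t_max Maximum horizon (hours).
#' @param dtol Derivative tolerance defining steady state.
#' @return Named vector of steady-state abundances.
#' @export
csle_steady_state <- function(params, x0, t_max = 200, dtol = 1e-9, dt = 0.05) {
  x0 <- align_x0(x0, params$species)
  out <- cpp_csle_steady(unname(params$mu), unname(params$K), params$K_comm,
                         x0, dt, t_max, dtol)
  if (out$diverged) stop("CSLE integration diverged")
  setNames(out$x, params$species)
}

align_x0 <- function(x0, species) {
  if (!is.null(names(x0))) {
    miss <- setdiff(species, names(x0))
    if (length(miss)) stop("x0 missing species: ", paste(miss, collapse = ", "))
    x0 <- x0[species]
  }
  if (length(x0) != length(species)) stop("x0 length does not match species")
  if (any(x0 < 0)) stop("initial abundances must be >= 0")
  unname(as.numeric(x0))
}

states_to_tidy <- function(states, times, species) {
  colnames(states) <- species
  tibble::as_tibble(states) |>
    dplyr::mutate(time_h = times, .before = 1) |>
    tidyr::pivot_longer(-"time_h", names_to = "species", values_to = "abundance")
}

#' Infer CSLE parameters from monoculture growth data
#'
#' Two parameterization routes:
#' \describe{
#'   \item{`empirical`}{Per-species logistic fits supply (mu, K); `K_comm`
#'     is an observed full-community endpoint OD600 passed by the caller.}
#'   \item{`joint`}{All `2S + 1` parameters — including `K_comm` — are
#'     inferred together by bounded L1-penalized least squares against every
#'     monoculture time series (in monoculture the constraint reads
#'     `(1 - x/K_comm)`).}
#' }
#' Bounds: mu <= 10 /h, K <= 10 OD600, K_comm <= 5 OD600, all >= 0.
#'
#' @param curves Long growth-curve tibble (blanked), all species.
#' @param route `"empirical"` or `"joint"`.
#' @param community_endpoint Observed community endpoint OD600 (empirical
#'   route only).
#' @param lambda L1 penalty weight for the joint route.
#' @param truncate_h Fitting horizon per curve (hours).
#' @param dt Integrator step.
#' @return A [csle_params()] object; attribute `sse` carries the joint-route
#'   residual.
#' @export
infer_csle <- function(curves, route = c("empirical", "joint"),
                       community_endpoint = NULL, lambda = 1e-4,
                       truncate_h = 30, dt = 0.05) {
  route <- match.arg(route)
  species <- sort(unique(curves$species))
  if (route == "empirical") {
    if (is.null(community_endpoint))
      stop("empirical route requires `community_endpoint` (OD600)")
    fits <- purrr::map(species, function(sp) {
      cu <- dplyr::filter(curves, .data$species == sp) |>
        dplyr::group_by(.data$time_h) |>
        dplyr::summarise(od600 = mean(.data$od600),
                         inoc_density = mean(.data$inoc_density),
                         .groups = "drop")
      fit_logistic(cu$time_h, cu$od600, cu$inoc_density[1],
                   truncate_h = truncate_h, dt = dt)
    })
    return(csle_params(purrr::map_dbl(fits, "mu"), purrr::map_dbl(fits, "K"),
                       community_endpoint, species))
  }
  # joint route: par = (mu_s, K_s per species, K_comm)
  S <- length(species)
  curve_list <- curves |>
    dplyr::filter(.data$time_h <= truncate_h) |>
    dplyr::group_by(.data$species, .data$condition_id, .data$replicate) |>
    dplyr::group_split()
  sp_index <- purrr::map_int(curve_list, ~ match(.x$species[1], species))
  start_fits <- purrr::map(species, function(sp) {
    cu <- dplyr::filter(curves, .data$species == sp)
    cu <- dplyr::filter(cu, .data$replicate == cu$replicate[1],
                        .data$condition_id == cu$condition_id[1],
                        .data$time_h <= truncate_h)
    fit_logistic(cu$time_h, cu$od600, cu$inoc_density[1],
                 truncate_h = truncate_h, dt = dt)
  })
  par0 <- c(purrr::map_dbl(start_fits, "mu"),
            pmin(purrr::map_dbl(start_fits, "K"), 5), 2.5)
  obj <- function(p) {
    mu <- p[seq_len(S)]; K <- p[S + seq_len(S)]; Kc <- p[2 * S + 1]
    tot <- 0
    for (i in seq_along(curve_list)) {
      cu <- curve_list[[i]]
      s <- sp_index[i]
      sim <- cpp_csle_simulate(mu[s], K[s], Kc, cu$inoc_density[1],
                               cu$time_h, dt)
      if (sim$diverged) return(1e10)
      tot <- tot + sum((sim$states[, 1] - cu$od600)^2)
    }
    tot + lambda * sum(abs(p))
  }
  fit <- optim(par0, obj, method = "L-BFGS-B",
               lower = rep(1e-6, 2 * S + 1),
               upper = c(rep(10, S), rep(10, S), 5),
               control = list(factr = 1e5, maxit = 500))
  out <- csle_params(fit$par[seq_len(S)], fit$par[S + seq_len(S)],
                     fit$par[2 * S + 1], species)
  attr(out, "sse") <- fit$value
  out
}

#' Diversity-maximizing inoculum under the constrained logistic system
#'
#' Maximizes the Shannon diversity of the predicted steady-state composition
#' over the vector of initial densities, subject to box bounds and two linear
#' caps: the total inoculum must not exceed `total_cap`, and the sum over
#' non-pinned species must not exceed `free_cap`. Pinned species are held at
#' their stated density. Optimization uses multi-start bounded local search
#' in raw density space with an exact penalty on the linear caps, followed by
#' projection onto the feasible set.
#'
#' @param params A [csle_params()] object with `sum(K) > K_comm` (otherwise
#'   the steady state is composition-independent full growth).
#' @param total_cap Cap on the total inoculum (OD600, default 0.02).
#' @param free_cap Cap on the non-pinned species sum (default 0.01).
#' @param pinned Named vector of fixed inoculation densities.
#' @param lower Per-species lower bound (OD600; the practical floor below
#'   which inocula fail to grow).
#' @param upper Per-species upper bound.
#' @param n_starts Random multi-starts.
#' @param seed Seed for the starts.
#' @param dt,t_max,dtol Steady-state integration controls.
#' @return List: `x0` (named optimal inoculum), `endpoint`, `diversity`.
#' @export
optimize_inoculum_csle <- function(params, total_cap = 0.02, free_cap = 0.01,
                                   pinned = NULL, lower = 1e-7, upper = 0.01,
                                   n_starts = 20, seed = 1, dt = 0.05,
                                   t_max = 200, dtol = 1e-9) {
  species <- params$species
  S <- length(species)
  if (sum(params$K) <= params$K_comm)
    warning("sum(K) <= K_comm: steady-state composition is insensitive to the inoculum")
  free <- setdiff(species, names(pinned))
  nf <- length(free)
  if (!nf) stop("no free species to optimize")
  pin_sum <- sum(pinned)
  if (pin_sum > total_cap) stop("pinned densities alone exceed total_cap")
  cap <- min(free_cap, total_cap - pin_sum)
  lower <- rep_len(lower, nf); upper <- pmin(rep_len(upper, nf), cap)
  if (sum(lower) > cap) stop("infeasible: lower bounds exceed the free cap")

  project <- function(xf) {
    xf <- pmin(pmax(xf, lower), upper)
    if (sum(xf) > cap) xf <- lower + (xf - lower) * (cap - sum(lower)) / (sum(xf) - sum(lower))
    xf
  }
  assemble <- function(xf) {
    x0 <- setNames(numeric(S), species)
    x0[free] <- xf
    if (length(pinned)) x0[names(pinned)] <- pinned
    x0
  }
  objective <- function(xf) {
    xf <- project(xf)
    xs <- csle_steady_state(params, assemble(xf), t_max, dtol, dt)
    fr <- to_relative(pmax(xs, 0))
    if (is_failed_culture(fr)) return(1e6)
    -shannon_diversity(fr, tol = 1e-3) + 1e3 * max(0, sum(xf) - cap)^2
  }
  rng <- local({ set.seed(seed); purrr::map(seq_len(n_starts - 1), ~ runif(nf)) })
  starts <- c(list(rep(cap / nf, nf)),
              purrr::map(rng, ~ project(10^(log10(lower) + .x * (log10(upper) - log10(lower))))))
  best <- NULL
  for (s in starts) {
    fit <- try(optim(s, objective, method = "L-BFGS-B", lower = lower,
                     upper = upper, control = list(factr = 1e7)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("inoculum optimization failed from every start")
  xf <- project(best$par)
  x0 <- assemble(xf)
  endpoint <- csle_steady_state(params, x0, t_max, dtol, dt)
  list(x0 = x0, endpoint = endpoint,
       diversity = shannon_diversity(to_relative(endpoint), tol = 1e-3))
}

#' Calibrate designed inoculum levels from the constrained logistic model
#'
#' Finds, for one species, the initial density whose steady-state abundance
#' is `fold` times its abundance at the center-point inoculum, holding every
#' other species at the center point. The low level is then set
#' log-symmetrically about the center (`low = center^2 / high`), so the
#' coded design brackets a predicted `fold^2`-range of endpoint abundances.
#'
#' @param params A [csle_params()] object.
#' @param center_x0 Named center-point inoculum (all species).
#' @param species Species to calibrate.
#' @param fold Target steady-state fold change (default 3.3).
#' @param search_upper Upper bound of the density search (OD600).
#' @param tol Relative tolerance on the achieved fold change.
#' @param ... Steady-state controls passed to [csle_steady_state()].
#' @return Tibble: species, low, center, high, achieved_fold, at_bound.
#' @export
calibrate_levels_csle <- function(params, center_x0, species = params$species,
                                  fold = 3.3, search_upper = 0.1, tol = 1e-3,
                                  ...) {
  center_x0 <- setNames(align_x0(center_x0, params$species), params$species)
  purrr::map_dfr(species, function(sp) {
    base <- csle_steady_state(params, center_x0, ...)[sp]
    target <- fold * base
    g <- function(lx) {
      x0 <- center_x0
      x0[sp] <- 10^lx
      csle_steady_state(params, x0, ...)[sp] - target
    }
    lc <- log10(center_x0[sp]); lu <- log10(search_upper)
    at_bound <- FALSE
    hi <- if (fold == 1) {
      center_x0[sp]
    } else if (g(lu) < 0) {
      at_bound <- TRUE
      warning(sp, ": fold change ", fold, " unreachable within bounds; returning bound")
      search_upper
    } else {
      10^uniroot(g, c(lc, lu), tol = 1e-10)$root
    }
    achieved <- csle_steady_state(params, {
      x0 <- center_x0; x0[sp] <- hi; x0
    }, ...)[sp] / base
    tibble::tibble(species = sp, low = center_x0[sp]^2 / hi,
                   center = center_x0[sp], high = hi,
                   achieved_fold = unname(achieved), at_bound = at_bound)
  })
}
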