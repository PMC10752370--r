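#' Blank growth curves to the known inoculum density
#'
#' Plate-reader baselines drift, so each series is shifted by a constant so
#' that its first reading equals the known inoculation density:
#' `od600 - (od600[1] - inoc_density)`. The shift preserves all differences
#' between timepoints and is idempotent.
#'
#' @param df Long growth-curve tibble (see [read_growth_curves()]).
#' @return The tibble with `od600` blanked per curve.
#' @export
blank_growth_curves <- function(df) {
  df |>
    dplyr::group_by(.data$species, .data$condition_id, .data$replicate) |>
    dplyr::arrange(.data$time_h, .by_group = TRUE) |>
    dplyr::mutate(od600 = .data$od600 - (.data$od600[1] - .data$inoc_density[1])) |>
    dplyr::ungroup()
}

#' Detect non-growing replicates by z-score
#'
#' Within each species/condition, replicates are summarized (mean OD600 over
#' time by default, or the endpoint reading) and z-scored across replicates
#' using the population standard deviation. Replicates with z below
#' `-z_threshold` are flagged for omission — only on the low side, since the
#' aim is to drop cultures that failed to grow — and never more than one
#' replicate per condition (the most extreme wins).
#'
#' @param df Long growth-curve tibble.
#' @param z_threshold Positive z-score cutoff (default 1.5).
#' @param stat `"mean"` (mean OD over time) or `"endpoint"` (last reading).
#' @param min_drop Magnitude guard: a replicate is only omitted when its
#'   summary value is also below `(1 - min_drop)` times the condition median.
#'   Z-scores are scale-free, so without this guard a set of essentially
#'   identical replicates could flag pure plate-reader noise as "no growth".
#' @return Tibble with one row per replicate: summary value, z-score and an
#'   `omitted` flag. Conditions with fewer than 3 replicates are kept whole
#'   with a warning.
#' @export
detect_nongrowing <- function(df, z_threshold = 1.5, stat = c("mean", "endpoint"),
                              min_drop = 0.5) {
  stat <- match.arg(stat)
  reps <- df |>
    dplyr::group_by(.data$species, .data$condition_id, .data$replicate) |>
    dplyr::summarise(
      value = if (stat == "mean") mean(.data$od600) else .data$od600[which.max(.data$time_h)],
      .groups = "drop_last"
    )
  out <- reps |>
    dplyr::mutate(
      n_rep = dplyr::n(),
      zscore = {
        s <- sqrt(mean((.data$value - mean(.data$value))^2)) # population SD
        if (s == 0) rep(0, dplyr::n()) else (.data$value - mean(.data$value)) / s
      },
      omitted = .data$n_rep >= 3 & .data$zscore < -z_threshold &
        .data$value < (1 - min_drop) * median(.data$value) &
        rank(.data$zscore, ties.method = "first") == 1
    ) |>
    dplyr::ungroup()
  if (any(out$n_rep < 3))
    warning("conditions with fewer than 3 replicates: no exclusion performed")
  dplyr::select(out, -"n_rep")
}

#' Drop replicates flagged by [detect_nongrowing()]
#' @param df Long growth-curve tibble.
#' @param flags Output of [detect_nongrowing()].
#' @return Filtered tibble.
#' @export
filter_growing <- function(df, flags) {
  bad <- dplyr::filter(flags, .data$omitted)
  dplyr::anti_join(df, bad, by = c("species", "condition_id", "replicate"))
}

logistic_simulate <- function(mu, K, x0, times, dt = 0.05) {
  A <- matrix(-mu / K, 1, 1)
  cpp_glv_simulate(mu, A, x0, times, dt)$states[, 1]
}

#' Fit a logistic growth model to one OD600 time series
#'
#' Bounded nonlinear least squares over (mu, K); the model trajectory is the
#' numerically integrated logistic ODE started at the known inoculation
#' density, compared against data truncated at `truncate_h`. A deterministic
#' 5-point multi-start around a heuristic initial guess (growth rate from the
#' steepest log-OD slope, capacity from the smoothed maximum) guards against
#' local minima.
#'
#' @param times,od Numeric vectors (hours ascending, OD600).
#' @param inoc_density Known initial density (OD600).
#' @param truncate_h Fitting horizon in hours (default 30).
#' @param bounds Named list with `mu` and `K` ranges.
#' @param dt Integrator step (hours).
#' @return A `logistic_fit` object: `mu`, `K`, `x0`, `sse`, `degenerate`.
#' @export
fit_logistic <- function(times, od, inoc_density, truncate_h = 30,
                         bounds = list(mu = c(0, 10), K = c(1e-4, 10)),
                         dt = 0.05) {
  if (length(times) != length(od)) stop("times and od differ in length")
  if (is.unsorted(times, strictly = TRUE)) stop("times must be strictly increasing")
  keep <- times <= truncate_h
  times <- times[keep]; od <- od[keep]
  if (length(times) < 4) stop("need at least 4 timepoints within the horizon")

  degenerate <- (max(od) - min(od)) < 3 * max(1e-3, inoc_density)
  sm <- stats::filter(od, rep(1 / 3, 3), sides = 2)
  K_guess <- max(od, na.rm = TRUE)
  if (any(!is.na(sm))) K_guess <- max(sm, na.rm = TRUE)
  K_guess <- min(max(K_guess, bounds$K[1] * 1.01), bounds$K[2])
  pos <- od > max(inoc_density / 2, 1e-4)
  mu_guess <- 0.3
  if (sum(pos) >= 2) {
    sl <- diff(log(od[pos])) / diff(times[pos])
    if (any(is.finite(sl))) mu_guess <- max(sl[is.finite(sl)], 0.05)
  }
  mu_guess <- min(max(mu_guess, bounds$mu[1] + 1e-3), bounds$mu[2])

  obj <- function(p) {
    pred <- logistic_simulate(p[1], p[2], inoc_density, times, dt)
    if (any(!is.finite(pred))) return(1e10)
    sum((pred - od)^2)
  }
  starts <- list(c(mu_guess, K_guess),
                 c(mu_guess * 0.5, K_guess), c(mu_guess * 2, K_guess),
                 c(mu_guess, K_guess * 0.8), c(mu_guess * 1.5, K_guess * 1.2))
  best <- NULL
  for (s in starts) {
    s <- pmin(pmax(s, c(bounds$mu[1], bounds$K[1])), c(bounds$mu[2], bounds$K[2]))
    fit <- try(optim(s, obj, method = "L-BFGS-B",
                     lower = c(bounds$mu[1], bounds$K[1]),
                     upper = c(bounds$mu[2], bounds$K[2]),
                     control = list(factr = 1e4)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("logistic fit failed to converge from any start")
  structure(
    list(mu = best$par[1], K = best$par[2], x0 = inoc_density,
         sse = best$value,
         degenerate = degenerate || best$par[2] <= bounds$K[1] * 1.001),
    class = "logistic_fit"
  )
}

#' @exportS3Method
print.logistic_fit <- function(x, ...) {
  cat(sprintf("logistic fit: mu = %.4g /h, K = %.4g OD600, sse = %.3g%s\n",
              x$mu, x$K, x$sse, if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' @export
tidy.logistic_fit <- function(x, ...) {
  tibble::tibble(term = c("mu", "K"), estimate = c(x$mu, x$K))
}

#' @export
glance.logistic_fit <- function(x, ...) {
  tibble::tibble(mu = x$mu, K = x$K, x0 = x$x0, sse = x$sse,
                 degenerate = x$degenerate)
}

#' Fit a shared logistic model to a 10-fold dilution series
#'
#' All curves of one species under serial inoculum dilution share one (mu, K);
#' each curve gets its own fitted initial condition. Readings below the
#' plate-reader detection limit `lod` are masked out of the residual, since
#' they carry no growth signal. After the joint fit, a log-log linear
#' regression maps experimental initial densities to the fitted ones.
#'
#' @param curves Tibble with columns `condition_id` (or `replicate`), `time_h`,
#'   `od600`, `inoc_density`, one species only; each curve one condition.
#' @param lod Lower limit of detection (OD600, default 0.05).
#' @param bounds As in [fit_logistic()].
#' @param dt Integrator step.
#' @return List: `fit` (shared `logistic_fit`), `curves` tibble with
#'   `x0_experimental` and `x0_fitted`, `mapping` (slope/intercept of the
#'   log10-log10 regression).
#' @export
fit_dilution_series <- function(curves, lod = 0.05,
                                bounds = list(mu = c(0, 10), K = c(1e-4, 10)),
                                dt = 0.05) {
  key <- if ("condition_id" %in% names(curves)) "condition_id" else "replicate"
  split_curves <- split(curves, curves[[key]])
  usable <- purrr::keep(split_curves, ~ sum(.x$od600 >= lod) >= 3)
  if (length(usable) < 2) {
    warning("fewer than 2 usable dilution curves; falling back to per-curve fits")
    fits <- purrr::map(split_curves, ~ fit_logistic(.x$time_h, .x$od600,
                                                    .x$inoc_density[1],
                                                    bounds = bounds, dt = dt))
    return(list(fit = fits[[1]], curves = NULL, mapping = NULL, joint = FALSE))
  }
  x0_exp <- purrr::map_dbl(usable, ~ .x$inoc_density[1])
  dense <- usable[[which.max(purrr::map_dbl(usable, ~ max(.x$od600)))]]
  dense <- dense[dense$od600 >= lod, ] # the start, too, ignores sub-LOD data
  init_fit <- fit_logistic(dense$time_h, dense$od600, dense$inoc_density[1],
                           truncate_h = max(dense$time_h), bounds = bounds, dt = dt)
  n <- length(usable)
  # par = (mu, K, log10 x0 per curve)
  par0 <- c(init_fit$mu, init_fit$K, log10(pmax(x0_exp, 1e-9)))
  lower <- c(bounds$mu[1], bounds$K[1], rep(-10, n))
  upper <- c(bounds$mu[2], bounds$K[2], rep(0, n))
  obj <- function(p) {
    tot <- 0
    for (i in seq_len(n)) {
      cu <- usable[[i]]
      m <- cu$od600 >= lod
      if (!any(m)) next
      pred <- logistic_simulate(p[1], p[2], 10^p[2 + i], cu$time_h[m], dt)
      if (any(!is.finite(pred))) return(1e10)
      tot <- tot + sum((pred - cu$od600[m])^2)
    }
    tot
  }
  fit <- optim(par0, obj, method = "L-BFGS-B", lower = lower, upper = upper,
               control = list(factr = 1e4, maxit = 500))
  x0_fit <- 10^fit$par[2 + seq_len(n)]
  map_lm <- stats::lm(log10(x0_fit) ~ log10(x0_exp))
  shared <- structure(list(mu = unname(fit$par[1]), K = unname(fit$par[2]),
                           x0 = NA_real_,
                           sse = fit$value, degenerate = FALSE),
                      class = "logistic_fit")
  list(
    fit = shared,
    curves = tibble::tibble(!!key := names(usable),
                            x0_experimental = x0_exp, x0_fitted = x0_fit),
    mapping = list(intercept = unname(stats::coef(map_lm)[1]),
                   slope = unname(stats::coef(map_lm)[2])),
    joint = TRUE
  )
}

#' Fit logistic models to every curve in a growth table
#'
#' Convenience wrapper mapping [fit_logistic()] over all
#' species/condition/replicate curves of a long growth tibble.
#'
#' @param df Long growth-curve tibble (blanked).
#' @param ... Passed to [fit_logistic()].
#' @return Tibble: species, condition_id, replicate, mu, K, sse, degenerate.
#' @export
fit_growth_table <- function(df, ...) {
  df |>
    dplyr::group_by(.data$species, .data$condition_id, .data$replicate) |>
    dplyr::group_modify(function(g, k) {
      f <- fit_logistic(g$time_h, g$od600, g$inoc_density[1], ...)
      tibble::tibble(mu = f$mu, K = f$K, sse = f$sse, degenerate = f$degenerate)
    }) |>
    dplyr::ungroup()
}
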