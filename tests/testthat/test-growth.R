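sim_curve <- function(mu, K, x0, times = seq(0, 30, 2)) {
  tibble::tibble(time_h = times,
                 od600 = logistic_closed_form(mu, K, x0, times))
}

test_that("blanking shifts curves to the known inoculum and is idempotent", {
  df <- tibble::tibble(species = "A", condition_id = "c", replicate = 1,
                       time_h = seq(0, 10, 2),
                       od600 = 0.09 + c(0, 0.02, 0.08, 0.2, 0.4, 0.5),
                       inoc_density = 0.01)
  b1 <- blank_growth_curves(df)
  expect_equal(b1$od600[1], 0.01)
  expect_equal(b1$od600, df$od600 - 0.08)
  expect_equal(diff(b1$od600), diff(df$od600)) # differences preserved
  expect_equal(blank_growth_curves(b1), b1)    # idempotent
})

test_that("non-growing replicates are flagged, capped at one per condition", {
  base <- sim_curve(0.5, 1, 0.01)
  mk <- function(rep, scale) dplyr::mutate(base, species = "A",
                                           condition_id = "c",
                                           replicate = rep,
                                           od600 = .data$od600 * scale,
                                           inoc_density = 0.01)
  # four identical replicates: nothing flagged
  same <- dplyr::bind_rows(lapply(1:4, mk, scale = 1))
  expect_false(any(detect_nongrowing(same)$omitted))
  # one flat replicate: flagged
  with_flat <- dplyr::bind_rows(mk(1, 1), mk(2, 1), mk(3, 1), mk(4, 0.01))
  flags <- detect_nongrowing(with_flat)
  expect_equal(flags$replicate[flags$omitted], 4)
  expect_equal(nrow(filter_growing(with_flat, flags)),
               nrow(with_flat) - nrow(base))
  # two low replicates: only the more extreme removed
  two_low <- dplyr::bind_rows(mk(1, 1), mk(2, 1), mk(3, 1), mk(4, 1),
                              mk(5, 0.2), mk(6, 0.05))
  flags2 <- detect_nongrowing(two_low)
  expect_equal(sum(flags2$omitted), 1)
  expect_equal(flags2$replicate[flags2$omitted], 6)
  # < 3 replicates: warn, keep all
  expect_warning(f3 <- detect_nongrowing(dplyr::bind_rows(mk(1, 1), mk(2, 0.01))),
                 "fewer than 3")
  expect_false(any(f3$omitted))
})

test_that("fit_logistic recovers generating parameters from noiseless data", {
  for (tr in list(c(0.5, 1.0), c(0.9, 0.4), c(0.25, 0.8))) {
    cu <- sim_curve(tr[1], tr[2], 0.01)
    f <- fit_logistic(cu$time_h, cu$od600, 0.01)
    expect_equal(f$mu, tr[1], tolerance = 1e-3)
    expect_equal(f$K, tr[2], tolerance = 1e-3)
    expect_lt(f$sse, 1e-8)
    expect_false(f$degenerate)
  }
})

test_that("fit_logistic flags degenerate flat curves", {
  flat <- tibble::tibble(time_h = seq(0, 30, 2), od600 = rep(0.01, 16))
  f <- fit_logistic(flat$time_h, flat$od600, 0.01)
  expect_true(f$degenerate)
})

test_that("fitted K tracks the generator's K monotonically", {
  set.seed(5)
  Ks <- sort(runif(5, 0.3, 1.5))
  fits <- vapply(Ks, function(K) {
    cu <- sim_curve(0.6, K, 0.01)
    fit_logistic(cu$time_h, cu$od600, 0.01)$K
  }, numeric(1))
  expect_false(is.unsorted(fits))
})

test_that("data beyond the truncation horizon are ignored", {
  cu <- sim_curve(0.5, 1, 0.01, times = seq(0, 60, 2))
  corrupted <- cu
  corrupted$od600[corrupted$time_h > 30] <- 5 # garbage after the horizon
  f <- fit_logistic(corrupted$time_h, corrupted$od600, 0.01, truncate_h = 30)
  expect_equal(f$K, 1, tolerance = 1e-3)
})

test_that("dilution series joint fit recovers shared kinetics and x0s", {
  mu <- 0.55; K <- 0.9
  x0s <- 0.01 / 10^(0:2)
  curves <- purrr::imap_dfr(x0s, function(x0, i) {
    dplyr::mutate(sim_curve(mu, K, x0, seq(0, 40, 2)),
                  condition_id = paste0("dil", i), inoc_density = x0)
  })
  out <- fit_dilution_series(curves, lod = 0.05)
  expect_true(out$joint)
  expect_equal(out$fit$mu, mu, tolerance = 1e-3)
  expect_equal(out$fit$K, K, tolerance = 1e-3)
  expect_equal(out$curves$x0_fitted, out$curves$x0_experimental,
               tolerance = 0.05)
  # identity map on self-consistent data
  expect_equal(out$mapping$slope, 1, tolerance = 0.05)
  expect_equal(out$mapping$intercept, 0, tolerance = 0.15)
})

test_that("readings below the detection limit never contribute to the fit", {
  mu <- 0.55; K <- 0.9
  x0s <- 0.01 / 10^(0:1)
  curves <- purrr::imap_dfr(x0s, function(x0, i) {
    dplyr::mutate(sim_curve(mu, K, x0, seq(0, 40, 2)),
                  condition_id = paste0("dil", i), inoc_density = x0)
  })
  perturbed <- curves |>
    dplyr::mutate(od600 = ifelse(.data$od600 < 0.05, .data$od600 * 0.3,
                                 .data$od600)) # stays below the limit
  a <- fit_dilution_series(curves, lod = 0.05)
  b <- fit_dilution_series(perturbed, lod = 0.05)
  expect_equal(a$fit$mu, b$fit$mu, tolerance = 1e-6)
  expect_equal(a$fit$K, b$fit$K, tolerance = 1e-6)
})

test_that("tidiers expose logistic fit parameters", {
  cu <- sim_curve(0.5, 1, 0.01)
  f <- fit_logistic(cu$time_h, cu$od600, 0.01)
  td <- tidy(f)
  expect_equal(td$term, c("mu", "K"))
  expect_equal(nrow(glance(f)), 1)
})
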