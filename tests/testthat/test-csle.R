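test_that("single species with a slack community cap follows the logistic", {
  p <- csle_params(0.6, 0.8, K_comm = 1e6, species = "A")
  traj <- simulate_csle(p, c(A = 0.01), t_end = 40)
  oracle <- logistic_closed_form(0.6, 0.8, 0.01, unique(traj$time_h))
  expect_equal(traj$abundance, oracle, tolerance = 1e-6)
  # even a mildly slack cap leaves the endpoint at the species' own K
  p2 <- csle_params(0.6, 0.8, K_comm = 100, species = "A")
  xs <- csle_steady_state(p2, c(A = 0.01))
  expect_equal(unname(xs), 0.8, tolerance = 1e-6)
})

test_that("absent species stay absent and endpoints respect the community cap", {
  p <- csle_params(c(0.5, 0.7, 0.4), c(0.5, 0.7, 0.6), K_comm = 0.9)
  traj <- simulate_csle(p, c(0.01, 0, 0.005), t_end = 48)
  expect_true(all(traj$abundance[traj$species == "sp2"] == 0))
  xs <- csle_steady_state(p, c(0.01, 0.002, 0.005))
  expect_equal(sum(xs), 0.9, tolerance = 1e-6)
})

test_that("endpoint total conserves K_comm over random parameter draws", {
  set.seed(31)
  for (i in 1:25) {
    S <- sample(3:6, 1)
    mu <- runif(S, 0.2, 1.2)
    K <- runif(S, 0.2, 1)
    Kc <- runif(1, 0.3, 0.9) * sum(K) # ensure sum(K) > K_comm
    p <- csle_params(mu, K, Kc)
    x0 <- 10^runif(S, -4, -2)
    # convergence to the sum = K_comm manifold slows as K_comm approaches
    # sum(K); integrate deep into equilibrium
    xs <- csle_steady_state(p, x0, t_max = 3000, dtol = 1e-13)
    expect_lt(abs(sum(xs) - Kc), 1e-6)
  }
})

test_that("the constrained system reduces to independent logistics as K_comm grows", {
  mu <- c(0.5, 0.8); K <- c(0.6, 0.4)
  x0 <- c(0.01, 0.005)
  times <- seq(0, 30, 0.5)
  p <- csle_params(mu, K, K_comm = 1e6)
  traj <- simulate_csle(p, x0, times = times)
  for (i in 1:2) {
    got <- traj$abundance[traj$species == paste0("sp", i)]
    expect_lt(max(abs(got - logistic_closed_form(mu[i], K[i], x0[i], times))),
              1e-4)
  }
})

test_that("higher growth rate wins the endpoint race at equal x0 and K", {
  set.seed(17)
  for (i in 1:10) {
    mu <- sort(runif(2, 0.2, 1.5))
    K <- rep(runif(1, 0.4, 1), 2)
    p <- csle_params(mu, K, K_comm = 0.8 * sum(K))
    xs <- csle_steady_state(p, rep(0.005, 2))
    expect_gt(xs[2], xs[1])
  }
})

test_that("steady state responds continuously to the inoculum", {
  p <- csle_params(c(0.5, 0.9), c(0.6, 0.5), K_comm = 0.7)
  base <- csle_steady_state(p, c(0.004, 0.004))
  bumped <- csle_steady_state(p, c(0.004 * 1.001, 0.004))
  expect_lt(max(abs(bumped - base)), 0.01)
})

test_that("empirical parameterization uses the supplied community endpoint", {
  w <- make_world(3, seed = 12)
  mono <- blank_growth_curves(
    synthesize_monocultures(w, replicates = 1, noise = FALSE))
  fit <- infer_csle(mono, route = "empirical", community_endpoint = 0.89)
  expect_equal(fit$K_comm, 0.89)
  K_true <- unname(w$K)
  expect_equal(unname(fit$K), K_true, tolerance = 0.01)
  expect_error(infer_csle(mono, route = "empirical"), "community_endpoint")
})

test_that("joint inference recovers known CSLE parameters within bounds", {
  # monoculture curves generated by the constrained model itself
  truth <- csle_params(c(0.5, 0.8, 0.65), c(0.6, 0.9, 0.5), K_comm = 1.2)
  times <- seq(0, 40, 2)
  mono <- purrr::map_dfr(seq_along(truth$species), function(i) {
    x0 <- setNames(numeric(3), truth$species)
    x0[i] <- 0.01
    traj <- simulate_csle(truth, x0, times = times, dt = 0.02)
    tibble::tibble(species = truth$species[i], condition_id = "m",
                   replicate = 1, time_h = times,
                   od600 = traj$abundance[traj$species == truth$species[i]],
                   inoc_density = 0.01)
  })
  fit <- infer_csle(mono, route = "joint", lambda = 1e-8, truncate_h = 40)
  expect_equal(unname(fit$mu), unname(truth$mu), tolerance = 0.01)
  expect_equal(unname(fit$K), unname(truth$K), tolerance = 0.01)
  expect_true(all(fit$mu <= 10) && all(fit$K <= 10) && fit$K_comm <= 5)
})

test_that("inoculum optimization returns the even solution under symmetry", {
  p <- csle_params(rep(0.6, 4), rep(0.5, 4), K_comm = 1)
  opt <- optimize_inoculum_csle(p, n_starts = 6, seed = 2)
  expect_equal(opt$diversity, log(4), tolerance = 1e-3)
  expect_lte(sum(opt$x0), 0.02 + 1e-12)
})

test_that("inoculum optimization matches a 2-species grid oracle", {
  p <- csle_params(c(0.4, 1.1), c(0.6, 0.7), K_comm = 0.8)
  opt <- optimize_inoculum_csle(p, total_cap = 0.02, free_cap = 0.02,
                                n_starts = 8, seed = 4)
  g <- expand.grid(a = 10^seq(-7, -2, length.out = 41),
                   b = 10^seq(-7, -2, length.out = 41))
  g <- g[g$a + g$b <= 0.02, ]
  div <- vapply(seq_len(nrow(g)), function(i) {
    xs <- csle_steady_state(p, c(g$a[i], g$b[i]))
    shannon_diversity(to_relative(xs), tol = 1e-3)
  }, numeric(1))
  expect_gte(opt$diversity, max(div) - 0.01)
})

test_that("pinned species and caps are honored at the optimum", {
  p <- csle_params(c(0.5, 0.8, 1.0), c(0.5, 0.6, 0.7), K_comm = 0.9)
  opt <- optimize_inoculum_csle(p, pinned = c(sp1 = 0.01), n_starts = 6,
                                seed = 3)
  expect_equal(unname(opt$x0["sp1"]), 0.01)
  expect_lte(sum(opt$x0), 0.02 + 1e-12)
  expect_lte(sum(opt$x0[c("sp2", "sp3")]), 0.01 + 1e-12)
})

test_that("level calibration achieves the target steady-state fold change", {
  # endpoints well below the per-species capacities, so a 3.3-fold change in
  # steady-state abundance is reachable by moving the inoculum
  p <- csle_params(c(0.5, 0.55, 0.6, 0.52, 0.58), rep(1.5, 5), K_comm = 0.9)
  center <- setNames(rep(1e-3, 5), p$species)
  cal <- calibrate_levels_csle(p, center, fold = 3.3, search_upper = 0.3)
  expect_false(any(cal$at_bound))
  expect_equal(cal$achieved_fold, rep(3.3, 5), tolerance = 0.01)
  expect_true(all(cal$high > cal$center))
  expect_equal(cal$high / cal$center, cal$center / cal$low, tolerance = 1e-9)
  # fold 1 is the identity
  cal1 <- calibrate_levels_csle(p, center, species = "sp1", fold = 1)
  expect_equal(unname(cal1$high), 1e-3)
  # monotonicity of the high level in the fold target
  cal2 <- calibrate_levels_csle(p, center, species = "sp1", fold = 2)
  expect_lt(cal2$high, cal$high[1])
  # unreachable fold returns the bound with a warning
  expect_warning(
    calb <- calibrate_levels_csle(p, center, species = "sp1", fold = 500),
    "unreachable")
  expect_true(calb$at_bound)
})
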