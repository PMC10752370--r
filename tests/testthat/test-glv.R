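test_that("diagonal gLV reproduces the logistic closed form", {
  mu <- c(0.5, 0.9); K <- c(0.8, 0.5)
  p <- glv_params(mu, diag(-mu / K))
  times <- seq(0, 40, 0.5)
  traj <- simulate_glv(p, c(0.01, 0.02), times = times)
  for (i in 1:2) {
    got <- traj$abundance[traj$species == paste0("sp", i)]
    want <- logistic_closed_form(mu[i], K[i], c(0.01, 0.02)[i], times)
    expect_lt(max(abs(got - want)), 1e-6)
  }
})

test_that("gLV simulation matches a reference stiff integrator", {
  fx <- lv2_fixture()
  times <- seq(0, 60, 1)
  traj <- simulate_glv(glv_params(fx$mu, fx$A), c(0.01, 0.03), times = times)
  ref <- glv_desolve(fx$mu, fx$A, c(0.01, 0.03), times)
  got <- matrix(traj$abundance, ncol = 2, byrow = TRUE)
  expect_lt(max(abs(got - ref)), 1e-6)
})

test_that("two-species endpoint approaches the analytic coexistence point", {
  fx <- lv2_fixture()
  xe <- glv_endpoint(glv_params(fx$mu, fx$A), c(0.01, 0.01), t_end = 400)
  expect_equal(unname(xe), fx$xstar, tolerance = 1e-5)
})

test_that("absent species never appear and invalid parameters are rejected", {
  fx <- lv2_fixture()
  traj <- simulate_glv(glv_params(fx$mu, fx$A), c(0.01, 0))
  expect_true(all(traj$abundance[traj$species == "sp2"] == 0))
  expect_error(glv_params(c(0.5, 4), fx$A), "\\[0, 3\\]")
  expect_error(glv_params(fx$mu, matrix(c(0.1, 0, 0, -1), 2, 2)), "<= 0")
  expect_error(simulate_glv(glv_params(c(0.5, 0.5), diag(c(0, -1))),
                            c(0.01, 0.01), t_end = 60), "diverged")
})

test_that("training data assembly chains passages by the dilution factor", {
  sp <- c("A", "B")
  comps <- tibble::tibble(condition_id = "r1", replicate = 1, passage = 1:2,
                          total_od600 = c(0.5, 0.6),
                          A = c(0.4, 0.3), B = c(0.6, 0.7))
  inoc <- tibble::tibble(condition_id = "r1", A = 1e-3, B = 2e-3)
  td <- glv_training(sp) |> add_communities(comps, inoc, dilution = 25)
  expect_equal(td$type, c("community", "passage"))
  expect_equal(td$x0[[1]], c(1e-3, 2e-3))
  expect_equal(td$x0[[2]], c(0.4, 0.6) * 0.5 / 25) # previous endpoint / 25
  expect_equal(td$obs[[2]][1, ], c(0.3, 0.7) * 0.6)
})

small_glv_study <- function(seed = 3, n_cond = 24, noise = FALSE,
                            n_species = 3) {
  w <- make_world(n_species, seed = seed)
  set.seed(seed + 1)
  X0 <- matrix(10^runif(n_cond * n_species, -5, -2), n_cond, n_species,
               dimnames = list(NULL, w$species))
  runs <- tibble::as_tibble(X0)
  runs$run_id <- sprintf("r%02d", seq_len(n_cond))
  comps <- synthesize_communities(w, runs, replicates = 1, noise = noise)
  mono <- synthesize_monocultures(w, replicates = 1, noise = noise)
  td <- glv_training(w$species) |>
    add_monocultures(blank_growth_curves(mono)) |>
    add_communities(comps, dplyr::rename(runs, condition_id = run_id))
  list(world = w, data = td)
}

test_that("fit_glv recovers a small noiseless world and respects bounds", {
  st <- small_glv_study()
  fit <- fit_glv(st$data, lambda = 1e-6, n_starts = 1, maxit = 200)
  off <- row(fit$A) != col(fit$A)
  expect_gt(cor(fit$A[off], st$world$glv$A[off]), 0.95)
  expect_equal(unname(fit$mu), unname(st$world$glv$mu), tolerance = 0.05)
  expect_true(all(fit$mu >= 0 & fit$mu <= 3))
  expect_true(all(diag(fit$A) <= 0) && all(abs(fit$A) <= 10))
})

test_that("a huge L1 penalty collapses the model to independent logistics", {
  st <- small_glv_study()
  fit <- fit_glv(st$data, lambda = 1e4, n_starts = 1, maxit = 150)
  off <- row(fit$A) != col(fit$A)
  expect_lt(max(abs(fit$A[off])), 1e-3)
})

test_that("relative-abundance scoring is invariant to per-condition rescaling", {
  st <- small_glv_study()
  comm <- st$data[st$data$type != "monoculture", ]
  attr(comm, "species") <- st$world$species
  sc1 <- score_glv(st$world$glv, comm)
  rescaled <- comm
  rescaled$obs <- purrr::map(rescaled$obs, ~ .x * runif(1, 0.5, 2))
  attr(rescaled, "species") <- st$world$species
  sc2 <- score_glv(st$world$glv, rescaled)
  expect_equal(sc1$table$observed_rel, sc2$table$observed_rel)
  expect_equal(sc1$pearson, sc2$pearson)
})

test_that("train/test split withholds only community conditions, reproducibly", {
  st <- small_glv_study(n_cond = 30)
  sp1 <- split_train_test(st$data, test_frac = 0.1, seed = 5)
  sp2 <- split_train_test(st$data, test_frac = 0.1, seed = 5)
  expect_identical(sp1$test$condition_id, sp2$test$condition_id)
  expect_equal(nrow(sp1$test), 3) # 10% of 30
  expect_true(all(sp1$test$type != "monoculture"))
  expect_true(all(st$data$condition_id[st$data$type == "monoculture"] %in%
                    sp1$train$condition_id))
})

test_that("cross-validation folds cover every community condition once", {
  st <- small_glv_study(n_cond = 10)
  # probe the fold bookkeeping via a degenerate 2-value grid
  scan <- select_regularization(st$data, k = 5, coarse_grid = c(1e-6, 1e-2),
                                refine = FALSE, n_starts = 1, maxit = 40)
  expect_equal(nrow(scan$curve), 2)
  expect_true(scan$best_lambda %in% c(1e-6, 1e-2))
  expect_true(all(is.finite(scan$curve$mean_oof_pearson)))
})

test_that("bootstrap of noiseless data has near-zero parameter spread", {
  st <- small_glv_study(n_cond = 12)
  bs <- bootstrap_glv(st$data, B = 8, lambda = 1e-6, seed = 2,
                      n_starts = 1, maxit = 80)
  expect_equal(bs$n_failed, 0)
  expect_lt(median(bs$summary$iqr), 0.05)
  pred <- bootstrap_predict(bs$fits, rep(1e-3, 3), t_end = 28)
  expect_equal(dplyr::n_distinct(pred$draw), 8)
  # determinism under the seed
  bs2 <- bootstrap_glv(st$data, B = 8, lambda = 1e-6, seed = 2,
                       n_starts = 1, maxit = 80)
  expect_equal(bs$summary$median, bs2$summary$median)
})

test_that("shuffled nulls are exact derangements preserving the multiset", {
  w <- make_world(10, seed = 9)
  sh <- shuffle_null(w$glv, n = 100, seed = 1)
  expect_gt(sh$n_accepted, 20)
  expect_lt(sh$n_accepted, 55)
  off <- row(w$glv$A) != col(w$glv$A)
  for (s in sh$accepted[seq_len(min(10, sh$n_accepted))]) {
    expect_equal(sort(s$A[off]), sort(w$glv$A[off])) # permutation invariant
    moved <- s$A[off] != w$glv$A[off]
    # every entry with a distinct value moved; duplicated values (zeros)
    # can coincide, so check displacement on the unique values only
    vals <- w$glv$A[off]
    expect_true(all(moved[!duplicated(vals) & !duplicated(vals, fromLast = TRUE)]))
    expect_equal(diag(s$A), diag(w$glv$A))
    expect_equal(s$mu, w$glv$mu)
  }
})

test_that("parameter recovery degrades gracefully with measurement noise", {
  w <- make_world(3, seed = 3)
  off <- row(w$glv$A) != col(w$glv$A)
  r_at <- vapply(c(0, 0.35), function(sdlog) {
    w2 <- make_world(3, seed = 3, noise_sdlog = sdlog)
    set.seed(4)
    X0 <- matrix(10^runif(24 * 3, -5, -2), 24, 3,
                 dimnames = list(NULL, w2$species))
    runs <- tibble::as_tibble(X0)
    runs$run_id <- sprintf("r%02d", 1:24)
    comps <- synthesize_communities(w2, runs, replicates = 3,
                                    noise = sdlog > 0, seed = 5)
    avg <- comps |>
      dplyr::group_by(.data$condition_id, .data$passage) |>
      dplyr::summarise(dplyr::across(dplyr::all_of(c(w2$species, "total_od600")),
                                     mean), .groups = "drop")
    avg$replicate <- 1
    mono <- blank_growth_curves(
      synthesize_monocultures(w2, replicates = 1, noise = FALSE))
    td <- glv_training(w2$species) |>
      add_monocultures(mono) |>
      add_communities(avg, dplyr::rename(runs, condition_id = "run_id"))
    fit <- fit_glv(td, lambda = 1e-3, n_starts = 1, maxit = 120)
    cor(fit$A[off], w$glv$A[off])
  }, numeric(1))
  expect_gt(r_at[1], r_at[2]) # noiseless beats heavy noise
  expect_gt(r_at[1], 0.9)
})

test_that("derangement acceptance converges to 1/e over many runs", {
  w <- make_world(5, seed = 2)
  fracs <- vapply(1:40, function(s)
    shuffle_null(w$glv, n = 50, seed = s)$n_accepted / 50, numeric(1))
  expect_equal(mean(fracs), exp(-1), tolerance = 0.05)
})
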