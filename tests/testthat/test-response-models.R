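test_that("feature expansion has the documented term counts and ordering", {
  runs4 <- matrix(runif(8 * 4), 8, 4, dimnames = list(NULL, paste0("x", 1:4)))
  F4 <- build_features(runs4, include_three_way = TRUE)
  expect_equal(ncol(F4), 4 + 4 + choose(4, 2) + choose(4, 3)) # 18
  runs10 <- matrix(10^runif(12 * 10, -4, -2), 12, 10,
                   dimnames = list(NULL, paste0("s", 1:10)))
  F10 <- build_features(runs10, log10_transform = TRUE)
  expect_equal(ncol(F10), 10 + 10 + choose(10, 2)) # 65
  # log10 transform applied before expansion
  expect_equal(F10[, "s1"], log10(runs10[, 1]))
  expect_equal(F10[, "s1:s2"], log10(runs10[, 1]) * log10(runs10[, 2]))
  # all-zero coded center row maps to all-zero features
  center <- build_features(rbind(runs4, 0), include_three_way = TRUE)
  expect_equal(unname(center[9, ]), rep(0, 18))
  expect_error(build_features(matrix(c(1, NA), 1, 2)), "non-finite")
})

make_linear_screen <- function() {
  # 3x3 full factorial in two factors: least squares on every LOO fold is
  # fully determined, so the no-penalty limit has a closed-form oracle
  X <- as.matrix(expand.grid(x1 = c(-1, 0, 1), x2 = c(-1, 0, 1)))
  F <- build_features(X)
  y <- 2 * X[, 1] - X[, 2] + 0.5
  list(F = F, y = y, X = X)
}

test_that("ensemble recovers a noiseless sparse linear response per fold", {
  d <- make_linear_screen()
  # negligible penalty floor: noiseless data are fit exactly on every fold
  ens <- fit_ensemble(d$F, d$y, lambda_grid = 10^seq(-8, -6, length.out = 5))
  for (f in ens$folds) {
    expect_equal(unname(f$beta["x1"]), 2, tolerance = 0.01)
    expect_equal(unname(f$beta["x2"]), -1, tolerance = 0.01)
    expect_equal(unname(f$beta["(Intercept)"]), 0.5, tolerance = 0.01)
  }
  expect_gt(cor(ens$oof, d$y), 0.99)
})

test_that("constant and zero responses yield flagged intercept-only models", {
  d <- make_linear_screen()
  ens0 <- fit_ensemble(d$F, rep(0, nrow(d$F)))
  expect_true(ens0$constant)
  expect_equal(as.numeric(predict(ens0, d$X)), rep(0, nrow(d$X)))
  ensc <- fit_ensemble(d$F, rep(0.4, nrow(d$F)))
  expect_equal(as.numeric(predict(ensc, d$X)), rep(0.4, nrow(d$X)))
})

test_that("out-of-fold predictions never see their own run (no leakage)", {
  d <- make_linear_screen()
  # corrupt one response: its own fold's oof prediction must not chase it
  y2 <- d$y
  y2[5] <- y2[5] + 100
  ens <- fit_ensemble(d$F, y2)
  expect_lt(abs(ens$oof[5] - d$y[5]), 50) # trained without row 5
})

test_that("a huge penalty floor drives all coefficients to zero", {
  d <- make_linear_screen()
  ens <- fit_ensemble(d$F, d$y, lambda_grid = c(1e6, 5e5))
  for (f in ens$folds)
    expect_equal(unname(f$beta[-1]), rep(0, ncol(d$F)))
})

test_that("ensemble prediction averages folds and clips negatives", {
  d <- make_linear_screen()
  ens <- fit_ensemble(d$F, d$y)
  # identical folds would equal the single-model prediction; here check mean
  manual <- rowMeans(vapply(ens$folds, function(f)
    f$beta[1] + as.numeric(d$F %*% f$beta[-1]), numeric(nrow(d$F))))
  expect_equal(as.numeric(predict(ens, d$X, clip = FALSE)), manual)
  low <- matrix(c(-1, 1), 1, 2,
                dimnames = list(NULL, paste0("x", 1:2))) * 5
  p <- predict(ens, low)
  expect_true(all(p >= 0))
  expect_error(predict(ens, matrix(0, 1, 3)), "dimension")
})

test_that("media optimization matches a brute-force grid oracle", {
  # two species with opposite linear responses over 2 factors; diversity is
  # maximized where predicted capacities are equal
  X <- as.matrix(expand.grid(x1 = seq(-1, 1, 0.5), x2 = seq(-1, 1, 0.5)))
  F <- build_features(X)
  yA <- 0.5 + 0.3 * X[, 1] + 0.1 * X[, 2]
  yB <- 0.5 - 0.2 * X[, 1] + 0.05 * X[, 2]
  ensembles <- list(A = fit_ensemble(F, yA), B = fit_ensemble(F, yB))
  bounds <- tibble::tibble(name = c("x1", "x2"), lower = -1, upper = 1)
  opt <- optimize_media(ensembles, bounds, n_starts = 10, seed = 3)
  # oracle: exhaustive 101 x 101 grid on the same ensembles
  grid <- as.matrix(expand.grid(x1 = seq(-1, 1, length.out = 101),
                                x2 = seq(-1, 1, length.out = 101)))
  colnames(grid) <- c("x1", "x2")
  pa <- predict(ensembles$A, grid); pb <- predict(ensembles$B, grid)
  div <- vapply(seq_len(nrow(grid)), function(i) {
    k <- c(pa[i], pb[i]); if (sum(k) <= 0) return(0)
    shannon_diversity(k / sum(k), tol = 1e-9)
  }, numeric(1))
  expect_gte(opt$diversity, max(div) - 1e-4)
  expect_true(all(opt$profile >= -1 & opt$profile <= 1))
})

test_that("identical response models make every feasible point optimal", {
  X <- as.matrix(expand.grid(x1 = c(-1, 0, 1), x2 = c(-1, 0, 1)))
  F <- build_features(X)
  y <- 0.4 + 0.2 * X[, 1]
  shared <- fit_ensemble(F, y)
  ensembles <- purrr::map(setNames(1:10, paste0("sp", 1:10)), ~shared)
  bounds <- tibble::tibble(name = c("x1", "x2"), lower = -1, upper = 1)
  opt <- optimize_media(ensembles, bounds, n_starts = 5, seed = 1)
  expect_equal(opt$diversity, log(10), tolerance = 1e-6)
})

test_that("inoculum optimization hits an achievable target exactly", {
  set.seed(9)
  X <- matrix(10^runif(30 * 2, -4, -2), 30, 2,
              dimnames = list(NULL, c("A", "B")))
  F <- build_features(X, log10_transform = TRUE)
  yA <- 0.1 - 0.02 * log10(X[, 1]) + 0.01 * log10(X[, 2])
  yB <- 0.2 + 0.03 * log10(X[, 2])
  ens <- list(A = fit_ensemble(F, yA), B = fit_ensemble(F, yB))
  bounds <- tibble::tibble(name = c("A", "B"), lower = 1e-4, upper = 1e-2)
  # target the model's own prediction at an interior point
  xstar <- matrix(c(1e-3, 1e-3), 1, 2, dimnames = list(NULL, c("A", "B")))
  target <- c(A = unname(predict(ens$A, xstar)),
              B = unname(predict(ens$B, xstar)))
  opt <- optimize_inoculum(ens, target, bounds, n_starts = 10, seed = 2)
  expect_lt(opt$objective, 1e-8)
  # grid-search oracle over the 2-species log space
  g <- as.matrix(expand.grid(A = 10^seq(-4, -2, length.out = 61),
                             B = 10^seq(-4, -2, length.out = 61)))
  obj <- vapply(seq_len(nrow(g)), function(i) {
    run <- g[i, , drop = FALSE]
    sum((target - c(predict(ens$A, run), predict(ens$B, run)))^2)
  }, numeric(1))
  expect_lte(opt$objective, min(obj) + 1e-8)
  expect_error(optimize_inoculum(list(), target, bounds), "no predictive")
})

test_that("even-composition targets follow the printed rule", {
  t <- even_target(0.8, paste0("s", 1:10))
  expect_equal(unname(t), rep(0.08, 10))
})
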