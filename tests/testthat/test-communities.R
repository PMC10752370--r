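test_that("subcommunity enumeration counts match the combinatorial identity", {
  subs <- enumerate_subcommunities(10)
  expect_equal(length(subs), 2^10 - 12) # sum(choose(10, 2:9)) = 1012
  expect_equal(length(enumerate_subcommunities(3, sizes = 2)), 3)
  keys <- purrr::map_chr(subs, paste, collapse = "|")
  expect_equal(anyDuplicated(keys), 0)
  expect_error(enumerate_subcommunities(4, sizes = 4), "\\[2, S-1\\]")
})

test_that("passage chains follow the dilution rule and keep absentees absent", {
  fx <- lv2_fixture()
  p <- glv_params(fx$mu, fx$A)
  s <- simulate_passages(p, c(0.01, 0.004), n_passages = 4, dilution = 25)
  expect_equal(s$passage, 1:4)
  # manual chain with the same integrator settings
  x <- c(0.01, 0.004)
  for (i in 1:2) x <- glv_endpoint(p, x, t_end = 28) / 25
  x2 <- glv_endpoint(p, x * 25 / 25 * 25, t_end = 28) # no-op guard
  manual <- glv_endpoint(p, x, t_end = 28)
  expect_equal(as.numeric(s[3, c("sp1", "sp2")]),
               unname(manual / sum(manual)), tolerance = 1e-9)
  # diagonal-only model: composition from independent logistic chain
  mu <- c(0.5, 0.9); K <- c(0.8, 0.5)
  pd <- glv_params(mu, diag(-mu / K))
  sd_ <- simulate_passages(pd, c(0.01, 0.01), n_passages = 2)
  x1 <- logistic_closed_form(mu, K, c(0.01, 0.01), 28)
  x2 <- logistic_closed_form(mu, K, x1 / 25, 28)
  expect_equal(as.numeric(sd_[2, c("sp1", "sp2")]), x2 / sum(x2),
               tolerance = 1e-5)
  # absent species stay absent
  s0 <- simulate_passages(p, c(0.01, 0), n_passages = 4)
  expect_true(all(s0$sp2 == 0))
})

test_that("variability scores behave at the constant-series limits", {
  const <- tibble::tibble(passage = 1:4, a = 0.5, b = 0.5)
  expect_equal(variability_score(const, "high"), 0)
  expect_equal(variability_score(const, "low"), 4 * log(2) / 1e-6)
  # hand-computed two-state fixture
  series <- tibble::tibble(passage = 1:4,
                           a = c(0.5, 0.6, 0.5, 0.6),
                           b = c(0.5, 0.4, 0.5, 0.4))
  sd_sum <- sum(apply(series[, c("a", "b")], 1, function(x) -sum(x * log(x))))
  eu_sum <- 3 * sqrt(2 * 0.1^2)
  expect_equal(variability_score(series, "low"), sd_sum / eu_sum)
  expect_equal(variability_score(series, "high"), sd_sum * eu_sum)
})

test_that("design_communities matches a grid oracle on a 3-species world", {
  w <- make_world(3, seed = 23)
  subs <- list(w$species[1:2])
  des <- design_communities(w$glv, subs, mode = "low", n_starts = 6, seed = 1)
  # coarse grid oracle over the two present species
  g <- expand.grid(a = 10^seq(-6, -2, length.out = 25),
                   b = 10^seq(-6, -2, length.out = 25))
  best <- max(vapply(seq_len(nrow(g)), function(i) {
    x0 <- c(g$a[i], g$b[i], 0)
    s <- simulate_passages(w$glv, x0)
    variability_score(s, "low")
  }, numeric(1)))
  expect_gte(des$objective[1], best * 0.99)
  # absent species zero everywhere in the predicted series
  expect_true(all(des$series[[1]]$sp03 == 0))
  expect_true(all(des$x0[[1]][w$species[3]] == 0))
  expect_true(all(des$x0[[1]][1:2] > 0 & des$x0[[1]][1:2] <= 0.01))
})

test_that("symmetric two-species worlds yield even, stable low-mode designs", {
  mu <- c(0.6, 0.6); K <- c(0.6, 0.6)
  A <- diag(-mu / K)
  A[1, 2] <- A[2, 1] <- -0.2
  p <- glv_params(mu, A)
  des <- design_communities(p, list(c("sp1", "sp2")), mode = "low",
                            n_starts = 6, seed = 2)
  final <- des$series[[1]][4, c("sp1", "sp2")]
  expect_equal(as.numeric(final), c(0.5, 0.5), tolerance = 0.02)
})

test_that("deduplication collapses near-identical endpoint compositions", {
  w <- make_world(3, seed = 23)
  # the same subset twice must collapse to one unique design
  des <- design_communities(w$glv, list(w$species[1:2], w$species[1:2]),
                            mode = "low", n_starts = 4, seed = 3)
  expect_equal(length(unique(des$dedup_group)), 1)
  expect_equal(sum(des$is_unique), 1)
  # tolerance monotonicity: larger tol never yields more clusters
  des_loose <- design_communities(w$glv, enumerate_subcommunities(w$species),
                                  mode = "low", dedup_tol = 0.2,
                                  n_starts = 3, seed = 4)
  des_tight <- design_communities(w$glv, enumerate_subcommunities(w$species),
                                  mode = "low", dedup_tol = 0.01,
                                  n_starts = 3, seed = 4)
  expect_lte(length(unique(des_loose$dedup_group)),
             length(unique(des_tight$dedup_group)))
})

test_that("passage simulation is deterministic", {
  w <- make_world(4, seed = 6)
  x0 <- c(0.003, 0.001, 0.002, 0.004)
  expect_identical(simulate_passages(w$glv, x0), simulate_passages(w$glv, x0))
})

test_that("greedy validation cover includes every species at least twice", {
  w <- make_world(4, seed = 8)
  des <- design_communities(w$glv, enumerate_subcommunities(w$species),
                            mode = "low", n_starts = 3, seed = 5)
  sel <- select_validation_designs(des, w$species, min_times = 2)
  counts <- table(unlist(sel$members))
  expect_true(all(w$species %in% names(counts)))
  expect_true(all(counts >= 2))
})

test_that("evaluate_design compares CV distributions between groups", {
  set.seed(14)
  mk_series <- function(community, group, wobble) {
    base <- c(0.4, 0.6)
    purrr::map_dfr(1:4, function(p) {
      x <- to_relative(pmax(base + rnorm(2, 0, wobble), 1e-3))
      tibble::tibble(community = community, group = group, passage = p,
                     a = x[1], b = x[2])
    })
  }
  measured <- dplyr::bind_rows(
    purrr::map_dfr(1:6, ~ mk_series(paste0("L", .x), "low", 0.01)),
    purrr::map_dfr(1:6, ~ mk_series(paste0("H", .x), "high", 0.15)))
  out <- evaluate_design(measured)
  expect_lt(out$test$p.value, 0.05)
  low_cv <- mean(out$cv$cv_pct[out$cv$group == "low"])
  high_cv <- mean(out$cv$cv_pct[out$cv$group == "high"])
  expect_lt(low_cv, high_cv)
  # identical groups: no detectable difference
  same <- dplyr::bind_rows(
    purrr::map_dfr(1:5, ~ mk_series(paste0("L", .x), "low", 0.05)),
    purrr::map_dfr(1:5, ~ mk_series(paste0("H", .x), "high", 0.05)))
  out2 <- evaluate_design(same)
  expect_gt(out2$test$p.value, 0.05)
})
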