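#' Elastic-net response ensemble with nested leave-one-out cross validation
#'
#' The data-limited screening designs (9-21 runs) are fit with an ensemble:
#' for each outer leave-one-out partition, an inner leave-one-out grid search
#' over the elastic-net mixing parameter and penalty strength selects the
#' hyperparameters minimizing out-of-fold MSE; the model is then refit on the
#' outer-fold training rows with those hyperparameters. One parameter set per
#' outer fold; predictions average over folds. Each fold's hyperparameters
#' are selected without ever seeing its held-out run, and the out-of-fold
#' predictions returned alongside are honest validation statistics.
#'
#' Replicates must be averaged per condition before calling (otherwise
#' replicate copies of a condition leak across folds).
#'
#' @param features Feature matrix from [build_features()].
#' @param response Numeric response vector (per-species carrying capacity or
#'   endpoint abundance).
#' @param alpha_grid Elastic-net mixing grid (1 = lasso).
#' @param lambda_grid Penalty grid; default 50 log-spaced values 1e-6..1e2.
#' @param thresh,glm_maxit Coordinate-descent convergence tolerance and
#'   iteration cap passed to glmnet; the defaults trade a little path
#'   precision for robustness on badly scaled feature sets.
#' @return A `response_ensemble`: per-fold coefficients and hyperparameters,
#'   feature map, out-of-fold predictions.
#' @export
fit_ensemble <- function(features, response,
                         alpha_grid = seq(0.1, 1, by = 0.1),
                         lambda_grid = 10^seq(-6, 2, length.out = 50),
                         thresh = 1e-7, glm_maxit = 1e5) {
  n <- nrow(features)
  if (n < 5) stop("need at least 5 runs")
  if (length(response) != n) stop("response length mismatch")
  lambda_grid <- sort(lambda_grid, decreasing = TRUE)
  fmap <- attr(features, "feature_map")

  if (sd(response) == 0) {
    folds <- purrr::map(seq_len(n), ~ list(
      beta = setNames(c(response[1], numeric(ncol(features))),
                      c("(Intercept)", colnames(features))),
      alpha = NA_real_, lambda = NA_real_))
    return(structure(list(folds = folds, feature_map = fmap,
                          oof = rep(response[1], n), response = response,
                          constant = TRUE),
                     class = "response_ensemble"))
  }

  # inner LOO error over the (alpha, lambda) grid, computed with direct
  # coefficient access: one path fit per left-out inner row per alpha, with
  # predictions assembled by hand (the S4 predict machinery costs more than
  # the solver at these problem sizes)
  path_predict <- function(fit, x) {
    as.numeric(fit$a0) + as.numeric(x %*% fit$beta)
  }
  oof <- numeric(n)
  folds <- purrr::map(seq_len(n), function(r) {
    Xtr <- features[-r, , drop = FALSE]
    ytr <- response[-r]
    m <- nrow(Xtr)
    best <- list(cvm = Inf)
    for (a in alpha_grid) {
      errs <- matrix(NA_real_, m, length(lambda_grid))
      for (j in seq_len(m)) {
        fit_j <- glmnet::glmnet(Xtr[-j, , drop = FALSE], ytr[-j], alpha = a,
                                lambda = lambda_grid, standardize = TRUE,
                                thresh = thresh, maxit = glm_maxit)
        pred <- path_predict(fit_j, Xtr[j, , drop = FALSE])
        # short paths (early stopping) keep their last solution for smaller
        # lambdas, matching how the full grid would be evaluated
        k <- length(pred)
        errs[j, ] <- (c(pred, rep(pred[k], length(lambda_grid) - k)) - ytr[j])^2
      }
      cvm <- colMeans(errs)
      i <- which.min(cvm)
      if (cvm[i] < best$cvm)
        best <- list(cvm = cvm[i], alpha = a, lambda = lambda_grid[i])
    }
    fit <- glmnet::glmnet(Xtr, ytr, alpha = best$alpha, lambda = lambda_grid,
                          standardize = TRUE, thresh = thresh,
                          maxit = glm_maxit)
    b <- as.numeric(stats::coef(fit, s = best$lambda))
    names(b) <- c("(Intercept)", colnames(features))
    oof[r] <<- b[1] + sum(b[-1] * features[r, ])
    list(beta = b, alpha = best$alpha, lambda = best$lambda)
  })
  structure(list(folds = folds, feature_map = fmap, oof = oof,
                 response = response, constant = FALSE),
            class = "response_ensemble")
}

#' @exportS3Method
print.response_ensemble <- function(x, ...) {
  cat(sprintf("response ensemble: %d folds, %d features%s\n",
              length(x$folds), length(x$folds[[1]]$beta) - 1,
              if (x$constant) " [constant response]" else ""))
  cat(sprintf("out-of-fold Pearson r = %.3f\n",
              suppressWarnings(cor(x$oof, x$response))))
  invisible(x)
}

#' @export
tidy.response_ensemble <- function(x, ...) {
  purrr::imap_dfr(x$folds, function(f, i)
    tibble::tibble(fold = i, term = names(f$beta), estimate = unname(f$beta),
                   alpha = f$alpha, lambda = f$lambda))
}

#' @export
glance.response_ensemble <- function(x, ...) {
  r <- suppressWarnings(cor(x$oof, x$response))
  tibble::tibble(n_folds = length(x$folds),
                 oof_pearson = r,
                 oof_rmse = sqrt(mean((x$oof - x$response)^2)),
                 constant = x$constant)
}

#' Mean ensemble coefficients
#' @param x A `response_ensemble`.
#' @return Named vector averaging the per-fold coefficient vectors.
#' @export
ensemble_coef <- function(x) {
  Reduce(`+`, purrr::map(x$folds, "beta")) / length(x$folds)
}

#' Predict from a response ensemble
#'
#' Per-fold predictions are averaged to a scalar per run. Growth responses
#' are physical abundances, so negative means are clipped at zero; the
#' returned vector carries a `clipped` attribute marking where.
#'
#' @param object A `response_ensemble`.
#' @param newdata Matrix/tibble of raw factor levels (the stored feature map
#'   is applied), or a prebuilt feature matrix with matching columns.
#' @param clip Clip negative predictions at 0?
#' @param ... Unused.
#' @return Numeric predictions (one per row).
#' @export
predict.response_ensemble <- function(object, newdata, clip = TRUE, ...) {
  fm <- object$feature_map
  feat_names <- names(object$folds[[1]]$beta)[-1]
  F <- if (is.matrix(newdata) && identical(colnames(newdata), feat_names)) {
    newdata
  } else {
    build_features(newdata, include_three_way = fm$include_three_way,
                   log10_transform = fm$log10_transform)
  }
  if (ncol(F) != length(feat_names))
    stop("newdata feature dimension (", ncol(F), ") does not match the ensemble (",
         length(feat_names), ")")
  preds <- purrr::map(object$folds, function(f)
    f$beta[1] + as.numeric(F %*% f$beta[-1]))
  out <- Reduce(`+`, preds) / length(preds)
  clipped <- out < 0
  if (clip) out[clipped] <- 0
  attr(out, "clipped") <- clipped
  out
}
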