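#' Fit an elastic-net regression of transformed age on beta values
#'
#' Solves the penalized least-squares problem
#' \deqn{\frac{1}{2n}\sum_i (y_i - b_0 - x_i^T b)^2 +
#'   \lambda\left(\alpha\|b\|_1 + \frac{1-\alpha}{2}\|b\|_2^2\right)}
#' by cyclic coordinate descent with soft-thresholding updates, warm starts
#' along the penalty path, and an active-set strategy. Predictors are
#' standardized internally (mean 0, unit 1/n-variance) and coefficients are
#' returned on the original beta scale; zero-variance predictors always get
#' coefficient zero and never affect the others. When `lambda` is a grid of
#' more than one value, the penalty is chosen by k-fold cross-validation
#' (minimum mean squared prediction error); fold assignment is deterministic
#' given `seed`.
#'
#' @param x Numeric matrix, samples in rows, probes in columns (colnames =
#'   probe IDs). No missing values (impute first; [train_clock()] does).
#' @param y Numeric response: age on the calibrated transformed scale.
#' @param alpha Elastic-net mixing in \[0,1\]: 1 = lasso, 0 = ridge.
#'   Default 0.5, the conventional choice for methylation clocks.
#' @param lambda Optional decreasing vector of penalty values. Default: a
#'   100-point log-spaced grid from the smallest penalty that zeroes every
#'   coefficient down to a small fraction of it.
#' @param nlambda,lambda_min_ratio Grid size and ratio of smallest to
#'   largest penalty for the default grid.
#' @param folds Number of cross-validation folds (default 10). Ignored when
#'   `lambda` has length 1.
#' @param standardize Standardize predictors internally (default `TRUE`).
#' @param adult_age Age-transform anchor recorded in the returned model.
#' @param seed Integer seed governing fold assignment. Default 1.
#' @param tol,max_iter Coordinate-descent convergence tolerance (on the
#'   largest squared coefficient update) and sweep cap.
#' @return A [clock_model()] with the non-zero weights, the intercept, the
#'   per-probe training means, the selected `lambda`, and (when
#'   cross-validated) the CV error curve in `meta$cv`.
#' @export
fit_elastic_net <- function(x, y, alpha = 0.5, lambda = NULL,
                            nlambda = 100, lambda_min_ratio = NULL,
                            folds = 10, standardize = TRUE,
                            adult_age = 20, seed = 1,
                            tol = 1e-12, max_iter = 10000L) {
  x <- as.matrix(x)
  n <- nrow(x)
  p <- ncol(x)
  if (length(y) != n) abort("`y` must have one value per row of `x`.")
  if (anyNA(x)) abort("`x` contains missing values; impute or drop first.")
  if (anyNA(y)) abort("`y` contains missing values.")
  if (sd(y) == 0) abort("No age variation: `y` is constant.")
  if (alpha < 0 || alpha > 1) abort("`alpha` must lie in [0, 1].")
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(p))

  if (is.null(lambda)) {
    lambda <- default_lambda_grid(x, y, alpha, nlambda, lambda_min_ratio,
                                  standardize)
  }
  lambda <- sort(unique(as.numeric(lambda)), decreasing = TRUE)
  if (any(lambda < 0)) abort("`lambda` values must be non-negative.")

  cv <- NULL
  if (length(lambda) > 1) {
    if (folds < 2) abort("`folds` must be at least 2.")
    if (n < folds) abort(sprintf("Fewer samples (%d) than folds (%d).", n, folds))
    cv <- cv_elnet(x, y, alpha, lambda, folds, standardize, seed, tol, max_iter)
    lambda_sel <- cv$lambda[which.min(cv$mean_cv_error)]
  } else {
    lambda_sel <- lambda
  }

  # exact warm-started path down to the selected penalty (no truncation)
  grid_fit <- lambda[lambda >= lambda_sel]
  path <- elnet_path(x, y, alpha, grid_fit, standardize, tol, max_iter,
                     fdev = 0)
  k <- match(lambda_sel, grid_fit)
  b <- path$beta[, k]
  b0 <- path$intercept[k]

  # polish at the selected penalty until the stationarity (KKT) residual is
  # at solver precision, not merely the sweep-update tolerance
  s <- standardize_x(x, standardize)
  yc <- y - mean(y)
  t_polish <- tol
  repeat {
    kkt <- elnet_kkt(x, y, b0, b, lambda_sel, alpha, standardize)
    if (kkt < 1e-7 || t_polish < 1e-20) break
    t_polish <- t_polish * 1e-4
    b_std <- b * ifelse(s$sx > 0, s$sx, 1)
    b_std <- cd_elnet_cpp(s$xs, yc, lambda_sel, alpha, b_std, s$xvar,
                          t_polish, max_iter)
    b <- b_std / ifelse(s$sx > 0, s$sx, 1)
    b[s$xvar == 0] <- 0
    b0 <- mean(y) - as.numeric(crossprod(s$mx, b))
  }

  meta <- list(n_train = n, n_candidates = p, seed = seed, alpha = alpha,
               lambda_grid = lambda, standardize = standardize)
  if (!is.null(cv)) meta$cv <- cv
  clock_model(
    intercept = b0,
    weights = setNames(b, colnames(x)),
    probe_means = setNames(colMeans(x), colnames(x)),
    adult_age = adult_age, alpha = alpha, lambda = lambda_sel, meta = meta
  )
}

# Smallest lambda that zeroes all coefficients, on the internal
# (standardized) scale: max_j |(1/n) x_j'(y - ybar)| / max(alpha, 1e-3).
default_lambda_grid <- function(x, y, alpha, nlambda, lambda_min_ratio,
                                standardize) {
  s <- standardize_x(x, standardize)
  yc <- y - mean(y)
  g <- abs(crossprod(s$xs, yc)) / nrow(x)
  lambda_max <- max(g) / max(alpha, 1e-3)
  if (lambda_max <= 0) lambda_max <- 1e-3
  if (is.null(lambda_min_ratio)) {
    lambda_min_ratio <- if (nrow(x) > ncol(x)) 1e-4 else 1e-2
  }
  exp(seq(log(lambda_max), log(lambda_max * lambda_min_ratio),
          length.out = nlambda))
}

# Center columns; optionally scale to unit 1/n-variance. Zero-variance
# columns get scale 0 and are frozen at coefficient 0 by the solver.
standardize_x <- function(x, standardize) {
  mx <- colMeans(x)
  xc <- sweep(x, 2, mx, "-")
  if (standardize) {
    sx <- sqrt(colMeans(xc^2))
    xs <- xc
    ok <- sx > 0
    xs[, ok] <- sweep(xc[, ok, drop = FALSE], 2, sx[ok], "/")
    xvar <- as.numeric(ok)
  } else {
    sx <- rep(1, ncol(x))
    xs <- xc
    xvar <- colMeans(xc^2)
  }
  list(xs = xs, mx = mx, sx = sx, xvar = xvar)
}

# Fit the whole lambda path with warm starts; returns coefficients on the
# original predictor scale. Path refinement stops early once the fraction
# of variance explained saturates (change < fdev per step, or > 0.999
# overall); remaining lambdas inherit the last solution, keeping the grid
# shape deterministic.
elnet_path <- function(x, y, alpha, lambda, standardize, tol, max_iter,
                       fdev = 1e-5) {
  s <- standardize_x(x, standardize)
  ybar <- mean(y)
  yc <- y - ybar
  p <- ncol(x)
  tss <- sum(yc^2)
  beta <- matrix(0, p, length(lambda))
  b <- rep(0, p)
  rsq_prev <- 0
  for (k in seq_along(lambda)) {
    b <- cd_elnet_cpp(s$xs, yc, lambda[k], alpha, b, s$xvar, tol, max_iter)
    beta[, k] <- b
    if (length(lambda) > 1 && tss > 0) {
      rsq <- 1 - sum((yc - s$xs %*% b)^2) / tss
      if (k > 1 && (rsq - rsq_prev < fdev * rsq || rsq > 0.999)) {
        if (k < length(lambda)) beta[, (k + 1):length(lambda)] <- b
        break
      }
      rsq_prev <- rsq
    }
  }
  scale_div <- ifelse(s$sx > 0, s$sx, 1)
  beta_orig <- beta / scale_div
  beta_orig[s$xvar == 0, ] <- 0
  intercept <- ybar - as.numeric(crossprod(s$mx, beta_orig))
  list(beta = beta_orig, intercept = intercept, lambda = lambda)
}

# k-fold CV over a lambda grid; returns a tibble lambda / mean_cv_error /
# se_cv_error. Mean CV error is the mean squared held-out prediction error
# pooled over all samples; the SE is across fold means.
cv_elnet <- function(x, y, alpha, lambda, folds, standardize, seed,
                     tol, max_iter) {
  n <- nrow(x)
  fold_id <- make_folds(n, folds, seed)
  errs <- matrix(NA_real_, n, length(lambda))
  cv_tol <- max(tol, 1e-9)
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    path <- elnet_path(x[tr, , drop = FALSE], y[tr], alpha, lambda,
                       standardize, cv_tol, max_iter)
    pred <- x[!tr, , drop = FALSE] %*% path$beta
    pred <- sweep(pred, 2, path$intercept, "+")
    errs[!tr, ] <- (y[!tr] - pred)^2
  }
  fold_means <- vapply(seq_len(folds), function(f) {
    colMeans(errs[fold_id == f, , drop = FALSE])
  }, numeric(length(lambda)))
  tibble(
    lambda = lambda,
    mean_cv_error = colMeans(errs),
    se_cv_error = apply(fold_means, 1, sd) / sqrt(folds)
  )
}

make_folds <- function(n, k, seed) {
  with_private_seed(seed, sample(rep_len(seq_len(k), n)))
}

# Maximum violation of the elastic-net stationarity (KKT) conditions at a
# fitted solution, evaluated on the internal standardized problem. Zero (to
# solver tolerance) iff the coefficients minimize the objective.
elnet_kkt <- function(x, y, intercept, beta_orig, lambda, alpha,
                      standardize = TRUE) {
  s <- standardize_x(x, standardize)
  yc <- y - mean(y)
  b <- beta_orig * s$sx
  ok <- s$xvar > 0
  r <- yc - s$xs %*% b
  g <- as.numeric(crossprod(s$xs, r)) / nrow(x)
  l1 <- lambda * alpha
  l2 <- lambda * (1 - alpha)
  viol <- ifelse(b != 0,
                 abs(g - l1 * sign(b) - l2 * b),
                 pmax(0, abs(g) - l1))
  max(viol[ok], 0)
}
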