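# Baseline ridge correction: per dependent probe, fit y ~ alpha + X beta on
# all samples (no group term), pick the penalty by leave-one-out
# cross-validation, and return the cross-validated residuals that carry only
# the association NOT shared by the two groups.

# SVD of the column-centered covariate block, reused across the lambda grid.
.ridge_svd <- function(X) {
  X <- as.matrix(X)
  if (ncol(X) == 0L) {
    return(list(U = matrix(0, nrow(X), 0), d = numeric(0),
                V = matrix(0, 0, 0), xbar = numeric(0), n = nrow(X)))
  }
  xbar <- colMeans(X)
  Xc <- sweep(X, 2, xbar, "-")
  sv <- svd(Xc)
  keep <- sv$d > max(sv$d, 0) * 1e-12
  list(U = sv$u[, keep, drop = FALSE], d = sv$d[keep],
       V = sv$v[, keep, drop = FALSE], xbar = xbar, n = nrow(X))
}

# Exact LOOCV predictions at one lambda from the precomputed SVD.
# The unpenalized-intercept ridge smoother is H = 11'/n + U S U' with
# S = diag(d^2/(d^2+lambda)); because the penalty matrix is fixed, the
# rank-one (Sherman-Morrison) leave-one-out identity
#   yhat^{-i}_i = (yhat_i - h_ii y_i) / (1 - h_ii)
# is exact, including the re-centering of the training fold.
.loocv_svd <- function(y, sv, lam) {
  n <- sv$n
  ybar <- mean(y)
  yc <- y - ybar
  if (length(sv$d)) {
    s <- sv$d^2 / (sv$d^2 + lam)
    Uy <- crossprod(sv$U, yc)
    fitted <- ybar + drop(sv$U %*% (s * Uy))
    h <- 1 / n + rowSums(sv$U^2 * rep(s, each = n))
  } else {
    fitted <- rep(ybar, n)
    h <- rep(1 / n, n)
  }
  y - (y - fitted) / (1 - h)
}

#' Exact leave-one-out ridge predictions
#'
#' For each sample `i`, the prediction of `y[i]` from a ridge regression of
#' `y` on `X` (intercept unpenalized, penalty `lam` on the slopes) fitted on
#' the other `n - 1` samples. The default `"shortcut"` path uses the
#' closed-form leave-one-out identity on the ridge smoother and is exact;
#' `"refit"` literally refits the model `n` times (the independent oracle
#' used in the test suite).
#'
#' @param y numeric response vector, length `n >= 3`, non-constant.
#' @param X numeric matrix `n x p` of covariates.
#' @param lam positive ridge penalty.
#' @param method `"shortcut"` (fast, exact) or `"refit"` (explicit oracle).
#' @return numeric vector of length `n` of held-out predictions.
#' @export
loocv_predictions <- function(y, X, lam, method = c("shortcut", "refit")) {
  method <- match.arg(method)
  X <- as.matrix(X)
  n <- length(y)
  if (n < 3L) stop_dsim("need at least 3 samples for leave-one-out cross-validation")
  if (nrow(X) != n) stop_dsim("nrow(X) must equal length(y)")
  if (stats::sd(y) == 0) stop_dsim("zero-variance response (degenerate probe)")
  if (!is.finite(lam) || lam <= 0) stop_dsim("lam must be a positive number")
  if (method == "shortcut") {
    return(.loocv_svd(y, .ridge_svd(X), lam))
  }
  p <- ncol(X)
  out <- numeric(n)
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    xb <- colMeans(X[tr, , drop = FALSE])
    Xc <- sweep(X[tr, , drop = FALSE], 2, xb, "-")
    yb <- mean(y[tr])
    b <- solve(crossprod(Xc) + diag(lam, p), crossprod(Xc, y[tr] - yb))
    out[i] <- yb + drop((X[i, ] - xb) %*% b)
  }
  out
}

#' Default logarithmic penalty grid
#'
#' 50 points, logarithmically spaced over six decades centered (in log space)
#' on the mean squared singular value of the centered covariate matrix, so
#' coverage is invariant to the scale of `X`.
#'
#' @param X numeric covariate matrix (samples by probes).
#' @param n_grid number of grid points.
#' @param decades half-width of the grid in powers of ten.
#' @return increasing numeric vector of penalties.
#' @export
lambda_grid_default <- function(X, n_grid = 50, decades = 3) {
  sv <- .ridge_svd(as.matrix(X))
  s <- if (length(sv$d)) mean(sv$d^2) else 1
  if (!is.finite(s) || s <= 0) s <- 1
  exp(seq(log(10^(-decades) * s), log(10^decades * s), length.out = n_grid))
}

#' Select the ridge penalty by cross-validated likelihood
#'
#' Scores every penalty on the grid by the Gaussian cross-validated
#' log-likelihood with the plug-in variance `sigma2_cv = PRESS / n`, a
#' monotone transform of the predictive squared error
#' `PRESS = sum((y - yhat^{-i})^2)`; maximizing it is equivalent to
#' minimizing PRESS. Ties go to the smallest penalty. The cross-validated
#' predictions at the selected penalty give the residuals passed on to the
#' group-association test.
#'
#' @inheritParams loocv_predictions
#' @param grid increasing vector of positive penalties; default
#'   [lambda_grid_default()].
#' @return object of class `ridge_baseline`: list with `lambda_grid`,
#'   `cv_criterion` (CV log-likelihood per grid point), `press`,
#'   `lambda_star`, `intercept_alpha`, `coefficients` (full-data fit at
#'   `lambda_star`; diagnostic), `cv_predictions` and `residuals`.
#' @export
select_lambda <- function(y, X, grid = NULL) {
  X <- as.matrix(X)
  if (is.null(grid)) grid <- lambda_grid_default(X)
  if (!length(grid) || any(!is.finite(grid)) || any(grid <= 0)) {
    stop_dsim("grid must be non-empty, finite and strictly positive")
  }
  if (is.unsorted(grid, strictly = FALSE)) stop_dsim("grid must be sorted ascending")
  n <- length(y)
  if (stats::sd(y) == 0) stop_dsim("zero-variance response (degenerate probe)")
  if (n < 3L) stop_dsim("need at least 3 samples")
  sv <- .ridge_svd(X)
  press <- cvll <- numeric(length(grid))
  preds <- NULL
  best <- -Inf
  best_idx <- 1L
  for (g in seq_along(grid)) {
    pr <- .loocv_svd(y, sv, grid[g])
    press[g] <- sum((y - pr)^2)
    s2 <- press[g] / n
    cvll[g] <- -n / 2 * (log(2 * pi * s2) + 1)
    if (cvll[g] > best) {  # strict: ties keep the smallest lambda
      best <- cvll[g]
      best_idx <- g
      preds <- pr
    }
  }
  lam <- grid[best_idx]
  # full-data coefficients at lambda*, diagnostic only
  yc <- y - mean(y)
  beta <- if (length(sv$d)) {
    drop(sv$V %*% (sv$d / (sv$d^2 + lam) * crossprod(sv$U, yc)))
  } else {
    numeric(ncol(X))
  }
  structure(
    list(
      lambda_grid = grid, cv_criterion = cvll, press = press,
      lambda_star = lam, intercept_alpha = mean(y) - sum(sv$xbar * beta),
      coefficients = beta, cv_predictions = preds, residuals = y - preds,
      n = n, p = ncol(X)
    ),
    class = "ridge_baseline"
  )
}

#' @export
print.ridge_baseline <- function(x, ...) {
  cat(sprintf(
    "ridge_baseline: n=%d, p=%d, lambda*=%.4g (grid of %d), PRESS=%.4g\n",
    x$n, x$p, x$lambda_star, length(x$lambda_grid),
    x$press[match(x$lambda_star, x$lambda_grid)]
  ))
  invisible(x)
}

#' Cross-validated residuals
#'
#' The corrected dependent data: `R = y - cv_predictions`, the part of the
#' probe's signal not explained (out of sample) by its covariate window.
#'
#' @param result a [select_lambda()] fit computed from this `y`.
#' @param y the response vector the fit was computed from.
#' @return numeric residual vector.
#' @export
cv_residuals <- function(result, y) {
  if (!inherits(result, "ridge_baseline")) stop_dsim("result must be a ridge_baseline")
  if (length(y) != length(result$cv_predictions)) {
    stop_dsim("length(y) does not match the fitted cross-validated predictions")
  }
  y - result$cv_predictions
}
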