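# Variance-component (global) score test. The random-coefficient model puts
# gamma_k ~ N(0, theta^2) on the covariate (or interaction) columns and tests
# H0: theta^2 = 0 with a quadratic form in the null-model residuals. The same
# core backs the group-differential test (kernel M M', null design = contrast)
# and the per-group baseline test (kernel X X', null design = intercept).

# Imhof (1961) integral for P(sum_k lambda_k * chi^2_1 > q), lambda_k >= 0.
# Numerical integration of the characteristic-function inversion; accurate to
# well below 1e-6 for the sizes used here.
.imhof_pvalue <- function(q, lambda) {
  lambda <- lambda[lambda > max(lambda) * 1e-12]
  if (!length(lambda)) return(1)
  if (q <= 0) return(1)
  scale <- max(lambda)
  lambda <- lambda / scale
  q <- q / scale
  if (length(lambda) == 1L) {
    return(stats::pchisq(q / lambda, df = 1, lower.tail = FALSE))
  }
  f <- function(u) {
    theta <- 0.5 * colSums(atan(outer(lambda, u))) - 0.5 * q * u
    logrho <- 0.25 * colSums(log1p(outer(lambda^2, u^2)))
    sin(theta) * exp(-logrho) / u
  }
  # The integrand oscillates with asymptotic frequency q/2 and decays like
  # u^(-1 - K/2); integrate one oscillation period at a time and stop once
  # successive pieces are negligible (alternating pieces cancel, so the
  # truncated tail is bounded by the last piece).
  step <- min(4 * pi / max(q, 0.5), 4)
  total <- 0
  a <- 0
  small <- 0L
  for (piece in seq_len(20000L)) {
    val <- stats::integrate(f, a, a + step, rel.tol = 1e-9, abs.tol = 1e-13,
                            subdivisions = 200L, stop.on.error = FALSE)$value
    total <- total + val
    a <- a + step
    small <- if (abs(val) < 1e-12) small + 1L else 0L
    if (small >= 3L) break
  }
  min(max(0.5 + total / pi, 0), 1)
}

# Lean core shared by global_test() and the permutation loop.
# R_tilde: null-projected residuals; sigma2: R'R/(n-q); M: kernel matrix
# (columns already in original scale); proj: function projecting columns onto
# the orthocomplement of the null design.
.gt_core <- function(R_tilde, sigma2, M, proj, exact = FALSE) {
  p <- ncol(M)
  Q <- sum(crossprod(M, R_tilde)^2)          # R~' M M' R~
  Tstat <- Q / (p * sigma2)
  AM <- proj(M)
  G <- crossprod(AM)
  tr1 <- sum(diag(G))
  if (Tstat <= 0 || tr1 <= 0) {
    return(list(statistic = 0, p = 1, G = G, AM = AM))
  }
  if (exact) {
    ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
    pval <- .imhof_pvalue(Q / sigma2, pmax(ev, 0))
  } else {
    tr2 <- sum(G^2)                          # trace((A M M' A)^2)
    a <- tr2 / tr1                           # Satterthwaite scale
    nu <- tr1^2 / tr2                        # Satterthwaite df
    pval <- stats::pchisq((Q / sigma2) / a, df = nu, lower.tail = FALSE)
  }
  list(statistic = Tstat, p = pval, G = G, AM = AM)
}

#' Global (variance-component score) test
#'
#' Tests whether the residuals `R` carry any linear signal along the columns
#' of `M`, treating the column coefficients as random effects with variance
#' `theta^2` and testing `H0: theta^2 = 0`. After projecting `R` on the
#' orthocomplement of the null design, the statistic is the quadratic form
#' `T = R~' M M' R~ / (p * sigma2)` with `sigma2 = R~'R~ / (n - q)`. The
#' asymptotic p-value comes from the weighted chi-square null distribution of
#' the quadratic form, by a Satterthwaite moment-matched scaled chi-square
#' (default) or by exact numerical inversion (`p_method = "exact"`).
#'
#' @param R numeric residual vector (length `n`).
#' @param M numeric `n x p` matrix: an [make_interaction()] matrix for the
#'   group-differential test, or the covariate block itself for a baseline
#'   association test.
#' @param null_design `n x q` numeric matrix of null covariates. Default:
#'   intercept plus the contrast column when `M` is an `interaction_matrix`,
#'   otherwise an intercept column. The intercept matters: any group-mean
#'   structure in the covariates lands in `span(1, c)` after the interaction
#'   with the contrast, and must be projected out of the kernel or it
#'   inflates the null scale and destroys power (see the methods vignette).
#'   Pass `matrix(contrast)` explicitly for the intercept-free variant.
#' @param p_method `"satterthwaite"` or `"exact"`.
#' @return object of class `global_test_result`: list with `statistic`,
#'   `p_value`, `z_scores` (per-covariate standardized influences),
#'   `dof_null`, `p_method`.
#' @export
global_test <- function(R, M, null_design = NULL,
                        p_method = c("satterthwaite", "exact")) {
  p_method <- match.arg(p_method)
  n <- length(R)
  Mm <- as.matrix(M)
  if (nrow(Mm) != n) stop_dsim("nrow(M) must equal length(R)")
  if (ncol(Mm) == 0L) stop_dsim("M has no columns (empty covariate window)")
  if (is.null(null_design)) {
    null_design <- if (inherits(M, "interaction_matrix")) {
      cbind(1, attr(M, "contrast"))
    } else {
      matrix(1, n, 1)
    }
  }
  D <- as.matrix(null_design)
  if (nrow(D) != n) stop_dsim("null_design must have length(R) rows")
  qr_d <- qr(D)
  q <- qr_d$rank
  if (q >= n) stop_dsim("null design leaves no residual degrees of freedom")
  R_tilde <- qr.resid(qr_d, R)
  sigma2 <- sum(R_tilde^2) / (n - q)
  if (sigma2 <= .Machine$double.eps * mean(R^2 + 1)) {
    return(structure(
      list(statistic = 0, p_value = 1, z_scores = rep(0, ncol(Mm)),
           dof_null = q, p_method = p_method),
      class = "global_test_result"
    ))
  }
  proj <- function(cols) qr.resid(qr_d, cols)
  core <- .gt_core(R_tilde, sigma2, Mm, proj, exact = (p_method == "exact"))
  mnorm <- sqrt(colSums(core$AM^2))
  z <- drop(crossprod(Mm, R_tilde)) / (sqrt(sigma2) * mnorm)
  z[mnorm <= 0] <- 0
  structure(
    list(statistic = core$statistic, p_value = core$p, z_scores = z,
         dof_null = q, p_method = p_method),
    class = "global_test_result"
  )
}

#' @export
print.global_test_result <- function(x, ...) {
  cat(sprintf("global test: T = %.4g, p = %.4g (%s, null rank %d)\n",
              x$statistic, x$p_value, x$p_method, x$dof_null))
  invisible(x)
}
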