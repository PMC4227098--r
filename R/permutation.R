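# Permutation null and Meinshausen FDP control. The null distribution of the
# group-association statistic is unknown after the ridge step, so sample
# labels of the covariate matrix are permuted B times; the SAME B
# permutations are used for every dependent probe (Meinshausen's procedure
# needs the cross-probe dependence preserved). Because the baseline fit never
# sees the grouping, the selected penalty and the cross-validated residuals
# are reused across permutations by default.

#' Observed and permuted global-test p-values
#'
#' Builds the m x (B + 1) p-value matrix: column 1 holds the observed
#' asymptotic global-test p-value per dependent probe; column `b + 1` holds
#' the p-value after permuting the sample rows of the covariate matrix with
#' the b-th shared permutation (the zero-sum contrast stays with the
#' samples). Probes with an empty window or degenerate residuals get a row
#' of 1 with a warning.
#'
#' @param R_all numeric m x n matrix of cross-validated residuals (one row
#'   per dependent probe), or a 1-row matrix / vector for a single probe.
#' @param X covariate [omics_matrix()] (probes x samples) or a numeric
#'   samples x probes matrix with probe columns named.
#' @param windows [build_windows()] map (list of covariate probe ids per
#'   dependent probe, aligned with rows of `R_all`).
#' @param contrast [make_contrast()] object over the same samples.
#' @param B number of permutations (>= 1).
#' @param seed integer seed for the shared permutations.
#' @param recompute_residuals if `TRUE`, refit the leave-one-out residuals at
#'   the stored penalty for every permutation (slow path; requires `Y` and
#'   `lambda_star`). Default `FALSE`: reuse the observed residuals.
#' @param Y dependent probes x samples matrix (only for the slow path).
#' @param lambda_star numeric vector of per-probe selected penalties (only
#'   for the slow path).
#' @return object of class `perm_pvalues`: list with `values` (m x (B+1)),
#'   `B`, `seed`, `shared_permutations = TRUE`, `probe_ids`.
#' @export
permuted_pvalues <- function(R_all, X, windows, contrast, B, seed = 1L,
                             recompute_residuals = FALSE,
                             Y = NULL, lambda_star = NULL) {
  if (B < 1L) stop_dsim("B must be at least 1")
  if (is.vector(R_all)) R_all <- matrix(R_all, nrow = 1)
  m <- nrow(R_all)
  n <- ncol(R_all)
  Xs <- if (inherits(X, "omics_matrix")) t(unclass(X)) else as.matrix(X)  # samples x probes
  if (nrow(Xs) != n) stop_dsim("covariate matrix sample count does not match residuals")
  if (length(windows) != m) stop_dsim("window map length does not match number of dependent probes")
  cvec <- contrast$c
  perms <- with_seed(seed, replicate(B, sample.int(n)))
  if (recompute_residuals && (is.null(Y) || is.null(lambda_star))) {
    stop_dsim("recompute_residuals = TRUE requires Y and lambda_star")
  }
  csq <- sum(cvec^2)
  P <- matrix(1, m, B + 1L)
  n_skip <- 0L
  for (i in seq_len(m)) {
    w <- windows[[i]]
    if (!length(w)) { n_skip <- n_skip + 1L; next }
    Xw <- Xs[, w, drop = FALSE]
    Ri <- R_all[i, ]
    if (stats::sd(Ri) == 0) { n_skip <- n_skip + 1L; next }
    P[i, 1L] <- .perm_gt_p(Ri, Xw, cvec, csq)
    for (b in seq_len(B)) {
      pi_ <- perms[, b]
      Rb <- if (recompute_residuals) {
        yb <- Y[i, ]
        yb - loocv_predictions(yb, Xw[pi_, , drop = FALSE], lambda_star[i])
      } else {
        Ri
      }
      P[i, b + 1L] <- .perm_gt_p(Rb, Xw[pi_, , drop = FALSE], cvec, csq)
    }
  }
  if (n_skip) {
    warning(n_skip, " probe(s) with empty window or degenerate residuals set to p = 1",
            call. = FALSE)
  }
  structure(
    list(values = P, B = B, seed = seed, shared_permutations = TRUE,
         probe_ids = rownames(R_all) %||% paste0("probe_", seq_len(m))),
    class = "perm_pvalues"
  )
}

# Lean one-shot global-test p-value for the permutation loop: projects R on
# span(1, c) (1 and c are orthogonal since sum(c) = 0), builds M = Xw * c
# and evaluates the Satterthwaite p. Must stay numerically identical to
# global_test(R, make_interaction(Xw, c)).
.perm_gt_p <- function(R, Xw, cvec, csq) {
  n <- length(R)
  R_tilde <- R - mean(R) - cvec * (sum(cvec * R) / csq)
  sigma2 <- sum(R_tilde^2) / (n - 2L)
  if (sigma2 <= .Machine$double.eps * mean(R^2 + 1)) return(1)
  M <- Xw * cvec
  Q <- sum(crossprod(M, R_tilde)^2)
  AM <- sweep(M, 2, colMeans(M), "-")
  AM <- AM - tcrossprod(cvec, crossprod(AM, cvec)) / csq
  G <- crossprod(AM)
  tr1 <- sum(diag(G))
  if (Q <= 0 || tr1 <= 0) return(1)
  tr2 <- sum(G^2)
  stats::pchisq((Q / sigma2) * tr1 / tr2, df = tr1^2 / tr2, lower.tail = FALSE)
}

#' Empirical permutation p-value for one probe
#'
#' Standard permutation p with the observed value included in the reference
#' set: `(1 + #\{b : p_b <= p_obs\}) / (B + 1)`; bounded below by `1/(B+1)`.
#'
#' @param row numeric vector of length `B + 1`: observed p first, then the
#'   `B` permuted p-values.
#' @return a single p-value.
#' @export
empirical_pvalue <- function(row) {
  if (length(row) < 2L) stop_dsim("row must contain the observed value plus permutations")
  (1 + sum(row[-1L] <= row[1L])) / length(row)
}

#' Meinshausen permutation-based FDP adjustment
#'
#' For each observed p-value threshold `t_(k)` (the k-th smallest observed
#' p), counts how many permuted p-values fall at or below it in each
#' permutation column, takes the `ceiling((1 - confidence_alpha) * B)`-th
#' smallest of those counts as the (1 - alpha)-confidence upper bound
#' `Vbar(t_(k))` on false discoveries, and bounds the FDP of the top-k set by
#' `Vbar(t_(k)) / k`. A running maximum over k enforces monotonicity; tied
#' observed p-values share the larger adjusted value. Probes with
#' `adjusted <= level` form the selected set.
#'
#' @param P a [permuted_pvalues()] object (or plain m x (B+1) matrix).
#' @param confidence_alpha 1 minus the confidence level of the FDP bound
#'   (default 0.05).
#' @param level selection threshold applied to the adjusted values.
#' @param include_observed if `TRUE`, the observed column is added to the
#'   null counts (more conservative variant).
#' @return object of class `fdp_result`: list with `adjusted`, `selected`,
#'   `level`, `confidence_alpha`, `probe_ids`.
#' @export
meinshausen_adjust <- function(P, confidence_alpha = 0.05, level = 0.01,
                               include_observed = FALSE) {
  if (inherits(P, "perm_pvalues")) {
    vals <- P$values
    ids <- P$probe_ids
  } else {
    vals <- as.matrix(P)
    ids <- rownames(vals) %||% paste0("probe_", seq_len(nrow(vals)))
  }
  if (confidence_alpha <= 0 || confidence_alpha >= 1) {
    stop_dsim("confidence_alpha must be in (0, 1)")
  }
  if (level <= 0 || level >= 1) stop_dsim("level must be in (0, 1)")
  obs <- vals[, 1L]
  perm <- vals[, -1L, drop = FALSE]
  if (include_observed) perm <- cbind(obs, perm)
  B <- ncol(perm)
  idx <- ceiling((1 - confidence_alpha) * B)
  if (idx > B) {
    stop_dsim("B = ", B, " permutations are too few for confidence_alpha = ",
              confidence_alpha, "; increase B")
  }
  m <- length(obs)
  ord <- order(obs)
  t_sorted <- obs[ord]
  # counts[b, k] = #{i : perm[i, b] <= t_(k)}
  counts <- vapply(seq_len(B), function(b) {
    findInterval(t_sorted, sort(perm[, b]))
  }, numeric(m))
  counts <- matrix(counts, nrow = m)  # m x B (k in rows)
  vbar <- apply(counts, 1L, function(v) sort(v)[idx])
  bound <- pmin(1, vbar / seq_len(m))
  adj_sorted <- cummax(bound)
  adj_sorted <- stats::ave(adj_sorted, t_sorted, FUN = max)
  adjusted <- numeric(m)
  adjusted[ord] <- adj_sorted
  structure(
    list(adjusted = adjusted, selected = adjusted <= level, level = level,
         confidence_alpha = confidence_alpha, probe_ids = ids),
    class = "fdp_result"
  )
}

#' @export
print.fdp_result <- function(x, ...) {
  cat(sprintf(
    "fdp_result: %d of %d probes selected at level %g (FDP confidence %g)\n",
    sum(x$selected), length(x$adjusted), x$level, 1 - x$confidence_alpha
  ))
  invisible(x)
}
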