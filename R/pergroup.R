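# Classical per-group baseline analysis: fit the association model within
# each sample group independently (variance-component test of the window
# coefficients, H0: omega^2 = 0) with Benjamini-Hochberg FDR control. Used
# as a comparator: its power differs with group size, which is exactly the
# failure mode the joint differential test avoids.

#' Per-group association test for one dependent probe
#'
#' Global test of the dependent values against their covariate window,
#' restricted to a sample subset (one group), null design = intercept only.
#'
#' @param y numeric dependent vector over all samples.
#' @param X_window numeric samples x probes covariate block.
#' @param samples integer or logical index of the subset (>= 3 samples).
#' @param p_method passed to [global_test()].
#' @return asymptotic p-value; 1 (with a warning) for a degenerate subset.
#' @export
sim_test <- function(y, X_window, samples, p_method = "satterthwaite") {
  ys <- y[samples]
  Xs <- as.matrix(X_window)[samples, , drop = FALSE]
  if (length(ys) < 3L) stop_dsim("subset must contain at least 3 samples")
  if (stats::sd(ys) == 0) {
    warning("degenerate (constant) response on subset; p = 1", call. = FALSE)
    return(1)
  }
  gt <- global_test(ys, Xs, null_design = matrix(1, length(ys), 1),
                    p_method = p_method)
  gt$p_value
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up FDR adjusted values with enforced monotonicity.
#'
#' @param p numeric p-values in `[0, 1]`.
#' @param fdr selection threshold on the adjusted values.
#' @return list with `q` (adjusted values) and `selected` (`q <= fdr`).
#' @export
bh_adjust <- function(p, fdr = 0.05) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop_dsim("p-values must lie in [0, 1]")
  q <- stats::p.adjust(p, method = "BH")
  list(q = q, selected = !is.na(q) & q <= fdr)
}

#' Per-group baseline association analysis
#'
#' Runs [sim_test()] for every dependent probe within each group separately
#' and applies Benjamini-Hochberg control per group. Note the caveat: with
#' unequal group sizes the larger group has more power, so differing
#' selection sets do NOT establish differential association.
#'
#' @param Y dependent [omics_matrix()] (probes x samples).
#' @param X covariate [omics_matrix()] (probes x samples), same samples.
#' @param windows [build_windows()] map aligned with rows of `Y`.
#' @param groups [make_contrast()] object (or two-level label vector).
#' @param fdr FDR level for selection.
#' @return object of class `pergroup_result`: list per group level with
#'   `p`, `q`, `selected`; plus `probe_ids`, `fdr`.
#' @export
run_pergroup <- function(Y, X, windows, groups, fdr = 0.05) {
  contrast <- if (inherits(groups, "group_contrast")) groups else make_contrast(groups)
  Ym <- unclass(Y)
  Xs <- t(unclass(X))  # samples x probes
  m <- nrow(Ym)
  if (length(windows) != m) stop_dsim("window map does not match dependent probes")
  res <- list()
  for (g in 1:2) {
    idx <- which(contrast$labels == contrast$levels[g])
    p <- rep(NA_real_, m)
    for (i in seq_len(m)) {
      w <- windows[[i]]
      if (!length(w)) next
      p[i] <- suppressWarnings(sim_test(Ym[i, ], Xs[, w, drop = FALSE], idx))
    }
    p_filled <- ifelse(is.na(p), 1, p)
    adj <- bh_adjust(p_filled, fdr)
    res[[contrast$levels[g]]] <- list(p = p_filled, q = adj$q, selected = adj$selected,
                                      n_samples = length(idx))
  }
  structure(
    list(groups = res, probe_ids = rownames(Ym), fdr = fdr,
         levels = contrast$levels),
    class = "pergroup_result"
  )
}

#' @export
print.pergroup_result <- function(x, ...) {
  cat("per-group association analysis (power differs with group size!)\n")
  for (lv in x$levels) {
    g <- x$groups[[lv]]
    cat(sprintf("  group '%s' (n=%d): %d of %d probes selected at FDR %g\n",
                lv, g$n_samples, sum(g$selected), length(g$p), x$fdr))
  }
  invisible(x)
}
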