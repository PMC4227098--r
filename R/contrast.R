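#' Zero-sum group contrast
#'
#' Encodes a two-level grouping as the zero-sum contrast vector `c` with
#' `c_j = n_G2 / n` for group-1 samples and `c_j = -n_G1 / n` for group-2
#' samples, so that `sum(c) == 0` and group effects are orthogonal to the
#' overall mean of the residuals. Group 1 is the first level of the labels
#' (factor level order, or sorted unique values).
#'
#' @param labels per-sample group labels (vector or factor) with exactly two
#'   distinct values, each occurring at least twice. Names, if present, are
#'   kept as sample ids.
#' @return object of class `group_contrast`: list with `labels`, `levels`,
#'   `n_g1`, `n_g2`, `n` and the contrast vector `c`.
#' @export
make_contrast <- function(labels) {
  f <- if (is.factor(labels)) droplevels(labels) else factor(labels, levels = sort(unique(as.character(labels))))
  lev <- levels(f)
  if (length(lev) != 2L) {
    stop_dsim("grouping must have exactly two levels, got ", length(lev))
  }
  n1 <- sum(f == lev[1]); n2 <- sum(f == lev[2]); n <- n1 + n2
  if (n1 < 2L || n2 < 2L) stop_dsim("each group needs at least 2 samples (got ", n1, " and ", n2, ")")
  cvec <- ifelse(f == lev[1], n2 / n, -n1 / n)
  names(cvec) <- names(labels)
  structure(
    list(labels = as.character(f), levels = lev, n_g1 = n1, n_g2 = n2, n = n, c = cvec),
    class = "group_contrast"
  )
}

#' @export
print.group_contrast <- function(x, ...) {
  cat(sprintf(
    "group_contrast: '%s' (n=%d, c=%+.4g) vs '%s' (n=%d, c=%+.4g)\n",
    x$levels[1], x$n_g1, x$c[match(x$levels[1], x$labels)],
    x$levels[2], x$n_g2, x$c[match(x$levels[2], x$labels)]
  ))
  invisible(x)
}

#' Gene-by-group interaction matrix
#'
#' Multiplies each row of the samples-by-probes covariate matrix by the
#' sample's contrast value: `M[j, k] = X[j, k] * c[j]`. The coefficients of
#' `M` in the residual model carry the group-differential association; no
#' centering is applied (the contrast already sums to zero).
#'
#' @param X numeric matrix, samples in rows, covariate probes in columns.
#' @param contrast a [make_contrast()] object (or numeric contrast vector).
#' @return numeric matrix of the same shape, class `interaction_matrix`,
#'   with the contrast attached as attribute `contrast`.
#' @export
make_interaction <- function(X, contrast) {
  cvec <- if (inherits(contrast, "group_contrast")) contrast$c else as.numeric(contrast)
  X <- as.matrix(X)
  if (nrow(X) != length(cvec)) {
    stop_dsim("X has ", nrow(X), " rows but the contrast has length ", length(cvec))
  }
  M <- X * cvec  # column-wise recycling = row scaling
  structure(M, class = c("interaction_matrix", "matrix", "array"), contrast = cvec)
}
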