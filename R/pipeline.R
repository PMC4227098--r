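# End-to-end orchestration: per dependent probe, window -> ridge/LOOCV
# baseline correction -> cross-validated residuals -> group-interaction
# global test -> shared-permutation null -> Meinshausen FDP adjustment
# across all probes jointly.

#' Run the differential-association analysis
#'
#' The core engine. For each dependent probe with a non-empty covariate
#' window: the penalty and the leave-one-out residuals are fitted once on
#' all samples with no group term; observed and permuted group-association
#' p-values are computed with one shared set of permutations; finally
#' Meinshausen's FDP adjustment is applied jointly across probes.
#' Deterministic given `seed`.
#'
#' @param Y dependent [omics_matrix()] (probes x samples).
#' @param X covariate [omics_matrix()] (probes x samples), same samples in
#'   the same order.
#' @param windows [build_windows()] map aligned with the rows of `Y`.
#' @param groups [make_contrast()] object or two-level label vector aligned
#'   with the samples.
#' @param lambda_grid penalty grid, or `NULL` for the scale-free default
#'   per probe.
#' @param B number of permutations.
#' @param seed master seed (permutations are the only randomness).
#' @param level selection threshold on adjusted values.
#' @param confidence_alpha 1 minus the FDP confidence level.
#' @param recompute_residuals refit residuals at the stored penalty for each
#'   permutation (slow path) instead of reusing the observed residuals.
#' @return object of class `dsim_result`: list with `table` (per-probe
#'   data.frame: `probe_id`, `lambda_star`, `p_observed`, `p_empirical`,
#'   `adjusted`, `selected`, `skipped`), `fdp` ([meinshausen_adjust()]
#'   result), `perm` ([permuted_pvalues()] object), `contrast`, `B`, `seed`.
#' @export
dsim_fit <- function(Y, X, windows, groups, lambda_grid = NULL, B = 99,
                     seed = 1L, level = 0.01, confidence_alpha = 0.05,
                     recompute_residuals = FALSE) {
  contrast <- if (inherits(groups, "group_contrast")) groups else make_contrast(groups)
  Ym <- unclass(Y)
  Xs <- t(unclass(X))  # samples x probes
  if (ncol(Ym) != nrow(Xs)) stop_dsim("Y and X disagree on samples; align first")
  if (length(contrast$c) != ncol(Ym)) stop_dsim("groups do not match samples; align first")
  m <- nrow(Ym)
  if (length(windows) != m) stop_dsim("window map does not match dependent probes")
  R_all <- matrix(0, m, ncol(Ym), dimnames = list(rownames(Ym), colnames(Ym)))
  lambda_star <- rep(NA_real_, m)
  skipped <- character(m)
  for (i in seq_len(m)) {
    w <- windows[[i]]
    if (!length(w)) { skipped[i] <- "empty window"; next }
    yi <- Ym[i, ]
    if (stats::sd(yi) == 0) { skipped[i] <- "zero-variance probe"; next }
    fit <- tryCatch(
      select_lambda(yi, Xs[, w, drop = FALSE], grid = lambda_grid),
      error = function(e) {
        stop_dsim("probe '", rownames(Ym)[i], "', baseline ridge stage: ",
                  conditionMessage(e))
      }
    )
    lambda_star[i] <- fit$lambda_star
    R_all[i, ] <- fit$residuals
  }
  perm <- suppressWarnings(permuted_pvalues(
    R_all, X, windows, contrast, B = B, seed = seed,
    recompute_residuals = recompute_residuals,
    Y = Ym, lambda_star = lambda_star
  ))
  fdp <- meinshausen_adjust(perm, confidence_alpha = confidence_alpha, level = level)
  p_emp <- apply(perm$values, 1, empirical_pvalue)
  tab <- data.frame(
    probe_id = rownames(Ym) %||% paste0("probe_", seq_len(m)),
    lambda_star = lambda_star,
    p_observed = perm$values[, 1],
    p_empirical = p_emp,
    adjusted = fdp$adjusted,
    selected = fdp$selected,
    skipped = skipped,
    stringsAsFactors = FALSE
  )
  structure(
    list(table = tab, fdp = fdp, perm = perm, contrast = contrast,
         B = B, seed = seed, level = level,
         confidence_alpha = confidence_alpha),
    class = "dsim_result"
  )
}

#' @export
print.dsim_result <- function(x, ...) {
  n_skip <- sum(nzchar(x$table$skipped))
  cat(sprintf(
    "differential association: %d probes (%d skipped), B = %d permutations\n",
    nrow(x$table), n_skip, x$B
  ))
  cat(sprintf("  selected at level %g (FDP confidence %g): %d probes\n",
              x$level, 1 - x$confidence_alpha, sum(x$table$selected)))
  invisible(x)
}

#' File-driven run configuration
#'
#' @param y_path,x_path dependent / covariate matrix TSVs.
#' @param y_ann_path,x_ann_path probe annotation TSVs.
#' @param groups_path sample grouping TSV.
#' @param window_mode `"arm"` or `"bp_window"`.
#' @param window_bp window width in bp for `bp_window` mode.
#' @param B,seed,level,confidence_alpha,recompute_residuals see [dsim_fit()].
#' @param out_dir output directory for result TSVs (`NULL` = do not write).
#' @param bed annotation files use BED coordinates.
#' @param na_policy missing-value policy for the matrices.
#' @return list of class `run_config`.
#' @export
run_config <- function(y_path, x_path, y_ann_path, x_ann_path, groups_path,
                       window_mode = "arm", window_bp = NULL, B = 99,
                       seed = 1L, level = 0.01, confidence_alpha = 0.05,
                       recompute_residuals = FALSE, out_dir = NULL,
                       bed = FALSE, na_policy = "strict") {
  cfg <- list(
    y_path = y_path, x_path = x_path, y_ann_path = y_ann_path,
    x_ann_path = x_ann_path, groups_path = groups_path,
    window_mode = window_mode, window_bp = window_bp,
    B = as.integer(B), seed = as.integer(seed), level = as.numeric(level),
    confidence_alpha = as.numeric(confidence_alpha),
    recompute_residuals = isTRUE(recompute_residuals) || identical(recompute_residuals, "true"),
    out_dir = out_dir, bed = isTRUE(bed) || identical(bed, "true"),
    na_policy = na_policy
  )
  if (cfg$B < 1) stop_dsim("B must be at least 1")
  if (cfg$level <= 0 || cfg$level >= 1) stop_dsim("level must be in (0, 1)")
  if (cfg$confidence_alpha <= 0 || cfg$confidence_alpha >= 1) {
    stop_dsim("confidence_alpha must be in (0, 1)")
  }
  structure(cfg, class = "run_config")
}

#' Run the full analysis from files
#'
#' Reads the matrices, annotation and grouping named in the configuration,
#' aligns samples, builds windows, runs [dsim_fit()] and (optionally) writes
#' `dsim_results.tsv` to the output directory.
#'
#' @param config a [run_config()].
#' @return the [dsim_fit()] result, invisibly when writing files.
#' @export
run_dsim <- function(config) {
  stopifnot(inherits(config, "run_config"))
  Y <- read_omics_matrix(config$y_path, role = "dependent", na_policy = config$na_policy)
  X <- read_omics_matrix(config$x_path, role = "covariate", na_policy = config$na_policy)
  y_ann <- read_probe_annotation(config$y_ann_path, bed = config$bed)
  x_ann <- read_probe_annotation(config$x_ann_path, bed = config$bed)
  groups <- read_groups(config$groups_path)
  al <- align_samples(Y, X, groups)
  dep_ann <- y_ann[match(rownames(al$y), y_ann$probe_id), , drop = FALSE]
  if (anyNA(dep_ann$probe_id)) stop_dsim("dependent probe(s) missing from annotation")
  windows <- build_windows(dep_ann, x_ann, mode = config$window_mode,
                           window_bp = config$window_bp)
  windows <- lapply(windows, intersect, rownames(al$x))
  class(windows) <- "window_map"
  res <- dsim_fit(al$y, al$x, windows, al$contrast,
                  B = config$B, seed = config$seed, level = config$level,
                  confidence_alpha = config$confidence_alpha,
                  recompute_residuals = config$recompute_residuals)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(res$table,
                       file.path(config$out_dir, "dsim_results.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(res))
  }
  res
}
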