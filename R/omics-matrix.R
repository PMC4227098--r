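#' Omics matrix container
#'
#' A thin, validated wrapper around a numeric probes-by-samples matrix with
#' probe and sample identifiers and a declared role. The dependent matrix
#' (role `"dependent"`, e.g. copy number) supplies the outcome `y` for each
#' probe; the covariate matrix (role `"covariate"`, e.g. gene expression)
#' supplies the regressors within each probe's genomic window.
#'
#' @param values numeric matrix, probes in rows, samples in columns.
#' @param probe_ids character vector of unique probe identifiers
#'   (defaults to rownames).
#' @param sample_ids character vector of unique sample identifiers
#'   (defaults to colnames).
#' @param role `"dependent"` or `"covariate"`.
#' @param na_policy how to handle missing values: `"strict"` (error, the
#'   default) or `"impute_rowmean"` (replace each NA by its probe's mean over
#'   the non-missing samples).
#' @return an object of class `omics_matrix`: the numeric matrix with
#'   dimnames set and attributes `role`.
#' @export
omics_matrix <- function(values, probe_ids = rownames(values),
                         sample_ids = colnames(values),
                         role = c("dependent", "covariate"),
                         na_policy = c("strict", "impute_rowmean")) {
  role <- match.arg(role)
  na_policy <- match.arg(na_policy)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(probe_ids) || is.null(sample_ids)) {
    stop_dsim("omics_matrix requires probe and sample identifiers")
  }
  probe_ids <- as.character(probe_ids)
  sample_ids <- as.character(sample_ids)
  if (length(probe_ids) != nrow(values) || length(sample_ids) != ncol(values)) {
    stop_dsim("identifier lengths do not match matrix dimensions")
  }
  dup_p <- probe_ids[duplicated(probe_ids)]
  if (length(dup_p)) {
    stop_dsim("duplicated probe id(s): ", paste(unique(dup_p), collapse = ", "))
  }
  dup_s <- sample_ids[duplicated(sample_ids)]
  if (length(dup_s)) {
    stop_dsim("duplicated sample id(s): ", paste(unique(dup_s), collapse = ", "))
  }
  if (anyNA(values) || any(!is.finite(values))) {
    if (na_policy == "strict") {
      bad <- which(!is.finite(values), arr.ind = TRUE)[1, ]
      stop_dsim(
        "non-finite value at probe '", probe_ids[bad[1]],
        "', sample '", sample_ids[bad[2]],
        "' (na_policy = \"strict\")"
      )
    }
    values[!is.finite(values)] <- NA_real_
    rm_ <- rowMeans(values, na.rm = TRUE)
    if (anyNA(rm_)) {
      stop_dsim("probe(s) with all values missing cannot be imputed")
    }
    idx <- which(is.na(values), arr.ind = TRUE)
    values[idx] <- rm_[idx[, 1]]
  }
  dimnames(values) <- list(probe_ids, sample_ids)
  structure(values, class = c("omics_matrix", "matrix", "array"), role = role)
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(
    sprintf(
      "omics_matrix (%s): %d probes x %d samples\n",
      attr(x, "role"), nrow(x), ncol(x)
    )
  )
  invisible(x)
}

probe_ids <- function(x) rownames(x)
sample_ids_of <- function(x) colnames(x)

#' Read an omics matrix from tab-delimited text
#'
#' Expects a header row of sample identifiers and a first column of probe
#' identifiers; the body must be numeric. Row and column order are preserved.
#'
#' @param path file path.
#' @inheritParams omics_matrix
#' @return an [omics_matrix()].
#' @export
read_omics_matrix <- function(path, role = c("dependent", "covariate"),
                              na_policy = c("strict", "impute_rowmean")) {
  role <- match.arg(role)
  na_policy <- match.arg(na_policy)
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE, colClasses = "character")
  if (ncol(df) < 2) stop_dsim("matrix file needs a probe id column plus samples: ", path)
  ids <- df[[1]]
  body <- df[, -1, drop = FALSE]
  num <- suppressWarnings(vapply(body, as.numeric, numeric(nrow(body))))
  if (nrow(body) == 1L) num <- matrix(num, nrow = 1, dimnames = list(NULL, colnames(body)))
  bad <- which(is.na(num) & !(toupper(trimws(as.matrix(body))) %in% c("NA", "")), arr.ind = TRUE)
  if (nrow(bad <- as.matrix(bad))) {
    stop_dsim(
      "non-numeric cell at probe '", ids[bad[1, 1]], "', sample '",
      colnames(body)[bad[1, 2]], "' in ", path
    )
  }
  omics_matrix(num, probe_ids = ids, sample_ids = colnames(body),
               role = role, na_policy = na_policy)
}

#' Write an omics matrix as tab-delimited text
#'
#' Inverse of [read_omics_matrix()] up to numeric formatting precision.
#'
#' @param x an [omics_matrix()].
#' @param path output file path.
#' @export
write_omics_matrix <- function(x, path) {
  df <- data.frame(probe_id = rownames(x), as.data.frame(unclass(x)[, , drop = FALSE]),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read probe annotation
#'
#' Tab-delimited with columns `probe_id`, `chromosome`, `arm`, `start`, `end`.
#' Coordinates are 1-based inclusive; with `bed = TRUE` they are interpreted
#' as 0-based half-open and converted on read.
#'
#' @param path file path.
#' @param bed logical; input uses BED (0-based half-open) coordinates.
#' @return data.frame with the five columns above plus `midpoint`.
#' @export
read_probe_annotation <- function(path, bed = FALSE) {
  ann <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("probe_id", "chromosome", "arm", "start", "end")
  miss <- setdiff(need, names(ann))
  if (length(miss)) stop_dsim("annotation missing column(s): ", paste(miss, collapse = ", "))
  probe_annotation(ann$probe_id, ann$chromosome, ann$arm, ann$start, ann$end, bed = bed)
}

#' Construct probe annotation
#'
#' @param probe_id,chromosome,arm,start,end vectors of equal length; `arm`
#'   may be NA when only bp-window mapping is used.
#' @param bed logical; coordinates given as 0-based half-open intervals.
#' @return data.frame of class `probe_annotation`.
#' @export
probe_annotation <- function(probe_id, chromosome, arm = NA, start, end, bed = FALSE) {
  start <- as.numeric(start); end <- as.numeric(end)
  if (bed) start <- start + 1  # half-open end is already the inclusive end
  ann <- data.frame(
    probe_id = as.character(probe_id),
    chromosome = as.character(chromosome),
    arm = as.character(arm),
    start = start, end = end,
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(ann$probe_id)) {
    stop_dsim("duplicated probe id(s) in annotation: ",
              paste(unique(ann$probe_id[duplicated(ann$probe_id)]), collapse = ", "))
  }
  if (any(ann$start > ann$end)) stop_dsim("annotation has start > end")
  ann$midpoint <- (ann$start + ann$end) / 2
  class(ann) <- c("probe_annotation", "data.frame")
  ann
}

#' Read sample grouping
#'
#' Tab-delimited `sample_id<TAB>group` with exactly two group levels.
#'
#' @param path file path.
#' @return named vector of group labels (names are sample ids).
#' @export
read_groups <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop_dsim("groups file needs columns sample_id, group")
  g <- as.character(df[[2]])
  names(g) <- as.character(df[[1]])
  if (anyDuplicated(names(g))) stop_dsim("duplicated sample id(s) in groups file")
  g
}

#' Align samples across matrices and grouping
#'
#' Restricts the dependent matrix, covariate matrix and group labels to their
#' common samples, in a single shared ordering (the dependent matrix's order).
#' Dropped samples are reported via a warning.
#'
#' @param y_mat dependent [omics_matrix()].
#' @param x_mat covariate [omics_matrix()].
#' @param groups named group-label vector (see [read_groups()]).
#' @return list with elements `y`, `x`, `groups`, `contrast` (a
#'   [make_contrast()] object over the aligned samples).
#' @export
align_samples <- function(y_mat, x_mat, groups) {
  common <- intersect(intersect(colnames(y_mat), colnames(x_mat)), names(groups))
  if (!length(common)) stop_dsim("no samples shared by the dependent matrix, covariate matrix and groups")
  keep <- colnames(y_mat)[colnames(y_mat) %in% common]
  dropped <- setdiff(
    unique(c(colnames(y_mat), colnames(x_mat), names(groups))), keep
  )
  if (length(dropped)) {
    warning("dropping ", length(dropped), " sample(s) absent from some input: ",
            paste(utils::head(dropped, 5), collapse = ", "),
            if (length(dropped) > 5) ", ..." else "", call. = FALSE)
  }
  y2 <- omics_matrix(unclass(y_mat)[, keep, drop = FALSE], role = attr(y_mat, "role"))
  x2 <- omics_matrix(unclass(x_mat)[, keep, drop = FALSE], role = attr(x_mat, "role"))
  g2 <- groups[keep]
  contrast <- make_contrast(g2)
  list(y = y2, x = x2, groups = g2, contrast = contrast)
}

#' Map dependent probes to covariate windows
#'
#' For each dependent probe, finds the covariate probes forming its gene set:
#' either all covariates on the same chromosome arm (`mode = "arm"`) or all
#' covariates whose midpoint lies within `window_bp / 2` of the dependent
#' probe's midpoint (`mode = "bp_window"`, closed interval). Windows are
#' ordered by genomic position, ties broken by probe id.
#'
#' @param dep_ann dependent-probe [probe_annotation()].
#' @param cov_ann covariate-probe [probe_annotation()].
#' @param mode `"arm"` or `"bp_window"`.
#' @param window_bp total window width in bp (`bp_window` mode); the window
#'   extends `window_bp/2` either side of the dependent probe midpoint.
#' @return named list (one element per dependent probe, in `dep_ann` order)
#'   of covariate probe-id character vectors; class `window_map`.
#' @export
build_windows <- function(dep_ann, cov_ann, mode = c("arm", "bp_window"),
                          window_bp = NULL) {
  mode <- match.arg(mode)
  if (mode == "bp_window" && (is.null(window_bp) || window_bp <= 0)) {
    stop_dsim("mode = \"bp_window\" requires window_bp > 0")
  }
  ord <- order(cov_ann$chromosome, cov_ann$midpoint, cov_ann$probe_id)
  cov <- cov_ann[ord, , drop = FALSE]
  out <- vector("list", nrow(dep_ann))
  names(out) <- dep_ann$probe_id
  for (i in seq_len(nrow(dep_ann))) {
    if (mode == "arm") {
      hit <- cov$chromosome == dep_ann$chromosome[i] &
        !is.na(cov$arm) & !is.na(dep_ann$arm[i]) & cov$arm == dep_ann$arm[i]
    } else {
      half <- window_bp / 2
      hit <- cov$chromosome == dep_ann$chromosome[i] &
        abs(cov$midpoint - dep_ann$midpoint[i]) <= half
    }
    out[[i]] <- cov$probe_id[hit]
  }
  n_empty <- sum(lengths(out) == 0L)
  if (n_empty) {
    warning(n_empty, " dependent probe(s) have an empty covariate window and will be skipped",
            call. = FALSE)
  }
  structure(out, class = "window_map")
}
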