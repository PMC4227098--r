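test_that("matrix TSV round trip preserves ids, shape and values", {
  m <- toy_matrix(3, 4, seed = 11)
  path <- file.path(tempdir(), "mat.tsv")
  write_omics_matrix(m, path)
  back <- read_omics_matrix(path, role = "dependent")
  expect_equal(dim(back), c(3, 4))
  expect_identical(rownames(back), rownames(m))
  expect_identical(colnames(back), colnames(m))
  expect_equal(unclass(back), unclass(m), tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("duplicate and non-numeric inputs fail with informative errors", {
  expect_error(
    omics_matrix(matrix(1:4, 2), probe_ids = c("a", "a"), sample_ids = c("s1", "s2")),
    "duplicated probe id.*a"
  )
  expect_error(
    omics_matrix(matrix(1:4, 2), probe_ids = c("a", "b"), sample_ids = c("s", "s")),
    "duplicated sample id"
  )
  path <- write_tsv_fixture(
    data.frame(probe_id = c("p1", "p2"), s1 = c("1.5", "oops"), s2 = c("2", "3")),
    "bad.tsv"
  )
  expect_error(read_omics_matrix(path, "covariate"), "p2.*s1|non-numeric")
})

test_that("missing-value policy: strict errors, impute_rowmean fills row means", {
  vals <- matrix(c(1, 2, NA, 4, 5, 6), 2, 3,
                 dimnames = list(c("p1", "p2"), c("s1", "s2", "s3")))
  expect_error(omics_matrix(vals, role = "dependent"), "non-finite")
  imp <- omics_matrix(vals, role = "dependent", na_policy = "impute_rowmean")
  expect_equal(unclass(imp)["p1", "s2"], mean(c(1, 5)))  # row mean over observed
})

test_that("align_samples reorders, drops extras with a warning, and is idempotent", {
  y <- toy_matrix(2, 4, seed = 1)
  x_vals <- with_test_seed(2, matrix(rnorm(15), 3, 5))
  x <- omics_matrix(x_vals, probe_ids = paste0("g", 1:3),
                    sample_ids = c("s3", "s1", "s4", "s2", "s9"), role = "covariate")
  groups <- stats::setNames(c("1", "1", "2", "2"), c("s4", "s2", "s1", "s3"))
  expect_warning(al <- align_samples(y, x, groups), "dropping 1 sample")
  expect_identical(colnames(al$y), colnames(al$x))
  expect_identical(colnames(al$y), names(al$groups))
  expect_equal(sum(al$contrast$c), 0, tolerance = 1e-14)
  # idempotent on already-aligned inputs
  al2 <- align_samples(al$y, al$x, al$groups)
  expect_identical(unclass(al2$y), unclass(al$y))
  expect_identical(unclass(al2$x), unclass(al$x))
  # disjoint samples are a hard error
  x_disjoint <- omics_matrix(x_vals, probe_ids = paste0("g", 1:3),
                             sample_ids = paste0("z", 1:5), role = "covariate")
  expect_error(align_samples(y, x_disjoint, groups), "no samples shared")
})

test_that("arm windows collect all same-arm covariates", {
  dep <- probe_annotation(c("d1", "d2"), "1", "q", c(1e6, 5e6), c(1e6, 5e6) + 10)
  cov <- probe_annotation(paste0("g", 1:5), "1", c("q", "q", "q", "p", "p"),
                          c(2, 4, 6, 1, 3) * 1e6, c(2, 4, 6, 1, 3) * 1e6 + 10)
  w <- build_windows(dep, cov, mode = "arm")
  expect_identical(w[["d1"]], c("g1", "g2", "g3"))
  expect_identical(w[["d2"]], c("g1", "g2", "g3"))
})

test_that("bp windows use closed midpoint intervals of width window_bp", {
  dep <- probe_annotation("d1", "1", "q", 10e6 - 10, 10e6 + 10)  # midpoint 10 Mb
  cov <- probe_annotation(paste0("g", 1:3), "1", "q",
                          c(9.1e6, 11e6, 11.1e6) - 10, c(9.1e6, 11e6, 11.1e6) + 10)
  w <- build_windows(dep, cov, mode = "bp_window", window_bp = 2e6)
  # 11 Mb midpoint sits exactly on the boundary and is included
  expect_identical(w[["d1"]], c("g1", "g2"))
  expect_error(build_windows(dep, cov, mode = "bp_window"), "window_bp")
})

test_that("window membership is invariant to annotation row order; empty windows warn", {
  dep <- probe_annotation(c("d1", "d2"), c("1", "2"), "q", c(1e6, 1e6), c(1e6, 1e6) + 10)
  cov <- probe_annotation(paste0("g", 1:4), "1", "q",
                          c(3, 1, 2, 4) * 5e5, c(3, 1, 2, 4) * 5e5 + 10)
  expect_warning(w1 <- build_windows(dep, cov, mode = "arm"), "empty covariate window")
  shuf <- cov[c(4, 1, 3, 2), ]
  expect_warning(w2 <- build_windows(dep, shuf, mode = "arm"))
  expect_identical(w1[["d1"]], w2[["d1"]])
  expect_length(w1[["d2"]], 0)
})

test_that("BED annotation coordinates convert to 1-based inclusive", {
  ann <- probe_annotation("p1", "1", "q", 100, 200, bed = TRUE)
  expect_equal(ann$start, 101)
  expect_equal(ann$end, 200)
  expect_error(probe_annotation("p1", "1", "q", 300, 200), "start > end")
})
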