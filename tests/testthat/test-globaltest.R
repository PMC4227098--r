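test_that("contrast encoding matches the zero-sum parameterization", {
  ct <- make_contrast(rep(c("g1", "g2"), c(30, 15)))
  expect_equal(unique(ct$c[1:30]), 1 / 3, tolerance = 1e-14)
  expect_equal(unique(ct$c[31:45]), -2 / 3, tolerance = 1e-14)
  expect_equal(sum(ct$c), 0, tolerance = 1e-12)
  ct_eq <- make_contrast(rep(c("a", "b"), each = 4))
  expect_equal(sort(unique(ct_eq$c)), c(-0.5, 0.5), tolerance = 1e-14)
  expect_error(make_contrast(rep("a", 5)), "two levels")
  expect_error(make_contrast(c("a", "b", "c", "a", "b", "c")), "two levels")
  expect_error(make_contrast(c("a", "a", "a", "b")), "at least 2")
})

test_that("relabeling the groups flips the contrast but not the statistic", {
  set.seed(20)
  n <- 16
  labs <- rep(c("ctrl", "case"), each = 8)
  flipped <- ifelse(labs == "ctrl", "case", "ctrl")
  X <- matrix(rnorm(n * 4), n, 4)
  R <- rnorm(n)
  ct1 <- make_contrast(labs)
  ct2 <- make_contrast(flipped)
  expect_equal(ct2$c, -ct1$c, tolerance = 1e-14)
  g1 <- global_test(R, make_interaction(X, ct1))
  g2 <- global_test(R, make_interaction(X, ct2))
  expect_equal(g1$statistic, g2$statistic, tolerance = 1e-12)
  expect_equal(g1$p_value, g2$p_value, tolerance = 1e-12)
})

test_that("interaction matrix is the row-wise contrast scaling of X", {
  set.seed(21)
  X <- matrix(rnorm(12 * 3), 12, 3)
  ct <- make_contrast(rep(1:2, each = 6))
  M <- make_interaction(X, ct)
  expect_equal(unclass(M), X * ct$c, ignore_attr = TRUE)
  expect_equal(colSums(unclass(M)^2), colSums(ct$c^2 * X^2), tolerance = 1e-12)
  # degenerate all-equal contrast (precondition bypassed): M proportional to X
  M2 <- make_interaction(X, rep(0.3, 12))
  expect_equal(unclass(M2), 0.3 * X, ignore_attr = TRUE)
  expect_error(make_interaction(X, ct$c[-1]), "rows")
})

test_that("zero kernel gives statistic 0 and p-value 1", {
  gt <- global_test(rnorm(10), matrix(0, 10, 3), null_design = matrix(1, 10, 1))
  expect_equal(gt$statistic, 0)
  expect_equal(gt$p_value, 1)
  expect_error(global_test(rnorm(10), matrix(rnorm(10), 5, 2)), "nrow")
})

test_that("statistic equals the naive dense quadratic form", {
  set.seed(22)
  for (r in 1:5) {
    n <- 15; p <- 8
    R <- rnorm(n)
    X <- matrix(rnorm(n * p), n, p)
    ct <- make_contrast(rep(1:2, c(7, 8)))
    M <- make_interaction(X, ct)
    D <- cbind(1, ct$c)
    gt <- global_test(R, M)
    expect_equal(gt$statistic, oracle_global_stat(R, unclass(M), D),
                 tolerance = 1e-10)
    # intercept-only null (per-group baseline test form)
    gt0 <- global_test(R, X, null_design = matrix(1, n, 1))
    expect_equal(gt0$statistic, oracle_global_stat(R, X, matrix(1, n, 1)),
                 tolerance = 1e-10)
  }
})

test_that("Satterthwaite p tracks the exact-series p within 0.02 in [0.01, 0.5]", {
  set.seed(23)
  checked <- 0
  for (r in 1:60) {
    n <- sample(12:25, 1); p <- sample(3:10, 1)
    R <- rnorm(n)
    X <- matrix(rnorm(n * p), n, p)
    ct <- make_contrast(rep(1:2, c(floor(n / 2), ceiling(n / 2))))
    M <- make_interaction(X, ct)
    p_sat <- global_test(R, M)$p_value
    p_ex <- global_test(R, M, p_method = "exact")$p_value
    if (p_ex >= 0.01 && p_ex <= 0.5) {
      checked <- checked + 1
      expect_lt(abs(p_sat - p_ex), 0.02)
    }
  }
  expect_gt(checked, 10)
})

test_that("statistic is invariant to residual scale and null-space shifts", {
  set.seed(24)
  n <- 20
  R <- rnorm(n)
  X <- matrix(rnorm(n * 5), n, 5)
  ct <- make_contrast(rep(1:2, each = 10))
  M <- make_interaction(X, ct)
  base <- global_test(R, M)
  expect_equal(global_test(5 * R, M)$statistic, base$statistic, tolerance = 1e-10)
  shifted <- R + 2.5 + 1.7 * ct$c  # add a vector in span(null design)
  expect_equal(global_test(shifted, M)$statistic, base$statistic, tolerance = 1e-9)
})

test_that("z-scores are standardized: invariant to column rescaling", {
  set.seed(25)
  n <- 18
  R <- rnorm(n)
  X <- matrix(rnorm(n * 4), n, 4)
  ct <- make_contrast(rep(1:2, each = 9))
  z1 <- global_test(R, make_interaction(X, ct))$z_scores
  Xs <- sweep(X, 2, c(10, 0.1, 3, 1), "*")
  z2 <- global_test(R, make_interaction(Xs, ct))$z_scores
  expect_equal(z1, z2, tolerance = 1e-10)
})

test_that("degenerate all-zero residuals return the logged degenerate result", {
  gt <- global_test(rep(0, 12), matrix(rnorm(36), 12, 3),
                    null_design = matrix(1, 12, 1))
  expect_equal(gt$statistic, 0)
  expect_equal(gt$p_value, 1)
})
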