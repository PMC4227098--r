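test_that("identity permutation reproduces the observed column exactly", {
  sim <- tiny_sim(seed = 31)
  R <- t(vapply(seq_len(nrow(sim$Y)), function(i) {
    select_lambda(unclass(sim$Y)[i, ], t(unclass(sim$X))[, sim$windows[[i]]])$residuals
  }, numeric(ncol(sim$Y))))
  ct <- make_contrast(sim$groups)
  P <- suppressWarnings(
    permuted_pvalues(R, sim$X, sim$windows, ct, B = 3, seed = 5)
  )
  # same code path as column 1, identity ordering
  Xs <- t(unclass(sim$X))
  csq <- sum(ct$c^2)
  obs <- vapply(seq_len(nrow(R)), function(i) {
    dsim:::.perm_gt_p(R[i, ], Xs[, sim$windows[[i]], drop = FALSE], ct$c, csq)
  }, numeric(1))
  expect_identical(P$values[, 1], obs)
  # and matches the user-facing global_test to numerical precision
  gt <- global_test(R[2, ], make_interaction(Xs[, sim$windows[[2]]], ct))
  expect_equal(P$values[2, 1], gt$p_value, tolerance = 1e-12)
})

test_that("the permutation matrix is deterministic given the seed", {
  sim <- tiny_sim(seed = 32)
  R <- t(vapply(seq_len(nrow(sim$Y)), function(i) {
    select_lambda(unclass(sim$Y)[i, ], t(unclass(sim$X))[, sim$windows[[i]]])$residuals
  }, numeric(ncol(sim$Y))))
  ct <- make_contrast(sim$groups)
  P1 <- permuted_pvalues(R, sim$X, sim$windows, ct, B = 10, seed = 99)
  P2 <- permuted_pvalues(R, sim$X, sim$windows, ct, B = 10, seed = 99)
  expect_identical(P1$values, P2$values)
  P3 <- permuted_pvalues(R, sim$X, sim$windows, ct, B = 10, seed = 100)
  expect_false(identical(P3$values[, -1], P1$values[, -1]))
  expect_identical(P3$values[, 1], P1$values[, 1])  # observed column has no randomness
  expect_error(permuted_pvalues(R, sim$X, sim$windows, ct, B = 0), "at least 1")
})

test_that("empty windows produce a p = 1 row with a warning", {
  sim <- tiny_sim(seed = 33)
  w <- sim$windows
  w[[1]] <- character(0)
  R <- matrix(rnorm(nrow(sim$Y) * ncol(sim$Y)), nrow(sim$Y))
  ct <- make_contrast(sim$groups)
  expect_warning(P <- permuted_pvalues(R, sim$X, w, ct, B = 2, seed = 1),
                 "empty window")
  expect_true(all(P$values[1, ] == 1))
})

test_that("pooled permuted p-values are near-uniform under the null", {
  d <- sim_design(n_g1 = 15, n_g2 = 15, m = 20, cov_per_probe = 2,
                  aberration_regions = list(list(range = c(5, 10), shift = c(1, 1))))
  sim <- simulate_dataset(d, seed = 34)
  R <- t(vapply(seq_len(nrow(sim$Y)), function(i) {
    select_lambda(unclass(sim$Y)[i, ], t(unclass(sim$X))[, sim$windows[[i]]])$residuals
  }, numeric(ncol(sim$Y))))
  P <- permuted_pvalues(R, sim$X, sim$windows, make_contrast(sim$groups),
                        B = 200, seed = 34)
  pooled <- as.vector(P$values[, -1])
  ks <- suppressWarnings(stats::ks.test(pooled, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("empirical p-values count permutations at or below the observed value", {
  expect_equal(empirical_pvalue(c(0.001, 0.2, 0.5, 0.9)), 1 / 4)
  expect_equal(empirical_pvalue(c(1, 0.3, 0.6, 0.9, 0.2)), 1)
  expect_equal(empirical_pvalue(c(0.5, 0.2, 0.4, 0.6, 0.8)), 3 / 5)  # hand count
  expect_error(empirical_pvalue(0.5), "observed value plus permutations")
})

test_that("the hand-enumerated FDP adjustment instance reproduces exactly", {
  # m = 3, B = 2, confidence_alpha = 0.5: quantile index ceiling(0.5 * 2) = 1.
  # thresholds 0.01 / 0.50 / 0.90; per-permutation exceedance counts
  # (0,0), (1,1), (2,3) -> Vbar = (0, 1, 2) -> bounds (0, 1/2, 2/3),
  # running maximum leaves (0, 1/2, 2/3).
  P <- cbind(c(0.01, 0.50, 0.90), c(0.30, 0.60, 0.95), c(0.20, 0.70, 0.80))
  fdp <- meinshausen_adjust(P, confidence_alpha = 0.5, level = 0.25)
  expect_equal(fdp$adjusted, c(0, 1 / 2, 2 / 3), tolerance = 1e-14)
  expect_identical(fdp$selected, c(TRUE, FALSE, FALSE))
})

test_that("dominant observed signal adjusts to zero everywhere", {
  set.seed(35)
  m <- 12; B <- 20
  perm <- matrix(runif(m * B, min = 0.3), m, B)
  obs <- runif(m, max = 0.05)
  fdp <- meinshausen_adjust(cbind(obs, perm), confidence_alpha = 0.05, level = 0.1)
  expect_true(all(fdp$adjusted == 0))
  expect_true(all(fdp$selected))
})

test_that("adjusted values are monotone in the observed ordering and rank-based", {
  set.seed(36)
  m <- 15; B <- 40
  vals <- cbind(runif(m), matrix(runif(m * B), m, B))
  fdp <- meinshausen_adjust(vals, confidence_alpha = 0.1, level = 0.05)
  ord <- order(vals[, 1])
  expect_true(all(diff(fdp$adjusted[ord]) >= -1e-14))
  # invariant under a simultaneous strictly monotone transform of all entries
  fdp2 <- meinshausen_adjust(vals^3, confidence_alpha = 0.1, level = 0.05)
  expect_equal(fdp2$adjusted, fdp$adjusted, tolerance = 1e-14)
  expect_error(meinshausen_adjust(vals, confidence_alpha = 1.2), "confidence_alpha")
})

test_that("pure-null selection happens no more often than the confidence level", {
  hits <- 0
  reps <- 60
  for (r in seq_len(reps)) {
    set.seed(4000 + r)
    m <- 20; B <- 39
    vals <- matrix(runif(m * (B + 1)), m, B + 1)  # observed exchangeable with permuted
    fdp <- meinshausen_adjust(vals, confidence_alpha = 0.05, level = 0.01)
    hits <- hits + any(fdp$selected)
  }
  # binomial(60, <= 0.05): observing more than 9 would be wildly inconsistent
  expect_lte(hits, 9)
})
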