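# Shared fixture builders. Everything is generated in code; file-based
# fixtures are written to tempdir() on demand.

toy_matrix <- function(m = 3, n = 4, role = "dependent", seed = 1,
                       probe_prefix = "p", sample_prefix = "s") {
  vals <- with_test_seed(seed, matrix(round(rnorm(m * n), 4), m, n))
  omics_matrix(vals,
               probe_ids = paste0(probe_prefix, seq_len(m)),
               sample_ids = paste0(sample_prefix, seq_len(n)),
               role = role)
}

with_test_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

write_tsv_fixture <- function(df, name) {
  path <- file.path(tempdir(), name)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Small two-group dataset with a built-in differential window, for pipeline
# smoke tests: m dependent probes, 2 covariates each.
tiny_sim <- function(seed = 1, m = 6, n_g1 = 10, n_g2 = 10) {
  d <- sim_design(n_g1 = n_g1, n_g2 = n_g2, m = m, cov_per_probe = 2,
                  aberration_regions = list(list(range = c(2, 3), shift = c(1, 1))),
                  association_regions = list(list(range = c(2, 3), coef = c(1, -0.5))))
  simulate_dataset(d, seed = seed)
}

# Explicit ridge refit with per-training-fold centering: the independent
# oracle for the leave-one-out shortcut.
oracle_loo <- function(y, X, lam) {
  n <- length(y)
  vapply(seq_len(n), function(i) {
    tr <- setdiff(seq_len(n), i)
    xb <- colMeans(X[tr, , drop = FALSE])
    Xc <- sweep(X[tr, , drop = FALSE], 2, xb, "-")
    b <- solve(crossprod(Xc) + diag(lam, ncol(X)), crossprod(Xc, y[tr] - mean(y[tr])))
    mean(y[tr]) + drop((X[i, ] - xb) %*% b)
  }, numeric(1))
}

# Naive dense evaluation of the global-test quadratic form, independent of
# the package's linear-algebra path.
oracle_global_stat <- function(R, M, D) {
  n <- length(R)
  H0 <- D %*% solve(crossprod(D)) %*% t(D)
  A <- diag(n) - H0
  Rt <- A %*% R
  sigma2 <- drop(crossprod(Rt)) / (n - qr(D)$rank)
  drop(t(Rt) %*% M %*% t(M) %*% Rt) / (ncol(M) * sigma2)
}
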