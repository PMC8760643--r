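test_that("config validation enforces the thin-dictionary regime", {
  expect_error(dyndlt_config(m = 0), "positive integer")
  expect_error(dyndlt_config(m = 3, sparsity_s = 5), "1 <= s <= m")
  expect_error(dyndlt_config(m = 3, learn_penalty = 0), "learn_penalty")
  x <- expression_matrix(matrix(runif(200), nrow = 20))
  expect_error(learn_dictionary(x, dyndlt_config(m = 10)),
               "thin-dictionary violation")
  expect_error(learn_dictionary(x, dyndlt_config(m = 12)),
               "thin-dictionary violation")
})

test_that("expression_matrix validates entries and identifiers", {
  expect_error(expression_matrix(matrix(c(1, -2, 3, 4), 2)), "negative entry")
  expect_error(expression_matrix(matrix(c(1, NA, 3, 4), 2)), "non-finite")
  expect_error(expression_matrix(matrix(1:4, 2), gene_ids = c("a", "a")),
               "duplicate gene")
  expect_error(expression_matrix(matrix(1:6, nrow = 2, ncol = 3)),
               "transposed")
  x <- expression_matrix(matrix(1:6, nrow = 3, ncol = 2))
  expect_identical(dim(x), c(3L, 2L))
})

test_that("rank-1 positive data yields the generating direction as the atom", {
  set.seed(3)
  v <- abs(rnorm(50)) + 0.1
  X <- expression_matrix(v %o% runif(20, 0.5, 2))
  fit <- fit_dyndlt(X, dyndlt_config(m = 1, transform = "none"))
  d <- fit$dictionary[, 1]
  cosine <- sum(d * v) / sqrt(sum(d^2) * sum(v^2))
  expect_gte(cosine, 0.999)
  expect_lte(fit$reconstruction_error / sqrt(sum(X$values^2)), 1e-6)
})

test_that("learned dictionaries are non-negative with unit-norm atoms", {
  set.seed(4)
  X <- expression_matrix(matrix(abs(rnorm(100 * 40)), 100, 40))
  fit <- learn_dictionary(X, dyndlt_config(m = 3, transform = "none"))
  expect_identical(dim(fit$dictionary), c(100L, 3L))
  expect_gte(min(fit$dictionary), 0)
  expect_equal(colSums(fit$dictionary^2), rep(1, 3), tolerance = 1e-6)
})

test_that("coefficients with orthonormal dictionary equal the projection", {
  set.seed(5)
  Q <- qr.Q(qr(matrix(rnorm(50 * 4), 50, 4)))
  X <- matrix(rnorm(50 * 10), 50, 10)
  R <- compute_coefficients(X, Q, s = 4)
  expect_equal(R, crossprod(Q, X), tolerance = 1e-10)
})

test_that("a single atom codes a scaled copy of itself exactly", {
  d <- random_dictionary(30, 1)
  R <- compute_coefficients(3 * d, d, s = 1)
  expect_equal(drop(R), 3, tolerance = 1e-10)
})

test_that("full-sparsity OMP matches the normal-equations solution", {
  set.seed(6)
  D <- random_dictionary(50, 4)
  X <- matrix(rnorm(50 * 10), 50, 10)
  R <- compute_coefficients(X, D, s = 4)
  oracle <- solve(crossprod(D), crossprod(D, X))   # column-wise least squares
  expect_lt(max(abs(R - oracle)), 1e-8)
})

test_that("greedy OMP at s < m picks the dominant atom first", {
  D <- cbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  x <- matrix(c(0.1, 5, 0.2), ncol = 1)
  R <- compute_coefficients(x, D, s = 1)
  expect_equal(drop(R), c(0, 5, 0))
})

test_that("rank-deficient dictionaries fall back to minimum-norm coding", {
  d <- random_dictionary(20, 1)
  D <- cbind(d, d)          # exactly collinear atoms
  X <- matrix(rnorm(20 * 3), 20, 3)
  R <- compute_coefficients(X, D, s = 2)
  expect_true(isTRUE(attr(R, "rank_deficient")))
  expect_equal(D %*% R, d %*% crossprod(d, X), tolerance = 1e-8)
})

test_that("fits are bit-reproducible for a fixed seed", {
  ds <- tiny_sim(p = 120, n = 40, g_sim_size = 30, seed = 7)
  f1 <- fit_dyndlt(ds, dyndlt_config(m = 3, seed = 11))
  f2 <- fit_dyndlt(ds, dyndlt_config(m = 3, seed = 11))
  expect_identical(f1$dictionary, f2$dictionary)
  expect_identical(f1$coefficients, f2$coefficients)
})

test_that("reconstruction error trends downwards as m grows", {
  ds <- tiny_sim(p = 150, n = 48, g_sim_size = 50, noise_scale = 1, seed = 8)
  errs <- vapply(1:8, function(m) {
    fit_dyndlt(ds, dyndlt_config(m = m, seed = 0))$reconstruction_error
  }, numeric(1))
  violations <- sum(diff(errs) > 1e-8)
  expect_lte(violations, 1)   # allow rare non-convexity bumps
})

test_that("dynamic atoms recover the simulated pattern and genes on clean data", {
  ## well-expressed toy baseline: every pattern gene carries usable signal
  cfg <- sim_config(g_sim_size = 100, pattern = "increasing", noise_scale = 0,
                    p_total = 400, n = 300, mean_range = c(5, 50),
                    zero_fraction = 0.1, seed = 0)
  ds <- simulate_dataset(cfg)
  fit <- fit_dyndlt(ds, dyndlt_config(m = 3, seed = 0))
  overlaps <- vapply(1:3, function(j) {
    top <- marker_genes(fit$dictionary, j, k = 100)
    length(intersect(top$gene_index, ds$g_sim))
  }, numeric(1))
  expect_gte(max(overlaps), 90)
  cors <- apply(fit$coefficients, 1,
                function(r) abs(spearman_cor(r, seq_len(300))))
  expect_gte(max(cors), 0.95)
})

test_that("tidy and glance expose coefficients and diagnostics", {
  ds <- tiny_sim(p = 100, n = 32, g_sim_size = 20, seed = 1)
  fit <- fit_dyndlt(ds, dyndlt_config(m = 2, seed = 0))
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_identical(nrow(td), 2L * 32L)
  expect_setequal(unique(td$atom), 1:2)
  gl <- glance(fit)
  expect_identical(nrow(gl), 1L)
  expect_identical(gl$m, 2L)
  expect_s3_class(autoplot(fit), "ggplot")
})
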