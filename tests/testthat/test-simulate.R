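test_that("synthetic baseline has the configured shape and integer counts", {
  cfg <- sim_config(p_total = 800, n = 120, g_sim_size = 50, seed = 0)
  b <- make_baseline(cfg)
  expect_identical(dim(b), c(800L, 120L))
  expect_true(all(b$values >= 0))
  expect_true(all(b$values == round(b$values)))
})

test_that("zero-inflation tuning reaches the target zero fraction", {
  for (target in c(0.4, 0.5, 0.6)) {
    cfg <- sim_config(p_total = 1500, n = 200, g_sim_size = 50,
                      zero_fraction = target, seed = 1)
    z <- mean(make_baseline(cfg)$values == 0)
    expect_gte(z, target - 0.05)
    expect_lte(z, target + 0.05)
  }
})

test_that("file baselines are shuffled, filtered, and subsampled columns of the input", {
  set.seed(9)
  vals <- matrix(rpois(600 * 70, 5), 600, 70)
  x <- expression_matrix(vals)
  tf <- file.path(withr::local_tempdir(), "base.tsv")
  write_counts(x, tf)
  cfg <- sim_config(baseline = tf, p_total = 500, n = 50, g_sim_size = 20,
                    seed = 3)
  b <- make_baseline(cfg)
  expect_identical(dim(b), c(500L, 50L))
  incols <- apply(b$values, 2, function(col) {
    any(apply(vals, 2, function(orig) {
      all(col == orig[match(b$gene_ids, x$gene_ids)])
    }))
  })
  expect_true(all(incols))
  small <- sim_config(baseline = tf, p_total = 1000, n = 50, g_sim_size = 20)
  expect_error(make_baseline(small), "too small")
})

test_that("increasing pattern sorts each simulated gene over samples", {
  ds <- tiny_sim(p = 150, n = 40, g_sim_size = 60, noise_scale = 0, seed = 4)
  for (g in ds$g_sim) {
    expect_true(all(diff(ds$matrix$values[g, ]) >= 0))
  }
})

test_that("fluctuating pattern rises and falls over the four segments", {
  ds <- tiny_sim(p = 150, n = 40, g_sim_size = 60, pattern = "fluctuating",
                 noise_scale = 0, seed = 5)
  q <- 10L
  for (g in ds$g_sim) {
    v <- ds$matrix$values[g, ]
    expect_true(all(diff(v[1:q]) >= 0))
    expect_true(all(diff(v[(q + 1):(2 * q)]) <= 0))
    expect_true(all(diff(v[(2 * q + 1):(3 * q)]) >= 0))
    expect_true(all(diff(v[(3 * q + 1):(4 * q)]) <= 0))
  }
})

test_that("the two-subpattern dataset splits the simulated genes in half", {
  ds <- tiny_sim(p = 300, n = 40, g_sim_size = 100,
                 pattern = "half_increasing_half_fluctuating",
                 noise_scale = 0, seed = 6)
  expect_identical(sum(ds$pattern_labels == "increasing"), 50L)
  expect_identical(sum(ds$pattern_labels == "fluctuating"), 50L)
})

test_that("unperturbed simulated genes are permutations of their source genes", {
  cfg <- sim_config(p_total = 200, n = 40, g_sim_size = 80, seed = 7)
  b <- make_baseline(cfg)
  ds <- inject_pattern(b, cfg)
  for (i in seq_along(ds$g_sim)) {
    src <- ds$source_gene_map[[i]]
    expect_identical(sort(ds$matrix$values[ds$g_sim[i], ]),
                     sort(b$values[src, ]))
  }
})

test_that("noise perturbation respects non-negativity, integrality, and scale", {
  for (scale in c(1, 2)) {
    ## counts large enough that negative-noise clipping is essentially
    ## impossible, so the full empirical noise sd is observable
    cfg <- sim_config(p_total = 300, n = 500, g_sim_size = 40,
                      noise_scale = scale, mean_range = c(200, 400),
                      dispersion_range = c(150, 250), zero_fraction = 0,
                      seed = 8)
    b <- make_baseline(cfg)
    clean <- inject_pattern(b, cfg)
    pert <- perturb(clean, cfg)
    v <- pert$matrix$values
    expect_true(all(v >= 0))
    expect_true(all(v == round(v)))
    for (i in seq_along(clean$g_sim)) {
      g <- clean$g_sim[i]
      cl <- clean$matrix$values[g, ]
      s <- sd(cl)
      emp <- sd(pert$matrix$values[g, ] - cl)
      expect_gte(emp, 0.85 * sqrt(scale) * s)
      expect_lte(emp, 1.15 * sqrt(scale) * s)
    }
  }
})

test_that("a constant-valued gene is unchanged by noise", {
  cfg <- sim_config(p_total = 50, n = 20, g_sim_size = 5, noise_scale = 1,
                    seed = 9)
  b <- make_baseline(cfg)
  b$values[1:50, ] <- 7L         # all genes constant => sigma = 0
  ds <- perturb(inject_pattern(expression_matrix(b$values), cfg), cfg)
  expect_true(all(ds$matrix$values == 7L))
})

test_that("zero-count reinstatement conserves the source gene's zero count", {
  cfg <- sim_config(p_total = 250, n = 200, g_sim_size = 50, noise_scale = 2,
                    reinstate_zero_counts = TRUE, seed = 10)
  b <- make_baseline(cfg)
  ds <- perturb(inject_pattern(b, cfg), cfg)
  for (i in seq_along(ds$g_sim)) {
    src <- ds$source_gene_map[[i]]
    expect_identical(sum(ds$matrix$values[ds$g_sim[i], ] == 0),
                     sum(b$values[src, ] == 0))
  }
})

test_that("datasets are bit-identical across repeated generation", {
  cfg <- sim_config(p_total = 120, n = 40, g_sim_size = 30, noise_scale = 2,
                    reinstate_zero_counts = TRUE, seed = 11)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$matrix$values, d2$matrix$values)
  expect_identical(d1$g_sim, d2$g_sim)
})

test_that("representative vectors encode the subpatterns", {
  expect_identical(representative_vector("increasing", 4), as.numeric(1:4))
  fl <- representative_vector("fluctuating", 8)
  expect_identical(rank(fl, ties.method = "min"),
                   rank(c(1, 2, 2, 1, 1, 2, 2, 1), ties.method = "min"))
  incr <- representative_vector("increasing", 12)
  expect_equal(spearman_cor(incr, rev(incr)), -1)
  expect_error(representative_vector("fluctuating", 10), "divisible by 4")
  expect_error(representative_vector("wiggly", 8), "unknown subpattern")
})

test_that("the benchmark grid has the designed structure", {
  g <- build_grid()
  expect_identical(nrow(g), 120L)
  expect_identical(sum(g$n_eval_rows), 160L)
  expect_true(all(table(g$g_sim_size) == 12L))
  one <- build_grid(500L)
  restricted <- one[one$pattern == "increasing", ]
  expect_identical(nrow(restricted), 4L)   # 2 noise scales x 2 zero settings
})
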