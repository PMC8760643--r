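test_that("Spearman correlation handles the canonical cases", {
  expect_equal(spearman_cor(1:4, c(10, 20, 30, 40)), 1)
  expect_equal(spearman_cor(1:7, 7:1), -1)
  expect_error(spearman_cor(1:4, 1:5), "length mismatch")
  expect_error(spearman_cor(1:2, 1:2), "at least 3")
})

test_that("Spearman matches the rank-then-Pearson formula", {
  set.seed(24)
  for (rep in 1:8) {
    a <- rnorm(20)
    b <- if (rep %% 2) rnorm(20) else sample(1:5, 20, replace = TRUE)  # ties
    expect_equal(spearman_cor(a, b), spearman_oracle(a, b),
                 tolerance = 1e-12)
  }
})

test_that("constant vectors give a flagged zero correlation", {
  r <- spearman_cor(rep(1, 5), 1:5)
  expect_identical(as.numeric(r), 0)
  expect_true(attr(r, "undefined"))
})

test_that("score_dataset finds a perfectly matching coefficient row", {
  ds <- tiny_sim(p = 60, n = 24, g_sim_size = 10, noise_scale = 0, seed = 25)
  ref <- ds$representative_vectors$increasing
  emb <- rbind(rnorm(24), ref + 0.5)
  rep <- structure(list(method = "tsne", components = NULL, embedding = emb,
                        params = list(perplexity = 10), seed = 0L,
                        gene_ids = ds$matrix$gene_ids,
                        sample_ids = ds$matrix$sample_ids),
                   class = "low_dim_rep")
  rec <- score_dataset(rep, ds, "toy")
  expect_equal(rec$best_correlation, 1)
  expect_identical(rec$best_component, 2L)
  expect_true(is.na(rec$marker_overlap_pct))
})

test_that("marker overlap is 0 for disjoint top-k and 100 for perfect recovery", {
  ds <- tiny_sim(p = 60, n = 24, g_sim_size = 10, noise_scale = 0, seed = 26)
  comp <- matrix(0, 60, 1)
  comp[setdiff(seq_len(60), ds$g_sim)[1:10], 1] <- 1   # disjoint from g_sim
  rep <- structure(list(method = "dyndlt", components = comp,
                        embedding = rbind(rnorm(24)),
                        params = list(n_components = 1), seed = 0L,
                        gene_ids = ds$matrix$gene_ids,
                        sample_ids = ds$matrix$sample_ids),
                   class = "low_dim_rep")
  expect_equal(score_dataset(rep, ds, "d")$marker_overlap_pct, 0)
  comp2 <- matrix(0, 60, 1)
  comp2[ds$g_sim, 1] <- runif(10, 0.5, 1)
  rep$components <- comp2
  expect_equal(score_dataset(rep, ds, "d")$marker_overlap_pct, 100)
})

test_that("scores are invariant to component sign flips and reordering", {
  ds <- tiny_sim(p = 100, n = 32, g_sim_size = 30, noise_scale = 0, seed = 27)
  fit <- fit_dyndlt(ds, dyndlt_config(m = 3, seed = 0))
  rep0 <- structure(list(method = "dyndlt", components = fit$dictionary,
                         embedding = fit$coefficients,
                         params = list(n_components = 3), seed = 0L,
                         gene_ids = fit$gene_ids, sample_ids = fit$sample_ids),
                    class = "low_dim_rep")
  r0 <- score_dataset(rep0, ds, "d")
  rep1 <- rep0
  rep1$embedding <- rep1$embedding[c(3, 1, 2), ] * c(-1, 1, -1)
  rep1$components <- rep1$components[, c(3, 1, 2)] %*% diag(c(-1, 1, -1))
  r1 <- score_dataset(rep1, ds, "d")
  expect_equal(r1$best_correlation, r0$best_correlation)
  expect_equal(r1$marker_overlap_pct, r0$marker_overlap_pct)
})

test_that("two-subpattern datasets are scored once per subpattern", {
  ds <- tiny_sim(p = 150, n = 40, g_sim_size = 40,
                 pattern = "half_increasing_half_fluctuating",
                 noise_scale = 0, seed = 28)
  fit <- fit_dyndlt(ds, dyndlt_config(m = 4, seed = 0))
  rec <- score_dataset(fit, ds, "d")
  expect_identical(nrow(rec), 2L)
  expect_setequal(rec$subpattern, c("increasing", "fluctuating"))
})

test_that("experimental-time truth scores against plain time labels", {
  ds <- tiny_sim(p = 80, n = 24, g_sim_size = 30, noise_scale = 0, seed = 29)
  fit <- fit_dyndlt(ds, dyndlt_config(m = 2, seed = 0))
  rec <- score_dataset(fit, seq_len(24), "d")
  expect_identical(rec$subpattern, "none")
  expect_gte(rec$best_correlation, 0.9)
})

test_that("subtype merging weights correlations by subtype share", {
  times <- rep(1:10, 2)
  pt_perfect <- times
  one <- merge_subtype_correlations(pt_perfect, times, rep("a", 20))
  expect_equal(as.numeric(one), 1)
  ## two equal halves: one perfect, one with exactly zero rank correlation
  times4 <- rep(1:4, 2)
  pt <- c(1:4, c(3, 1, 4, 2))   # second block: Spearman 0 against 1:4
  two <- merge_subtype_correlations(pt, times4, rep(c("a", "b"), each = 4))
  expect_equal(as.numeric(two), 0.5, tolerance = 1e-9)
  ## three perfect subtypes of sizes 50/30/20
  times3 <- c(1:50, 1:30, 1:20)
  labs3 <- rep(c("a", "b", "c"), c(50, 30, 20))
  expect_equal(as.numeric(merge_subtype_correlations(times3, times3, labs3)), 1)
})

test_that("undersized subtypes are excluded and weights renormalised", {
  times <- c(1:10, 1, 2)
  labs <- rep(c("big", "tiny"), c(10, 2))
  r <- merge_subtype_correlations(times, times, labs)
  expect_equal(as.numeric(r), 1)
  expect_identical(attr(r, "excluded"), "tiny")
  expect_error(merge_subtype_correlations(1:2, 1:2, c("a", "b")), "at least 3")
})

test_that("grid summaries count thresholds correctly", {
  recs <- tibble::tibble(
    dataset_id = paste0("d", 1:6), method = "dyndlt",
    subpattern = "increasing",
    best_correlation = c(1, 0.95, 0.8, 0.99, 0.5, 0.91),
    marker_overlap_pct = c(100, 95, 50, 99, 10, 92),
    g_sim_size = c(100, 400, 400, 700, 200, 1000)
  )
  s <- summarise_grid(recs)
  expect_identical(s$overall$n_eval, 6L)
  expect_identical(s$overall$n_cor_gt_0.9, 4L)
  expect_identical(s$overall$n_overlap_gt_90, 4L)
  expect_identical(s$overall$n_joint_gt300, 3L)
  expect_equal(s$overall$median_correlation, median(recs$best_correlation))
  expect_identical(nrow(s$per_gsim), 5L)
})

test_that("win/tie/loss fractions sum to 100 and reflect the scores", {
  recs <- tibble::tibble(
    dataset_id = rep(paste0("d", 1:4), each = 2),
    subpattern = "increasing",
    method = rep(c("dyndlt", "ica"), 4),
    best_correlation = c(0.9, 0.8, 0.7, 0.7, 0.6, 0.9, 0.95, 0.5),
    marker_overlap_pct = NA_real_
  )
  w <- compare_win_rate(recs, "dyndlt", "ica")
  expect_equal(w$win_pct + w$tie_pct + w$loss_pct, 100)
  expect_equal(w$win_pct, 50)
  expect_equal(w$tie_pct, 25)
})
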