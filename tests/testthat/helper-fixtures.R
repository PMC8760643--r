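# Small programmatic fixtures shared across test files.

# Tiny negative-binomial count matrix with an increasing pattern injected
# into `g_sim_size` genes; defaults are desk-sized, not benchmark-sized.
tiny_sim <- function(p = 200L, n = 60L, g_sim_size = 100L,
                     pattern = "increasing", noise_scale = 0,
                     reinstate = FALSE, seed = 0L) {
  cfg <- sim_config(g_sim_size = g_sim_size, pattern = pattern,
                    noise_scale = noise_scale,
                    reinstate_zero_counts = reinstate,
                    p_total = p, n = n, seed = seed)
  simulate_dataset(cfg)
}

# Random non-negative matrix with unit-norm dictionary columns.
random_dictionary <- function(p, m, seed = 1L) {
  set.seed(seed)
  D <- matrix(abs(rnorm(p * m)), p, m)
  sweep(D, 2, sqrt(colSums(D^2)), "/")
}

# Rank-then-Pearson Spearman, written independently of spearman_cor().
spearman_oracle <- function(a, b) {
  ra <- rank(a, ties.method = "average")
  rb <- rank(b, ties.method = "average")
  sum((ra - mean(ra)) * (rb - mean(rb))) /
    sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
}

# Exhaustive minimum-spanning-tree weight via Prufer enumeration of all
# labelled trees on n nodes (n <= 7 keeps this to at most 16807 trees).
brute_force_mst_weight <- function(dm) {
  n <- nrow(dm)
  stopifnot(n >= 2L, n <= 7L)
  if (n == 2L) return(dm[1L, 2L])
  decode_prufer <- function(pr) {
    n <- length(pr) + 2L
    degree <- rep(1L, n)
    for (v in pr) degree[v] <- degree[v] + 1L
    edges <- matrix(0L, n - 1L, 2L)
    k <- 1L
    for (v in pr) {
      leaf <- which(degree == 1L)[1L]
      edges[k, ] <- c(leaf, v); k <- k + 1L
      degree[leaf] <- degree[leaf] - 1L
      degree[v] <- degree[v] - 1L
    }
    last <- which(degree == 1L)
    edges[k, ] <- last
    edges
  }
  seqs <- as.matrix(expand.grid(rep(list(seq_len(n)), n - 2L)))
  best <- Inf
  for (r in seq_len(nrow(seqs))) {
    ed <- decode_prufer(seqs[r, ])
    w <- sum(dm[ed])
    if (w < best) best <- w
  }
  best
}

# All-pairs maximum path weight in a tree, by walking from every node.
brute_force_diameter <- function(edges, n) {
  adj <- vector("list", n)
  for (k in seq_len(nrow(edges))) {
    i <- edges$from[k]; j <- edges$to[k]; w <- edges$weight[k]
    adj[[i]] <- rbind(adj[[i]], c(j, w))
    adj[[j]] <- rbind(adj[[j]], c(i, w))
  }
  walk <- function(root) {
    dist <- rep(NA_real_, n); dist[root] <- 0; stack <- root
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      nb <- adj[[v]]
      if (is.null(nb)) next
      for (r in seq_len(nrow(nb))) {
        u <- nb[r, 1L]
        if (is.na(dist[u])) { dist[u] <- dist[v] + nb[r, 2L]; stack <- c(stack, u) }
      }
    }
    dist
  }
  max(vapply(seq_len(n), function(v) max(walk(v)), numeric(1)))
}
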