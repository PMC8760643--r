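#' Simulation configuration
#'
#' Describes one simulated dataset: a count baseline (synthetic
#' negative-binomial draws or a user-supplied real count matrix), the number
#' of genes that receive a dynamic pattern, the pattern itself, and the
#' perturbations applied afterwards. Samples are implicitly ordered by
#' simulated time (column order).
#'
#' The synthetic baseline emulates a shuffled single-cell count matrix:
#' gene-specific negative-binomial draws with means log-uniform on
#' `mean_range`, dispersions uniform on `dispersion_range`, and additional
#' zero-inflation tuned so that the realised zero fraction approaches
#' `zero_fraction`.
#'
#' @param g_sim_size Number of simulated (pattern-carrying) genes.
#' @param pattern One of `"increasing"`, `"fluctuating"`,
#'   `"half_increasing_half_fluctuating"`.
#' @param noise_scale Variance multiplier for the noise perturbation: 1 for
#'   the plain noise setting, 2 for the high-noise setting. `0` disables
#'   noise.
#' @param reinstate_zero_counts Restore each simulated gene's zero count to
#'   that of its source gene after the noise perturbation.
#' @param baseline Either `"synthetic"` or a path to a dense count matrix
#'   readable by [read_counts()].
#' @param p_total,n Baseline dimensions (genes x samples).
#' @param mean_range,dispersion_range,zero_fraction Synthetic-baseline
#'   parameters (see Details).
#' @param seed Random seed; the full dataset is bit-reproducible given the
#'   configuration and seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(g_sim_size = 500L,
                       pattern = c("increasing", "fluctuating",
                                   "half_increasing_half_fluctuating"),
                       noise_scale = 1,
                       reinstate_zero_counts = FALSE,
                       baseline = "synthetic",
                       p_total = 10000L,
                       n = 500L,
                       mean_range = c(0.1, 50),
                       dispersion_range = c(0.5, 3),
                       zero_fraction = 0.5,
                       seed = 0L) {
  pattern <- match.arg(pattern)
  g_sim_size <- as.integer(g_sim_size)
  p_total <- as.integer(p_total)
  n <- as.integer(n)
  if (g_sim_size < 1L || g_sim_size > p_total) {
    stop("`g_sim_size` must be in [1, p_total]", call. = FALSE)
  }
  if (pattern != "increasing" && n %% 4L != 0L) {
    stop("the fluctuating pattern needs `n` divisible by 4 (four equal segments)",
         call. = FALSE)
  }
  if (pattern == "half_increasing_half_fluctuating" && g_sim_size %% 2L != 0L) {
    stop("`g_sim_size` must be even for the two-subpattern dataset", call. = FALSE)
  }
  if (!noise_scale %in% c(0, 1, 2)) {
    warning("`noise_scale` outside the benchmark settings {0, 1, 2}")
  }
  structure(
    list(g_sim_size = g_sim_size, pattern = pattern, noise_scale = noise_scale,
         reinstate_zero_counts = isTRUE(reinstate_zero_counts),
         baseline = baseline, p_total = p_total, n = n,
         mean_range = mean_range, dispersion_range = dispersion_range,
         zero_fraction = zero_fraction, seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Generate (or load) the simulation baseline
#'
#' Synthetic mode draws a `p_total x n` integer matrix of gene-wise
#' negative-binomial counts with gene-specific means and dispersions, then
#' zero-inflates uniformly to reach the configured zero fraction. File mode
#' reads a count matrix, shuffles its columns (to destroy any time ordering),
#' applies a light outlier rule (genes expressed in < 1% of samples dropped;
#' samples whose library size is more than 3 median-absolute-deviations from
#' the median dropped), and subsamples to `p_total x n`.
#'
#' @param cfg A [sim_config()].
#' @return An `expression_matrix`.
#' @export
make_baseline <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  if (identical(cfg$baseline, "synthetic")) {
    p <- cfg$p_total; n <- cfg$n
    mu <- exp(stats::runif(p, log(cfg$mean_range[1]), log(cfg$mean_range[2])))
    size <- stats::runif(p, cfg$dispersion_range[1], cfg$dispersion_range[2])
    vals <- matrix(stats::rnbinom(p * n, mu = rep(mu, n), size = rep(size, n)),
                   nrow = p, ncol = n)
    z0 <- mean(vals == 0)
    if (z0 < cfg$zero_fraction) {
      ## inflate uniformly: P(zeroed) chosen so the overall fraction hits target
      pi0 <- (cfg$zero_fraction - z0) / (1 - z0)
      vals[stats::runif(p * n) < pi0] <- 0L
    }
    storage.mode(vals) <- "integer"
    return(expression_matrix(vals, allow_wide = TRUE))
  }
  x <- read_counts(cfg$baseline)
  vals <- x$values[, sample.int(ncol(x$values)), drop = FALSE]  # shuffle samples
  expressed <- rowMeans(vals > 0) >= 0.01
  vals <- vals[expressed, , drop = FALSE]
  gene_ids <- x$gene_ids[expressed]
  libs <- colSums(vals)
  keep_s <- abs(libs - stats::median(libs)) <= 3 * stats::mad(libs) | stats::mad(libs) == 0
  vals <- vals[, keep_s, drop = FALSE]
  if (nrow(vals) < cfg$p_total || ncol(vals) < cfg$n) {
    stop(sprintf("baseline too small after outlier removal: %d x %d < %d x %d",
                 nrow(vals), ncol(vals), cfg$p_total, cfg$n), call. = FALSE)
  }
  gi <- sort(sample.int(nrow(vals), cfg$p_total))
  si <- sort(sample.int(ncol(vals), cfg$n))
  expression_matrix(vals[gi, si, drop = FALSE], gene_ids = gene_ids[gi],
                    allow_wide = TRUE)
}

sort_fluctuating <- function(v) {
  n <- length(v)
  q <- n %/% 4L
  ## random equal-size partition of the value multiset into the 4 segments
  grp <- sample(rep(1:4, each = q))
  out <- numeric(n)
  idx <- split(seq_len(n), rep(1:4, each = q))
  for (s in 1:4) {
    vv <- sort(v[grp == s])
    if (s %% 2L == 0L) vv <- rev(vv)   # segments 2 and 4 decrease
    out[idx[[s]]] <- vv
  }
  out
}

#' Inject a dynamic pattern into a baseline
#'
#' Selects `g_sim_size` gene rows at random; each simulated gene's values
#' are replaced by a reordering of the value multiset of a randomly drawn
#' baseline source gene. `"increasing"` sorts the values ascending across
#' samples; `"fluctuating"` randomly partitions them into four equal
#' segments sorted ascending/descending/ascending/descending; the
#' two-subpattern dataset gives half of the simulated genes the increasing
#' and half the fluctuating treatment. Non-simulated genes are untouched.
#'
#' @param baseline An `expression_matrix` from [make_baseline()].
#' @param cfg A [sim_config()].
#' @return A `sim_dataset`: list with `matrix`, `g_sim`, `pattern_labels`,
#'   `representative_vectors`, `source_gene_map`, `perturbation`, `config`.
#' @export
inject_pattern <- function(baseline, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  baseline <- as_matrix_input(baseline)
  vals <- baseline$values
  p <- nrow(vals); n <- ncol(vals)
  set.seed(cfg$seed + 1L)
  g_sim <- sort(sample.int(p, cfg$g_sim_size))
  src <- sample.int(p, cfg$g_sim_size, replace = TRUE)
  labels <- switch(
    cfg$pattern,
    increasing = rep("increasing", cfg$g_sim_size),
    fluctuating = rep("fluctuating", cfg$g_sim_size),
    half_increasing_half_fluctuating =
      rep(c("increasing", "fluctuating"), each = cfg$g_sim_size %/% 2L)
  )
  for (i in seq_along(g_sim)) {
    v <- baseline$values[src[i], ]   # always the untouched baseline gene
    vals[g_sim[i], ] <- if (labels[i] == "increasing") sort(v) else sort_fluctuating(v)
  }
  reps <- lapply(unique(labels), representative_vector, n = n)
  names(reps) <- unique(labels)
  structure(
    list(matrix = expression_matrix(vals, gene_ids = baseline$gene_ids,
                                    sample_ids = baseline$sample_ids,
                                    allow_wide = TRUE),
         g_sim = g_sim,
         pattern_labels = labels,
         representative_vectors = reps,
         source_gene_map = stats::setNames(src, g_sim),
         perturbation = list(noise_scale = 0, reinstate_zero_counts = FALSE),
         config = cfg),
    class = "sim_dataset"
  )
}

#' Perturb a simulated dataset
#'
#' Adds gene-wise Gaussian noise with variance `noise_scale * sigma^2` of
#' the gene's clean (post-pattern) values, rounds to integers, and restores
#' entries that became negative to their pre-noise values. If zero-count
#' reinstatement is enabled, the gene's zero count is then matched exactly
#' to the zero count of its source gene: missing zeros are placed at
#' randomly chosen non-zero positions; surplus zeros (positions where the
#' noise itself rounded to zero) are resolved by restoring randomly chosen
#' zero positions with a positive pre-noise value.
#'
#' @param ds A `sim_dataset` from [inject_pattern()].
#' @param cfg A [sim_config()] (defaults to the dataset's own config).
#' @return The perturbed `sim_dataset`.
#' @export
perturb <- function(ds, cfg = ds$config) {
  stopifnot(inherits(ds, "sim_dataset"))
  vals <- ds$matrix$values
  set.seed(cfg$seed + 2L)
  n <- ncol(vals)
  for (i in seq_along(ds$g_sim)) {
    g <- ds$g_sim[i]
    clean <- vals[g, ]
    if (cfg$noise_scale > 0) {
      s <- stats::sd(clean)
      if (s > 0) {
        noisy <- round(clean + stats::rnorm(n, 0, sqrt(cfg$noise_scale) * s))
        vals[g, ] <- ifelse(noisy < 0, clean, noisy)
      }
    }
    if (cfg$reinstate_zero_counts) {
      target <- sum(clean == 0)   # clean row is a permutation of the source gene
      row <- vals[g, ]
      cur <- sum(row == 0)
      if (cur < target) {
        nz <- which(row != 0)
        row[nz[sample.int(length(nz), target - cur)]] <- 0
      } else if (cur > target) {
        restorable <- which(row == 0 & clean > 0)
        sel <- restorable[sample.int(length(restorable), cur - target)]
        row[sel] <- clean[sel]   # restore each chosen position's pre-noise value
      }
      vals[g, ] <- row
    }
  }
  storage.mode(vals) <- "integer"
  ds$matrix <- expression_matrix(vals, gene_ids = ds$matrix$gene_ids,
                                 sample_ids = ds$matrix$sample_ids,
                                 allow_wide = TRUE)
  ds$perturbation <- list(noise_scale = cfg$noise_scale,
                          reinstate_zero_counts = cfg$reinstate_zero_counts)
  ds
}

#' Representative rank vector for a simulation subpattern
#'
#' Ground-truth per-sample sequence encoding a subpattern, used as the
#' reference for Spearman correlations. `"increasing"` is simply `1..n`;
#' `"fluctuating"` is a triangle wave over the four segments
#' (`1..n/4`, `n/4..1`, `1..n/4`, `n/4..1`).
#'
#' @param pattern `"increasing"` or `"fluctuating"`.
#' @param n Number of samples (divisible by 4 for `"fluctuating"`).
#' @return Numeric vector of length `n`.
#' @examples
#' representative_vector("fluctuating", 8)
#' @export
representative_vector <- function(pattern, n) {
  if (pattern == "increasing") return(as.numeric(seq_len(n)))
  if (pattern == "fluctuating") {
    if (n %% 4L != 0L) stop("`n` must be divisible by 4", call. = FALSE)
    q <- n %/% 4L
    return(as.numeric(c(seq_len(q), rev(seq_len(q)), seq_len(q), rev(seq_len(q)))))
  }
  stop(sprintf("unknown subpattern label '%s'", pattern), call. = FALSE)
}

#' Simulate one benchmark dataset
#'
#' Convenience wrapper: baseline (or a pre-built one), pattern injection,
#' perturbation.
#'
#' @param cfg A [sim_config()].
#' @param baseline Optional pre-built baseline `expression_matrix`; when
#'   several datasets share one baseline this avoids regenerating it.
#' @return A `sim_dataset`.
#' @export
simulate_dataset <- function(cfg, baseline = NULL) {
  if (is.null(baseline)) baseline <- make_baseline(cfg)
  perturb(inject_pattern(baseline, cfg), cfg)
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("<sim_dataset> %d x %d, pattern '%s', |g_sim| = %d\n",
              nrow(x$matrix$values), ncol(x$matrix$values),
              x$config$pattern, length(x$g_sim)))
  cat(sprintf("  perturbation: noise_scale = %g, zero-count reinstatement %s\n",
              x$perturbation$noise_scale,
              if (x$perturbation$reinstate_zero_counts) "on" else "off"))
  invisible(x)
}

#' Benchmark grid manifest
#'
#' One row per simulated dataset of the benchmark: 3 patterns x 2 noise
#' scales x zero-count reinstatement on/off = 12 datasets per `|g_sim|`
#' value. Two-subpattern datasets are evaluated once per subpattern, so each
#' contributes two evaluation rows.
#'
#' @param g_sim_values Vector of `|g_sim|` values (default `seq(100, 1000, 100)`).
#' @param seed Run seed; per-dataset seeds are derived deterministically.
#' @return A tibble with one row per dataset: `dataset_id`, `g_sim_size`,
#'   `pattern`, `noise_scale`, `reinstate_zero_counts`, `n_eval_rows`, `seed`.
#' @examples
#' nrow(build_grid())         # 120 datasets
#' sum(build_grid()$n_eval_rows)  # 160 evaluation rows
#' @export
build_grid <- function(g_sim_values = seq(100L, 1000L, by = 100L), seed = 0L) {
  grid <- tidyr::expand_grid(
    g_sim_size = as.integer(g_sim_values),
    pattern = c("increasing", "fluctuating", "half_increasing_half_fluctuating"),
    noise_scale = c(1, 2),
    reinstate_zero_counts = c(FALSE, TRUE)
  )
  set.seed(seed)
  grid <- dplyr::mutate(
    grid,
    dataset_id = sprintf("gsim%04d_%s_noise%g_%s",
                         .data$g_sim_size,
                         c(increasing = "incr", fluctuating = "fluct",
                           half_increasing_half_fluctuating = "incrfluct")[.data$pattern],
                         .data$noise_scale,
                         ifelse(.data$reinstate_zero_counts, "zeros", "nozeros")),
    n_eval_rows = ifelse(.data$pattern == "half_increasing_half_fluctuating", 2L, 1L),
    seed = sample.int(.Machine$integer.max %/% 2L, dplyr::n())
  )
  dplyr::relocate(grid, "dataset_id")
}
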