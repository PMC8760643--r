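#' Spearman correlation with a defined constant-vector convention
#'
#' Pearson correlation of tie-averaged ranks. If either vector is constant
#' the correlation is undefined; this returns 0 with attribute
#' `undefined = TRUE` so that uninformative components score worst instead
#' of propagating `NA` through a benchmark.
#'
#' @param a,b Numeric vectors of equal length (>= 3).
#' @return Correlation in `[-1, 1]`.
#' @examples
#' spearman_cor(1:4, c(10, 20, 30, 40))
#' @export
spearman_cor <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch", call. = FALSE)
  if (length(a) < 3L) stop("need at least 3 observations", call. = FALSE)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    return(structure(0, undefined = TRUE))
  }
  stats::cor(a, b, method = "spearman")
}

#' Score a representation against simulated ground truth
#'
#' For each subpattern present in the dataset: the Spearman correlation of
#' every embedding component with the subpattern's representative rank
#' vector, the best component by absolute correlation (ties to the lowest
#' index), and -- for linear methods -- the marker-overlap percentage, i.e.
#' the share of the subpattern's simulated genes among the top-`k` entries
#' of the best-overlapping component (`k` = size of that subpattern's gene
#' set, so `|g_sim|/2` per subpattern of the two-subpattern datasets).
#' Absolute entry values are used so that sign-indefinite methods (ICA,
#' PCA) are scored on the same footing.
#'
#' @param rep A `low_dim_rep` (or `dyndlt_model`).
#' @param truth A `sim_dataset`, or a numeric vector of per-sample times.
#' @param dataset_id Optional identifier copied into the output.
#' @return A tibble (class `evaluation_record`) with one row per subpattern:
#'   `dataset_id`, `method`, `param`, `subpattern`, `best_correlation`,
#'   `best_component`, `marker_overlap_pct`, `per_component_correlation`
#'   (list column).
#' @export
score_dataset <- function(rep, truth, dataset_id = NA_character_) {
  if (inherits(rep, "dyndlt_model")) {
    rep <- structure(
      list(method = "dyndlt", components = rep$dictionary,
           embedding = rep$coefficients,
           params = list(n_components = rep$config$m),
           seed = rep$config$seed, gene_ids = rep$gene_ids,
           sample_ids = rep$sample_ids),
      class = "low_dim_rep")
  }
  stopifnot(inherits(rep, "low_dim_rep"))
  E <- rep$embedding
  n <- ncol(E)
  param <- unlist(rep$params)[1L]
  if (inherits(truth, "sim_dataset")) {
    if (ncol(truth$matrix$values) != n) {
      stop("truth and representation have different sample counts", call. = FALSE)
    }
    subpatterns <- unique(truth$pattern_labels)
    rows <- lapply(subpatterns, function(sp) {
      ref <- truth$representative_vectors[[sp]]
      cors <- apply(E, 1L, function(r) spearman_cor(r, ref))
      best <- which.max(abs(cors))
      genes_sp <- truth$g_sim[truth$pattern_labels == sp]
      overlap <- NA_real_
      if (!is.null(rep$components)) {
        k <- length(genes_sp)
        overlap <- max(vapply(seq_len(ncol(rep$components)), function(j) {
          top <- marker_genes(rep$components, j, k = k, use_absolute = TRUE)
          100 * length(intersect(top$gene_index, genes_sp)) / k
        }, numeric(1)))
      }
      tibble::tibble(
        dataset_id = dataset_id, method = rep$method, param = param,
        subpattern = sp,
        best_correlation = abs(cors[best]),
        best_component = as.integer(best),
        marker_overlap_pct = overlap,
        per_component_correlation = list(unname(cors))
      )
    })
    out <- dplyr::bind_rows(rows)
  } else {
    if (length(truth) != n) {
      stop("truth and representation have different sample counts", call. = FALSE)
    }
    cors <- apply(E, 1L, function(r) spearman_cor(r, truth))
    best <- which.max(abs(cors))
    out <- tibble::tibble(
      dataset_id = dataset_id, method = rep$method, param = param,
      subpattern = "none",
      best_correlation = abs(cors[best]),
      best_component = as.integer(best),
      marker_overlap_pct = NA_real_,
      per_component_correlation = list(unname(cors))
    )
  }
  class(out) <- c("evaluation_record", class(out))
  out
}

#' Subtype-weighted pseudotime correlation
#'
#' For datasets whose samples split into subtypes (branching timelines),
#' the per-subtype absolute Spearman correlations between pseudotime and
#' experimental time are scaled by the fraction of samples in each subtype
#' and summed. Subtypes with fewer than 3 samples are excluded and the
#' weights renormalised (recorded in the `excluded` attribute).
#'
#' @param pseudotime Per-sample pseudotime values.
#' @param times Per-sample experimental times.
#' @param subtypes Per-sample subtype labels.
#' @return Weighted correlation in `[0, 1]`.
#' @export
merge_subtype_correlations <- function(pseudotime, times, subtypes) {
  stopifnot(length(pseudotime) == length(times),
            length(times) == length(subtypes))
  groups <- split(seq_along(times), subtypes)
  sizes <- lengths(groups)
  usable <- sizes >= 3L
  if (!any(usable)) stop("no subtype has at least 3 samples", call. = FALSE)
  w <- sizes[usable] / sum(sizes[usable])
  cors <- vapply(groups[usable], function(idx) {
    abs(spearman_cor(pseudotime[idx], times[idx]))
  }, numeric(1))
  structure(sum(w * cors), excluded = names(groups)[!usable])
}

#' Summarise a grid of evaluation records
#'
#' Benchmark-level statistics over evaluation rows: counts of rows whose
#' best correlation exceeds 0.9 and whose marker overlap exceeds 90%, mean
#' and median correlation, joint successes among rows with `|g_sim| > 300`,
#' and a per-`|g_sim|` breakdown.
#'
#' @param records Bound rows of [score_dataset()] output, with a
#'   `g_sim_size` column joined in (as produced by [benchmark_datasets()]).
#' @return A list with elements `overall` (one-row tibble), `per_gsim`
#'   (tibble), and `records` (the input).
#' @export
summarise_grid <- function(records) {
  has_gsim <- "g_sim_size" %in% names(records)
  overall <- tibble::tibble(
    n_eval = nrow(records),
    n_cor_gt_0.9 = sum(records$best_correlation > 0.9),
    mean_correlation = mean(records$best_correlation),
    median_correlation = stats::median(records$best_correlation),
    n_overlap_gt_90 = sum(records$marker_overlap_pct > 90, na.rm = TRUE),
    n_joint_gt300 = if (has_gsim) {
      sum(records$best_correlation > 0.9 & records$marker_overlap_pct > 90 &
            records$g_sim_size > 300, na.rm = TRUE)
    } else NA_integer_,
    n_gt300 = if (has_gsim) sum(records$g_sim_size > 300) else NA_integer_
  )
  per_gsim <- if (has_gsim) {
    dplyr::summarise(
      dplyr::group_by(records, .data$g_sim_size),
      n = dplyr::n(),
      mean_correlation = mean(.data$best_correlation),
      median_overlap = stats::median(.data$marker_overlap_pct, na.rm = TRUE),
      .groups = "drop")
  } else tibble::tibble()
  list(overall = overall, per_gsim = per_gsim, records = records)
}

#' Head-to-head comparison of two methods
#'
#' Win/tie/loss fractions (in percent) of method `a` against method `b`
#' over matched evaluation rows (same dataset and subpattern, best
#' parameter per method).
#'
#' @param records Evaluation records for at least the two methods.
#' @param a,b Method tags.
#' @param metric Column to compare (default `best_correlation`).
#' @return One-row tibble with `win_pct`, `tie_pct`, `loss_pct`.
#' @export
compare_win_rate <- function(records, a, b, metric = "best_correlation") {
  best <- records |>
    dplyr::group_by(.data$dataset_id, .data$subpattern, .data$method) |>
    dplyr::summarise(score = max(.data[[metric]], na.rm = TRUE), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "method", values_from = "score")
  if (!all(c(a, b) %in% names(best))) {
    stop("records do not contain both methods", call. = FALSE)
  }
  d <- best[[a]] - best[[b]]
  tibble::tibble(
    method_a = a, method_b = b, n = length(d),
    win_pct = 100 * mean(d > 0),
    tie_pct = 100 * mean(d == 0),
    loss_pct = 100 * mean(d < 0)
  )
}

#' Run the simulation benchmark over a dataset grid
#'
#' Materialises each dataset of `grid` (sharing one baseline), runs each
#' method over its parameter grid, and scores every fit. This is the
#' engine behind both the reduced (desk-scale) and the full benchmark.
#'
#' @param grid Manifest tibble from [build_grid()] (possibly filtered).
#' @param methods Methods to run (default `"dyndlt"`).
#' @param baseline_cfg A [sim_config()] supplying baseline parameters; its
#'   `seed` fixes the shared baseline.
#' @param params Optional integer vector restricting each linear method's
#'   component grid (default: the full [parameter_grid()]).
#' @param transform Expression transform for all methods.
#' @param verbose Print one line per dataset.
#' @return A tibble of evaluation records with grid columns joined in.
#' @export
benchmark_datasets <- function(grid, methods = "dyndlt",
                               baseline_cfg = sim_config(),
                               params = NULL, transform = "log1p",
                               verbose = FALSE) {
  baseline <- make_baseline(baseline_cfg)
  out <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cfg <- sim_config(
      g_sim_size = grid$g_sim_size[i], pattern = grid$pattern[i],
      noise_scale = grid$noise_scale[i],
      reinstate_zero_counts = grid$reinstate_zero_counts[i],
      p_total = baseline_cfg$p_total, n = baseline_cfg$n,
      mean_range = baseline_cfg$mean_range,
      dispersion_range = baseline_cfg$dispersion_range,
      zero_fraction = baseline_cfg$zero_fraction,
      seed = grid$seed[i])
    ds <- perturb(inject_pattern(baseline, cfg), cfg)
    recs <- list()
    for (method in methods) {
      pg <- parameter_grid(method)$param
      if (!is.null(params) && method %in% c("dyndlt", "ica", "nmf", "pca")) {
        pg <- intersect(pg, params)
      }
      for (pv in pg) {
        rec <- tryCatch(
          score_dataset(run_method(ds, method, pv, seed = cfg$seed,
                                   transform = transform),
                        ds, dataset_id = grid$dataset_id[i]),
          error = function(e) NULL)
        recs <- c(recs, list(rec))
      }
    }
    recs <- dplyr::bind_rows(recs)
    out[[i]] <- dplyr::left_join(
      recs, dplyr::select(grid, "dataset_id", "g_sim_size", "pattern",
                          "noise_scale", "reinstate_zero_counts"),
      by = "dataset_id")
    if (verbose) {
      message(sprintf("[%d/%d] %s: best cor %.3f",
                      i, nrow(grid), grid$dataset_id[i],
                      max(out[[i]]$best_correlation)))
    }
  }
  dplyr::bind_rows(out)
}

#' Best-per-dataset reduction of benchmark records
#'
#' Collapses records to one row per (dataset, subpattern, method): the
#' maximum best-atom correlation and maximum marker overlap over the
#' parameter grid, mirroring "the best performing component among all
#' components among all evaluated dimensionalities".
#'
#' @param records Output of [benchmark_datasets()].
#' @return A tibble with `best_correlation` and `marker_overlap_pct`
#'   maximised over the parameter grid.
#' @export
best_per_dataset <- function(records) {
  records |>
    dplyr::group_by(.data$dataset_id, .data$subpattern, .data$method,
                    .data$g_sim_size, .data$pattern, .data$noise_scale,
                    .data$reinstate_zero_counts) |>
    dplyr::summarise(
      best_correlation = max(.data$best_correlation),
      marker_overlap_pct = if (all(is.na(.data$marker_overlap_pct))) NA_real_
        else max(.data$marker_overlap_pct, na.rm = TRUE),
      .groups = "drop")
}

#' Plot benchmark results against the pattern strength
#'
#' Best correlation (or marker overlap) per dataset/subpattern against
#' `|g_sim|`, one line per pattern/perturbation combination, faceted by
#' method.
#'
#' @param records Output of [benchmark_datasets()].
#' @param metric `"best_correlation"` or `"marker_overlap_pct"`.
#' @return A ggplot object.
#' @export
plot_benchmark <- function(records, metric = c("best_correlation",
                                               "marker_overlap_pct")) {
  metric <- match.arg(metric)
  d <- best_per_dataset(records)
  d$setting <- paste0(d$pattern, "/", d$subpattern,
                      " noise", d$noise_scale,
                      ifelse(d$reinstate_zero_counts, "+zeros", ""))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$g_sim_size, y = .data[[metric]],
                                  colour = .data$setting)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~method) +
    ggplot2::labs(x = "|g_sim| (genes carrying the simulated pattern)",
                  y = metric) +
    ggplot2::theme_minimal()
}
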