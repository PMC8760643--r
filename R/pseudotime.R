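#' Pseudotime from a single coefficient row
#'
#' The order of the coefficients of one atom across samples is used as the
#' pseudotemporal ordering: ranks (average-rank ties) of `R[atom, ]`. A
#' constant row carries no ordering information and is flagged.
#'
#' @param R Coefficient matrix (`m x n`), or a `dyndlt_model`.
#' @param atom Atom (row) index, `1..m`.
#' @param sample_ids Optional sample identifiers.
#' @return A tibble of class `pseudotime_result` with columns `sample_id`,
#'   `coefficient`, `pseudotime_rank`; attributes `source`, `orientation`,
#'   `uninformative`.
#' @examples
#' pseudotime_from_atom(rbind(c(0.1, 0.5, 0.3)), 1)
#' @export
pseudotime_from_atom <- function(R, atom, sample_ids = NULL) {
  if (inherits(R, "dyndlt_model")) {
    sample_ids <- sample_ids %||% R$sample_ids
    R <- R$coefficients
  }
  if (atom < 1L || atom > nrow(R)) {
    stop(sprintf("`atom` must be in 1..%d", nrow(R)), call. = FALSE)
  }
  v <- R[atom, ]
  n <- length(v)
  sample_ids <- sample_ids %||% paste0("sample_", seq_len(n))
  uninformative <- stats::sd(v) == 0
  if (uninformative) {
    warning(sprintf("atom %d has a constant coefficient row; pseudotime is uninformative", atom))
  }
  out <- tibble::tibble(
    sample_id = sample_ids,
    coefficient = v,
    pseudotime_rank = rank(v, ties.method = "average")
  )
  structure(out, class = c("pseudotime_result", class(out)),
            source = paste0("atom_", atom), orientation = 1L,
            uninformative = uninformative)
}

#' Select the component best correlated with a reference ordering
#'
#' Supervised/evaluation setting only: returns the component (row of the
#' embedding) with the largest absolute Spearman correlation against
#' per-sample reference values; ties go to the lowest index. Without a
#' reference the choice of the dynamic atom is an open problem -- use the
#' MST polygonal-reconstruction mode ([trajectory_pseudotime()]) to exploit
#' the whole representation instead.
#'
#' @param R Coefficient/embedding matrix (`m x n`), or a `dyndlt_model`.
#' @param reference_times Per-sample reference values (length `n`).
#' @return A list with `component` (index) and `correlation` (the achieved
#'   absolute Spearman correlation).
#' @export
select_component <- function(R, reference_times = NULL) {
  if (inherits(R, "dyndlt_model")) R <- R$coefficients
  if (is.null(reference_times)) {
    stop(paste0("unsolved selection: identifying the dynamic atom without a ",
                "reference is an open problem; supply `reference_times` or ",
                "use trajectory_pseudotime() on the whole representation"),
         call. = FALSE)
  }
  if (length(reference_times) != ncol(R)) {
    stop("`reference_times` length must equal the number of samples", call. = FALSE)
  }
  cors <- apply(R, 1L, function(r) abs(spearman_cor(r, reference_times)))
  j <- which.max(cors)   # which.max returns the first (lowest-index) maximum
  list(component = unname(j), correlation = unname(cors[j]))
}

#' Marker genes from a dictionary-like component
#'
#' The `k` genes with the largest entries of one dictionary column,
#' interpreted as the marker genes of the gene module that the atom
#' represents. For methods whose components can be negative (ICA, PCA) use
#' `use_absolute = TRUE`; for positive dictionaries the two orderings
#' coincide. Ties are broken by gene index, so shorter lists are prefixes of
#' longer ones.
#'
#' @param D Dictionary-like matrix (`p x m`), or a `dyndlt_model`.
#' @param component Column index.
#' @param k Number of genes to return (default 500, the usual export size
#'   for real-data enrichment analyses).
#' @param use_absolute Rank genes by absolute entry value.
#' @param gene_ids Optional gene identifiers.
#' @return A tibble with columns `rank`, `gene_index`, `gene_id`, `weight`,
#'   sorted by decreasing magnitude.
#' @export
marker_genes <- function(D, component, k = 500L, use_absolute = FALSE,
                         gene_ids = NULL) {
  if (inherits(D, "dyndlt_model")) {
    gene_ids <- gene_ids %||% D$gene_ids
    D <- D$dictionary
  }
  if (inherits(D, "low_dim_rep")) {
    gene_ids <- gene_ids %||% D$gene_ids
    if (is.null(D$components)) {
      stop(sprintf(paste0("method '%s' is non-linear and returns no ",
                          "dictionary-like matrix; marker genes are ",
                          "unsupported"), D$method), call. = FALSE)
    }
    D <- D$components
  }
  if (is.null(D)) {
    stop("no dictionary-like matrix available (non-linear method?)",
         call. = FALSE)
  }
  p <- nrow(D)
  if (component < 1L || component > ncol(D)) {
    stop(sprintf("`component` must be in 1..%d", ncol(D)), call. = FALSE)
  }
  if (k < 1L || k > p) {
    stop(sprintf("`k` must be in 1..%d (number of genes)", p), call. = FALSE)
  }
  w <- D[, component]
  score <- if (use_absolute) abs(w) else w
  ord <- order(score, seq_len(p), decreasing = c(TRUE, FALSE), method = "radix")
  idx <- ord[seq_len(k)]
  gene_ids <- gene_ids %||% paste0("gene_", seq_len(p))
  tibble::tibble(rank = seq_len(k), gene_index = idx,
                 gene_id = gene_ids[idx], weight = w[idx])
}
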