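#' Construct an expression matrix
#'
#' Wraps a non-negative gene-by-sample matrix of (normalised) counts together
#' with gene and sample identifiers. Genes are rows, samples are columns --
#' the conventional orientation for transcriptomic count data, and the one
#' required for dictionary atoms to be interpretable as gene modules.
#'
#' @param values Numeric matrix, genes x samples, all entries finite and >= 0.
#' @param gene_ids Character vector of unique gene identifiers (defaults to
#'   rownames, or `gene_1..gene_p`).
#' @param sample_ids Character vector of unique sample identifiers (defaults
#'   to colnames, or `sample_1..sample_n`).
#' @param allow_wide Set to `TRUE` to accept a matrix with more samples than
#'   genes. By default such input is rejected because it usually indicates a
#'   transposed matrix: with samples as rows the dictionary would live in
#'   sample space and its atoms could not be read as gene modules.
#'
#' @return An object of class `expression_matrix`: a list with elements
#'   `values`, `gene_ids`, `sample_ids`.
#' @examples
#' x <- expression_matrix(matrix(rpois(50, 5), nrow = 10))
#' dim(x)
#' @export
expression_matrix <- function(values, gene_ids = NULL, sample_ids = NULL,
                              allow_wide = FALSE) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix (genes x samples)", call. = FALSE)
  }
  if (nrow(values) < 1L || ncol(values) < 1L) {
    stop("expression matrix must have at least one gene and one sample",
         call. = FALSE)
  }
  if (anyNA(values) || any(!is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite entry at gene %d, sample %d", bad[1L], bad[2L]),
         call. = FALSE)
  }
  if (any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative entry at gene %d, sample %d (counts must be >= 0)",
                 bad[1L], bad[2L]), call. = FALSE)
  }
  if (!allow_wide && nrow(values) < ncol(values)) {
    stop(paste0("matrix has more samples (", ncol(values), ") than genes (",
                nrow(values), "); this usually means it is transposed. ",
                "Pass `allow_wide = TRUE` to accept it as-is."), call. = FALSE)
  }
  gene_ids <- gene_ids %||% rownames(values) %||%
    paste0("gene_", seq_len(nrow(values)))
  sample_ids <- sample_ids %||% colnames(values) %||%
    paste0("sample_", seq_len(ncol(values)))
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (length(gene_ids) != nrow(values)) {
    stop("length of `gene_ids` does not match the number of rows", call. = FALSE)
  }
  if (length(sample_ids) != ncol(values)) {
    stop("length of `sample_ids` does not match the number of columns",
         call. = FALSE)
  }
  if (anyDuplicated(gene_ids)) stop("duplicate gene identifiers", call. = FALSE)
  if (anyDuplicated(sample_ids)) stop("duplicate sample identifiers", call. = FALSE)
  dimnames(values) <- NULL
  structure(
    list(values = values, gene_ids = gene_ids, sample_ids = sample_ids),
    class = "expression_matrix"
  )
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  cat(sprintf("  zero fraction: %.3f; value range: [%g, %g]\n",
              mean(x$values == 0), min(x$values), max(x$values)))
  invisible(x)
}

#' Expression transform applied before factorisation
#'
#' Count matrices span several orders of magnitude across genes; on the raw
#' scale a matrix factorisation is dominated by the sampling noise of the
#' most highly expressed genes. A `log1p` transform puts genes on comparable
#' scales so that weakly expressed genes carrying a dynamic pattern remain
#' visible to the dictionary, while keeping the matrix non-negative (which
#' the positive dictionary and the NMF comparison both require).
#'
#' @param x An `expression_matrix` or numeric matrix.
#' @param transform `"log1p"` (default) or `"none"`.
#' @return Numeric matrix on the transformed scale.
#' @export
transform_counts <- function(x, transform = c("log1p", "none")) {
  transform <- match.arg(transform)
  m <- if (inherits(x, "expression_matrix")) x$values else x
  if (transform == "log1p") log1p(m) else m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

as_matrix_input <- function(x) {
  if (inherits(x, "expression_matrix")) return(x)
  if (inherits(x, "sim_dataset")) return(x$matrix)
  if (is.matrix(x)) return(expression_matrix(x))
  stop("expected an expression_matrix, sim_dataset, or numeric matrix",
       call. = FALSE)
}
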