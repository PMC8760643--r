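#' Read a count matrix
#'
#' Dense TSV/CSV (rows = genes, first column = gene identifier, header =
#' sample identifiers) or MatrixMarket MTX with `genes.tsv` / `samples.tsv`
#' sidecar files in the same directory. Negative or non-finite entries and
#' duplicate identifiers are rejected.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"tsv"`, `"csv"`, or `"mtx"`.
#' @return An `expression_matrix`.
#' @export
read_counts <- function(path, format = c("auto", "tsv", "csv", "mtx")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("input file not found: %s", path),
                               call. = FALSE)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     tsv = "tsv", txt = "tsv", csv = "csv", mtx = "mtx",
                     stop(sprintf("cannot infer format from '%s'", path),
                          call. = FALSE))
  }
  if (format == "mtx") {
    m <- as.matrix(Matrix::readMM(path))
    dir <- dirname(path)
    gf <- file.path(dir, "genes.tsv")
    sf <- file.path(dir, "samples.tsv")
    if (!file.exists(gf) || !file.exists(sf)) {
      stop("MTX input needs `genes.tsv` and `samples.tsv` sidecars", call. = FALSE)
    }
    genes <- readLines(gf)
    samples <- readLines(sf)
    if (length(genes) != nrow(m) || length(samples) != ncol(m)) {
      stop(sprintf(paste0("sidecar dimensions (%d genes, %d samples) do not ",
                          "match the matrix (%d x %d)"),
                   length(genes), length(samples), nrow(m), ncol(m)),
           call. = FALSE)
    }
    return(expression_matrix(m, gene_ids = genes, sample_ids = samples,
                             allow_wide = TRUE))
  }
  sep <- if (format == "tsv") "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  gene_ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric entries in count matrix", call. = FALSE)
  bad <- which(!is.finite(m) | m < 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("invalid count at gene '%s', sample '%s'",
                 gene_ids[bad[1L, 1L]], colnames(m)[bad[1L, 2L]]),
         call. = FALSE)
  }
  expression_matrix(m, gene_ids = gene_ids, sample_ids = colnames(m),
                    allow_wide = TRUE)
}

#' Write a count matrix
#'
#' @param x An `expression_matrix` (or `sim_dataset`).
#' @param path Output path; extension selects the format as in
#'   [read_counts()]. MTX output writes the two sidecar files alongside.
#' @param format See [read_counts()].
#' @return `path`, invisibly.
#' @export
write_counts <- function(x, path, format = c("auto", "tsv", "csv", "mtx")) {
  format <- match.arg(format)
  x <- as_matrix_input(x)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     tsv = "tsv", csv = "csv", mtx = "mtx", "tsv")
  }
  if (format == "mtx") {
    Matrix::writeMM(Matrix::Matrix(x$values, sparse = TRUE), path)
    writeLines(x$gene_ids, file.path(dirname(path), "genes.tsv"))
    writeLines(x$sample_ids, file.path(dirname(path), "samples.tsv"))
  } else {
    sep <- if (format == "tsv") "\t" else ","
    df <- data.frame(gene_id = x$gene_ids, x$values, check.names = FALSE)
    colnames(df) <- c("gene_id", x$sample_ids)
    utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Write a fitted dynDLT model to a directory
#'
#' `dictionary.tsv`, `coefficients.tsv`, and `diagnostics.json` (m, s,
#' seed, iterations, reconstruction error).
#'
#' @param model A `dyndlt_model`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_model <- function(model, dir) {
  stopifnot(inherits(model, "dyndlt_model"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dd <- data.frame(gene_id = model$gene_ids, model$dictionary)
  colnames(dd) <- c("gene_id", paste0("atom_", seq_len(ncol(model$dictionary))))
  utils::write.table(dd, file.path(dir, "dictionary.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cd <- data.frame(atom = paste0("atom_", seq_len(nrow(model$coefficients))),
                   model$coefficients)
  colnames(cd) <- c("atom", model$sample_ids)
  utils::write.table(cd, file.path(dir, "coefficients.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  diag <- list(m = model$config$m, s = model$config$sparsity_s,
               seed = model$config$seed,
               transform = model$config$transform,
               iterations = model$diagnostics$iterations,
               converged = model$diagnostics$converged,
               reconstruction_error = model$reconstruction_error)
  jsonlite::write_json(diag, file.path(dir, "diagnostics.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a dynDLT model directory written by [write_model()]
#'
#' @param dir Model directory.
#' @return A list with `dictionary`, `coefficients`, `diagnostics`,
#'   `gene_ids`, `sample_ids`.
#' @export
read_model <- function(dir) {
  dd <- utils::read.table(file.path(dir, "dictionary.tsv"), header = TRUE,
                          sep = "\t", check.names = FALSE)
  cd <- utils::read.table(file.path(dir, "coefficients.tsv"), header = TRUE,
                          sep = "\t", check.names = FALSE)
  list(
    dictionary = as.matrix(dd[, -1L, drop = FALSE]),
    coefficients = as.matrix(cd[, -1L, drop = FALSE]),
    diagnostics = jsonlite::read_json(file.path(dir, "diagnostics.json"),
                                      simplifyVector = TRUE),
    gene_ids = as.character(dd[[1L]]),
    sample_ids = colnames(cd)[-1L]
  )
}

#' Write a run manifest
#'
#' Records the command, configuration snapshot, seed, package version and
#' timestamp so that any output directory can be regenerated from the
#' command line alone.
#'
#' @param dir Output directory.
#' @param command Command or function name.
#' @param config Named list snapshot of the configuration.
#' @param seed The run seed.
#' @return Path of the manifest, invisibly.
#' @export
write_manifest <- function(dir, command, config = list(), seed = NA) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    command = command,
    config = config,
    seed = seed,
    package_version = as.character(utils::packageVersion("dyndlt")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
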