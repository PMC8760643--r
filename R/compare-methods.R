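#' Parameter grid for the benchmark
#'
#' The varied hyperparameter per method: number of components 1..10 for the
#' linear methods (dynDLT, ICA, NMF, PCA), perplexity 10, 20, ..., 100 for
#' t-SNE (dimensionality fixed at 2), and number of neighbours 1..10 for
#' UMAP (dimensionality fixed at 2; the implementation default of 5 sits in
#' the middle of the range). All other parameters stay at their defaults.
#'
#' @param method One of `"dyndlt"`, `"ica"`, `"nmf"`, `"pca"`, `"tsne"`,
#'   `"umap"`.
#' @return A tibble with columns `method`, `param_name`, `param`.
#' @examples
#' parameter_grid("tsne")
#' @export
parameter_grid <- function(method = c("dyndlt", "ica", "nmf", "pca",
                                      "tsne", "umap")) {
  method <- match.arg(method)
  if (method %in% c("dyndlt", "ica", "nmf", "pca")) {
    tibble::tibble(method = method, param_name = "n_components", param = 1:10)
  } else if (method == "tsne") {
    tibble::tibble(method = method, param_name = "perplexity",
                   param = seq(10L, 100L, by = 10L))
  } else {
    tibble::tibble(method = method, param_name = "n_neighbours", param = 1:10)
  }
}

#' Run one dimension-reduction method
#'
#' Uniform adapter: every method returns a `low_dim_rep` with an `m x n`
#' embedding and, for the linear methods only, a `p x m` dictionary-like
#' component matrix such that `components %*% embedding` approximates the
#' (transformed, and for PCA gene-centred) data. Marker genes can therefore
#' be extracted from linear methods only.
#'
#' @param X An `expression_matrix`, `sim_dataset`, or numeric matrix.
#' @param method Method tag.
#' @param param The method's varied parameter (see [parameter_grid()]).
#' @param seed Random seed for the stochastic methods.
#' @param transform Expression transform, see [transform_counts()].
#' @return A `low_dim_rep`: list with `method`, `components` (or `NULL`),
#'   `embedding`, `params`, `seed`, `gene_ids`, `sample_ids`.
#' @export
run_method <- function(X, method = c("dyndlt", "ica", "nmf", "pca",
                                     "tsne", "umap"),
                       param, seed = 0L, transform = c("log1p", "none")) {
  method <- match.arg(method)
  transform <- match.arg(transform)
  X <- as_matrix_input(X)
  M <- transform_counts(X, transform)
  n <- ncol(M)
  param <- as.integer(param)
  components <- NULL
  params <- list()
  if (method == "dyndlt") {
    fit <- fit_dyndlt(X, dyndlt_config(m = param, seed = seed,
                                       transform = transform))
    components <- fit$dictionary
    embedding <- fit$coefficients
    params <- list(n_components = param)
  } else if (method == "ica") {
    fit <- fast_ica(M, m = param, seed = seed)
    components <- fit$mixing
    embedding <- fit$sources
    params <- list(n_components = param)
  } else if (method == "nmf") {
    if (any(M < 0)) stop("NMF requires a non-negative matrix", call. = FALSE)
    fit <- nmf_factorise(M, m = param, seed = seed)
    components <- fit$W
    embedding <- fit$H
    params <- list(n_components = param)
  } else if (method == "pca") {
    Mc <- M - rowMeans(M)          # centre each gene across samples
    sv <- svd(Mc, nu = param, nv = param)
    components <- sv$u %*% diag(sv$d[seq_len(param)], param, param)
    embedding <- t(sv$v)
    params <- list(n_components = param)
  } else if (method == "tsne") {
    if (n - 1 < 3 * param) {
      stop(sprintf("perplexity %d too large for n = %d samples", param, n),
           call. = FALSE)
    }
    set.seed(seed)
    emb <- Rtsne::Rtsne(t(M), dims = 2, perplexity = param,
                        check_duplicates = FALSE, pca = TRUE)$Y
    embedding <- t(emb)
    params <- list(perplexity = param, dims = 2)
  } else {
    if (param < 2L) {
      stop("UMAP needs at least 2 neighbours", call. = FALSE)
    }
    emb <- uwot::umap(t(M), n_neighbors = param, n_components = 2,
                      seed = seed)
    embedding <- t(emb)
    params <- list(n_neighbours = param, dims = 2)
  }
  structure(
    list(method = method, components = components, embedding = embedding,
         params = params, seed = as.integer(seed),
         gene_ids = X$gene_ids, sample_ids = X$sample_ids),
    class = "low_dim_rep"
  )
}

#' @export
print.low_dim_rep <- function(x, ...) {
  cat(sprintf("<low_dim_rep> method '%s', embedding %d x %d, components %s\n",
              x$method, nrow(x$embedding), ncol(x$embedding),
              if (is.null(x$components)) "absent (non-linear method)"
              else paste(dim(x$components), collapse = " x ")))
  invisible(x)
}

## FastICA (deflation, logcosh contrast) on the sample-by-gene view of the
## data: genes are centred, samples are whitened to `m` principal
## directions, and independent source directions are extracted one by one.
## Returns mixing (p x m) and sources (m x n) with
## mixing %*% sources ~ gene-centred data.
fast_ica <- function(M, m, seed = 0L, max_iter = 200L, tol = 1e-6) {
  p <- nrow(M); n <- ncol(M)
  if (m > min(p, n)) stop("too many ICA components", call. = FALSE)
  set.seed(seed)
  Mc <- M - rowMeans(M)
  ## whiten in sample space: eigen of the n x n Gram matrix
  G <- crossprod(Mc) / p
  eg <- eigen(G, symmetric = TRUE)
  keep <- seq_len(m)
  ev <- pmax(eg$values[keep], 1e-12)
  K <- eg$vectors[, keep, drop = FALSE] %*% diag(1 / sqrt(ev), m, m)  # n x m
  Z <- t(K) %*% t(Mc) / sqrt(p)       # m x p whitened signals
  W <- matrix(0, m, m)
  for (comp in seq_len(m)) {
    w <- stats::rnorm(m)
    w <- w / sqrt(sum(w^2))
    for (it in seq_len(max_iter)) {
      wx <- drop(w %*% Z)
      g <- tanh(wx)
      gp <- 1 - g^2
      w_new <- Z %*% g / ncol(Z) - mean(gp) * w
      w_new <- drop(w_new)
      if (comp > 1L) {   # deflation: remove projections on earlier components
        Wp <- W[seq_len(comp - 1L), , drop = FALSE]
        w_new <- w_new - drop(t(Wp) %*% (Wp %*% w_new))
      }
      w_new <- w_new / sqrt(sum(w_new^2))
      conv <- abs(abs(sum(w_new * w)) - 1) < tol
      w <- w_new
      if (conv) break
    }
    W[comp, ] <- w
  }
  ## sources are length-n sample profiles; mixing holds the gene loadings
  S <- W %*% t(K)                      # m x n rotation of the whitened samples
  SS <- tcrossprod(S)
  mixing <- t(solve(SS, S %*% t(Mc)))  # least squares: mixing %*% S ~ Mc
  list(mixing = mixing, sources = S)
}

## Multiplicative-update NMF (Frobenius loss), seeded random initialisation.
nmf_factorise <- function(M, m, seed = 0L, max_iter = 300L, tol = 1e-5) {
  p <- nrow(M); n <- ncol(M)
  set.seed(seed)
  sc <- sqrt(mean(M) / m)
  W <- matrix(stats::runif(p * m, 0, 2 * sc), p, m)
  H <- matrix(stats::runif(m * n, 0, 2 * sc), m, n)
  err_old <- Inf
  for (it in seq_len(max_iter)) {
    H <- H * (crossprod(W, M) / pmax(crossprod(W) %*% H, 1e-12))
    W <- W * (M %*% t(H) / pmax(W %*% tcrossprod(H), 1e-12))
    if (it %% 10L == 0L) {
      err <- sum((M - W %*% H)^2)
      if (is.finite(err_old) && abs(err_old - err) <= tol * err_old) break
      err_old <- err
    }
  }
  list(W = W, H = H)
}
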