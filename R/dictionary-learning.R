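#' Configuration for a dynDLT fit
#'
#' dynDLT learns a thin (`m < n`), positive, unit-norm dictionary from a
#' gene-by-sample matrix and then codes every sample densely with `s = m`
#' non-zero coefficients, so that each sample receives a usable coefficient
#' for every atom. The thin-dictionary requirement is what separates this
#' use of dictionary learning from the classical overcomplete setting: with
#' `m >= n` the data matrix itself is an optimal (and uninformative)
#' dictionary.
#'
#' @param m Number of dictionary atoms (gene modules); must satisfy
#'   `1 <= m < n`.
#' @param sparsity_s Sparsity of the coding stage; dynDLT requires
#'   `sparsity_s = m` (the default) so that no sample gets a structurally
#'   zero coefficient. Values below `m` give classical sparse coding.
#' @param learn_penalty l1 penalty weight used during dictionary learning.
#' @param max_iter Cap on alternating minimisation iterations.
#' @param tol Relative objective-decrease threshold for convergence.
#' @param seed Random seed controlling initialisation.
#' @param positive_dictionary Constrain dictionary entries to be >= 0
#'   (default). Coefficients are unconstrained in sign either way.
#' @param positive_coefficients Additionally constrain coefficients to be
#'   >= 0 (off by default; kept for experimentation).
#' @param transform Expression transform applied before factorisation,
#'   see [transform_counts()].
#'
#' @return A list of class `dyndlt_config`.
#' @export
dyndlt_config <- function(m,
                          sparsity_s = m,
                          learn_penalty = 1,
                          max_iter = 25,
                          tol = 1e-4,
                          seed = 0,
                          positive_dictionary = TRUE,
                          positive_coefficients = FALSE,
                          transform = c("log1p", "none")) {
  m <- as.integer(m)
  sparsity_s <- as.integer(sparsity_s)
  if (length(m) != 1L || is.na(m) || m < 1L) {
    stop("`m` must be a positive integer", call. = FALSE)
  }
  if (sparsity_s < 1L || sparsity_s > m) {
    stop("`sparsity_s` must satisfy 1 <= s <= m", call. = FALSE)
  }
  if (learn_penalty <= 0) stop("`learn_penalty` must be > 0", call. = FALSE)
  structure(
    list(m = m, sparsity_s = sparsity_s, learn_penalty = learn_penalty,
         max_iter = as.integer(max_iter), tol = tol, seed = as.integer(seed),
         positive_dictionary = isTRUE(positive_dictionary),
         positive_coefficients = isTRUE(positive_coefficients),
         transform = match.arg(transform)),
    class = "dyndlt_config"
  )
}

## l1-penalised coding of all sample columns at once.
## Coordinate descent on  0.5*||x - D r||^2 + lambda*||r||_1  shares the
## Gram matrix G = D'D across columns, so each sweep updates one coefficient
## row for every sample simultaneously.
code_l1 <- function(X, D, lambda, positive = FALSE,
                    sweeps = 50L, tol = 1e-6, G = NULL, C = NULL) {
  m <- ncol(D)
  if (is.null(G)) G <- crossprod(D)
  if (is.null(C)) C <- crossprod(D, X)
  R <- matrix(0, m, ncol(C))
  scale_ref <- max(abs(C)) + 1e-12
  for (it in seq_len(sweeps)) {
    delta <- 0
    for (j in seq_len(m)) {
      gjj <- G[j, j]
      if (gjj < 1e-12) { R[j, ] <- 0; next }
      rj_old <- R[j, ]
      resid <- C[j, ] - drop(G[j, ] %*% R) + gjj * rj_old
      rj <- if (positive) {
        pmax(resid - lambda, 0) / gjj
      } else {
        sign(resid) * pmax(abs(resid) - lambda, 0) / gjj
      }
      R[j, ] <- rj
      delta <- max(delta, max(abs(rj - rj_old)))
    }
    if (delta < tol * scale_ref) break
  }
  R
}

## One block-coordinate pass over the dictionary columns given fixed
## coefficients (Mairal-style update), with projection onto the
## non-negative orthant and the unit l2 ball. Degenerate (unused) atoms are
## re-seeded from the residual-maximising sample column.
update_dictionary <- function(X, D, R, positive = TRUE, A = NULL) {
  if (is.null(A)) A <- tcrossprod(R)   # m x m
  B <- tcrossprod(X, R)                # p x m
  m <- ncol(D)
  reseeded <- integer(0)
  for (j in seq_len(m)) {
    if (A[j, j] < 1e-12) {
      res <- X - D %*% R
      col <- which.max(colSums(res * res))
      u <- if (positive) pmax(X[, col], 0) else X[, col]
      if (sum(u * u) < 1e-24) u <- abs(stats::rnorm(nrow(D)))
      D[, j] <- u / sqrt(sum(u * u))
      reseeded <- c(reseeded, j)
      next
    }
    u <- D[, j] + (B[, j] - D %*% A[, j]) / A[j, j]
    if (positive) u <- pmax(u, 0)
    nu <- sqrt(sum(u * u))
    if (nu < 1e-12) {
      u <- abs(stats::rnorm(nrow(D)))
      nu <- sqrt(sum(u * u))
      reseeded <- c(reseeded, j)
    }
    D[, j] <- u / nu
  }
  attr(D, "reseeded") <- reseeded
  D
}

#' Learn a thin positive dictionary from expression data
#'
#' Alternating minimisation of the penalised dictionary-learning objective
#' `0.5 * ||X - D R||_F^2 + lambda * sum(|R|)` with unit-l2, entry-wise
#' non-negative atoms. Sample columns are coded jointly by coordinate
#' descent; atoms are updated by block coordinate descent with projection
#' onto the non-negative orthant. Atoms are initialised from randomly drawn
#' sample columns (non-negative by construction for count data).
#'
#' @param X An `expression_matrix` (or numeric matrix).
#' @param cfg A [dyndlt_config()].
#' @return A list with elements `dictionary` (p x m), `iterations`,
#'   `converged`, `objective`, and `reseeded_atoms`.
#' @export
learn_dictionary <- function(X, cfg) {
  X <- as_matrix_input(X)
  stopifnot(inherits(cfg, "dyndlt_config"))
  n <- ncol(X$values)
  if (cfg$m >= n) {
    stop(sprintf(paste0("thin-dictionary violation: m = %d must be smaller ",
                        "than the number of samples n = %d"), cfg$m, n),
         call. = FALSE)
  }
  M <- transform_counts(X, cfg$transform)
  set.seed(cfg$seed)
  cols <- sample.int(n, cfg$m)
  D <- M[, cols, drop = FALSE] + 1e-6
  if (cfg$positive_dictionary) D <- pmax(D, 0)
  D <- sweep(D, 2, pmax(sqrt(colSums(D^2)), 1e-12), "/")
  obj_old <- Inf
  converged <- FALSE
  reseeded <- integer(0)
  it <- 0L
  normX2 <- sum(M * M)
  for (it in seq_len(cfg$max_iter)) {
    G <- crossprod(D)
    C <- crossprod(D, M)
    R <- code_l1(M, D, cfg$learn_penalty,
                 positive = cfg$positive_coefficients, G = G, C = C)
    A <- tcrossprod(R)
    ## ||M - DR||^2 expanded through the Gram matrices (no p x n product)
    obj <- 0.5 * (normX2 - 2 * sum(C * R) + sum(G * A)) +
      cfg$learn_penalty * sum(abs(R))
    D <- update_dictionary(M, D, R, positive = cfg$positive_dictionary, A = A)
    reseeded <- union(reseeded, attr(D, "reseeded"))
    if (is.finite(obj_old) && abs(obj_old - obj) <= cfg$tol * abs(obj_old)) {
      converged <- TRUE
      break
    }
    obj_old <- obj
  }
  attr(D, "reseeded") <- NULL
  list(dictionary = D, iterations = it, converged = converged,
       objective = obj, reseeded_atoms = reseeded)
}

#' Compute coefficient vectors by orthogonal matching pursuit
#'
#' Codes each sample column greedily against the dictionary. With
#' `s = ncol(D)` (the dynDLT setting) the support is the full atom set and
#' the result is exactly the least-squares projection of each sample onto
#' `span(D)`; rank-deficient dictionaries fall back to the minimum-norm
#' solution (flagged in the `"rank_deficient"` attribute).
#'
#' @param X An `expression_matrix` or numeric matrix (already transformed if
#'   a plain matrix; `expression_matrix` input is transformed according to
#'   `transform`).
#' @param D Dictionary matrix with (approximately) unit-norm columns.
#' @param s Sparsity: maximum number of non-zero coefficients per sample.
#' @param transform Expression transform for `expression_matrix` input.
#' @return An `m x n` coefficient matrix.
#' @export
compute_coefficients <- function(X, D, s = ncol(D),
                                 transform = c("log1p", "none")) {
  transform <- match.arg(transform)
  M <- if (inherits(X, "expression_matrix")) {
    transform_counts(X, transform)
  } else if (inherits(X, "sim_dataset")) {
    transform_counts(X$matrix, transform)
  } else X
  m <- ncol(D)
  s <- as.integer(s)
  if (s < 1L || s > m) stop("`s` must satisfy 1 <= s <= ncol(D)", call. = FALSE)
  if (s == m) {
    G <- crossprod(D)
    ok <- tryCatch({
      R <- solve(G, crossprod(D, M))
      TRUE
    }, error = function(e) FALSE)
    if (!ok) {
      R <- MASS::ginv(G) %*% crossprod(D, M)
      attr(R, "rank_deficient") <- TRUE
    }
    return(R)
  }
  omp_code(M, D, s)
}

## Greedy OMP per column: pick the atom most correlated with the residual,
## re-solve least squares on the active set, repeat s times.
omp_code <- function(M, D, s) {
  m <- ncol(D)
  n <- ncol(M)
  R <- matrix(0, m, n)
  for (i in seq_len(n)) {
    x <- M[, i]
    active <- integer(0)
    resid <- x
    coefs <- numeric(0)
    for (k in seq_len(s)) {
      scores <- abs(crossprod(D, resid))
      scores[active] <- -Inf
      j <- which.max(scores)
      active <- c(active, j)
      Da <- D[, active, drop = FALSE]
      coefs <- tryCatch(qr.solve(Da, x),
                        error = function(e) MASS::ginv(Da) %*% x)
      resid <- x - Da %*% coefs
      if (sum(resid^2) < 1e-20) break
    }
    R[active, i] <- coefs
  }
  R
}

#' Fit the dynDLT model
#'
#' Learns the dictionary with [learn_dictionary()] and derives dense
#' (`s = m`) coefficient vectors with [compute_coefficients()]. The recorded
#' reconstruction error is the Frobenius residual on the transformed scale.
#'
#' @param X An `expression_matrix` (or numeric matrix, or `sim_dataset`).
#' @param cfg A [dyndlt_config()]; alternatively pass `m` and friends via
#'   `...` to have a config built for you.
#' @param ... Arguments forwarded to [dyndlt_config()] when `cfg` is missing.
#' @return An object of class `dyndlt_model` with fields `dictionary`,
#'   `coefficients`, `reconstruction_error`, `config`, `diagnostics`,
#'   `gene_ids`, `sample_ids`.
#' @examples
#' x <- expression_matrix(matrix(rpois(600, 5), nrow = 60))
#' fit <- fit_dyndlt(x, m = 2)
#' fit
#' @export
fit_dyndlt <- function(X, cfg = NULL, ...) {
  X <- as_matrix_input(X)
  if (is.null(cfg)) cfg <- dyndlt_config(...)
  learned <- learn_dictionary(X, cfg)
  D <- learned$dictionary
  R <- compute_coefficients(X, D, s = cfg$sparsity_s, transform = cfg$transform)
  M <- transform_counts(X, cfg$transform)
  err <- sqrt(sum((M - D %*% R)^2))
  atom_norms <- sqrt(colSums(D^2))
  structure(
    list(dictionary = D,
         coefficients = R,
         reconstruction_error = err,
         config = cfg,
         diagnostics = list(
           iterations = learned$iterations,
           converged = learned$converged,
           objective = learned$objective,
           reseeded_atoms = learned$reseeded_atoms,
           degenerate_atoms = which(atom_norms < 0.5),
           rank_deficient = isTRUE(attr(R, "rank_deficient")),
           relative_error = err / sqrt(sum(M^2))
         ),
         gene_ids = X$gene_ids,
         sample_ids = X$sample_ids),
    class = "dyndlt_model"
  )
}

#' @export
print.dyndlt_model <- function(x, ...) {
  cat(sprintf("<dyndlt_model> %d genes, %d samples, m = %d atoms (s = %d)\n",
              nrow(x$dictionary), ncol(x$coefficients), x$config$m,
              x$config$sparsity_s))
  cat(sprintf("  relative reconstruction error: %.4f (%s after %d iterations)\n",
              x$diagnostics$relative_error,
              if (x$diagnostics$converged) "converged" else "not converged",
              x$diagnostics$iterations))
  invisible(x)
}

#' Tidy a dynDLT model
#'
#' One row per (atom, sample) with the coefficient value and the per-atom
#' pseudotime rank.
#'
#' @param x A `dyndlt_model`.
#' @param ... Unused.
#' @return A tibble with columns `atom`, `sample_id`, `coefficient`, `rank`.
#' @export
tidy.dyndlt_model <- function(x, ...) {
  R <- x$coefficients
  purrr::map_dfr(seq_len(nrow(R)), function(j) {
    tibble::tibble(
      atom = j,
      sample_id = x$sample_ids,
      coefficient = R[j, ],
      rank = rank(R[j, ], ties.method = "average")
    )
  })
}

#' Glance at a dynDLT model
#'
#' @param x A `dyndlt_model`.
#' @param ... Unused.
#' @return A one-row tibble of fit diagnostics.
#' @export
glance.dyndlt_model <- function(x, ...) {
  tibble::tibble(
    m = x$config$m,
    sparsity_s = x$config$sparsity_s,
    reconstruction_error = x$reconstruction_error,
    relative_error = x$diagnostics$relative_error,
    iterations = x$diagnostics$iterations,
    converged = x$diagnostics$converged,
    n_degenerate_atoms = length(x$diagnostics$degenerate_atoms),
    seed = x$config$seed
  )
}

#' Plot coefficient profiles of a dynDLT model
#'
#' Coefficient value per sample (in column order) for each atom; on
#' simulated data, sample order is simulated time, so a dynamic atom shows
#' its pattern directly.
#'
#' @param object A `dyndlt_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dyndlt_model <- function(object, ...) {
  d <- tidy.dyndlt_model(object)
  d$sample_index <- match(d$sample_id, object$sample_ids)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$sample_index,
                                  y = .data$coefficient)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::facet_wrap(~atom, scales = "free_y",
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "sample (column order)", y = "coefficient") +
    ggplot2::theme_minimal()
}
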