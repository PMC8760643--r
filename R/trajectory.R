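#' Euclidean minimum spanning tree of an embedding
#'
#' Prim's algorithm on the complete Euclidean graph over the embedded
#' samples. Ties between equal-weight candidate edges are broken by
#' (node index, node index), so the tree is deterministic; duplicated
#' points simply yield zero-weight edges.
#'
#' @param points `n x d` coordinate matrix (samples in rows -- the
#'   transposed embedding).
#' @return A tibble with columns `from`, `to`, `weight` (`n - 1` rows),
#'   `from < to` within each row.
#' @export
build_mst <- function(points) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < 2L) stop("need at least 2 points", call. = FALSE)
  if (anyNA(points) || any(!is.finite(points))) {
    stop("non-finite coordinates", call. = FALSE)
  }
  dm <- as.matrix(stats::dist(points))
  in_tree <- rep(FALSE, n)
  in_tree[1L] <- TRUE
  best_dist <- dm[1L, ]
  best_from <- rep(1L, n)
  edges <- matrix(0, n - 1L, 3L)
  for (k in seq_len(n - 1L)) {
    cand <- which(!in_tree)
    ## smallest attachment distance; ties by (existing node, new node) index
    j <- cand[order(best_dist[cand], best_from[cand], cand)[1L]]
    i <- best_from[j]
    edges[k, ] <- c(min(i, j), max(i, j), best_dist[j])
    in_tree[j] <- TRUE
    upd <- !in_tree & (dm[j, ] < best_dist |
                         (dm[j, ] == best_dist & j < best_from))
    best_dist[upd] <- dm[j, upd]
    best_from[upd] <- j
  }
  tibble::tibble(from = as.integer(edges[, 1L]), to = as.integer(edges[, 2L]),
                 weight = edges[, 3L])
}

tree_adjacency <- function(edges, n) {
  adj <- vector("list", n)
  for (k in seq_len(nrow(edges))) {
    i <- edges$from[k]; j <- edges$to[k]; w <- edges$weight[k]
    adj[[i]] <- rbind(adj[[i]], c(j, w))
    adj[[j]] <- rbind(adj[[j]], c(i, w))
  }
  adj
}

## weighted distances + parents from a root, by iterative DFS over the tree
tree_walk <- function(adj, root, n) {
  dist <- rep(NA_real_, n)
  parent <- rep(NA_integer_, n)
  dist[root] <- 0
  stack <- root
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    nb <- adj[[v]]
    if (is.null(nb)) next
    for (r in seq_len(nrow(nb))) {
      u <- nb[r, 1L]
      if (is.na(dist[u])) {
        dist[u] <- dist[v] + nb[r, 2L]
        parent[u] <- v
        stack <- c(stack, u)
      }
    }
  }
  list(dist = dist, parent = parent)
}

#' Weighted diameter path of a tree
#'
#' Double traversal: the farthest node from an arbitrary root is one
#' endpoint of a longest (maximum total weight) path; the farthest node
#' from that endpoint is the other. Distance ties are resolved toward the
#' smallest node index.
#'
#' @param mst_edges Edge tibble as returned by [build_mst()].
#' @param n Number of nodes (defaults to the largest index present).
#' @return Integer vector: the ordered node sequence of the diameter path.
#' @export
longest_path <- function(mst_edges, n = max(mst_edges$from, mst_edges$to)) {
  if (nrow(mst_edges) != n - 1L) {
    stop("input is not a spanning tree (need exactly n - 1 edges)", call. = FALSE)
  }
  adj <- tree_adjacency(mst_edges, n)
  w0 <- tree_walk(adj, 1L, n)
  if (anyNA(w0$dist)) stop("disconnected input", call. = FALSE)
  a <- which(w0$dist == max(w0$dist))[1L]
  w1 <- tree_walk(adj, a, n)
  b <- which(w1$dist == max(w1$dist))[1L]
  path <- b
  while (!is.na(w1$parent[path[1L]])) path <- c(w1$parent[path[1L]], path)
  ## canonical orientation: start at the smaller endpoint index
  if (path[length(path)] < path[1L]) path <- rev(path)
  as.integer(path)
}

#' Pseudotime by projection onto the diameter path
#'
#' Each sample is projected onto the nearest segment of the polyline through
#' the diameter-path nodes ("polygonal reconstruction"); its pseudotime is
#' the arc-length coordinate of the projection. A point equidistant to two
#' segments is assigned to the earlier one. `node_snap = TRUE` uses the
#' nearest path node instead of segment projection.
#'
#' @param points `n x d` coordinate matrix.
#' @param diameter_path Node sequence from [longest_path()].
#' @param node_snap Snap to nearest path node instead of projecting onto
#'   segments.
#' @return A `pseudotime_result` tibble with columns `sample_id`,
#'   `arc_position`, `pseudotime_rank`.
#' @export
project_to_path <- function(points, diameter_path, node_snap = FALSE) {
  points <- as.matrix(points)
  n <- nrow(points)
  pp <- points[diameter_path, , drop = FALSE]
  nseg <- nrow(pp) - 1L
  seglen <- if (nseg > 0) sqrt(rowSums((pp[-1L, , drop = FALSE] -
                                          pp[-nrow(pp), , drop = FALSE])^2)) else numeric(0)
  cum <- c(0, cumsum(seglen))
  arc <- numeric(n)
  if (node_snap || nseg == 0L) {
    for (i in seq_len(n)) {
      d2 <- colSums((t(pp) - points[i, ])^2)
      arc[i] <- cum[which.min(d2)]
    }
  } else {
    for (i in seq_len(n)) {
      x <- points[i, ]
      best <- Inf; best_arc <- 0
      for (s in seq_len(nseg)) {
        a <- pp[s, ]; b <- pp[s + 1L, ]
        ab <- b - a
        L2 <- sum(ab * ab)
        t_ <- if (L2 == 0) 0 else min(1, max(0, sum((x - a) * ab) / L2))
        proj <- a + t_ * ab
        d2 <- sum((x - proj)^2)
        if (d2 < best - 1e-12) {   # strict improvement: earlier segment wins ties
          best <- d2
          best_arc <- cum[s] + t_ * sqrt(L2)
        }
      }
      arc[i] <- best_arc
    }
  }
  out <- tibble::tibble(
    sample_id = rownames(points) %||% paste0("sample_", seq_len(n)),
    arc_position = arc,
    pseudotime_rank = rank(arc, ties.method = "average")
  )
  structure(out, class = c("pseudotime_result", class(out)),
            source = "mst_path", orientation = 1L,
            uninformative = stats::sd(arc) == 0)
}

#' MST polygonal-reconstruction pseudotime
#'
#' Full pipeline over a low-dimensional representation: Euclidean MST over
#' the embedded samples, weighted diameter path, projection of every sample
#' onto that path. This uses the entire representation, so no single
#' component has to be selected. Degenerate embeddings in which all samples
#' coincide admit no trajectory and raise an error.
#'
#' @param embedding `m x n` embedding (components x samples), a
#'   `dyndlt_model`, or a `low_dim_rep`.
#' @param node_snap See [project_to_path()].
#' @return A `pseudotime_result` tibble.
#' @export
trajectory_pseudotime <- function(embedding, node_snap = FALSE) {
  sample_ids <- NULL
  if (inherits(embedding, "dyndlt_model")) {
    sample_ids <- embedding$sample_ids
    embedding <- embedding$coefficients
  } else if (inherits(embedding, "low_dim_rep")) {
    sample_ids <- embedding$sample_ids
    embedding <- embedding$embedding
  }
  pts <- t(embedding)
  if (all(apply(pts, 2L, stats::sd) == 0)) {
    stop("degenerate embedding: all samples coincide, no trajectory exists",
         call. = FALSE)
  }
  if (!is.null(sample_ids)) rownames(pts) <- sample_ids
  mst <- build_mst(pts)
  path <- longest_path(mst, n = nrow(pts))
  project_to_path(pts, path, node_snap = node_snap)
}
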