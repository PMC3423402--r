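#' Threshold a penalized matrix into a sparse connected weighted graph
#'
#' Keeps only positive weights and removes edges in ascending weight order
#' until the target edge count `round(density * N(N-1)/2)` is reached,
#' skipping (retaining) any edge whose removal would disconnect the graph —
#' so the output is always a single component. Negative connections are
#' never retained.
#'
#' @param conn A penalized-stage `connectivity_matrix` (or plain symmetric
#'   matrix, zero diagonal).
#' @param density Target edge density in (0, 1\]; default 0.12.
#'
#' @return A `sparse_graph`: list with `weights` (symmetric nonnegative
#'   matrix, zero diagonal), `density` (realised), `target_density`,
#'   `n_edges`, and `min_connected` (TRUE when the bridge rule forbade
#'   reaching the target and the minimal connected graph was returned).
#' @export
threshold_graph <- function(conn, density = 0.12) {
  if (density <= 0 || density > 1) abort("`density` must lie in (0, 1].")
  w <- if (inherits(conn, "connectivity_matrix")) conn_weights(conn) else
    as.matrix(conn)
  check_symmetric(w, tol = 1e-8, arg = "conn")
  n <- nrow(w)
  w <- (w + t(w)) / 2
  diag(w) <- 0
  w[w < 0] <- 0
  target <- as.integer(round_half_away(density * n * (n - 1) / 2))
  target <- max(target, 1L)

  ut <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  if (nrow(ut) == 0L || !adjacency_connected(w)) {
    abort("positive weights do not form a connected graph.",
          class = "brainmod_disconnected")
  }
  n_edges <- nrow(ut)
  if (n_edges <= target) {
    return(new_sparse_graph(w, target, density, flagged = n_edges < target))
  }

  ord <- order(w[ut])          # ascending: weakest first
  # Fast path: if the `target` strongest edges already form a spanning
  # connected graph, no weaker edge is ever a bridge during the greedy
  # removal, so the result is exactly that edge set.
  keep_idx <- ut[ord[(n_edges - target + 1L):n_edges], , drop = FALSE]
  top <- matrix(0, n, n, dimnames = dimnames(w))
  top[keep_idx] <- w[keep_idx]
  top <- top + t(top)
  if (adjacency_connected(top)) {
    return(new_sparse_graph(top, target, density, flagged = FALSE))
  }

  # Greedy removal with bridge retention.
  adj <- w
  remaining <- n_edges
  for (k in ord) {
    if (remaining <= target) break
    i <- ut[k, 1L]; j <- ut[k, 2L]
    keep <- adj[i, j]
    adj[i, j] <- 0; adj[j, i] <- 0
    if (nodes_connected(adj, i, j)) {
      remaining <- remaining - 1L
    } else {
      adj[i, j] <- keep; adj[j, i] <- keep   # bridge: retain
    }
  }
  new_sparse_graph(adj, target, density, flagged = remaining > target)
}

new_sparse_graph <- function(w, target, target_density, flagged) {
  n_edges <- sum(w[upper.tri(w)] > 0)
  n <- nrow(w)
  structure(
    list(weights = w, density = n_edges / (n * (n - 1) / 2),
         target_density = target_density, n_edges = n_edges,
         min_connected = flagged),
    class = "sparse_graph"
  )
}

#' @export
print.sparse_graph <- function(x, ...) {
  cat(sprintf("<sparse_graph> %d nodes, %d edges (density %.3f%s)\n",
              nrow(x$weights), x$n_edges, x$density,
              if (x$min_connected) ", minimal-connected flag" else ""))
  invisible(x)
}

# igraph handle with edge lengths 1/weight for shortest-path metrics.
graph_igraph <- function(g) {
  ig <- igraph::graph_from_adjacency_matrix(g$weights, mode = "undirected",
                                            weighted = TRUE, diag = FALSE)
  igraph::E(ig)$length <- 1 / igraph::E(ig)$weight
  ig
}
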