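# Topological metrics on sparse weighted graphs. All shortest-path
# quantities use edge lengths 1/weight (the standard weighted convention).

graph_distances <- function(g) {
  ig <- graph_igraph(g)
  igraph::distances(ig, weights = igraph::E(ig)$length)
}

#' Characteristic path length
#'
#' Mean shortest-path distance over all unordered node pairs, with edge
#' lengths 1/weight.
#'
#' @param g A connected `sparse_graph`.
#' @return Scalar path length.
#' @export
path_length <- function(g) {
  d <- graph_distances(g)
  ut <- d[upper.tri(d)]
  if (any(!is.finite(ut))) {
    abort("path length is undefined on a disconnected graph.",
          class = "brainmod_infinite_distance")
  }
  mean(ut)
}

#' Global efficiency
#'
#' Mean inverse shortest-path distance over node pairs (a disconnected pair
#' contributes 0). `nodal = TRUE` returns each node's mean inverse distance
#' to all other nodes.
#'
#' @param g A `sparse_graph`.
#' @param nodal Return the per-node vector instead of the global mean.
#' @return Scalar, or numeric vector when `nodal = TRUE`.
#' @export
global_efficiency <- function(g, nodal = FALSE) {
  d <- graph_distances(g)
  inv <- 1 / d
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  node <- rowSums(inv) / (nrow(d) - 1)
  if (nodal) node else mean(inv[upper.tri(inv)])
}

#' Local efficiency
#'
#' Per-node efficiency of the subgraph induced by the node's neighbours
#' (Latora-Marchiori): the global efficiency computed within that
#' neighbourhood subgraph, 0 for nodes with fewer than 2 neighbours. The
#' graph value is the mean over nodes.
#'
#' @inheritParams global_efficiency
#' @return Scalar, or per-node vector when `nodal = TRUE`.
#' @export
local_efficiency <- function(g, nodal = FALSE) {
  w <- g$weights
  n <- nrow(w)
  eff <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(w[i, ] > 0)
    if (length(nb) < 2L) next
    sub <- w[nb, nb, drop = FALSE]
    d <- graph_distances(list(weights = sub))
    inv <- 1 / d
    diag(inv) <- 0
    inv[!is.finite(inv)] <- 0
    eff[i] <- mean(inv[upper.tri(inv)])
  }
  if (nodal) eff else mean(eff)
}

#' Weighted clustering coefficient (Onnela)
#'
#' Geometric-mean triangle intensity: with weights scaled by the maximum,
#' node clustering is the sum of cube-root weight products over triangles
#' at the node, divided by k(k-1). Nodes with degree < 2 score 0.
#'
#' @inheritParams global_efficiency
#' @return Scalar mean clustering, or per-node vector when `nodal = TRUE`.
#' @export
clustering_coefficient <- function(g, nodal = FALSE) {
  w <- g$weights
  mx <- max(w)
  if (mx == 0) {
    out <- rep(0, nrow(w))
    return(if (nodal) out else 0)
  }
  wh <- (w / mx)^(1 / 3)
  tri <- diag(wh %*% wh %*% wh)
  k <- rowSums(w > 0)
  cc <- ifelse(k >= 2, tri / (k * (k - 1)), 0)
  if (nodal) cc else mean(cc)
}

#' Betweenness centrality
#'
#' Unnormalised shortest-path betweenness on edge lengths 1/weight; when a
#' pair has multiple equal-length shortest paths the contribution is split
#' fractionally among them.
#'
#' @param g A connected `sparse_graph`.
#' @return Per-node numeric vector.
#' @export
betweenness_centrality <- function(g) {
  ig <- graph_igraph(g)
  as.numeric(igraph::betweenness(ig, weights = igraph::E(ig)$length,
                                 directed = FALSE))
}

#' Node-wise metric table of a sparse graph
#'
#' @param g A connected `sparse_graph`.
#' @return A tibble with one row per node: `node`, `region`, `degree`,
#'   `strength`, `BC`, `CC_node`, `LE_node`, `GE_node` and `LEGE`
#'   (local/global efficiency ratio).
#' @export
node_metrics <- function(g) {
  w <- g$weights
  ge <- global_efficiency(g, nodal = TRUE)
  le <- local_efficiency(g, nodal = TRUE)
  tibble::tibble(
    node = seq_len(nrow(w)),
    region = colnames(w) %||% as.character(seq_len(nrow(w))),
    degree = as.integer(rowSums(w > 0)),
    strength = rowSums(w),
    BC = betweenness_centrality(g),
    CC_node = clustering_coefficient(g, nodal = TRUE),
    LE_node = le,
    GE_node = ge,
    LEGE = ifelse(ge > 0, le / ge, 0)
  )
}

#' Degree-preserving random reference graph
#'
#' Maslov-Sneppen double-edge swaps with weights carried along the swapped
#' edges; swaps creating self-loops, multi-edges, or disconnecting the
#' graph are rejected. The degree sequence and the weight multiset are
#' preserved exactly.
#'
#' @param g A connected `sparse_graph`.
#' @param seed Integer seed.
#' @param n_swaps_per_edge Attempted swaps per edge (default 10).
#' @return A `sparse_graph` with identical degree sequence.
#' @export
random_reference <- function(g, seed = 1, n_swaps_per_edge = 10) {
  w <- g$weights
  n <- nrow(w)
  with_seed(seed, {
    edges <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
    wts <- w[edges]
    m <- nrow(edges)
    adj <- w
    for (att in seq_len(n_swaps_per_edge * m)) {
      ab <- sample.int(m, 2L)
      e1 <- edges[ab[1L], ]; e2 <- edges[ab[2L], ]
      a <- e1[1L]; b <- e1[2L]; c <- e2[1L]; d <- e2[2L]
      if (stats::runif(1) < 0.5) { tmp <- c; c <- d; d <- tmp }
      # propose (a-d), (c-b)
      if (a == d || c == b) next
      if (adj[a, d] > 0 || adj[c, b] > 0) next
      w1 <- adj[a, b]; w2 <- adj[c, d]
      adj[a, b] <- 0; adj[b, a] <- 0
      adj[c, d] <- 0; adj[d, c] <- 0
      adj[a, d] <- w1; adj[d, a] <- w1
      adj[c, b] <- w2; adj[b, c] <- w2
      if (!adjacency_connected(adj)) {
        adj[a, d] <- 0; adj[d, a] <- 0
        adj[c, b] <- 0; adj[b, c] <- 0
        adj[a, b] <- w1; adj[b, a] <- w1
        adj[c, d] <- w2; adj[d, c] <- w2
        next
      }
      edges[ab[1L], ] <- c(min(a, d), max(a, d))
      edges[ab[2L], ] <- c(min(c, b), max(c, b))
    }
    dimnames(adj) <- dimnames(w)
    new_sparse_graph(adj, g$n_edges, g$density, flagged = FALSE)
  })
}

#' Small-world index against reference graphs
#'
#' SWI = (CC / mean reference CC) / (PL / mean reference PL): normalised
#' clustering over normalised path length. A value above 1 indicates
#' small-world organisation (lattice-like clustering with random-like path
#' length).
#'
#' @param g A connected `sparse_graph`.
#' @param references List of reference `sparse_graph`s (>= 1), e.g. from
#'   [random_reference()].
#' @return Scalar SWI.
#' @export
small_world_index <- function(g, references) {
  if (length(references) < 1) abort("at least 1 reference is required.")
  cc_r <- mean(vapply(references, clustering_coefficient, numeric(1)))
  pl_r <- mean(vapply(references, path_length, numeric(1)))
  if (cc_r == 0) abort("reference clustering is zero.",
                       class = "brainmod_degenerate_reference")
  (clustering_coefficient(g) / cc_r) / (path_length(g) / pl_r)
}

#' Whole-brain metrics at one threshold
#'
#' @param conn Penalized-stage `connectivity_matrix`.
#' @param density Edge density for [threshold_graph()].
#' @param n_ref Number of random references for normalisation (0 skips
#'   normalisation; `PLn`, `CCn`, `SWI` are then `NA`).
#' @param seed Integer seed for the reference ensemble.
#' @return One-row tibble: `threshold`, `PL`, `CC`, `GE`, `LE`, `PLn`,
#'   `CCn`, `SWI`.
#' @export
global_metrics <- function(conn, density = 0.12, n_ref = 20, seed = 1) {
  g <- threshold_graph(conn, density)
  pl <- path_length(g)
  cc <- clustering_coefficient(g)
  pl_n <- cc_n <- swi <- NA_real_
  if (n_ref > 0) {
    refs <- purrr::map(seq_len(n_ref),
                       ~ random_reference(g, seed = derive_seed(seed, .x)))
    cc_r <- mean(vapply(refs, clustering_coefficient, numeric(1)))
    pl_r <- mean(vapply(refs, path_length, numeric(1)))
    if (cc_r == 0) abort("reference clustering is zero.",
                         class = "brainmod_degenerate_reference")
    pl_n <- pl / pl_r
    cc_n <- cc / cc_r
    swi <- cc_n / pl_n
  }
  tibble::tibble(threshold = density, PL = pl, CC = cc,
                 GE = global_efficiency(g), LE = local_efficiency(g),
                 PLn = pl_n, CCn = cc_n, SWI = swi)
}

#' Metrics across a grid of thresholds
#'
#' Computes [global_metrics()] across a density grid (default 10\% to 35\%
#' in 1\% increments, 26 points).
#'
#' @inheritParams global_metrics
#' @param thresholds Numeric vector of densities in (0, 1\].
#' @return A tibble of class `metric_curve`, one row per threshold.
#' @export
metric_threshold_curve <- function(conn, thresholds = seq(0.10, 0.35,
                                                          by = 0.01),
                                   n_ref = 20, seed = 1) {
  if (any(thresholds <= 0 | thresholds > 1)) {
    abort("`thresholds` must lie in (0, 1].")
  }
  out <- purrr::map_dfr(seq_along(thresholds), function(i) {
    global_metrics(conn, density = thresholds[i], n_ref = n_ref,
                   seed = derive_seed(seed, i))
  })
  class(out) <- c("metric_curve", class(out))
  out
}

#' Area under a metric-threshold curve
#'
#' Trapezoidal area of one metric over the threshold axis, pooling the
#' whole sweep into a single quantity per subject. Thresholds are sorted
#' internally.
#'
#' @param curve A [metric_threshold_curve()] tibble (or any data frame with
#'   a `threshold` column).
#' @param metric Name of the metric column (default `"PL"`).
#' @return Scalar area.
#' @export
curve_auc <- function(curve, metric = "PL") {
  if (nrow(curve) < 2) abort("at least 2 curve points are required.")
  ord <- order(curve$threshold)
  x <- curve$threshold[ord]
  y <- curve[[metric]][ord]
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}
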