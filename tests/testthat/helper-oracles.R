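# Independent oracles and fixture builders used across the suite. These
# deliberately avoid the package's own code paths (and igraph) so that
# agreement is a genuine cross-check.

# All set partitions of n elements as restricted-growth strings.
all_set_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, maxv) {
    if (length(prefix) == n) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    for (v in seq_len(maxv + 1L)) rec(c(prefix, v), max(maxv, v))
  }
  rec(1L, 1L)
  do.call(rbind, out)
}

# Exhaustive maximum of a partition-quality function over all partitions.
exhaustive_best_q <- function(w, qfun, partitions) {
  qs <- apply(partitions, 1, function(p) qfun(w, p))
  list(q = max(qs), assignment = partitions[which.max(qs), ])
}

# Floyd-Warshall all-pairs shortest paths on a length matrix (Inf where no
# edge), independent of igraph.
floyd_warshall <- function(len) {
  n <- nrow(len)
  d <- len
  diag(d) <- 0
  for (k in seq_len(n)) {
    dk <- outer(d[, k], d[k, ], "+")
    d <- pmin(d, dk)
  }
  d
}

length_matrix <- function(w) {
  len <- 1 / w
  len[w == 0] <- Inf
  diag(len) <- Inf
  len
}

# Brute-force betweenness: enumerate all shortest paths per pair by DFS
# (pruned with Floyd-Warshall distances), split multiplicities evenly.
brute_betweenness <- function(w, tol = 1e-9) {
  n <- nrow(w)
  len <- length_matrix(w)
  d <- floyd_warshall(len)
  bc <- numeric(n)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    if (!is.finite(d[s, t])) next
    paths <- list()
    dfs <- function(v, visited, dist) {
      if (v == t) {
        if (abs(dist - d[s, t]) < tol) paths[[length(paths) + 1L]] <<- visited
        return(invisible())
      }
      for (u in which(w[v, ] > 0)) {
        if (u %in% visited) next
        nd <- dist + len[v, u]
        if (nd + d[u, t] > d[s, t] + tol) next
        dfs(u, c(visited, u), nd)
      }
    }
    dfs(s, s, 0)
    npaths <- length(paths)
    for (pth in paths) {
      interior <- setdiff(pth, c(s, t))
      bc[interior] <- bc[interior] + 1 / npaths
    }
  }
  bc
}

brute_global_efficiency <- function(w) {
  d <- floyd_warshall(length_matrix(w))
  inv <- 1 / d
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  mean(inv[upper.tri(inv)])
}

brute_path_length <- function(w) {
  d <- floyd_warshall(length_matrix(w))
  mean(d[upper.tri(d)])
}

# Onnela weighted clustering by explicit triangle loops.
brute_onnela <- function(w) {
  n <- nrow(w)
  wh <- (w / max(w))^(1 / 3)
  cc <- numeric(n)
  for (i in seq_len(n)) {
    k <- sum(w[i, ] > 0)
    if (k < 2) next
    acc <- 0
    for (j in seq_len(n)) for (h in seq_len(n)) {
      acc <- acc + wh[i, j] * wh[j, h] * wh[h, i]
    }
    cc[i] <- acc / (k * (k - 1))
  }
  cc
}

# Independent mutual information (nats) from a contingency table.
indep_mi <- function(x, y) {
  tab <- table(x, y)
  p <- tab / sum(tab)
  px <- rowSums(p)
  py <- colSums(p)
  mi <- 0
  for (a in seq_len(nrow(p))) for (b in seq_len(ncol(p))) {
    if (p[a, b] > 0) mi <- mi + p[a, b] * log(p[a, b] / (px[a] * py[b]))
  }
  as.numeric(mi)
}

# Independent greedy mutual-information-difference ranking on
# pre-discretised integer features.
indep_mid_order <- function(d, y, n_select) {
  p <- ncol(d)
  rel <- vapply(seq_len(p), function(j) indep_mi(d[, j], y), numeric(1))
  sel <- integer(0)
  for (k in seq_len(n_select)) {
    crit <- vapply(seq_len(p), function(j) {
      if (j %in% sel) return(-Inf)
      red <- if (length(sel) == 0) 0 else
        mean(vapply(sel, function(s) indep_mi(d[, j], d[, s]), numeric(1)))
      rel[j] - red
    }, numeric(1))
    sel <- c(sel, which.max(crit))
  }
  sel
}

# Random connected weighted graph as a sparse_graph-compatible fixture.
random_connected_graph <- function(n, p_edge = 0.45, seed = 1) {
  set.seed(seed)
  repeat {
    w <- matrix(0, n, n)
    ut <- upper.tri(w)
    on <- stats::runif(sum(ut)) < p_edge
    w[ut][on] <- stats::runif(sum(on), 0.2, 1)
    w <- w + t(w)
    # connectivity via reachability of the boolean adjacency
    reach <- (w > 0) | diag(n) > 0
    for (k in seq_len(n)) reach <- reach | (reach %*% reach > 0)
    if (all(reach)) break
    seed <- seed + 1000
    set.seed(seed)
  }
  list(weights = w, density = mean(w[ut] > 0), n_edges = sum(w[ut] > 0),
       target_density = NA, min_connected = FALSE)
}

graph_from_weights <- function(w) {
  list(weights = w, density = NA, n_edges = sum(w[upper.tri(w)] > 0),
       target_density = NA, min_connected = FALSE)
}

# Small default-structured cohort for fast end-to-end tests.
tiny_cohort <- function(seed = 1, n_control = 5, n_patient = 5,
                        n_regions = 20, n_timepoints = 120,
                        k_modules = 3, n_down = 3, n_up = 2,
                        effect_size = 0.35) {
  simulate_cohort(n_control = n_control, n_patient = n_patient,
                  n_regions = n_regions, n_timepoints = n_timepoints,
                  k_modules = k_modules, n_down = n_down, n_up = n_up,
                  effect_size = effect_size, seed = seed)
}

# Independent greedy threshold simulation (ascending removal, bridge
# retention) using naive reachability, for small graphs only.
naive_threshold <- function(w, density) {
  n <- nrow(w)
  w[w < 0] <- 0
  diag(w) <- 0
  target <- floor(density * n * (n - 1) / 2 + 0.5)
  connected <- function(a) {
    reach <- (a > 0) | diag(n) > 0
    for (k in seq_len(n)) reach <- reach | (reach %*% reach > 0)
    all(reach)
  }
  repeat {
    m <- sum(w[upper.tri(w)] > 0)
    if (m <= target) break
    cand <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
    ord <- order(w[cand])
    removed <- FALSE
    for (k in ord) {
      i <- cand[k, 1]; j <- cand[k, 2]
      keep <- w[i, j]
      w[i, j] <- 0; w[j, i] <- 0
      if (connected(w)) { removed <- TRUE; break }
      w[i, j] <- keep; w[j, i] <- keep
    }
    if (!removed) break
  }
  w
}

# Independent connectivity check via boolean reachability closure.
adjacency_connected_oracle <- function(w) {
  n <- nrow(w)
  reach <- (w > 0) | diag(n) > 0
  for (k in seq_len(ceiling(log2(max(n, 2))) + 1)) {
    reach <- (reach %*% reach) > 0
  }
  all(reach)
}

# Thin accessors for internal helpers used in assertions.
brainmod_test_ari <- function(a, b) {
  e1071::classAgreement(table(a, b))$crand
}
derive_seed_test <- function(seed, k) brainmod:::derive_seed(seed, k)
pi_shares_for_test <- function(w, assignment) {
  brainmod:::pi_from_weights(w, assignment)
}
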