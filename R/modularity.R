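#' Signed modularity of a partition
#'
#' Asymmetric signed modularity: positive weights are scored at full
#' strength while the negative-weight term is down-weighted by
#' `v- / (v+ + v-)`, where `v+` and `v-` are the total positive and negative
#' weight. Positive weights should lie within modules; negative weights
#' delineate module boundaries. Operates on the full signed matrix — no
#' thresholding is required or expected.
#'
#' @param w Symmetric signed matrix (zero diagonal assumed).
#' @param assignment Integer module labels per node.
#' @return Scalar Q (at most 1).
#' @export
signed_modularity <- function(w, assignment) {
  w <- as.matrix(w)
  diag(w) <- 0
  wp <- pmax(w, 0); wn <- pmax(-w, 0)
  vp <- sum(wp); vn <- sum(wn)
  if (vp + vn == 0) {
    abort("all-zero matrix has no modular structure.",
          class = "brainmod_degenerate_graph")
  }
  delta <- outer(assignment, assignment, "==")
  qp <- if (vp > 0) {
    sp <- rowSums(wp)
    sum((wp - sp %o% sp / vp)[delta]) / vp
  } else 0
  qn <- if (vn > 0) {
    sn <- rowSums(wn)
    sum((wn - sn %o% sn / vn)[delta]) / vn
  } else 0
  qp - vn / (vp + vn) * qn
}

# Signed modularity matrix B: Q(partition) = sum of B over within-module
# pairs (diagonal included; it is partition-independent).
signed_modularity_matrix <- function(w) {
  w <- as.matrix(w)
  diag(w) <- 0
  wp <- pmax(w, 0); wn <- pmax(-w, 0)
  vp <- sum(wp); vn <- sum(wn)
  if (vp + vn == 0) {
    abort("all-zero matrix has no modular structure.",
          class = "brainmod_degenerate_graph")
  }
  b <- 0
  if (vp > 0) {
    sp <- rowSums(wp)
    b <- (wp - sp %o% sp / vp) / vp
  }
  if (vn > 0) {
    sn <- rowSums(wn)
    b <- b - (wn - sn %o% sn / vn) / (vp + vn)
  }
  b
}

# One full generalized-Louvain pass over modularity matrix `b`:
# local moving + aggregation, recursively, followed by a node-level
# refinement sweep. Returns an integer assignment.
louvain_on_b <- function(b, seed = 1L) {
  n <- nrow(b)
  with_seed(seed, {
    comm <- louvain_recurse(b)
    comm <- local_move(b, comm)
    relabel_partition(comm)
  })
}

louvain_recurse <- function(b) {
  n <- nrow(b)
  comm <- local_move(b, seq_len(n))
  k <- length(unique(comm))
  if (k == n || k == 1L) return(comm)
  s <- outer(comm, sort(unique(comm)), "==") * 1
  b2 <- t(s) %*% b %*% s
  upper <- louvain_recurse(b2)
  upper[comm]
}

# Repeated single-node best-move sweeps until no move improves the
# objective sum(B within communities). Self-terms excluded (constant).
local_move <- function(b, comm) {
  n <- nrow(b)
  comm <- relabel_partition(comm)
  repeat {
    improved <- FALSE
    for (i in sample.int(n)) {
      bi <- b[, i]
      bi[i] <- 0
      gains <- rowsum(bi, comm)
      labs <- as.integer(rownames(gains))
      cur <- which(labs == comm[i])
      best <- which.max(gains)
      if (gains[best] > gains[cur] + 1e-13) {
        comm[i] <- labs[best]
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  relabel_partition(comm)
}

new_partition <- function(assignment, q, names = NULL) {
  assignment <- relabel_partition(assignment)
  if (!is.null(names)) names(assignment) <- names
  structure(list(assignment = assignment,
                 K = length(unique(assignment)), Q = q),
            class = "brain_partition")
}

#' @export
print.brain_partition <- function(x, ...) {
  cat(sprintf("<brain_partition> %d nodes in %d modules, Q = %.4f\n",
              length(x$assignment), x$K, x$Q))
  invisible(x)
}

#' Detect community structure of a signed connectivity matrix
#'
#' Louvain-style greedy optimization of the asymmetric signed modularity on
#' the full (unthresholded) matrix. The number of modules is chosen by the
#' objective itself unless `k_target` is given, in which case the partition
#' is repaired to exactly `k_target` modules: excess modules are merged
#' pairwise at minimal Q cost; missing modules are created by spectrally
#' bisecting the largest module.
#'
#' @param conn Penalized-stage `connectivity_matrix` (or symmetric signed
#'   matrix).
#' @param seed Integer seed controlling node visit order.
#' @param k_target Optional exact module count.
#' @return A `brain_partition`: `assignment`, `K`, `Q`.
#' @export
signed_modularity_partition <- function(conn, seed = 1, k_target = NULL) {
  w <- if (inherits(conn, "connectivity_matrix")) conn_weights(conn) else
    as.matrix(conn)
  check_symmetric(w, tol = 1e-8, arg = "conn")
  b <- signed_modularity_matrix(w)
  comm <- louvain_on_b(b, seed = seed)
  if (!is.null(k_target)) comm <- enforce_k(b, comm, k_target)
  new_partition(comm, signed_modularity(w, comm), names = colnames(w))
}

# Repair a partition to exactly k modules on modularity matrix b.
enforce_k <- function(b, comm, k_target) {
  comm <- relabel_partition(comm)
  k <- max(comm)
  while (k > k_target) {
    s <- outer(comm, seq_len(k), "==") * 1
    agg <- t(s) %*% b %*% s
    diag(agg) <- -Inf
    best <- arrayInd(which.max(agg), dim(agg))
    comm[comm == best[2]] <- best[1]
    comm <- relabel_partition(comm)
    k <- max(comm)
  }
  while (k < k_target) {
    sizes <- tabulate(comm)
    target <- which.max(sizes)
    idx <- which(comm == target)
    sub <- b[idx, idx, drop = FALSE]
    half <- spectral_bisect(sub)
    comm[idx[half]] <- k + 1L
    comm <- relabel_partition(comm)
    k <- max(comm)
  }
  comm
}

# Split indices of a modularity submatrix into two groups by the leading
# eigenvector; falls back to a median split when the eigenvector does not
# change sign.
spectral_bisect <- function(sub) {
  n <- nrow(sub)
  if (n < 2L) abort("cannot split a single-node module.")
  v <- eigen(sub, symmetric = TRUE)$vectors[, 1]
  half <- which(v > 0)
  if (length(half) == 0L || length(half) == n) {
    half <- order(v)[seq_len(floor(n / 2))]
  }
  half
}

#' Best signed-modularity partition over random restarts
#'
#' Runs [signed_modularity_partition()] `n_restarts` times with derived
#' seeds and returns the partition with the highest Q. With `k_target`, the
#' best restart that naturally produced exactly `k_target` modules is
#' preferred; if none did, the overall best restart is repaired to
#' `k_target`.
#'
#' @inheritParams signed_modularity_partition
#' @param n_restarts Number of restarts (>= 1).
#' @return A `brain_partition`.
#' @export
best_partition <- function(conn, n_restarts = 20, seed = 1,
                           k_target = NULL) {
  if (n_restarts < 1) abort("`n_restarts` must be at least 1.")
  w <- if (inherits(conn, "connectivity_matrix")) conn_weights(conn) else
    as.matrix(conn)
  check_symmetric(w, tol = 1e-8, arg = "conn")
  b <- signed_modularity_matrix(w)
  runs <- purrr::map(seq_len(n_restarts), function(r) {
    comm <- louvain_on_b(b, seed = derive_seed(seed, r))
    list(comm = comm, q = signed_modularity(w, comm),
         k = length(unique(comm)))
  })
  pick_from <- runs
  if (!is.null(k_target)) {
    exact <- purrr::keep(runs, ~ .x$k == k_target)
    if (length(exact) > 0L) {
      pick_from <- exact
    } else {
      pick_from <- purrr::map(runs, function(r) {
        comm <- enforce_k(b, r$comm, k_target)
        list(comm = comm, q = signed_modularity(w, comm), k = k_target)
      })
    }
  }
  qs <- vapply(pick_from, function(r) r$q, numeric(1))
  best <- pick_from[[which.max(qs)]]
  new_partition(best$comm, best$q, names = colnames(w))
}

# Participation from a nonnegative weight matrix and a module assignment:
# PI_i = 1 - sum_m (s_im / s_i)^2.
pi_from_weights <- function(w, assignment) {
  s <- rowSums(w)
  if (any(s <= 0)) {
    abort("participation is undefined for isolated nodes.",
          class = "brainmod_undefined_pi")
  }
  mods <- sort(unique(assignment))
  sm <- w %*% outer(assignment, mods, "==")
  as.numeric(1 - rowSums((sm / s)^2))
}

#' Participation index of each node
#'
#' PI quantifies how a node's connection strength distributes over modules:
#' 0 when all strength stays within the node's own module, approaching 1
#' for an even spread across modules ("connector" nodes). Computed on the
#' thresholded nonnegative graph.
#'
#' @param g A connected [threshold_graph()] result.
#' @param partition A `brain_partition` (or integer assignment) covering
#'   the graph's nodes.
#' @return A tibble of class `pi_vector`: `node`, `region`, `pi`, and
#'   within-subject ascending `rank` (rank 1 = lowest PI; average ranks for
#'   ties).
#' @export
participation_index <- function(g, partition) {
  assignment <- if (inherits(partition, "brain_partition")) {
    partition$assignment
  } else as.integer(partition)
  w <- g$weights
  if (length(assignment) != nrow(w)) {
    abort("partition does not cover the graph's nodes.")
  }
  pi <- pi_from_weights(w, assignment)
  out <- tibble::tibble(
    node = seq_along(pi),
    region = colnames(w) %||% as.character(seq_along(pi)),
    pi = pi, rank = rank_pi(pi)
  )
  class(out) <- c("pi_vector", class(out))
  out
}

#' Rank participation values within a subject
#'
#' Ascending ranks (1 = lowest PI, N = highest); ties get the average of
#' their rank positions. Ranking removes inter-subject scale variance
#' before group comparison.
#'
#' @param pi Numeric vector of participation values.
#' @return Numeric vector of ranks summing to N(N+1)/2.
#' @export
rank_pi <- function(pi) {
  rank(pi, ties.method = "average")
}

#' Group-consensus partition across subjects
#'
#' A single module assignment shared by all subjects, obtained by iterative
#' consensus clustering: each subject's best partition contributes to a
#' node-by-node co-assignment matrix weighted by that subject's Q (a
#' subject with Q <= 0 contributes nothing); the co-assignment matrix,
#' centred on its mean off-diagonal agreement, is itself re-partitioned
#' repeatedly until all restarts agree (the matrix has become effectively
#' binary) or the partition is stable across two iterations. The final
#' partition is constrained to `k_target` modules.
#'
#' @param conns List of penalized-stage `connectivity_matrix` objects, one
#'   per subject.
#' @param k_target Exact module count of the consensus (>= 2).
#' @param seed Integer seed.
#' @param n_restarts Restarts per subject and per consensus iteration.
#' @param max_iter Maximum consensus iterations.
#' @return A `brain_partition` with attributes `iterations` (consensus
#'   iterations used) and `subject_q` (per-subject Q under the consensus
#'   assignment); its own `Q` is the mean subject Q.
#' @export
group_consensus_partition <- function(conns, k_target = 5, seed = 1,
                                      n_restarts = 10, max_iter = 20) {
  if (length(conns) < 2) abort("at least 2 subjects are required.")
  if (k_target < 2) abort("`k_target` must be at least 2.")
  ws <- purrr::map(conns, function(cc) {
    if (inherits(cc, "connectivity_matrix")) conn_weights(cc) else
      as.matrix(cc)
  })
  n <- nrow(ws[[1]])
  # One shared seed: each subject's partitions depend only on its matrix,
  # so the consensus is equivariant under subject relabelling.
  parts <- purrr::map(ws, function(w) {
    best_partition(w, n_restarts = n_restarts,
                   seed = derive_seed(seed, 50L))
  })
  qw <- pmax(vapply(parts, function(p) p$Q, numeric(1)), 0)
  if (sum(qw) == 0) abort("no subject has positive modularity.",
                          class = "brainmod_degenerate_graph")
  co <- matrix(0, n, n)
  for (i in seq_along(parts)) {
    a <- parts[[i]]$assignment
    co <- co + qw[i] * outer(a, a, "==")
  }
  co <- co / sum(qw)

  iterations <- 0L
  final <- NULL
  for (iter in seq_len(max_iter)) {
    iterations <- iter
    cb <- co - mean(co[upper.tri(co)])
    diag(cb) <- 0
    runs <- purrr::map(seq_len(n_restarts), function(r) {
      louvain_on_b(signed_modularity_matrix(cb),
                   seed = derive_seed(seed, 500L + iter * 37L + r))
    })
    canon <- purrr::map(runs, relabel_partition)
    agree <- all(vapply(canon[-1], identical, logical(1), canon[[1]]))
    if (agree) {
      final <- canon[[1]]
      break
    }
    co_new <- matrix(0, n, n)
    for (a in canon) co_new <- co_new + outer(a, a, "==")
    co_new <- co_new / length(canon)
    if (isTRUE(all.equal(co_new, co, tolerance = 1e-12))) {
      qs <- vapply(canon, function(a) signed_modularity(cb, a), numeric(1))
      final <- canon[[which.max(qs)]]
      break
    }
    co <- co_new
  }
  if (is.null(final)) {
    warn("consensus did not converge; returning best partition so far.")
    cb <- co - mean(co[upper.tri(co)])
    diag(cb) <- 0
    final <- louvain_on_b(signed_modularity_matrix(cb),
                          seed = derive_seed(seed, 999L))
  }
  cb <- co - mean(co[upper.tri(co)])
  diag(cb) <- 0
  final <- enforce_k(signed_modularity_matrix(cb), final, k_target)
  subject_q <- vapply(ws, function(w) signed_modularity(w, final),
                      numeric(1))
  out <- new_partition(final, mean(subject_q), names = colnames(ws[[1]]))
  attr(out, "iterations") <- iterations
  attr(out, "subject_q") <- subject_q
  out
}
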