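# Internal helpers shared across modules.

#' @importFrom rlang abort warn
NULL

# round() in R is banker's rounding; edge-count targets use the conventional
# half-away-from-zero rule.
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# Derive a child seed from a root seed; stays within 32-bit integer range.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 1103 * as.numeric(k)) %% 2147483647L)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Connectivity of an undirected graph given a symmetric nonneg adjacency
# matrix; vectorised BFS frontier expansion.
adjacency_connected <- function(adj) {
  n <- nrow(adj)
  if (n == 0L) return(TRUE)
  reached <- logical(n)
  reached[1L] <- TRUE
  frontier <- 1L
  while (length(frontier)) {
    hit <- if (length(frontier) == 1L) adj[frontier, ] > 0 else
      colSums(adj[frontier, , drop = FALSE]) > 0
    nxt <- which(hit & !reached)
    reached[nxt] <- TRUE
    frontier <- nxt
  }
  all(reached)
}

# Are nodes u and v connected in `adj`? Early-exit BFS from u.
nodes_connected <- function(adj, u, v) {
  n <- nrow(adj)
  reached <- logical(n)
  reached[u] <- TRUE
  frontier <- u
  while (length(frontier)) {
    hit <- if (length(frontier) == 1L) adj[frontier, ] > 0 else
      colSums(adj[frontier, , drop = FALSE]) > 0
    nxt <- which(hit & !reached)
    if (any(nxt == v)) return(TRUE)
    reached[nxt] <- TRUE
    frontier <- nxt
  }
  FALSE
}

check_symmetric <- function(m, tol = 1e-8, arg = "matrix") {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    abort(sprintf("`%s` must be a square matrix.", arg))
  }
  if (max(abs(m - t(m))) > tol) {
    abort(sprintf("`%s` must be symmetric (tolerance %g).", arg, tol))
  }
  invisible(m)
}

# Adjusted Rand index between two labellings (wraps e1071's crand).
adjusted_rand <- function(a, b) {
  e1071::classAgreement(table(a, b))$crand
}

# Relabel an assignment vector so module labels are contiguous 1..K in order
# of first appearance.
relabel_partition <- function(assignment) {
  as.integer(match(assignment, unique(assignment)))
}
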