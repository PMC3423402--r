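unit_graph <- function(edges, n) {
  w <- matrix(0, n, n)
  for (e in edges) { w[e[1], e[2]] <- w[e[2], e[1]] <- 1 }
  graph_from_weights(w)
}

test_that("path length and efficiency match enumerated toy values", {
  tri <- unit_graph(list(c(1, 2), c(2, 3), c(1, 3)), 3)
  expect_equal(path_length(tri), 1)
  expect_equal(global_efficiency(tri), 1)

  chain <- unit_graph(list(c(1, 2), c(2, 3)), 3)
  expect_equal(path_length(chain), 4 / 3)       # pairs: 1, 1, 2
  expect_equal(global_efficiency(chain), 5 / 6) # inverses: 1, 1, 1/2
})

test_that("shortest-path metrics agree with brute-force enumeration", {
  for (seed in 1:8) {
    g <- random_connected_graph(9, p_edge = 0.4, seed = seed)
    expect_equal(path_length(g), brute_path_length(g$weights),
                 tolerance = 1e-9)
    expect_equal(global_efficiency(g),
                 brute_global_efficiency(g$weights), tolerance = 1e-9)
    expect_equal(betweenness_centrality(g), brute_betweenness(g$weights),
                 tolerance = 1e-9)
    expect_equal(clustering_coefficient(g, nodal = TRUE),
                 brute_onnela(g$weights), tolerance = 1e-9)
  }
})

test_that("clustering scores cliques and stars at the extremes", {
  k5 <- unit_graph(utils::combn(5, 2, simplify = FALSE), 5)
  expect_equal(clustering_coefficient(k5), 1)
  star <- unit_graph(list(c(1, 2), c(1, 3), c(1, 4), c(1, 5)), 5)
  expect_equal(clustering_coefficient(star), 0)
  # 4-node toy with mixed weights against the hand triangle formula
  w <- matrix(0, 4, 4)
  w[1, 2] <- 0.8; w[2, 3] <- 0.4; w[1, 3] <- 0.6; w[3, 4] <- 0.2
  w <- w + t(w)
  wh <- (w / 0.8)^(1 / 3)
  c1 <- (2 * wh[1, 2] * wh[2, 3] * wh[3, 1]) / (2 * 1)
  got <- clustering_coefficient(graph_from_weights(w), nodal = TRUE)
  expect_equal(got[1], c1, tolerance = 1e-12)
  expect_equal(got[4], 0)
})

test_that("betweenness counts pair routes through hubs and leaves", {
  chain <- unit_graph(list(c(1, 2), c(2, 3)), 3)
  expect_equal(betweenness_centrality(chain), c(0, 1, 0))
  star <- unit_graph(list(c(1, 2), c(1, 3), c(1, 4), c(1, 5)), 5)
  expect_equal(betweenness_centrality(star), c(6, 0, 0, 0, 0))
})

test_that("local efficiency follows the neighbourhood-subgraph definition", {
  # node 1's neighbours {2,3} are connected: subgraph efficiency 1
  g <- unit_graph(list(c(1, 2), c(1, 3), c(2, 3)), 3)
  expect_equal(local_efficiency(g, nodal = TRUE), rep(1, 3))
  star <- unit_graph(list(c(1, 2), c(1, 3)), 3)
  # hub's neighbours are not mutually connected; leaves have one neighbour
  expect_equal(local_efficiency(star, nodal = TRUE), c(0, 0, 0))
})

test_that("random references preserve degrees and weights but break cliques", {
  # weighted ring lattice, each node tied to 2 neighbours per side
  n <- 16
  w <- matrix(0, n, n)
  for (i in seq_len(n)) for (s in 1:2) {
    j <- ((i + s - 1) %% n) + 1
    w[i, j] <- w[j, i] <- 1 + 0.01 * ((i + j) %% 5)
  }
  g <- graph_from_weights(w)
  refs <- lapply(1:20, function(s) random_reference(g, seed = s))
  for (r in refs[1:3]) {
    expect_equal(rowSums(r$weights > 0), rowSums(w > 0),
                 ignore_attr = TRUE)
    expect_equal(sort(r$weights[upper.tri(r$weights) & r$weights > 0]),
                 sort(w[upper.tri(w) & w > 0]))
    expect_true(adjacency_connected_oracle(r$weights))
  }
  cc_refs <- mean(vapply(refs, clustering_coefficient, numeric(1)))
  expect_lt(cc_refs, clustering_coefficient(g))
  expect_gt(small_world_index(g, refs), 1)
})

test_that("small-world index is 1 against the graph itself and consistent", {
  g <- random_connected_graph(10, p_edge = 0.5, seed = 3)
  expect_equal(small_world_index(g, list(g, g)), 1)
  gm <- global_metrics(g$weights, density = 1, n_ref = 5, seed = 2)
  expect_equal(gm$SWI, gm$CCn / gm$PLn, tolerance = 1e-12)
})

test_that("threshold curves have the expected grid and reduce to one call", {
  co <- tiny_cohort(seed = 12, n_control = 2, n_patient = 2,
                    n_regions = 14, n_timepoints = 80, n_down = 1,
                    n_up = 1)
  conn <- compute_correlation(co$subjects[[1]])
  pen <- apply_distance_penalty(conn,
                                fit_distance_trend(conn, co$parcellation),
                                co$parcellation)
  expect_length(seq(0.10, 0.35, by = 0.01), 26)  # default sweep size
  cv <- metric_threshold_curve(pen, thresholds = c(0.3, 0.5), n_ref = 0,
                               seed = 5)
  expect_equal(nrow(cv), 2)
  single <- global_metrics(pen, density = 0.3, n_ref = 0, seed = 1)
  expect_equal(cv$PL[1], single$PL)
  expect_equal(cv$CC[1], single$CC)
})

test_that("curve areas match closed forms and the midpoint rule", {
  flat <- tibble::tibble(threshold = seq(0.10, 0.35, by = 0.01), PL = 2)
  expect_equal(curve_auc(flat, "PL"), 0.25 * 2)
  lin <- tibble::tibble(threshold = c(0, 1), PL = c(0, 1))
  expect_equal(curve_auc(lin, "PL"), 0.5)
  set.seed(4)
  thr <- seq(0.1, 0.35, by = 0.05)
  y <- runif(length(thr))
  curve <- tibble::tibble(threshold = sample(thr), PL = 0)
  curve$PL <- y[match(curve$threshold, thr)]  # unsorted input
  trap <- curve_auc(curve, "PL")
  mid <- sum(diff(thr) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  expect_equal(trap, mid)
})
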