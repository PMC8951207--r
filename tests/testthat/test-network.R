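k_graph <- function(n) matrix(1, n, n) - diag(n)
path4 <- function() {
  A <- matrix(0, 4, 4)
  A[cbind(1:3, 2:4)] <- 1
  A + t(A)
}
ring_graph <- function(n) {
  A <- matrix(0, n, n)
  A[cbind(seq_len(n), c(seq_len(n - 1) + 1, 1))] <- 1
  A + t(A)
}

test_that("the default sparsity grid has exactly 36 strictly increasing levels", {
  g <- sparsity_grid()
  expect_length(g, 36)
  expect_equal(g[1], 0.05)
  expect_equal(g[36], 0.40)
  expect_true(all(diff(g) > 0))
})

test_that("proportional thresholding keeps round(S*N(N-1)/2) edges with deterministic ties", {
  set.seed(3)
  w <- random_weight_matrix(20)
  A <- binarize_by_sparsity(w, 0.05)
  expect_equal(sum(A) / 2, 10)  # round(0.05 * 190)
  expect_equal(unclass(A), t(unclass(A)))
  expect_equal(diag(A), rep(0L, 20))
  for (S in c(0.11, 0.2, 0.37)) {
    expect_equal(sum(binarize_by_sparsity(w, S)) / 2, floor(S * 190 + 0.5))
  }
  # the single strongest edge survives the smallest fraction
  top <- which(unclass(w) == max(w), arr.ind = TRUE)[1, ]
  A1 <- binarize_by_sparsity(w, 1 / 190)
  expect_equal(A1[top[1], top[2]], 1L)
  expect_equal(sum(A1) / 2, 1)
  # all-tied weights resolve identically on repeat evaluation
  wt <- matrix(0.5, 6, 6); diag(wt) <- 0
  expect_identical(binarize_by_sparsity(wt, 0.3),
                   binarize_by_sparsity(wt, 0.3))
  expect_error(binarize_by_sparsity(w, 1.2), "sparsity")
  # absolute-threshold mode keeps edges exceeding T
  expect_equal(sum(binarize_by_sparsity(w, 0.9, mode = "absolute")) / 2,
               sum(w[upper.tri(w)] > 0.9))
})

test_that("hand-computed metric values are reproduced exactly", {
  K4 <- k_graph(4)
  expect_equal(as.numeric(characteristic_path_length(K4)), 1)
  expect_equal(clustering_coefficient(K4), 1)
  expect_equal(global_efficiency(K4), 1)
  expect_equal(local_efficiency(K4), 1)

  P4 <- path4()
  expect_equal(as.numeric(characteristic_path_length(P4)), 5 / 3)
  expect_equal(global_efficiency(P4), 13 / 18)

  # star: no triangles, neighbor subgraphs edgeless
  star <- matrix(0, 5, 5); star[1, 2:5] <- 1; star <- star + t(star)
  expect_equal(clustering_coefficient(star), 0)
  expect_equal(local_efficiency(star), 0)

  # triangle plus pendant node: C = (1/3 + 1 + 1 + 0)/4 = 7/12
  tri <- matrix(0, 4, 4)
  tri[cbind(c(1, 1, 2, 1), c(2, 3, 3, 4))] <- 1
  tri <- tri + t(tri)
  expect_equal(clustering_coefficient(tri), 7 / 12)

  # two disconnected dyads: E_global = 2/6 with 1/inf = 0
  dy <- matrix(0, 4, 4); dy[1, 2] <- 1; dy[3, 4] <- 1; dy <- dy + t(dy)
  expect_equal(global_efficiency(dy), 1 / 3)
  lp <- characteristic_path_length(dy)
  expect_true(attr(lp, "fragmented"))
  expect_equal(as.numeric(lp), 1)

  # 20-ring: L_p = 100/19
  expect_equal(as.numeric(characteristic_path_length(ring_graph(20))),
               100 / 19)
  expect_equal(shortest_path_lengths(path4())[1, 4], 3)
  expect_error(characteristic_path_length(matrix(0, 3, 3)), "no edges")
})

test_that("all four metrics match the brute-force Floyd-Warshall oracle on random graphs", {
  set.seed(42)
  for (p in c(0.1, 0.3, 0.5)) {
    for (r in 1:10) {
      A <- random_graph(20, p)
      if (sum(A) == 0) next
      m <- graph_metrics(A)
      o <- oracle_metrics(A)
      expect_equal(as.numeric(m[names(o)]), as.numeric(o), tolerance = 1e-12)
      expect_equal(shortest_path_lengths(A), oracle_distances(A))
    }
  }
})

test_that("metrics agree with igraph on random graphs", {
  skip_if_not_installed("igraph")
  set.seed(17)
  for (r in 1:10) {
    A <- random_graph(20, 0.3)
    g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
    m <- graph_metrics(A)
    expect_equal(unname(m["E_global"]), igraph::global_efficiency(g),
                 tolerance = 1e-12)
    expect_equal(unname(m["C_c"]),
                 igraph::transitivity(g, type = "localaverage",
                                      isolates = "zero"),
                 tolerance = 1e-12)
    expect_equal(unname(m["L_p"]),
                 igraph::mean_distance(g, unconnected = TRUE),
                 tolerance = 1e-12)
  }
})

test_that("adding an edge never increases L_p nor decreases E_global", {
  # stated for connected graphs: with the connected-pairs-only L_p
  # convention, an edge that joins two components adds long finite paths
  # to the average and can raise it
  set.seed(8)
  checked <- 0
  for (r in 1:60) {
    A <- random_graph(12, 0.3)
    if (sum(A) == 0) next
    if (any(is.infinite(shortest_path_lengths(A)))) next
    absent <- which(A == 0 & upper.tri(A))
    if (!length(absent)) next
    checked <- checked + 1
    pick <- sample(absent, 1)
    B <- A
    B[pick] <- 1
    B[lower.tri(B)] <- t(B)[lower.tri(B)]
    expect_lte(as.numeric(characteristic_path_length(B)),
               as.numeric(characteristic_path_length(A)) + 1e-12)
    expect_gte(global_efficiency(B), global_efficiency(A) - 1e-12)
  }
  expect_gte(checked, 10)
  # E_global monotonicity needs no connectedness caveat
  set.seed(9)
  for (r in 1:20) {
    A <- random_graph(12, 0.15)
    absent <- which(A == 0 & upper.tri(A))
    if (!length(absent)) next
    B <- A
    B[sample(absent, 1)] <- 1
    B[lower.tri(B)] <- t(B)[lower.tri(B)]
    expect_gte(global_efficiency(B), global_efficiency(A) - 1e-12)
  }
})

test_that("topology curves cover the grid, flag fragmentation, and hit K20 values at S = 1", {
  set.seed(12)
  w <- random_weight_matrix(20)
  cv <- topology_curves(w)
  expect_equal(nrow(cv), 36 * 4)
  expect_equal(sort(unique(cv$sparsity)), sparsity_grid())
  # 10 edges on 20 nodes always leave isolated nodes
  expect_true(all(cv$fragmented[cv$sparsity == 0.05]))
  # E_global is non-decreasing in S (edges only get added)
  eg <- cv$value[cv$metric == "E_global"][order(cv$sparsity[cv$metric == "E_global"])]
  expect_true(all(diff(eg) >= -1e-12))
  full <- graph_metrics(binarize_by_sparsity(w, 1))
  expect_equal(as.numeric(full), c(1, 1, 1, 1), tolerance = 1e-12)
})
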