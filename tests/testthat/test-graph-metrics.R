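# Topology metrics: worked examples, oracle agreement, structural
# invariants, null-model contracts, small-world identities.

test_that("clustering matches hand-enumerated examples", {
  k4 <- tg_edges(c(1,2, 1,3, 1,4, 2,3, 2,4, 3,4), 4)
  cc <- clustering_coefficient(k4)
  expect_equal(unname(cc$node), rep(1, 4))
  expect_equal(cc$Cp, 1)

  star <- tg_edges(c(1,2, 1,3, 1,4, 1,5), 5)
  expect_equal(clustering_coefficient(star)$Cp, 0)

  tri_pendant <- tg_edges(c(1,2, 2,3, 1,3, 1,4), 4)
  cc <- clustering_coefficient(tri_pendant)
  expect_equal(unname(cc$node), c(1/3, 1, 1, 0))
  expect_equal(cc$Cp, 7/12)
})

test_that("path length uses finite pairs and matches enumeration", {
  k4 <- tg_edges(c(1,2, 1,3, 1,4, 2,3, 2,4, 3,4), 4)
  expect_equal(as.numeric(characteristic_path_length(k4)), 1)

  path4 <- tg_edges(c(1,2, 2,3, 3,4), 4)
  lp <- characteristic_path_length(path4)
  expect_equal(as.numeric(lp), 10/6)
  expect_equal(attr(lp, "n_infinite_pairs"), 0L)

  two_edges <- tg_edges(c(1,2, 3,4), 4)
  lp <- characteristic_path_length(two_edges)
  expect_equal(as.numeric(lp), 1)
  expect_equal(attr(lp, "n_infinite_pairs"), 4L)

  edgeless <- thresholded_graph(matrix(integer(0), ncol = 2), n_nodes = 3)
  expect_error(characteristic_path_length(edgeless), "empty path set")
})

test_that("efficiency matches enumeration, including degenerate graphs", {
  k4 <- tg_edges(c(1,2, 1,3, 1,4, 2,3, 2,4, 3,4), 4)
  ef <- efficiency(k4)
  expect_equal(ef$Eg, 1)
  expect_equal(ef$Eloc, 1)

  path4 <- tg_edges(c(1,2, 2,3, 3,4), 4)
  expect_equal(efficiency(path4)$Eg, 13/18)

  edgeless <- thresholded_graph(matrix(integer(0), ncol = 2), n_nodes = 4)
  ef <- efficiency(edgeless)
  expect_equal(ef$Eg, 0)
  expect_equal(ef$Eloc, 0)
})

test_that("betweenness matches hand-enumerated examples", {
  k4 <- tg_edges(c(1,2, 1,3, 1,4, 2,3, 2,4, 3,4), 4)
  expect_equal(unname(betweenness_centrality(k4)$node), rep(0, 4))

  star <- tg_edges(c(1,2, 1,3, 1,4, 1,5), 5)
  bw <- betweenness_centrality(star)
  expect_equal(unname(bw$node), c(6, 0, 0, 0, 0))
  expect_equal(bw$B, 1.2)

  path3 <- tg_edges(c(1,2, 2,3), 3)
  expect_equal(unname(betweenness_centrality(path3)$node)[2], 1)
})

test_that("metrics agree with the brute-force oracle on random graphs", {
  set.seed(42)
  for (r in 1:60) {
    n <- sample(4:7, 1)
    expect_matches_oracle(random_dense_graph(n))
  }
  for (r in 1:30) {
    n <- sample(5:10, 1)
    expect_matches_oracle(random_dense_graph(n, weighted = TRUE))
  }
})

test_that("adding an edge never increases Lp nor decreases Eg", {
  set.seed(7)
  for (r in 1:25) {
    n <- sample(6:10, 1)
    W <- random_dense_graph(n, p = 0.5)
    g <- igraph::graph_from_adjacency_matrix(W, "undirected")
    if (!igraph::is_connected(g)) next
    absent <- which(upper.tri(W) & W == 0)
    if (!length(absent)) next
    e <- sample(absent, 1)
    ij <- arrayInd(e, dim(W))
    W2 <- W; W2[ij[1], ij[2]] <- 1; W2[ij[2], ij[1]] <- 1
    tg1 <- thresholded_graph_from_dense(W)
    tg2 <- thresholded_graph_from_dense(W2)
    expect_lte(as.numeric(characteristic_path_length(tg2)),
               as.numeric(characteristic_path_length(tg1)))
    expect_gte(efficiency(tg2)$Eg, efficiency(tg1)$Eg)
  }
})

test_that("on trees, total betweenness equals sum over pairs of (d - 1)", {
  set.seed(11)
  for (r in 1:10) {
    n <- sample(5:9, 1)
    g <- igraph::sample_tree(n)
    W <- as.matrix(igraph::as_adjacency_matrix(g))
    tg <- thresholded_graph_from_dense(W)
    D <- oracle_distances(W)
    expect_equal(sum(betweenness_centrality(tg)$node),
                 sum(D[upper.tri(D)] - 1))
  }
})

test_that("rewired nulls preserve the degree sequence exactly", {
  set.seed(3)
  W <- random_dense_graph(12, p = 0.4)
  tg <- thresholded_graph_from_dense(W)
  nulls <- rewire_null(tg, n_rand = 15, seed = 9)
  deg0 <- sort(unname(rowSums(W > 0)))
  for (nl in nulls) {
    A <- adjacency_of(nl)
    expect_identical(sort(unname(rowSums(A > 0))), deg0)
    expect_equal(nrow(nl$edges), nrow(tg$edges))
  }
  # reproducible from the seed
  nulls2 <- rewire_null(tg, n_rand = 15, seed = 9)
  expect_identical(lapply(nulls, `[[`, "edges"), lapply(nulls2, `[[`, "edges"))
})

test_that("a triangle has no alternative rewiring and warns", {
  tri <- tg_edges(c(1,2, 2,3, 1,3), 3)
  expect_warning(nulls <- rewire_null(tri, n_rand = 5, seed = 1),
                 "no valid")
  for (nl in nulls) expect_equal(nrow(nl$edges), 3)
})

test_that("rewiring a ring lattice destroys clustering", {
  g <- igraph::sample_smallworld(1, 50, 3, 0) # pure lattice, k = 6
  W <- as.matrix(igraph::as_adjacency_matrix(g))
  tg <- thresholded_graph_from_dense(W)
  cp0 <- clustering_coefficient(tg)$Cp
  nulls <- rewire_null(tg, n_rand = 20, seed = 4)
  cpn <- mean(vapply(nulls, function(x) clustering_coefficient(x)$Cp,
                     numeric(1)))
  expect_lt(cpn, cp0)
})

test_that("small-world result satisfies its algebraic identities", {
  set.seed(21)
  g <- igraph::sample_smallworld(1, 90, 3, 0.1)
  W <- as.matrix(igraph::as_adjacency_matrix(g))
  tg <- thresholded_graph_from_dense(W)
  sw <- small_worldness(tg, n_rand = 20, seed = 5)
  expect_identical(sw$gamma, sw$Cp / sw$Cprand)
  expect_identical(sw$lambda, sw$Lp / sw$Lprand)
  expect_identical(sw$sigma, sw$gamma / sw$lambda)
  # sigma two ways
  expect_equal(sw$sigma, (sw$Cp * sw$Lprand) / (sw$Cprand * sw$Lp),
               tolerance = 1e-12)
  expect_true(sw$is_small_world)
  expect_gt(sw$sigma, 1)
})

test_that("weighted graphs use 1/weight distances throughout", {
  # path 1 -2- 3 with weights 2 and 0.5: d(1,3) = 1/2 + 2 = 2.5
  tgw <- tg_edges(c(1,2, 2,3), 3, weights = c(2, 0.5))
  expect_equal(as.numeric(characteristic_path_length(tgw)),
               mean(c(0.5, 2, 2.5)))
  ef <- efficiency(tgw)
  expect_equal(ef$Eg, mean(c(1/0.5, 1/2, 1/2.5)))
})
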