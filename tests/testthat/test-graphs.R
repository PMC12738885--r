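test_that("DEG-BRIN weights count shared genes with self-loops of set size", {
  sets <- list(r1 = c("a", "b"), r2 = c("b", "c"), r3 = c("d"))
  g <- build_degbrin(sets)
  expect_equal(g$W["r1", "r2"], 1)
  expect_equal(g$W["r1", "r3"], 0)
  expect_equal(g$W["r2", "r3"], 0)
  expect_equal(unname(diag(g$W)), c(2, 2, 1))

  # identical sets give the complete graph with off-diagonal weight m
  same <- list(r1 = letters[1:4], r2 = letters[1:4], r3 = letters[1:4])
  gs <- build_degbrin(same)
  off <- gs$W[upper.tri(gs$W)]
  expect_true(all(off == 4))
  expect_equal(unname(diag(gs$W)), rep(4, 3))

  expect_error(build_degbrin(list(r1 = "a")), "at least 2")
})

test_that("DEG-BRIN is permutation-equivariant in region order", {
  degs <- std_degs()
  g <- build_degbrin(degs)
  perm <- rev(names(degs$region_sets))
  g2 <- build_degbrin(degs$region_sets[perm], universal = degs$universal)
  expect_equal(g2$W, g$W[perm, perm])
})

test_that("default synthetic study has one node per configured region", {
  degs <- std_degs()
  g <- build_degbrin(degs)
  expect_length(g$nodes, 5)
  expect_true(all(diag(g$W) == lengths(g$region_sets)))
})

test_that("PPI thresholding is inclusive at tau and monotone across tiers", {
  edges <- data.frame(gene_a = c("a", "a", "b"),
                      gene_b = c("b", "c", "c"),
                      score = c(0.39, 0.40, 0.95))
  g04 <- threshold_ppi(edges, 0.4)
  expect_equal(nrow(g04$edges), 2)  # 0.39 dropped, 0.40 kept
  expect_equal(g04$W["a", "c"], 1)
  expect_equal(g04$W["a", "b"], 0)

  g0 <- threshold_ppi(edges, 0)
  expect_equal(nrow(g0$edges), 3)
  g1 <- threshold_ppi(edges, 1)
  expect_equal(nrow(g1$edges), 0)
  only_one <- threshold_ppi(rbind(edges, data.frame(gene_a = "d", gene_b = "e",
                                                    score = 1)), 1)
  expect_equal(nrow(only_one$edges), 1)

  # monotonicity: higher tau keeps a subset of edges
  set.seed(2)
  big <- generate_ppi(sprintf("g%02d", 1:30), edge_density = 0.3, seed = 2)
  taus <- c(0.2, 0.4, 0.7, 0.9)
  edge_key <- function(g) paste(g$edges$node_a, g$edges$node_b)
  keys <- lapply(taus, function(tau) edge_key(threshold_ppi(big, tau)))
  for (i in seq_len(length(taus) - 1)) {
    expect_true(all(keys[[i + 1]] %in% keys[[i]]))
  }

  bad <- edges
  bad$score[1] <- 1.2
  expect_error(threshold_ppi(bad, 0.4), "\\[0, 1\\]")
})

test_that("degree centrality counts neighbours, ignoring self-loops and weights", {
  star <- star_graph_k13()
  d <- degree_centrality(star)
  expect_equal(unname(d["center"]), 3L)
  expect_equal(unname(d[c("l1", "l2", "l3")]), rep(1L, 3))

  W <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  diag(W) <- 5
  iso <- weighted_graph(W)
  expect_equal(unname(degree_centrality(iso)), rep(0L, 3))

  # random graphs against igraph's degree
  for (seed in 1:5) {
    A <- random_weighted_graph(30, p_edge = 0.2, seed = seed)
    g <- weighted_graph(A)
    B <- A
    diag(B) <- 0
    ig <- igraph::graph_from_adjacency_matrix((B > 0) * 1, mode = "undirected")
    expect_equal(unname(degree_centrality(g)), unname(igraph::degree(ig)))
  }
})

test_that("betweenness matches brute-force shortest-path enumeration", {
  path <- path_graph_abc()
  bc <- betweenness_centrality(path)
  expect_equal(unname(bc), c(0, 1, 0))

  star <- star_graph_k13()
  expect_equal(unname(betweenness_centrality(star)["center"]), 3)

  # exhaustive path-counting oracle on random graphs up to 12 nodes
  for (seed in 1:10) {
    n <- sample(5:12, 1)
    A <- random_weighted_graph(n, p_edge = 0.35, seed = seed)
    g <- weighted_graph(A)
    expect_equal(unname(betweenness_centrality(g)), oracle_betweenness(A),
                 tolerance = 1e-9)
  }
  # and larger instances
  for (seed in 1:5) {
    A <- random_weighted_graph(30, p_edge = 0.12, seed = 100 + seed)
    g <- weighted_graph(A)
    expect_equal(unname(betweenness_centrality(g)), oracle_betweenness(A),
                 tolerance = 1e-9)
  }
})

test_that("hub selection requires both centralities in the top fraction", {
  cent <- data.frame(
    node = sprintf("n%02d", 1:10),
    degree = c(9, rep(3, 8), 5),
    betweenness = c(20, rep(1, 8), 0.5)
  )
  expect_identical(select_hubs(cent, 0.2), "n01")

  # top degree but mediocre betweenness is not a hub
  cent2 <- cent
  cent2$betweenness[1] <- 0
  expect_length(select_hubs(cent2, 0.1), 0)

  # degenerate ties: everyone at the quantile is returned
  flat <- data.frame(node = letters[1:6], degree = 2, betweenness = 1)
  expect_setequal(select_hubs(flat, 0.2), letters[1:6])
})

test_that("matched random graphs preserve counts, loops and determinism", {
  degs <- std_degs()
  brin <- build_degbrin(degs)
  m <- nrow(brin$edges)
  rg <- random_graph_matched(length(brin$nodes), m,
                             self_loop_weights = diag(brin$W), seed = 5)
  expect_equal(nrow(rg$edges), m)
  expect_equal(unname(diag(rg$W)), unname(diag(brin$W)))

  empty <- random_graph_matched(6, 0, self_loop_weights = 2, seed = 1)
  expect_equal(nrow(empty$edges), 0)
  expect_equal(unname(diag(empty$W)), rep(2, 6))

  r1 <- random_graph_matched(19, 40, seed = 3)
  r2 <- random_graph_matched(19, 40, seed = 3)
  r3 <- random_graph_matched(19, 40, seed = 4)
  expect_identical(r1$W, r2$W)
  expect_false(identical(r1$W, r3$W))

  expect_error(random_graph_matched(4, 7), "infeasible")
})

test_that("symmetric normalisation is bounded, symmetric and zero-preserving", {
  expect_equal(normalize_adjacency(diag(3)), diag(3), ignore_attr = TRUE)
  half <- normalize_adjacency(matrix(1, 2, 2))
  expect_equal(half, matrix(0.5, 2, 2), ignore_attr = TRUE)

  for (seed in 1:10) {
    A <- random_weighted_graph(15, p_edge = 0.3, seed = seed)
    A[A > 0] <- A[A > 0] * runif(sum(A > 0), 0.5, 3)
    A <- (A + t(A)) / 2
    diag(A) <- pmax(diag(A), 0.5)
    Ah <- normalize_adjacency(A)
    expect_equal(Ah, t(Ah), tolerance = 1e-12)
    expect_identical(Ah == 0, A == 0)
    expect_lte(max(abs(eigen(Ah, symmetric = TRUE,
                             only.values = TRUE)$values)), 1 + 1e-9)
  }

  W <- diag(c(1, 0, 1))
  expect_error(normalize_adjacency(W), "row sum")
})
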