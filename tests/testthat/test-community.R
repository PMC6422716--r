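test_that("node strength is the absolute row sum of the weight matrix", {
  W <- matrix(0, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  expect_equal(node_strength(W)$strength, c(0, 0, 0))
  W["a", "b"] <- W["b", "a"] <- 0.5
  expect_equal(node_strength(W)$strength, c(0.5, 0.5, 0))
  W["a", "c"] <- W["c", "a"] <- -0.3
  expect_equal(node_strength(W)$strength[1], 0.8)
  # identity with rowSums(|W|) on random graphs
  for (s in 1:10) {
    G <- random_signed_graph(6, s)
    expect_equal(node_strength(G)$strength, unname(rowSums(abs(G))))
  }
})

two_clique_pair <- function(w = 1) {
  W <- matrix(0, 4, 4, dimnames = rep(list(letters[1:4]), 2))
  W["a", "b"] <- W["b", "a"] <- w
  W["c", "d"] <- W["d", "c"] <- w
  W
}

test_that("modularity matches hand calculations and reduces to Newman Q", {
  W <- two_clique_pair()
  expect_equal(modularity_q(W, c(1, 1, 2, 2)), 0.5)
  # everything in one community: Q = 0 (null model saturates)
  expect_equal(modularity_q(W, c(1, 1, 1, 1)), 0, tolerance = 1e-12)
  # all-zero network defined as 0
  expect_equal(modularity_q(matrix(0, 3, 3), c(1, 2, 3)), 0)
  # no negative edges: equals igraph's Newman weighted modularity
  for (s in 1:10) {
    G <- abs(random_signed_graph(6, 100 + s))
    cm <- withr::with_seed(s, sample(1:3, 6, replace = TRUE))
    g <- igraph::graph_from_adjacency_matrix(G, mode = "undirected",
                                             weighted = TRUE, diag = FALSE)
    expect_equal(modularity_q(G, cm),
                 igraph::modularity(g, cm, weights = igraph::E(g)$weight),
                 tolerance = 1e-12)
  }
})

test_that("signed modularity weights the negative subnetwork asymmetrically", {
  for (s in 1:10) {
    W <- random_signed_graph(6, 200 + s)
    cm <- withr::with_seed(s, sample(1:3, 6, replace = TRUE))
    Wp <- pmax(W, 0)
    Wn <- pmax(-W, 0)
    gq <- function(A) { # independent textbook evaluation
      ss <- sum(A)
      if (ss == 0) return(0)
      k <- rowSums(A)
      q <- 0
      for (i in 1:6) for (j in 1:6) {
        if (cm[i] == cm[j]) q <- q + (A[i, j] - k[i] * k[j] / ss) / ss
      }
      q
    }
    expected <- gq(Wp) - sum(Wn) / (sum(Wp) + sum(Wn)) * gq(Wn)
    expect_equal(modularity_q(W, cm), expected, tolerance = 1e-12)
  }
})

test_that("louvain recovers unambiguous community structure", {
  # two disconnected positive 3-cliques
  W <- matrix(0, 6, 6, dimnames = rep(list(letters[1:6]), 2))
  W[1:3, 1:3] <- 1; W[4:6, 4:6] <- 1; diag(W) <- 0
  part <- louvain(W, seed = 5)
  expect_equal(unname(part$assignment), c(1, 1, 1, 2, 2, 2))
  # agreement with igraph's Louvain on this positive graph
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  ig <- withr::with_seed(1, igraph::cluster_louvain(g))
  expect_equal(unname(part$assignment), as.integer(igraph::membership(ig)))

  # empty network: all singletons, Q = 0
  part0 <- louvain(matrix(0, 4, 4), seed = 1)
  expect_equal(unname(part0$assignment), 1:4)
  expect_equal(part0$Q, 0)
})

test_that("louvain finds the brute-force optimum on small random graphs", {
  hits <- 0
  for (s in 1:20) {
    W <- random_signed_graph(5, 300 + s)
    opt <- modularity_optimum(W)
    bp <- best_partition(W, restarts = 50, seed = s)
    expect_lte(bp$Q, opt$Q + 1e-9) # heuristic never beats the oracle
    if (bp$Q >= opt$Q - 1e-9) hits <- hits + 1
  }
  expect_gte(hits, 19)
})

test_that("restarts only improve the attained modularity", {
  for (s in 1:5) {
    W <- random_signed_graph(7, 400 + s)
    q1 <- best_partition(W, restarts = 1, seed = s)$Q
    q100 <- best_partition(W, restarts = 100, seed = s)$Q
    expect_gte(q100, q1 - 1e-12)
  }
  # restarts = 1 is exactly one louvain run with the derived seed
  W <- random_signed_graph(6, 999)
  expect_equal(best_partition(W, restarts = 1, seed = 3)$assignment,
               louvain(W, seed = derive_seed(3, 1))$assignment)
})

test_that("partitions are canonicalized by first node appearance", {
  W <- two_clique_pair()
  part <- louvain(W, seed = 2)
  expect_equal(unname(part$assignment), c(1, 1, 2, 2))
  # determinism under a fixed seed
  expect_identical(louvain(W, seed = 7), louvain(W, seed = 7))
  td <- tidy(part)
  expect_identical(names(td), c("node", "community", "Q"))
})

test_that("co-assignment counts same-community proportions", {
  p1 <- louvain(two_clique_pair(), seed = 1) # {a,b | c,d}
  co <- coassignment(list(p1, p1, p1))
  expect_equal(co$P["a", "b"], 1)
  expect_equal(co$P["a", "c"], 0)
  expect_equal(diag(co$P), rep(1, 4), ignore_attr = TRUE)

  # counting definition: together in 84 of 100 partitions -> 0.84
  M <- matrix(1L, 100, 2, dimnames = list(NULL, c("a", "b")))
  M[1:16, 2] <- 2L
  expect_equal(coassignment(M)$P["a", "b"], 0.84)

  # invariance to community relabeling within each partition
  M2 <- M
  M2[, ] <- 3L - M2[, ] # swap labels 1 <-> 2 everywhere
  expect_equal(coassignment(M2)$P, coassignment(M)$P)
})

test_that("co-assignment rejects mismatched node sets", {
  p1 <- louvain(two_clique_pair(), seed = 1)
  W2 <- two_clique_pair()
  dimnames(W2) <- rep(list(c("a", "b", "c", "z")), 2)
  p2 <- louvain(W2, seed = 1)
  expect_error(coassignment(list(p1, p2)), "same node set")
})
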