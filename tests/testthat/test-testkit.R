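test_that("random graphs are connected, non-bipartite and reproducible", {
  for (seed in 1:25) {
    net <- randomConnectedGraph(20 + seed, 4, seed = seed)
    g <- igraph::graph_from_adjacency_matrix(adjacency(net),
                                             mode = "undirected")
    expect_true(igraph::is_connected(g))
    expect_false(igraph::bipartite_mapping(g)$res)
  }
  a <- randomConnectedGraph(50, 5, seed = 123)
  b <- randomConnectedGraph(50, 5, seed = 123)
  expect_identical(as.matrix(adjacency(a)), as.matrix(adjacency(b)))
  # minimal case is forced to a triangle
  expect_equal(numEdges(randomConnectedGraph(3, 2, seed = 1)), 3L)
  expect_error(randomConnectedGraph(2, 2, seed = 1), "3 nodes")
})

test_that("planted queries are induced subgraphs with injective truth", {
  target <- randomConnectedGraph(60, 5, seed = 9, prefix = "t")
  pl <- plantQuery(target, querySize = 8, rewireFraction = 0, seed = 4)
  expect_equal(numNodes(pl$query), 8L)
  expect_false(anyDuplicated(pl$truth) > 0)
  # rewireFraction = 0: exact induced subgraph of the unperturbed target
  expect_equal(as.matrix(adjacency(pl$query)),
               unname(as.matrix(adjacency(target))[pl$truth, pl$truth]))
  gq <- igraph::graph_from_adjacency_matrix(adjacency(pl$query),
                                            mode = "undirected")
  expect_true(igraph::is_connected(gq))
})

test_that("rewiring preserves the target degree sequence exactly", {
  target <- randomConnectedGraph(80, 5, seed = 11, prefix = "t")
  pl <- plantQuery(target, querySize = 6, rewireFraction = 0.2, seed = 5)
  expect_equal(sort(unname(nodeDegrees(pl$target))),
               sort(unname(nodeDegrees(target))))
  expect_equal(numEdges(pl$target), numEdges(target))
})

test_that("synthetic similarity marks true pairs and is reproducible", {
  target <- randomConnectedGraph(40, 4, seed = 21, prefix = "t")
  pl <- plantQuery(target, querySize = 5, rewireFraction = 0, seed = 6)
  sim0 <- synthSimilarity(pl$query, pl$target, pl$truth, signal = 1,
                          noisePairs = 0)
  expect_equal(length(sim0@score), 5L)
  expect_true(all(sim0@score == 1))
  expect_equal(sim0@targetIndex[order(sim0@queryIndex)], pl$truth)

  s1 <- synthSimilarity(pl$query, pl$target, pl$truth, noisePairs = 10,
                        seed = 33)
  s2 <- synthSimilarity(pl$query, pl$target, pl$truth, noisePairs = 10,
                        seed = 33)
  expect_identical(s1@score, s2@score)

  # rank-1 limit: with alpha = 0 the solved vector is the normalized
  # similarity itself, so argmax recovery is exact
  st <- sbcfwIsoRank(pl$query, pl$target, sim = sim0, alpha = 0,
                     nBlocks = 5, xi = 1e-10, seed = 2, maxIter = 2e4)
  op <- buildProductOperator(pl$query, pl$target, sim0, alpha = 0)
  expect_lt(sum(abs(scoreVector(st) - op@sbar)), 1e-6)
  res <- extractAlignment(st, pl$query, pl$target, truth = pl$truth)
  expect_equal(res@accuracy, 1)
})

test_that("the dense power-method oracle recovers known stationary vectors", {
  qn <- randomConnectedGraph(5, 3, seed = 61, prefix = "q")
  tn <- randomConnectedGraph(11, 4, seed = 62, prefix = "t")
  op <- buildProductOperator(qn, tn)
  d <- productDegrees(op)
  expect_lt(sum(abs(denseOracleStationary(op, tol = 1e-13) - d / sum(d))),
            1e-9)
  k3 <- triangleNet()
  opk <- buildProductOperator(k3, triangleNet(c("x", "y", "z")))
  expect_equal(denseOracleStationary(opk), rep(1 / 9, 9), tolerance = 1e-10)
})

test_that("the power oracle agrees with a dense eigendecomposition", {
  qn <- randomConnectedGraph(4, 3, seed = 71, prefix = "q")
  tn <- randomConnectedGraph(9, 4, seed = 72, prefix = "t")
  sim <- synthSimilarity(qn, tn, truth = 1:4, signal = 1, noisePairs = 3,
                         seed = 1)
  op <- buildProductOperator(qn, tn, sim, alpha = 0.5)
  xp <- denseOracleStationary(op, tol = 1e-14)
  ev <- eigen(denseTransition(op))
  lead <- Re(ev$vectors[, which.max(Re(ev$values))])
  lead <- lead / sum(lead)
  expect_lt(sum(abs(xp - lead)), 1e-8)
})

test_that("dense M is the PSD Hessian factorization", {
  set.seed(3)
  for (rep in 1:5) {
    qn <- randomConnectedGraph(4, 3, seed = 80 + rep, prefix = "q")
    tn <- randomConnectedGraph(7 + rep, 3, seed = 90 + rep, prefix = "t")
    op <- buildProductOperator(qn, tn)
    M <- denseM(op)
    expect_lt(max(abs(M - t(M))), 1e-12)
    x <- rnorm(productDim(op))
    expect_equal(as.numeric(t(x) %*% M %*% x),
                 sum((applyBhat(op, x) - x)^2), tolerance = 1e-10)
    expect_gte(min(eigen(M, symmetric = TRUE, only.values = TRUE)$values),
               -1e-10)
  }
})

test_that("planted instances solve to perfect recovery when easy", {
  inst <- plantedInstance(targetSize = 60, querySize = 5, meanDegree = 5,
                          rewireFraction = 0.03, noisePairs = 5, seed = 17)
  st <- sbcfwIsoRank(inst$query, inst$target, sim = inst$sim, alpha = 0.5,
                     nBlocks = 10, xi = 0.01, seed = 1, maxIter = 1e5)
  res <- extractAlignment(st, inst$query, inst$target, truth = inst$truth)
  expect_equal(res@accuracy, 1)
})
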