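#' @importFrom igraph graph_from_adjacency_matrix sample_gnp components
#'   bipartite_mapping is_connected rewire keeping_degseq as_edgelist gorder
#'   induced_subgraph ecount add_edges simplify adjacent_vertices
NULL

igraphFromNetwork <- function(net) {
  igraph::graph_from_adjacency_matrix(adjacency(net), mode = "undirected")
}

networkFromIgraph <- function(g, nodeNames) {
  el <- igraph::as_edgelist(g, names = FALSE)
  ppiNetwork(nodeNames, el)
}

#' Generate a random connected non-bipartite network
#'
#' Erdos-Renyi draw at the requested mean degree, followed by random
#' bridging edges until connected and, if the result is bipartite, one
#' planted triangle. Connected and non-bipartite inputs make the product
#' random walk ergodic, so the eigenvector problem has a unique solution.
#' Deterministic per seed.
#'
#' @param nNodes number of nodes (>= 3).
#' @param meanDegree target mean degree (>= 2).
#' @param seed integer seed.
#' @param prefix node-name prefix (names are `<prefix>1 ... <prefix>n`).
#' @return a [PPINetwork-class] that is connected and non-bipartite.
#' @export
randomConnectedGraph <- function(nNodes, meanDegree, seed, prefix = "v") {
  if (nNodes < 3) stop("need at least 3 nodes")
  if (meanDegree < 2) stop("need meanDegree >= 2")
  if (meanDegree >= nNodes) stop("meanDegree must be below nNodes")
  names <- paste0(prefix, seq_len(nNodes))
  edges <- withr_seed(seed, {
    p <- min(1, meanDegree / (nNodes - 1))
    g <- igraph::sample_gnp(nNodes, p)
    # bridge components with random edges until connected
    repeat {
      comp <- igraph::components(g)
      if (comp$no == 1L) break
      a <- sample(which(comp$membership == 1L), 1L)
      other <- sample(which(comp$membership != comp$membership[a]), 1L)
      g <- igraph::add_edges(g, c(a, other))
    }
    if (igraph::bipartite_mapping(g)$res) {
      tri <- sample.int(nNodes, 3L)
      g <- igraph::add_edges(g, c(tri[1], tri[2], tri[2], tri[3],
                                  tri[3], tri[1]))
    }
    igraph::as_edgelist(igraph::simplify(g), names = FALSE)
  })
  ppiNetwork(names, edges)
}

# Evaluate expr under a temporary seed, restoring the caller's RNG state.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, globalenv())
  })
  set.seed(seed)
  expr
}

#' Plant a known query subnetwork inside a target network
#'
#' Selects a random connected induced subgraph of the target as the query
#' (so the true node correspondence is known by construction), then
#' decorrelates the two networks by degree-preserving double-edge swaps on
#' a fraction of the target's edges — emulating two databases archiving
#' partially different interactions for the same organism.
#'
#' @param target a [PPINetwork-class], connected and non-bipartite.
#' @param querySize number of query nodes (3 <= querySize <= target size).
#' @param rewireFraction fraction of target edges to swap, in \[0, 0.5).
#' @param seed integer seed.
#' @return list with `query` ([PPINetwork-class], nodes renamed
#'   `q1...q<size>`), `target` (the rewired [PPINetwork-class]), and
#'   `truth` (integer vector, query index -> target index).
#' @export
plantQuery <- function(target, querySize, rewireFraction = 0, seed = 1L) {
  stopifnot(is(target, "PPINetwork"))
  if (querySize < 3 || querySize > numNodes(target))
    stop("querySize must be in [3, numNodes(target)]")
  if (rewireFraction < 0 || rewireFraction >= 0.5)
    stop("rewireFraction must be in [0, 0.5)")
  g <- igraphFromNetwork(target)
  res <- withr_seed(seed, {
    # grow a random connected induced subgraph by neighbor expansion
    pick <- NULL
    for (try in 1:50) {
      nodes <- sample.int(igraph::gorder(g), 1L)
      while (length(nodes) < querySize) {
        nb <- setdiff(unlist(igraph::adjacent_vertices(g, nodes)), nodes)
        if (!length(nb)) break
        nodes <- c(nodes, sample(nb, 1L))
      }
      sub <- igraph::induced_subgraph(g, sort(nodes))
      if (length(nodes) == querySize && igraph::is_connected(sub)) {
        pick <- sort(nodes); break
      }
    }
    if (is.null(pick))
      stop("could not find a connected induced subgraph of size ", querySize)
    sub <- igraph::induced_subgraph(g, pick)
    g2 <- g
    nSwap <- ceiling(rewireFraction * igraph::ecount(g))
    if (nSwap > 0) {
      for (try in 1:20) {
        cand <- igraph::rewire(g, igraph::keeping_degseq(niter = nSwap))
        if (igraph::is_connected(cand) &&
            !igraph::bipartite_mapping(cand)$res) {
          g2 <- cand; break
        }
      }
    }
    list(pick = pick, sub = sub, g2 = g2)
  })
  query <- networkFromIgraph(res$sub, paste0("q", seq_len(querySize)))
  newTarget <- networkFromIgraph(res$g2, nodeNames(target))
  list(query = query, target = newTarget, truth = as.integer(res$pick))
}

#' Synthetic cross-network similarity scores for a planted instance
#'
#' Every true pair (u, truth\[u\]) receives the score `signal`; `noisePairs`
#' additional uniformly random pairs receive scores drawn uniformly from
#' (0, signal), emulating noisy sequence-similarity hits. Normalization to a
#' unit-sum similarity vector happens inside the product operator.
#'
#' @param query,target the two [PPINetwork-class] objects.
#' @param truth integer vector, query index -> target index.
#' @param signal score assigned to true pairs (> 0).
#' @param noisePairs number of random decoy pairs.
#' @param seed integer seed.
#' @return a [SimilarityTable-class].
#' @export
synthSimilarity <- function(query, target, truth, signal = 1,
                            noisePairs = 0L, seed = 1L) {
  if (signal <= 0) stop("signal must be positive")
  Na <- numNodes(query); Nb <- numNodes(target)
  stopifnot(length(truth) == Na)
  qs <- seq_len(Na); ts <- as.integer(truth); sc <- rep(signal, Na)
  if (noisePairs > 0) {
    extra <- withr_seed(seed, {
      cbind(sample.int(Na, noisePairs, replace = TRUE),
            sample.int(Nb, noisePairs, replace = TRUE),
            stats::runif(noisePairs, 0, signal))
    })
    qs <- c(qs, extra[, 1]); ts <- c(ts, as.integer(extra[, 2]))
    sc <- c(sc, extra[, 3])
  }
  suppressWarnings(similarityTable(qs, ts, sc, query, target))
}

#' Convenience generator for a full planted benchmark instance
#'
#' @param targetSize,querySize node counts.
#' @param meanDegree target mean degree.
#' @param rewireFraction passed to [plantQuery()].
#' @param signal,noisePairs passed to [synthSimilarity()].
#' @param seed integer seed (sub-seeds are derived from it).
#' @return list with `query`, `target`, `truth`, `sim`.
#' @export
plantedInstance <- function(targetSize = 100L, querySize = 6L,
                            meanDegree = 6, rewireFraction = 0.05,
                            signal = 1, noisePairs = querySize,
                            seed = 1L) {
  target0 <- randomConnectedGraph(targetSize, meanDegree, seed = seed,
                                  prefix = "t")
  pl <- plantQuery(target0, querySize, rewireFraction, seed = seed + 1L)
  sim <- synthSimilarity(pl$query, pl$target, pl$truth, signal = signal,
                         noisePairs = noisePairs, seed = seed + 2L)
  list(query = pl$query, target = pl$target, truth = pl$truth, sim = sim)
}

#' Dense transition matrix of the product walk (test oracle)
#'
#' Explicitly materializes the similarity-mixed transition matrix from the
#' Kronecker product of the adjacencies — quadratic in N and intended only
#' for verification at small sizes.
#'
#' @param op a [ProductOperator-class] with `productDim(op) <= 10000`.
#' @return dense N x N matrix.
#' @export
denseTransition <- function(op) {
  N <- productDim(op)
  if (N > 10000) stop("dense oracle limited to N <= 10000")
  B <- kronecker(as.matrix(adjacency(op@qnet)),
                 as.matrix(adjacency(op@tnet)))
  dinv <- ifelse(op@d > 0, 1 / op@d, 0)
  Bbar <- B %*% diag(dinv, N)
  if (op@alpha == 1) return(Bbar)
  op@alpha * Bbar + (1 - op@alpha) * op@sbar %*% t(rep(1, N))
}

#' Dense power-method stationary vector (test oracle)
#'
#' Builds the dense transition matrix and iterates from the uniform simplex
#' point with L1 renormalization until the successive-iterate L1 change
#' falls below `tol`. This is the classical way of computing the maximal
#' right eigenvector and serves as the independent reference for the
#' stochastic solver.
#'
#' @param op a [ProductOperator-class] (N <= 10000).
#' @param tol L1 convergence tolerance.
#' @param maxIter iteration cap (error if exceeded).
#' @return stationary vector on the unit simplex.
#' @export
denseOracleStationary <- function(op, tol = 1e-12, maxIter = 1e5) {
  Bh <- denseTransition(op)
  N <- productDim(op)
  x <- rep(1 / N, N)
  for (it in seq_len(maxIter)) {
    xn <- as.numeric(Bh %*% x)
    s <- sum(xn)
    if (s <= 0) stop("power iteration collapsed to zero")
    xn <- xn / s
    if (sum(abs(xn - x)) < tol) return(xn)
    x <- xn
  }
  stop("power iteration did not converge in ", maxIter, " iterations")
}

#' Dense Hessian of the residual objective (test oracle)
#'
#' `M = (Bhat - I)' (Bhat - I)`, the positive semi-definite Hessian of the
#' eigenvector program; materialized only for verification at small sizes.
#'
#' @param op a [ProductOperator-class] with `productDim(op) <= 2000`.
#' @return dense symmetric N x N matrix.
#' @export
denseM <- function(op) {
  N <- productDim(op)
  if (N > 2000) stop("dense M limited to N <= 2000")
  E <- denseTransition(op) - diag(N)
  t(E) %*% E
}
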