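#' @import methods
#' @importFrom Matrix sparseMatrix drop0 rowSums t diag
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' Undirected protein-protein interaction network
#'
#' A node-indexed undirected graph with a symmetric binary sparse adjacency
#' matrix and no self-loops. Node order is first-appearance order from the
#' source edge list and is stable for the whole run; all pair indexing
#' downstream builds on it.
#'
#' @slot nodeNames character vector of unique node identifiers.
#' @slot adjacency symmetric binary \code{dgCMatrix} with zero diagonal.
#'
#' @seealso [readEdgeList()], [nodeDegrees()], [buildProductOperator()]
#' @export
setClass("PPINetwork",
  slots = c(nodeNames = "character", adjacency = "dgCMatrix"))

setValidity("PPINetwork", function(object) {
  A <- object@adjacency
  n <- length(object@nodeNames)
  msgs <- character()
  if (nrow(A) != n || ncol(A) != n)
    msgs <- c(msgs, "adjacency dimensions must match number of node names")
  if (anyDuplicated(object@nodeNames))
    msgs <- c(msgs, "node names must be unique")
  if (length(A@x) && !all(A@x == 1))
    msgs <- c(msgs, "adjacency must be binary")
  if (!Matrix::isSymmetric(A, checkDN = FALSE))
    msgs <- c(msgs, "adjacency must be symmetric")
  if (n > 0 && any(Matrix::diag(A) != 0))
    msgs <- c(msgs, "self-loops are not allowed (diagonal must be zero)")
  if (length(msgs)) msgs else TRUE
})

#' Cross-network node similarity table
#'
#' Non-negative similarity scores (for example BLAST bit-scores) between
#' nodes of a query network and nodes of a target network. Pairs not listed
#' carry an implicit score of zero. The table is the raw input for the
#' normalized similarity vector mixed into the product-graph transition
#' matrix.
#'
#' @slot queryIndex integer node indices into the query network.
#' @slot targetIndex integer node indices into the target network.
#' @slot score non-negative numeric scores, parallel to the index slots.
#' @slot queryNames character, node-name universe of the query network.
#' @slot targetNames character, node-name universe of the target network.
#'
#' @seealso [readSimilarity()], [similarityTable()]
#' @export
setClass("SimilarityTable",
  slots = c(queryIndex = "integer", targetIndex = "integer",
            score = "numeric", queryNames = "character",
            targetNames = "character"))

setValidity("SimilarityTable", function(object) {
  msgs <- character()
  nl <- lengths(list(object@queryIndex, object@targetIndex, object@score))
  if (length(unique(nl)) != 1L)
    msgs <- c(msgs, "index and score slots must have equal length")
  if (length(object@score) && any(object@score < 0))
    msgs <- c(msgs, "similarity scores must be non-negative")
  if (length(object@queryIndex) &&
      (any(object@queryIndex < 1L) ||
       any(object@queryIndex > length(object@queryNames))))
    msgs <- c(msgs, "query indices out of range")
  if (length(object@targetIndex) &&
      (any(object@targetIndex < 1L) ||
       any(object@targetIndex > length(object@targetNames))))
    msgs <- c(msgs, "target indices out of range")
  if (anyDuplicated(cbind(object@queryIndex, object@targetIndex)))
    msgs <- c(msgs, "duplicate (query, target) pairs must be merged")
  if (length(msgs)) msgs else TRUE
})

#' Implicit product-graph transition operator
#'
#' Represents the column-stochastic transition matrix of the random walk on
#' the Kronecker product of two networks, optionally mixed with a normalized
#' similarity vector, without ever forming the (Na*Nb) x (Na*Nb) matrix.
#' Only the two input adjacencies, the product degree vector and the
#' normalized similarity vector are stored, so memory stays O(N).
#'
#' Pair indexing is query-major: 1-based pair index
#' \code{t = (u - 1) * Nb + v} for query node u and target node v, so
#' reshaping a pair vector to an Na x Nb matrix puts query nodes on rows.
#'
#' @slot qnet,tnet the query and target [PPINetwork-class] objects.
#' @slot alpha mixing weight in \[0, 1\]; 1 means pure topology.
#' @slot d product degree vector (entry for (u,v) is deg(u) * deg(v)).
#' @slot sbar normalized similarity vector summing to 1, or length-0 numeric
#'   when \code{alpha = 1}.
#'
#' @seealso [buildProductOperator()], [applyBhat()], [applyBhatT()]
#' @export
setClass("ProductOperator",
  slots = c(qnet = "PPINetwork", tnet = "PPINetwork",
            alpha = "numeric", d = "numeric", sbar = "numeric"))

setValidity("ProductOperator", function(object) {
  msgs <- character()
  N <- numNodes(object@qnet) * numNodes(object@tnet)
  if (length(object@d) != N)
    msgs <- c(msgs, "product degree vector has wrong length")
  if (length(object@alpha) != 1L || object@alpha < 0 || object@alpha > 1)
    msgs <- c(msgs, "alpha must be a single value in [0, 1]")
  if (object@alpha < 1) {
    if (length(object@sbar) != N)
      msgs <- c(msgs, "sbar required (length N) when alpha < 1")
    else if (abs(sum(object@sbar) - 1) > 1e-12)
      msgs <- c(msgs, "sbar must sum to 1")
  }
  if (length(msgs)) msgs else TRUE
})

#' Coordinate block sampling scheme
#'
#' Partitions (or re-partitions) the N pair coordinates into n near-equal
#' blocks and samples one block per iteration. Carries its own RNG stream so
#' block sequences are reproducible from the seed and independent of the
#' caller's RNG state.
#'
#' @slot N total number of coordinates.
#' @slot nBlocks number of blocks n (1 <= n <= N).
#' @slot mode \code{"repartition"} draws a fresh uniform random block of size
#'   \code{ceiling(N / n)} each iteration; \code{"fixed_partition"} fixes n
#'   contiguous near-equal blocks once and picks one uniformly per iteration.
#' @slot seed integer seed for the scheme's private RNG stream.
#' @slot rngEnv environment holding the private RNG state.
#' @slot partition list of integer index blocks (fixed_partition mode only).
#'
#' @seealso [blockScheme()], [sampleBlock()]
#' @export
setClass("BlockScheme",
  slots = c(N = "integer", nBlocks = "integer", mode = "character",
            seed = "integer", rngEnv = "environment", partition = "list"))

setValidity("BlockScheme", function(object) {
  msgs <- character()
  if (object@nBlocks < 1L || object@nBlocks > object@N)
    msgs <- c(msgs, "need 1 <= nBlocks <= N")
  if (!object@mode %in% c("repartition", "fixed_partition"))
    msgs <- c(msgs, "mode must be 'repartition' or 'fixed_partition'")
  if (length(msgs)) msgs else TRUE
})

#' Solver state returned by the block-coordinate Frank-Wolfe loop
#'
#' @slot x final iterate on the unit simplex (pair-score vector).
#' @slot k number of iterations performed.
#' @slot objectiveTrace objective values f(x^0), ..., f(x^k).
#' @slot lastGamma last step size taken.
#' @slot lastBlock last sampled coordinate block.
#' @slot converged TRUE if the stopping rule fired before the iteration cap.
#' @slot stalls number of zero-progress iterations (sampled block carried no
#'   mass).
#' @slot diagnostics list of solver diagnostics (for example the largest
#'   deviation between tracked and recomputed residuals in debug runs).
#'
#' @seealso [sbcfwRun()], [sbcfwIsoRank()]
#' @export
setClass("SolverState",
  slots = c(x = "numeric", k = "integer", objectiveTrace = "numeric",
            lastGamma = "numeric", lastBlock = "integer",
            converged = "logical", stalls = "integer",
            diagnostics = "list"),
  prototype = list(diagnostics = list()))

#' One-to-one node alignment extracted from a pair-score vector
#'
#' @slot pairs data.frame with columns \code{query}, \code{target} (1-based
#'   node indices), \code{queryName}, \code{targetName}, \code{score},
#'   sorted by query index.
#' @slot method extraction method, \code{"greedy"} or \code{"argmax"}.
#' @slot accuracy fraction of query nodes aligned to their true partner, or
#'   NA when no ground truth was supplied.
#'
#' @seealso [greedyMatch()], [alignmentAccuracy()], [writeAlignment()]
#' @export
setClass("AlignmentResult",
  slots = c(pairs = "data.frame", method = "character",
            accuracy = "numeric"))

setValidity("AlignmentResult", function(object) {
  msgs <- character()
  p <- object@pairs
  need <- c("query", "target", "queryName", "targetName", "score")
  if (!all(need %in% names(p)))
    msgs <- c(msgs, "pairs must have columns query, target, queryName, targetName, score")
  else {
    if (nrow(p) && any(p$score < 0))
      msgs <- c(msgs, "scores must be non-negative")
    if (identical(object@method, "greedy") &&
        (anyDuplicated(p$query) || anyDuplicated(p$target)))
      msgs <- c(msgs, "greedy matching must be one-to-one")
    if (is.unsorted(p$query))
      msgs <- c(msgs, "pairs must be sorted by query index")
  }
  if (length(msgs)) msgs else TRUE
})
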