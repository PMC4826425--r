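#' Reshape a pair-score vector to a query x target score matrix
#'
#' Inverse of the query-major pair indexing: `X[u, v] = x[(u - 1) * Nb + v]`.
#'
#' @param x numeric vector of length `Na * Nb`.
#' @param Na,Nb numbers of query and target nodes.
#' @return numeric Na x Nb matrix.
#' @export
scoreMatrix <- function(x, Na, Nb) {
  if (length(x) != Na * Nb)
    stop("vector length ", length(x), " does not equal Na * Nb = ", Na * Nb)
  t(matrix(x, nrow = Nb, ncol = Na))
}

#' Greedy one-to-one matching from a score matrix
#'
#' Repeatedly selects the largest remaining score, records the pair and
#' removes its row and column, stopping after `min(Na, Nb)` pairs or when
#' only zero scores remain. Ties are broken toward the smallest query index,
#' then the smallest target index, so the extraction is deterministic.
#' An `argmax` mode (best target per query row, possibly many-to-one) is
#' available for diagnostics.
#'
#' @param X non-negative score matrix (query rows, target columns).
#' @param qnet,tnet optional networks supplying node names; defaults to
#'   `q<i>` / `t<j>` labels.
#' @param method `"greedy"` (default, one-to-one) or `"argmax"`.
#' @return an [AlignmentResult-class] with pairs sorted by query index.
#' @export
greedyMatch <- function(X, qnet = NULL, tnet = NULL,
                        method = c("greedy", "argmax")) {
  method <- match.arg(method)
  X <- as.matrix(X)
  if (any(X < 0)) stop("score matrix must be non-negative")
  Na <- nrow(X); Nb <- ncol(X)
  qn <- if (is.null(qnet)) paste0("q", seq_len(Na)) else nodeNames(qnet)
  tn <- if (is.null(tnet)) paste0("t", seq_len(Nb)) else nodeNames(tnet)
  if (method == "argmax") {
    ti <- apply(X, 1L, which.max)
    sc <- X[cbind(seq_len(Na), ti)]
    pairs <- data.frame(query = seq_len(Na), target = as.integer(ti),
                        queryName = qn, targetName = tn[ti], score = sc,
                        stringsAsFactors = FALSE)
    return(new("AlignmentResult", pairs = pairs, method = "argmax",
               accuracy = NA_real_))
  }
  W <- X
  qs <- integer(0); ts <- integer(0); sc <- numeric(0)
  for (step in seq_len(min(Na, Nb))) {
    m <- max(W)
    if (m <= 0) break
    hit <- which(W == m, arr.ind = TRUE)
    u <- min(hit[, 1])
    v <- min(hit[hit[, 1] == u, 2])
    qs <- c(qs, u); ts <- c(ts, v); sc <- c(sc, m)
    W[u, ] <- -Inf
    W[, v] <- -Inf
  }
  if (!length(qs))
    warning("all scores are zero; alignment is empty")
  ord <- order(qs)
  pairs <- data.frame(query = qs[ord], target = ts[ord],
                      queryName = qn[qs[ord]], targetName = tn[ts[ord]],
                      score = sc[ord], stringsAsFactors = FALSE)
  new("AlignmentResult", pairs = pairs, method = "greedy",
      accuracy = NA_real_)
}

#' Alignment accuracy against a ground-truth correspondence
#'
#' The number of query nodes aligned to their true target divided by the
#' total number of query nodes (unaligned query nodes count as wrong).
#'
#' @param result an [AlignmentResult-class].
#' @param truth integer vector, `truth[u]` the true target index of query
#'   node u, covering all query nodes.
#' @param Na number of query nodes; defaults to `length(truth)`.
#' @return accuracy in \[0, 1\].
#' @export
alignmentAccuracy <- function(result, truth, Na = length(truth)) {
  stopifnot(is(result, "AlignmentResult"))
  p <- result@pairs
  if (!nrow(p)) return(0)
  if (any(p$query > length(truth))) stop("truth must cover all query nodes")
  sum(truth[p$query] == p$target) / Na
}

#' Extract an alignment from a solver state
#'
#' Convenience wrapper: reshape the converged score vector, run the greedy
#' matching and (optionally) score it against a ground truth.
#'
#' @param state a [SolverState-class] from [sbcfwIsoRank()].
#' @param qnet,tnet the aligned networks.
#' @param truth optional ground-truth integer vector.
#' @param method passed to [greedyMatch()].
#' @return an [AlignmentResult-class].
#' @export
extractAlignment <- function(state, qnet, tnet, truth = NULL,
                             method = "greedy") {
  X <- scoreMatrix(scoreVector(state), numNodes(qnet), numNodes(tnet))
  res <- greedyMatch(X, qnet = qnet, tnet = tnet, method = method)
  if (!is.null(truth))
    res@accuracy <- alignmentAccuracy(res, truth, Na = numNodes(qnet))
  res
}
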