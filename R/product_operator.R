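#' Build the implicit product-graph transition operator
#'
#' Constructs the operator view of the random walk on the Kronecker product
#' B of the query and target adjacencies, i.e. the column-stochastic matrix
#' obtained by dividing each column of B by the product degree of its pair,
#' optionally mixed with the normalized similarity vector through the weight
#' `alpha`. Nothing of quadratic size is ever allocated: the operator stores
#' the two sparse adjacencies, the length-N product degree vector and (when
#' `alpha < 1`) the length-N normalized similarity vector.
#'
#' The pair index convention is query-major: pair (u, v) maps to 1-based
#' index `t = (u - 1) * Nb + v`, so a pair vector reshapes to an Na x Nb
#' score matrix with query nodes on rows (see [scoreMatrix()]).
#'
#' @param qnet,tnet query and target [PPINetwork-class] objects.
#' @param sim optional [SimilarityTable-class]; required when `alpha < 1`.
#' @param alpha mixing weight in \[0, 1\]: 1 is pure topology, 0 pure
#'   similarity. Default 0.5 when `sim` is given, 1 otherwise.
#' @return a [ProductOperator-class].
#' @examples
#' tri <- ppiNetwork(c("a", "b", "c"), rbind(c(1, 2), c(2, 3), c(3, 1)))
#' op <- buildProductOperator(tri, tri)
#' productDim(op)     # 9
#' productDegrees(op) # all 4: degree products 2 * 2
#' @export
buildProductOperator <- function(qnet, tnet, sim = NULL,
                                 alpha = if (is.null(sim)) 1 else 0.5) {
  stopifnot(is(qnet, "PPINetwork"), is(tnet, "PPINetwork"))
  if (length(alpha) != 1L || is.na(alpha) || alpha < 0 || alpha > 1)
    stop("alpha must be a single value in [0, 1]")
  da <- as.numeric(Matrix::rowSums(adjacency(qnet)))
  db <- as.numeric(Matrix::rowSums(adjacency(tnet)))
  Nb <- numNodes(tnet)
  d <- rep(da, each = Nb) * rep.int(db, numNodes(qnet))
  if (alpha < 1) {
    if (is.null(sim))
      stop("a similarity table is required when alpha < 1")
    stopifnot(is(sim, "SimilarityTable"))
    if (!identical(sim@queryNames, nodeNames(qnet)) ||
        !identical(sim@targetNames, nodeNames(tnet)))
      stop("similarity table was built for different networks")
    S <- similarityVector(sim)
    tot <- sum(S)
    if (tot <= 0)
      stop("similarity table has zero total score but alpha < 1")
    sbar <- S / tot
  } else {
    sbar <- numeric(0)
  }
  if (any(d == 0))
    warning(sum(d == 0), " zero-degree pair coordinate(s): the product ",
            "random walk is not ergodic and the stationary interpretation ",
            "may fail (inputs should be connected and non-bipartite)")
  new("ProductOperator", qnet = qnet, tnet = tnet, alpha = alpha,
      d = d, sbar = sbar)
}

# Shared kernel: y |-> vec(Aa %*% Y %*% Ab) in query-major pair order.
# The query-major vector reshapes column-major to an Nb x Na matrix Y0 with
# Y0[v, u] = y[(u-1)*Nb + v]; then (B y)[(u,v)] = (Ab %*% Y0 %*% Aa)[v, u].
applyKron <- function(op, y) {
  Nb <- numNodes(op@tnet)
  Na <- numNodes(op@qnet)
  Y0 <- matrix(y, nrow = Nb, ncol = Na)
  as.numeric(as.matrix(adjacency(op@tnet) %*% Y0 %*% adjacency(op@qnet)))
}

checkLen <- function(op, x) {
  if (length(x) != productDim(op))
    stop("vector length ", length(x), " does not match pair dimension ",
         productDim(op))
  if (!all(is.finite(x))) stop("vector must be finite")
  invisible(TRUE)
}

#' @rdname applyBbar
#' @export
setMethod("applyBbar", "ProductOperator", function(op, x) {
  checkLen(op, x)
  y <- ifelse(op@d > 0, x / op@d, 0)
  applyKron(op, y)
})

#' @rdname applyBbar
#' @export
setMethod("applyBhat", "ProductOperator", function(op, x) {
  if (op@alpha == 1) return(applyBbar(op, x))
  checkLen(op, x)
  y <- ifelse(op@d > 0, x / op@d, 0)
  op@alpha * applyKron(op, y) + (1 - op@alpha) * sum(x) * op@sbar
})

#' @rdname applyBbar
#' @export
setMethod("applyBhatT", "ProductOperator", function(op, p) {
  checkLen(op, p)
  z <- applyKron(op, p)
  z <- ifelse(op@d > 0, z / op@d, 0)
  if (op@alpha == 1) return(z)
  op@alpha * z + (1 - op@alpha) * sum(op@sbar * p)
})

#' Restrict a vector to a coordinate block
#'
#' Returns the vector with entries outside `block` set to zero (the action
#' of the block-selection projection used by partial gradients).
#'
#' @param x numeric vector.
#' @param block integer vector of unique 1-based indices into `x`.
#' @return numeric vector of the same length as `x`.
#' @export
restrictVector <- function(x, block) {
  block <- as.integer(block)
  if (length(block)) {
    if (anyDuplicated(block)) stop("block indices must be unique")
    if (any(block < 1L) || any(block > length(x)))
      stop("block index out of range")
  }
  out <- numeric(length(x))
  out[block] <- x[block]
  out
}
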