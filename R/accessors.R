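#' @rdname PPINetwork-class
#' @export
setMethod("nodeNames", "PPINetwork", function(x) x@nodeNames)

#' @rdname PPINetwork-class
#' @export
setMethod("numNodes", "PPINetwork", function(x) length(x@nodeNames))

#' @rdname PPINetwork-class
#' @export
setMethod("numEdges", "PPINetwork",
          function(x) as.integer(sum(x@adjacency) / 2))

#' @rdname PPINetwork-class
#' @export
setMethod("nodeDegrees", "PPINetwork", function(x) {
  d <- as.integer(Matrix::rowSums(x@adjacency))
  names(d) <- x@nodeNames
  d
})

#' @rdname PPINetwork-class
#' @export
setMethod("adjacency", "PPINetwork", function(x) x@adjacency)

setMethod("show", "PPINetwork", function(object) {
  cat(sprintf("PPINetwork with %d nodes and %d undirected edges\n",
              numNodes(object), numEdges(object)))
  nn <- nodeNames(object)
  if (length(nn))
    cat("  nodes: ", paste(utils::head(nn, 5), collapse = ", "),
        if (length(nn) > 5) ", ..." else "", "\n", sep = "")
})

#' @rdname ProductOperator-class
#' @export
setMethod("productDim", "ProductOperator",
          function(op) numNodes(op@qnet) * numNodes(op@tnet))

#' @rdname ProductOperator-class
#' @export
setMethod("productDegrees", "ProductOperator", function(op) op@d)

#' @rdname ProductOperator-class
#' @export
setMethod("mixingAlpha", "ProductOperator", function(op) op@alpha)

setMethod("show", "ProductOperator", function(object) {
  cat(sprintf(
    "ProductOperator: %d x %d nodes, pair dimension N = %d, alpha = %g\n",
    numNodes(object@qnet), numNodes(object@tnet),
    productDim(object), object@alpha))
  nz <- sum(object@d == 0)
  if (nz > 0)
    cat(sprintf("  %d zero-degree pair coordinates\n", nz))
})

setMethod("show", "BlockScheme", function(object) {
  cat(sprintf("BlockScheme: N = %d, n = %d blocks, mode = %s, seed = %d\n",
              object@N, object@nBlocks, object@mode, object@seed))
})

#' @rdname SolverState-class
#' @export
setMethod("scoreVector", "SolverState", function(object) object@x)

#' @rdname SolverState-class
#' @export
setMethod("objectiveTrace", "SolverState", function(object) object@objectiveTrace)

#' @rdname SolverState-class
#' @export
setMethod("iterations", "SolverState", function(object) object@k)

#' @rdname SolverState-class
#' @export
setMethod("converged", "SolverState", function(object) object@converged)

setMethod("show", "SolverState", function(object) {
  f <- object@objectiveTrace
  cat(sprintf(
    "SolverState: %d iterations, %s, f(x) = %.4e (from %.4e), %d stalls\n",
    object@k,
    if (object@converged) "converged" else "iteration cap reached",
    f[length(f)], f[1], object@stalls))
})

#' @rdname AlignmentResult-class
#' @export
setMethod("alignedPairs", "AlignmentResult", function(object) object@pairs)

setMethod("show", "AlignmentResult", function(object) {
  cat(sprintf("AlignmentResult (%s): %d aligned pairs",
              object@method, nrow(object@pairs)))
  if (!is.na(object@accuracy))
    cat(sprintf(", accuracy %.3f", object@accuracy))
  cat("\n")
  if (nrow(object@pairs))
    print(utils::head(object@pairs, 6), row.names = FALSE)
})
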