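#' @rdname PPINetwork-class
#' @param x,object a [PPINetwork-class] (or other) object.
#' @export
setGeneric("nodeNames", function(x) standardGeneric("nodeNames"))

#' @rdname PPINetwork-class
#' @export
setGeneric("numNodes", function(x) standardGeneric("numNodes"))

#' @rdname PPINetwork-class
#' @export
setGeneric("numEdges", function(x) standardGeneric("numEdges"))

#' @rdname PPINetwork-class
#' @export
setGeneric("nodeDegrees", function(x) standardGeneric("nodeDegrees"))

#' @rdname PPINetwork-class
#' @export
setGeneric("adjacency", function(x) standardGeneric("adjacency"))

#' Apply the implicit product-graph operators to a vector
#'
#' `applyBbar` applies the column-stochastic random-walk transition matrix of
#' the Kronecker product graph; `applyBhat` applies the similarity-mixed
#' transition matrix (identical to `applyBbar` when `alpha = 1`);
#' `applyBhatT` applies its transpose. All three run in time proportional to
#' the sparse inputs and never allocate a product-sized matrix.
#'
#' @param op a [ProductOperator-class].
#' @param x,p numeric vector of length `productDim(op)`.
#' @return numeric vector of length `productDim(op)`.
#' @seealso [buildProductOperator()]
#' @export
setGeneric("applyBbar", function(op, x) standardGeneric("applyBbar"))

#' @rdname applyBbar
#' @export
setGeneric("applyBhat", function(op, x) standardGeneric("applyBhat"))

#' @rdname applyBbar
#' @export
setGeneric("applyBhatT", function(op, p) standardGeneric("applyBhatT"))

#' @rdname ProductOperator-class
#' @param op a [ProductOperator-class].
#' @export
setGeneric("productDim", function(op) standardGeneric("productDim"))

#' @rdname ProductOperator-class
#' @export
setGeneric("productDegrees", function(op) standardGeneric("productDegrees"))

#' @rdname ProductOperator-class
#' @export
setGeneric("mixingAlpha", function(op) standardGeneric("mixingAlpha"))

#' @rdname SolverState-class
#' @param object a [SolverState-class].
#' @export
setGeneric("scoreVector", function(object) standardGeneric("scoreVector"))

#' @rdname SolverState-class
#' @export
setGeneric("objectiveTrace", function(object) standardGeneric("objectiveTrace"))

#' @rdname SolverState-class
#' @export
setGeneric("iterations", function(object) standardGeneric("iterations"))

#' @rdname SolverState-class
#' @export
setGeneric("converged", function(object) standardGeneric("converged"))

#' @rdname AlignmentResult-class
#' @param object an [AlignmentResult-class].
#' @export
setGeneric("alignedPairs", function(object) standardGeneric("alignedPairs"))
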