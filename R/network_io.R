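#' Construct a PPINetwork from node names and an edge index matrix
#'
#' Low-level constructor used by the readers and the synthetic generators.
#' Edges are undirected index pairs into `nodeNames`; duplicates are
#' collapsed and self-loops rejected.
#'
#' @param nodeNames character vector of unique node names.
#' @param edges two-column integer matrix of 1-based node index pairs; may
#'   have zero rows.
#' @return a [PPINetwork-class].
#' @export
ppiNetwork <- function(nodeNames, edges) {
  nodeNames <- as.character(nodeNames)
  n <- length(nodeNames)
  edges <- matrix(as.integer(edges), ncol = 2)
  if (nrow(edges)) {
    if (any(edges < 1L) || any(edges > n))
      stop("edge indices out of range")
    if (any(edges[, 1] == edges[, 2]))
      stop("self-loops are not allowed")
    i <- pmin(edges[, 1], edges[, 2])
    j <- pmax(edges[, 1], edges[, 2])
    keep <- !duplicated(cbind(i, j))
    i <- i[keep]; j <- j[keep]
    A <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = 1,
                              dims = c(n, n))
  } else {
    A <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                              dims = c(n, n))
  }
  A <- as(Matrix::drop0(A), "CsparseMatrix")
  A@x[] <- 1
  new("PPINetwork", nodeNames = nodeNames, adjacency = A)
}

#' Read an undirected network from a whitespace-delimited edge list
#'
#' Each non-comment line names one undirected edge as two node names; extra
#' tokens are ignored (a numeric third column triggers a warning that edge
#' weights are discarded — networks are treated as unweighted). Duplicate
#' edges are collapsed and self-loops dropped with a warning. Node order is
#' first-appearance order.
#'
#' @param path path to the edge-list file.
#' @param commentPrefix lines starting with this prefix are skipped.
#' @return a [PPINetwork-class].
#' @export
readEdgeList <- function(path, commentPrefix = "#") {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("empty edge-list file: ", path)
  keep <- !startsWith(trimws(lines), commentPrefix) & nzchar(trimws(lines))
  idx <- which(keep)
  if (!length(idx)) stop("no edges in file: ", path)
  toks <- strsplit(trimws(lines[idx]), "[ \t]+")
  bad <- which(lengths(toks) < 2L)
  if (length(bad))
    stop("unreadable edge-list line ", idx[bad[1]], " in ", path,
         " (need at least two tokens)")
  from <- vapply(toks, `[`, character(1), 1L)
  to <- vapply(toks, `[`, character(1), 2L)
  third <- vapply(toks, function(t) if (length(t) >= 3L) t[3L] else NA_character_,
                  character(1))
  if (any(!is.na(suppressWarnings(as.numeric(third)))))
    warning("numeric third column found; edge weights are ignored ",
            "(networks are treated as unweighted)")
  selfloop <- from == to
  if (any(selfloop))
    warning(sum(selfloop), " self-loop(s) dropped")
  from <- from[!selfloop]; to <- to[!selfloop]
  if (!length(from)) stop("no edges left after dropping self-loops: ", path)
  # first-appearance node order, interleaved per line
  nodes <- unique(as.vector(rbind(from, to)))
  net <- ppiNetwork(nodes, cbind(match(from, nodes), match(to, nodes)))
  if (numEdges(net) == 0L) stop("no edges in file: ", path)
  net
}

#' Write a network as a two-column edge list
#'
#' Inverse of [readEdgeList()]: one undirected edge per line, node names
#' separated by a tab, each edge written once with the lower-index endpoint
#' first, in ascending index order.
#'
#' @param net a [PPINetwork-class].
#' @param path output file path.
#' @return invisibly, the path.
#' @export
writeEdgeList <- function(net, path) {
  stopifnot(is(net, "PPINetwork"))
  A <- adjacency(net)
  Tm <- as(Matrix::triu(A), "TsparseMatrix")
  i <- Tm@i + 1L; j <- Tm@j + 1L
  if (!length(i)) stop("network has no edges")
  ord <- order(i, j)
  lines <- paste(nodeNames(net)[i[ord]], nodeNames(net)[j[ord]], sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Construct a similarity table from in-memory vectors
#'
#' @param query,target node names (character) or 1-based indices (numeric)
#'   into `qnet` / `tnet`.
#' @param score non-negative numeric scores.
#' @param qnet,tnet the query and target [PPINetwork-class] objects.
#' @return a [SimilarityTable-class] with duplicate pairs summed.
#' @export
similarityTable <- function(query, target, score, qnet, tnet) {
  qi <- if (is.character(query)) match(query, nodeNames(qnet)) else as.integer(query)
  ti <- if (is.character(target)) match(target, nodeNames(tnet)) else as.integer(target)
  if (anyNA(qi))
    stop("unknown query node name(s): ",
         paste(unique(query[is.na(qi)]), collapse = ", "))
  if (anyNA(ti))
    stop("unknown target node name(s): ",
         paste(unique(target[is.na(ti)]), collapse = ", "))
  score <- as.numeric(score)
  if (any(score < 0)) stop("negative similarity score")
  key <- paste(qi, ti)
  if (anyDuplicated(key)) {
    warning("duplicate (query, target) similarity pairs summed")
    agg <- rowsum(score, key, reorder = FALSE)
    first <- !duplicated(key)
    qi <- qi[first]; ti <- ti[first]
    score <- as.numeric(agg[match(key[first], rownames(agg)), 1])
  }
  ord <- order(qi, ti)
  new("SimilarityTable", queryIndex = qi[ord], targetIndex = ti[ord],
      score = score[ord], queryNames = nodeNames(qnet),
      targetNames = nodeNames(tnet))
}

#' Read a three-column similarity table
#'
#' Columns: query node name, target node name, non-negative numeric score.
#' Duplicate pairs are summed with a warning; names absent from the networks
#' are an error.
#'
#' @param path path to the TSV/whitespace file.
#' @param qnet,tnet the query and target [PPINetwork-class] objects.
#' @return a [SimilarityTable-class].
#' @export
readSimilarity <- function(path, qnet, tnet) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, header = FALSE, comment.char = "#",
                           col.names = c("query", "target", "score"),
                           colClasses = c("character", "character", "numeric"))
  if (!nrow(tab)) stop("similarity table is empty: ", path)
  similarityTable(tab$query, tab$target, tab$score, qnet, tnet)
}

setMethod("show", "SimilarityTable", function(object) {
  cat(sprintf("SimilarityTable: %d entries over %d x %d node pairs, total score %g\n",
              length(object@score), length(object@queryNames),
              length(object@targetNames), sum(object@score)))
})

#' Dense similarity vector in query-major pair order
#'
#' @param sim a [SimilarityTable-class].
#' @return numeric vector of length Na * Nb with missing pairs 0.
#' @keywords internal
similarityVector <- function(sim) {
  Nb <- length(sim@targetNames)
  N <- length(sim@queryNames) * Nb
  S <- numeric(N)
  t <- (sim@queryIndex - 1L) * Nb + sim@targetIndex
  S[t] <- sim@score
  S
}

#' Write an alignment to a tab-separated file
#'
#' Columns `query`, `target`, `score` (full precision), one row per aligned
#' pair, sorted by query index.
#'
#' @param result an [AlignmentResult-class] with at least one pair.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
writeAlignment <- function(result, path) {
  stopifnot(is(result, "AlignmentResult"))
  p <- result@pairs
  if (!nrow(p)) stop("alignment is empty")
  lines <- c("query\ttarget\tscore",
             sprintf("%s\t%s\t%.17g", p$queryName, p$targetName, p$score))
  writeLines(lines, path)
  invisible(path)
}

#' Read an alignment written by [writeAlignment()]
#'
#' @param path alignment TSV with header `query`, `target`, `score`.
#' @return data.frame with character columns query, target and numeric score.
#' @export
readAlignment <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    colClasses = c("character", "character", "numeric"))
}

#' Read a two-column ground-truth node correspondence
#'
#' @param path file with lines `query_name<TAB>target_name`.
#' @param qnet,tnet networks giving the name universes.
#' @return integer vector `truth` of length `numNodes(qnet)` with
#'   `truth[u]` the 1-based target index of query node u.
#' @export
readTruth <- function(path, qnet, tnet) {
  tab <- utils::read.table(path, header = FALSE, comment.char = "#",
                           col.names = c("query", "target"),
                           colClasses = "character")
  qi <- match(tab$query, nodeNames(qnet))
  ti <- match(tab$target, nodeNames(tnet))
  if (anyNA(qi) || anyNA(ti)) stop("truth file names unknown nodes")
  truth <- rep(NA_integer_, numNodes(qnet))
  truth[qi] <- ti
  if (anyNA(truth)) stop("truth file must cover every query node")
  truth
}

#' Write a ground-truth correspondence as a two-column file
#'
#' @param truth integer vector, query index -> target index.
#' @param qnet,tnet networks supplying node names.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeTruth <- function(truth, qnet, tnet, path) {
  writeLines(paste(nodeNames(qnet), nodeNames(tnet)[truth], sep = "\t"), path)
  invisible(path)
}
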