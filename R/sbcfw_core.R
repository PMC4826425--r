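#' Create a coordinate block sampling scheme
#'
#' @param N total number of coordinates (the pair dimension Na * Nb).
#' @param nBlocks number of near-equal blocks n; `n = 1` degenerates to full
#'   (deterministic) Frank-Wolfe.
#' @param mode `"repartition"` (default) re-randomizes the partition every
#'   iteration; `"fixed_partition"` fixes n contiguous blocks once.
#' @param seed integer seed for the scheme's private RNG stream; two schemes
#'   with the same seed produce identical block sequences.
#' @return a [BlockScheme-class].
#' @seealso [sampleBlock()], [sbcfwRun()]
#' @export
blockScheme <- function(N, nBlocks, mode = c("repartition", "fixed_partition"),
                        seed = 42L) {
  mode <- match.arg(mode)
  N <- as.integer(N); nBlocks <- as.integer(nBlocks); seed <- as.integer(seed)
  if (nBlocks < 1L || nBlocks > N) stop("need 1 <= nBlocks <= N")
  env <- new.env(parent = emptyenv())
  # initialize the private stream without touching the caller's RNG
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv())
  else assign(".Random.seed", old, globalenv())
  partition <- if (mode == "fixed_partition") {
    sizes <- rep(N %/% nBlocks, nBlocks)
    extra <- N %% nBlocks
    if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    split(seq_len(N), rep.int(seq_len(nBlocks), sizes))
  } else list()
  new("BlockScheme", N = N, nBlocks = nBlocks, mode = mode, seed = seed,
      rngEnv = env, partition = partition)
}

# Evaluate expr with the scheme's private RNG stream swapped in.
withSchemeRNG <- function(scheme, expr) {
  env <- scheme@rngEnv
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  assign(".Random.seed", env$state, globalenv())
  on.exit({
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, globalenv())
  })
  expr
}

#' Sample the coordinate block for one iteration
#'
#' In `fixed_partition` mode one of the n precomputed blocks is chosen
#' uniformly; in `repartition` mode a fresh uniform random partition is drawn
#' each call and one of its blocks chosen uniformly, which is equivalent to
#' drawing a uniform random subset of size `ceiling(N / n)` without
#' replacement (implemented as a partial Fisher-Yates shuffle, one uniform
#' draw per selected index). Consumes the scheme's private RNG stream only,
#' with the same draw sequence in the R and compiled solver engines, so both
#' engines visit identical blocks for a given seed.
#'
#' @param scheme a [BlockScheme-class].
#' @param k iteration counter (informational; sampling is driven by the
#'   scheme's RNG stream, not by k).
#' @return sorted integer vector of 1-based coordinate indices.
#' @export
sampleBlock <- function(scheme, k = 0L) {
  stopifnot(is(scheme, "BlockScheme"))
  N <- scheme@N
  if (scheme@nBlocks == 1L) return(seq_len(N))
  withSchemeRNG(scheme, {
    if (scheme@mode == "fixed_partition") {
      bi <- min(floor(stats::runif(1) * scheme@nBlocks),
                scheme@nBlocks - 1) + 1L
      scheme@partition[[bi]]
    } else {
      env <- scheme@rngEnv
      if (is.null(env$perm)) env$perm <- seq_len(N)
      b <- as.integer(ceiling(N / scheme@nBlocks))
      for (i in seq_len(b)) {
        r <- i + floor(stats::runif(1) * (N - i + 1))
        if (r > N) r <- N
        tmp <- env$perm[i]; env$perm[i] <- env$perm[r]; env$perm[r] <- tmp
      }
      sort(env$perm[seq_len(b)])
    }
  })
}

#' Generic stochastic block-coordinate Frank-Wolfe loop
#'
#' Minimizes a convex differentiable objective over a compact convex set by
#' repeatedly (i) sampling a coordinate block, (ii) solving the linearized
#' subproblem restricted to that block (all other coordinates pinned at
#' their current values), and (iii) moving with a step size in \[0, 1\]
#' toward the subproblem solution. The loop is problem-agnostic: the
#' objective, block linear-minimization oracle, step-size rule, feasibility
#' test and stopping rule are supplied as callbacks.
#'
#' @param problem list of callbacks:
#'   \describe{
#'     \item{`objective(x)`}{objective value, evaluated every iteration.}
#'     \item{`blockLMO(x, block)`}{feasible point s minimizing the
#'       linearized objective with `s = x` outside `block`.}
#'     \item{`stepSize(x, s, block)`}{step length in \[0, 1\].}
#'     \item{`isFeasible(x)`}{feasibility predicate.}
#'     \item{`stop(x)`}{stopping rule, checked before each iteration.}
#'     \item{`postUpdate(xNew, x, s, gamma, block)`}{optional hook run after
#'       each update (used to maintain tracked residuals).}
#'   }
#' @param scheme a [BlockScheme-class].
#' @param x0 feasible starting point.
#' @param maxIter iteration cap; hitting it returns `converged = FALSE`.
#' @param traceFile optional path for a per-iteration TSV log
#'   (k, blockSize, gamma, f, stall).
#' @return a [SolverState-class]. The objective trace is guaranteed
#'   non-increasing: an increase beyond 1e-9 aborts with an error since the
#'   exact line search makes ascent impossible for a correct problem
#'   definition.
#' @export
sbcfwRun <- function(problem, scheme, x0, maxIter = NULL, traceFile = NULL) {
  stopifnot(is.list(problem), is(scheme, "BlockScheme"))
  if (is.null(maxIter))
    maxIter <- 50L * scheme@nBlocks * as.integer(ceiling(log(max(scheme@N, 2))))
  if (!problem$isFeasible(x0)) stop("infeasible starting point")
  x <- as.numeric(x0)
  f <- problem$objective(x)
  trace <- numeric(maxIter + 1L)
  trace[1L] <- f
  k <- 0L
  stalls <- 0L
  gamma <- 0
  block <- integer(0)
  logCon <- NULL
  if (!is.null(traceFile)) {
    logCon <- file(traceFile, "w")
    on.exit(close(logCon))
    writeLines("k\tblockSize\tgamma\tf\tstall", logCon)
  }
  convergedFlag <- FALSE
  while (k < maxIter) {
    if (problem$stop(x)) { convergedFlag <- TRUE; break }
    block <- sampleBlock(scheme, k)
    s <- problem$blockLMO(x, block)
    gamma <- problem$stepSize(x, s, block)
    if (gamma < 0 || gamma > 1) stop("step size outside [0, 1]")
    stall <- identical(gamma, 0) || !any(s != x)
    if (stall) stalls <- stalls + 1L
    xNew <- x + gamma * (s - x)
    if (!is.null(problem$postUpdate))
      problem$postUpdate(xNew, x, s, gamma, block)
    fNew <- problem$objective(xNew)
    if (fNew > f + 1e-9)
      stop(sprintf(
        "objective increased from %.12e to %.12e at iteration %d; %s",
        f, fNew, k + 1L,
        "monotone descent is violated, which signals a defect"))
    x <- xNew
    f <- fNew
    k <- k + 1L
    trace[k + 1L] <- f
    if (!is.null(logCon))
      writeLines(sprintf("%d\t%d\t%.17g\t%.17g\t%d",
                         k, length(block), gamma, f, as.integer(stall)),
                 logCon)
  }
  if (!convergedFlag && k >= maxIter && problem$stop(x)) convergedFlag <- TRUE
  new("SolverState", x = x, k = k, objectiveTrace = trace[seq_len(k + 1L)],
      lastGamma = as.numeric(gamma), lastBlock = as.integer(block),
      converged = convergedFlag, stalls = stalls)
}
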