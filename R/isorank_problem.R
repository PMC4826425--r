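#' Block-sparse simplex initialization
#'
#' Draws one coordinate block from the scheme and puts mass 1/b on each of
#' its b coordinates, zero elsewhere. The iterate is exactly on the unit
#' simplex and block-sparse, so the first residual computation touches only
#' one block's worth of coordinates.
#'
#' @param scheme a [BlockScheme-class].
#' @return numeric vector of length `scheme@N` on the unit simplex.
#' @export
initSimplex <- function(scheme) {
  block <- sampleBlock(scheme)
  x <- numeric(scheme@N)
  x[block] <- 1 / length(block)
  x
}

#' Residual-based objective of the eigenvector program
#'
#' `f(x) = 0.5 * ||Bhat x - x||^2`, the convex quadratic whose minimum over
#' the unit simplex (value 0 for an ergodic walk) is attained at the
#' stationary distribution / maximal right eigenvector.
#'
#' @param op a [ProductOperator-class].
#' @param x numeric pair vector.
#' @return non-negative scalar.
#' @export
isorankObjective <- function(op, x) {
  r <- applyBhat(op, x) - x
  0.5 * sum(r * r)
}

#' Partial gradient of the residual objective on a block
#'
#' The full gradient is `M x = (Bhat - I)' (Bhat - I) x = Bhat' p - p` with
#' the tracked residual `p = Bhat x - x`; the block partial gradient is its
#' restriction to the block.
#'
#' @param op a [ProductOperator-class].
#' @param p current residual `Bhat x - x`.
#' @param block integer coordinate block.
#' @return numeric vector of length N, zero outside `block`.
#' @export
partialGradient <- function(op, p, block) {
  restrictVector(applyBhatT(op, p) - p, block)
}

#' Closed-form block linear-minimization oracle on the simplex
#'
#' The linearized subproblem restricted to a block (all other coordinates
#' pinned) is a linear program over a scaled simplex slice carrying the
#' block's mass L; its optimum is the vertex putting all of L on the block
#' coordinate with the smallest partial-gradient entry (ties broken by the
#' smallest coordinate index).
#'
#' @param x current iterate on the unit simplex.
#' @param g partial gradient (any vector whose entries at `block` are the
#'   block gradient).
#' @param block non-empty integer coordinate block.
#' @return list with `s` (the vertex, equal to `x` outside the block), `j`
#'   (chosen coordinate) and `L` (block mass).
#' @export
simplexBlockLMO <- function(x, g, block) {
  if (!length(block)) stop("empty coordinate block")
  block <- sort(as.integer(block))
  L <- sum(x[block])
  j <- block[which.min(g[block])]
  s <- x
  s[block] <- 0
  s[j] <- L
  list(s = s, j = j, L = L)
}

#' Analytic exact line search for the residual objective
#'
#' Along the segment from x to s the residual is `(1 - gamma) p + gamma q`
#' with `p = E x` and `q = E s`, so the objective is a scalar quadratic in
#' gamma minimized at `(p'p - p'q) / ||p - q||^2`, clipped to \[0, 1\]; a
#' non-positive unconstrained minimizer or a degenerate direction gives
#' gamma = 0.
#'
#' @param p residual at x.
#' @param q residual at s.
#' @return optimal step gamma in \[0, 1\].
#' @export
optimalStep <- function(p, q) {
  pp <- sum(p * p)
  pq <- sum(p * q)
  qq <- sum(q * q)
  denom <- pp - 2 * pq + qq           # ||p - q||^2
  if (denom < 1e-15) return(0)
  ghat <- (pp - pq) / denom
  if (ghat <= 0) 0 else min(1, ghat)
}

#' Residual recurrences for the tracked vectors p and q
#'
#' `computeQ` turns the residual at x into the residual at the oracle vertex
#' s using only the block-sparse difference `s - x`; `updateResidual`
#' advances the residual across the convex update `x + gamma (s - x)`.
#' Both avoid any full recomputation of `E x`.
#'
#' @param op a [ProductOperator-class].
#' @param p residual `Bhat x - x` at the current iterate.
#' @param s oracle vertex from [simplexBlockLMO()].
#' @param x current iterate.
#' @param gamma step size.
#' @param q residual at s (from `computeQ`).
#' @return numeric residual vector of length N.
#' @export
computeQ <- function(op, p, s, x) {
  delta <- s - x
  if (!any(delta != 0)) return(p)
  p + applyBhat(op, delta) - delta
}

#' @rdname computeQ
#' @export
updateResidual <- function(p, q, gamma) {
  (1 - gamma) * p + gamma * q
}

#' Relative-residual stopping rule
#'
#' Stops when `||Bhat x - x|| <= xi * ||x||`, evaluated from the tracked
#' residual so no extra operator application is needed.
#'
#' @param p tracked residual.
#' @param x current iterate.
#' @param xi positive relative tolerance.
#' @return logical.
#' @export
residualStop <- function(p, x, xi) {
  sqrt(sum(p * p)) <= xi * sqrt(sum(x * x))
}

#' Assemble the eigenvector problem callbacks for the generic solver
#'
#' Wires the residual objective, the closed-form block oracle, the analytic
#' step size, simplex feasibility and the relative-residual stopping rule
#' into the callback list consumed by [sbcfwRun()]. The tracked residual p
#' lives in a shared environment and is advanced by the cheap recurrences;
#' with `debug = TRUE` both p and q are checked against from-scratch
#' recomputation (tolerance 1e-10) at every iteration and the largest
#' deviations are recorded.
#'
#' @param op a [ProductOperator-class].
#' @param xi positive relative stopping tolerance.
#' @param x0 starting point (used to prime the tracked residual).
#' @param debug logical; verify the residual recurrences every iteration.
#' @return list of callbacks plus the shared state environment (`$env`).
#' @export
isorankProblem <- function(op, xi, x0, debug = FALSE) {
  env <- new.env(parent = emptyenv())
  env$p <- applyBhat(op, x0) - x0
  env$q <- NULL
  env$maxPErr <- 0
  env$maxQErr <- 0
  list(
    env = env,
    objective = function(x) 0.5 * sum(env$p * env$p),
    blockLMO = function(x, block) {
      g <- partialGradient(op, env$p, block)
      lmo <- simplexBlockLMO(x, g, block)
      env$q <- computeQ(op, env$p, lmo$s, x)
      if (debug) {
        qRef <- applyBhat(op, lmo$s) - lmo$s
        err <- max(abs(env$q - qRef))
        env$maxQErr <- max(env$maxQErr, err)
        if (err > 1e-10)
          stop("tracked q deviates from recomputed E s by ", err)
      }
      lmo$s
    },
    stepSize = function(x, s, block) optimalStep(env$p, env$q),
    isFeasible = function(x) {
      abs(sum(x) - 1) <= 1e-9 && min(x) >= -1e-12
    },
    stop = function(x) residualStop(env$p, x, xi),
    postUpdate = function(xNew, x, s, gamma, block) {
      env$p <- updateResidual(env$p, env$q, gamma)
      if (debug) {
        pRef <- applyBhat(op, xNew) - xNew
        err <- max(abs(env$p - pRef))
        env$maxPErr <- max(env$maxPErr, err)
        if (err > 1e-10)
          stop("tracked p deviates from recomputed E x by ", err)
      }
    })
}

#' Solve the network-alignment eigenvector program by stochastic
#' block-coordinate Frank-Wolfe
#'
#' End-to-end solver: builds the implicit product operator from the two
#' networks (and optional similarity table), initializes a block-sparse
#' simplex point, and runs the block-coordinate Frank-Wolfe loop with
#' closed-form oracles and exact line search until the relative residual
#' drops below `xi` or the iteration cap is hit. Per-iteration work is a
#' constant number of implicit operator applications; nothing of size N^2
#' is ever formed.
#'
#' @param qnet,tnet query and target [PPINetwork-class] objects.
#' @param sim optional [SimilarityTable-class].
#' @param alpha topology/similarity mixing weight; defaults to 0.5 with a
#'   similarity table and 1 without.
#' @param nBlocks number of coordinate blocks n.
#' @param xi relative residual stopping tolerance (default 0.1).
#' @param seed integer seed driving block sampling and initialization.
#' @param mode block sampling mode, see [blockScheme()].
#' @param maxIter iteration cap (default `50 * n * ceiling(log(N))`).
#' @param debug verify residual recurrences at every iteration (forces the
#'   reference R engine).
#' @param traceFile optional per-iteration TSV log path.
#' @param engine `"compiled"` (default) runs the iteration loop in C++ with
#'   block-sparse updates; `"reference"` runs the modular R loop built from
#'   [sbcfwRun()] and the callback operations. Both implement the identical
#'   algorithm and consume the same block-sampling RNG stream; the compiled
#'   engine exists because tight tolerances can take hundreds of thousands
#'   of (cheap) iterations.
#' @param x0 optional feasible starting point on the unit simplex; by
#'   default a block-sparse point drawn by [initSimplex()].
#' @return a [SolverState-class]; `scoreVector()` of the result is the
#'   converged pair-score vector on the unit simplex.
#' @examples
#' tri <- ppiNetwork(letters[1:3], rbind(c(1, 2), c(2, 3), c(3, 1)))
#' st <- sbcfwIsoRank(tri, tri, nBlocks = 3, xi = 1e-8, seed = 1)
#' round(scoreVector(st), 3)  # uniform 1/9: K3 x K3 is regular
#' @export
sbcfwIsoRank <- function(qnet, tnet, sim = NULL,
                         alpha = if (is.null(sim)) 1 else 0.5,
                         nBlocks = 30L, xi = 0.1, seed = 42L,
                         mode = c("repartition", "fixed_partition"),
                         maxIter = NULL, debug = FALSE, traceFile = NULL,
                         engine = c("compiled", "reference"), x0 = NULL) {
  mode <- match.arg(mode)
  engine <- match.arg(engine)
  if (debug) engine <- "reference"
  op <- buildProductOperator(qnet, tnet, sim = sim, alpha = alpha)
  N <- productDim(op)
  if (nBlocks > N) stop("nBlocks exceeds the pair dimension ", N)
  scheme <- blockScheme(N, nBlocks, mode = mode, seed = seed)
  if (is.null(x0)) {
    x0 <- initSimplex(scheme)
  } else {
    if (length(x0) != N || abs(sum(x0) - 1) > 1e-9 || min(x0) < -1e-12)
      stop("x0 must be a length-N point on the unit simplex")
    x0 <- as.numeric(x0)
  }
  if (is.null(maxIter))
    maxIter <- 50L * nBlocks * as.integer(ceiling(log(max(N, 2))))
  if (engine == "reference") {
    problem <- isorankProblem(op, xi = xi, x0 = x0, debug = debug)
    state <- sbcfwRun(problem, scheme, x0, maxIter = maxIter,
                      traceFile = traceFile)
    if (debug)
      state@diagnostics <- list(maxPErr = problem$env$maxPErr,
                                maxQErr = problem$env$maxQErr)
    return(state)
  }
  Aa <- adjacency(qnet)
  Ab <- adjacency(tnet)
  wantLog <- !is.null(traceFile)
  perm0 <- scheme@rngEnv$perm
  if (is.null(perm0)) perm0 <- integer(0)
  res <- withSchemeRNG(scheme,
    .sbcfwKernel(Aa@p, Aa@i, Ab@p, Ab@i,
                 numNodes(qnet), numNodes(tnet),
                 productDegrees(op), op@sbar, mixingAlpha(op),
                 x0, as.integer(nBlocks), mode, xi,
                 as.integer(maxIter), wantLog, as.integer(perm0)))
  if (wantLog) {
    k <- res$k
    log <- data.frame(k = seq_len(k), blockSize = res$sizeLog,
                      gamma = res$gammaLog, f = res$trace[-1],
                      stall = res$stallLog)
    utils::write.table(format(log, digits = 17), traceFile, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  new("SolverState", x = res$x, k = as.integer(res$k),
      objectiveTrace = res$trace, lastGamma = res$lastGamma,
      lastBlock = integer(0), converged = res$converged,
      stalls = as.integer(res$stalls), diagnostics = list())
}
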