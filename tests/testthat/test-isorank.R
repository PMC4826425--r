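smallInstance <- function(alpha = 1, seedQ = 1, seedT = 2) {
  qn <- randomConnectedGraph(5, 3, seed = seedQ, prefix = "q")
  tn <- randomConnectedGraph(10, 4, seed = seedT, prefix = "t")
  sim <- if (alpha < 1)
    synthSimilarity(qn, tn, truth = seq_len(5), signal = 1,
                    noisePairs = 4, seed = 3)
  op <- buildProductOperator(qn, tn, sim, alpha = alpha)
  list(qn = qn, tn = tn, sim = sim, op = op,
       E = denseBhatOracle(qn, tn, sim, alpha) - diag(productDim(op)))
}

test_that("block-sparse initialization lands exactly on the simplex", {
  sch <- blockScheme(9, 3, mode = "fixed_partition", seed = 2)
  x0 <- initSimplex(sch)
  expect_equal(sum(x0), 1)
  b <- which(x0 > 0)
  expect_equal(length(b), 3L)
  expect_equal(unique(x0[b]), 1 / 3)
  # single block: uniform start
  expect_equal(initSimplex(blockScheme(7, 1, seed = 1)), rep(1 / 7, 7))
  # non-divisible N: mass is 1/b for the chosen block's true size b
  x0b <- initSimplex(blockScheme(10, 3, seed = 6))
  expect_equal(sum(x0b), 1)
  expect_true(all(x0b >= 0))
})

test_that("objective is the squared residual and vanishes at stationarity", {
  inst <- smallInstance(alpha = 1)
  d <- productDegrees(inst$op)
  expect_equal(isorankObjective(inst$op, d / sum(d)), 0, tolerance = 1e-28)
  set.seed(5)
  for (rep in 1:5) {
    x <- runif(productDim(inst$op))
    expect_equal(isorankObjective(inst$op, x),
                 0.5 * sum((inst$E %*% x)^2), tolerance = 1e-12)
    expect_gte(isorankObjective(inst$op, x), 0)
  }
  # basis vector against the dense operator
  e4 <- numeric(productDim(inst$op)); e4[4] <- 1
  expect_equal(isorankObjective(inst$op, e4),
               0.5 * sum((inst$E %*% e4)^2), tolerance = 1e-14)
})

test_that("partial gradients restrict M x and sum across a partition", {
  inst <- smallInstance(alpha = 0.5)
  N <- productDim(inst$op)
  M <- t(inst$E) %*% inst$E
  set.seed(8)
  x <- as.numeric(stats::rgamma(N, 1)); x <- x / sum(x)
  p <- applyBhat(inst$op, x) - x
  full <- partialGradient(inst$op, p, seq_len(N))
  expect_lt(max(abs(full - M %*% x)), 1e-10)
  b1 <- seq_len(20); b2 <- setdiff(seq_len(N), b1)
  expect_equal(partialGradient(inst$op, p, b1) +
                 partialGradient(inst$op, p, b2), full, tolerance = 1e-14)
  # zero at the stationary point
  xs <- denseOracleStationary(inst$op, tol = 1e-14)
  ps <- applyBhat(inst$op, xs) - xs
  expect_lt(max(abs(partialGradient(inst$op, ps, seq_len(N)))), 1e-10)
})

test_that("the block oracle moves all block mass to the argmin vertex", {
  x <- c(0.2, 0.3, 0.5)
  g <- c(3, 1, 2)
  lmo <- simplexBlockLMO(x, g, 1:3)
  expect_equal(lmo$L, 1)
  expect_equal(lmo$j, 2L)
  expect_equal(lmo$s, c(0, 1, 0))

  # ties resolve to the smallest coordinate index
  lmoT <- simplexBlockLMO(c(0.5, 0.25, 0.25), c(1, 1, 1), 2:3)
  expect_equal(lmoT$j, 2L)
  expect_equal(lmoT$s, c(0.5, 0.5, 0))

  # empty block rejected; massless block is a no-op direction
  expect_error(simplexBlockLMO(x, g, integer(0)), "empty")
  lmo0 <- simplexBlockLMO(c(1, 0, 0), g, 2:3)
  expect_equal(lmo0$L, 0)
  expect_equal(lmo0$s, c(1, 0, 0))

  # block sums are conserved exactly
  set.seed(31)
  for (rep in 1:20) {
    x <- as.numeric(stats::rgamma(12, 1)); x <- x / sum(x)
    blk <- sort(sample.int(12, 5))
    s <- simplexBlockLMO(x, rnorm(12), blk)$s
    expect_identical(sum(s[blk]), sum(x[blk]))
    expect_identical(s[-blk], x[-blk])
  }
})

test_that("the analytic step size minimizes the residual quadratic", {
  p <- c(1, 0); q0 <- c(0, 0)
  expect_equal(optimalStep(p, p), 0)
  expect_equal(optimalStep(p, q0), 1)
  # p'p = 1, p'q = 0, q'q = 1 -> gamma = 0.5, confirmed by grid search
  p1 <- c(1, 0); q1 <- c(0, 1)
  expect_equal(optimalStep(p1, q1), 0.5)
  grid <- seq(0, 1, by = 1e-3)
  h <- vapply(grid, function(g) sum(((1 - g) * p1 + g * q1)^2), numeric(1))
  expect_equal(grid[which.min(h)], 0.5)
})

test_that("residual recurrences agree with dense from-scratch computation", {
  inst <- smallInstance(alpha = 0.5)
  N <- productDim(inst$op)
  set.seed(17)
  for (rep in 1:10) {
    x <- as.numeric(stats::rgamma(N, 1)); x <- x / sum(x)
    p <- applyBhat(inst$op, x) - x
    blk <- sort(sample.int(N, 8))
    g <- partialGradient(inst$op, p, blk)
    lmo <- simplexBlockLMO(x, g, blk)
    q <- computeQ(inst$op, p, lmo$s, x)
    expect_lt(max(abs(q - inst$E %*% lmo$s)), 1e-12)
    gam <- optimalStep(p, q)
    xn <- x + gam * (lmo$s - x)
    pn <- updateResidual(p, q, gam)
    expect_lt(max(abs(pn - inst$E %*% xn)), 1e-12)
    # q = p when the direction is null
    expect_identical(computeQ(inst$op, p, x, x), p)
  }
})

test_that("the stopping rule compares residual and iterate norms", {
  expect_true(residualStop(numeric(5), c(1, 0, 0, 0, 0), 1e-9))
  expect_false(residualStop(c(0.2, 0, 0), c(1, 0, 0), 0.1))
  expect_true(residualStop(c(0.09, 0, 0), c(1, 0, 0), 0.1))
})

test_that("the solver finds the degree-proportional stationary vector", {
  qn <- randomConnectedGraph(5, 3, seed = 21, prefix = "q")
  tn <- randomConnectedGraph(12, 4, seed = 22, prefix = "t")
  op <- buildProductOperator(qn, tn)
  d <- productDegrees(op)
  st <- sbcfwIsoRank(qn, tn, nBlocks = 4, xi = 1e-6, seed = 5,
                     maxIter = 5e5)
  expect_true(converged(st))
  expect_lt(sum(abs(scoreVector(st) - d / sum(d))), 1e-3)
})

test_that("identical seeds give identical runs and engines agree", {
  qn <- randomConnectedGraph(4, 3, seed = 31, prefix = "q")
  tn <- randomConnectedGraph(8, 3, seed = 32, prefix = "t")
  a <- sbcfwIsoRank(qn, tn, nBlocks = 6, xi = 1e-5, seed = 9, maxIter = 2e4)
  b <- sbcfwIsoRank(qn, tn, nBlocks = 6, xi = 1e-5, seed = 9, maxIter = 2e4)
  expect_identical(scoreVector(a), scoreVector(b))
  expect_identical(objectiveTrace(a), objectiveTrace(b))

  # reference R loop and compiled loop implement the same iteration
  r <- sbcfwIsoRank(qn, tn, nBlocks = 6, xi = 1e-5, seed = 9,
                    maxIter = 2e4, engine = "reference")
  n <- min(length(objectiveTrace(r)), length(objectiveTrace(a)))
  expect_lt(max(abs(objectiveTrace(r)[1:n] - objectiveTrace(a)[1:n])), 1e-12)
  expect_lte(abs(iterations(r) - iterations(a)), 1L)
})

test_that("n = 1 reproduces deterministic full Frank-Wolfe", {
  qn <- randomConnectedGraph(4, 3, seed = 41, prefix = "q")
  tn <- randomConnectedGraph(7, 3, seed = 42, prefix = "t")
  op <- buildProductOperator(qn, tn)
  N <- productDim(op)
  # asymmetric start so the argmin of the gradient is strict at every step
  xa <- (1 + seq_len(N)) / sum(1 + seq_len(N))
  oracle <- fullFWOracle(denseBhatOracle(qn, tn), xa, 100)
  for (eng in c("reference", "compiled")) {
    st <- sbcfwIsoRank(qn, tn, nBlocks = 1, xi = 1e-14, seed = 1,
                       maxIter = 100, engine = eng, x0 = xa)
    expect_equal(objectiveTrace(st), oracle$trace, tolerance = 1e-10)
    expect_equal(scoreVector(st), oracle$x, tolerance = 1e-8)
  }
})

test_that("every iterate stays on the simplex and f matches the residual", {
  inst <- smallInstance(alpha = 0.5)
  sch <- blockScheme(productDim(inst$op), 5, seed = 3)
  x0 <- initSimplex(sch)
  problem <- isorankProblem(inst$op, xi = 1e-7, x0 = x0)
  iterates <- list()
  innerPost <- problem$postUpdate
  problem$postUpdate <- function(xNew, x, s, gamma, block) {
    innerPost(xNew, x, s, gamma, block)
    iterates[[length(iterates) + 1L]] <<- xNew
  }
  st <- sbcfwRun(problem, sch, x0, maxIter = 300)
  for (x in iterates) {
    expect_lt(abs(sum(x) - 1), 1e-9)
    expect_gt(min(x), -1e-12)
  }
  fLast <- objectiveTrace(st)[iterations(st) + 1L]
  expect_equal(fLast, isorankObjective(inst$op, scoreVector(st)),
               tolerance = 1e-10)
})

test_that("debug mode certifies the tracked recurrences over a long run", {
  qn <- randomConnectedGraph(4, 3, seed = 51, prefix = "q")
  tn <- randomConnectedGraph(9, 3, seed = 52, prefix = "t")
  st <- sbcfwIsoRank(qn, tn, nBlocks = 4, xi = 1e-14, seed = 2,
                     maxIter = 500, debug = TRUE)
  expect_gte(iterations(st), 500L)
  expect_lt(st@diagnostics$maxPErr, 1e-10)
  expect_lt(st@diagnostics$maxQErr, 1e-10)
})

test_that("per-iteration trace files record the run", {
  qn <- randomConnectedGraph(4, 3, seed = 61, prefix = "q")
  tn <- randomConnectedGraph(8, 3, seed = 62, prefix = "t")
  tf <- tempfile(fileext = ".tsv")
  st <- sbcfwIsoRank(qn, tn, nBlocks = 4, xi = 1e-4, seed = 3,
                     maxIter = 500, traceFile = tf)
  log <- utils::read.table(tf, header = TRUE)
  expect_equal(nrow(log), iterations(st))
  expect_true(all(log$gamma >= 0 & log$gamma <= 1))
  expect_equal(log$f[nrow(log)],
               objectiveTrace(st)[iterations(st) + 1L], tolerance = 1e-9)
})
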