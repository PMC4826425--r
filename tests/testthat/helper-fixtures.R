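# Small graphs and independent dense oracles used across tests.
# The oracles build the product matrices with base kronecker() and never go
# through the package's implicit-operator code paths.

triangleNet <- function(names = c("a", "b", "c")) {
  ppiNetwork(names, rbind(c(1, 2), c(2, 3), c(3, 1)))
}

pathNet <- function(n = 3, prefix = "p") {
  ppiNetwork(paste0(prefix, seq_len(n)), cbind(seq_len(n - 1), 2:n))
}

# dense Kronecker-product pieces in the package's query-major convention
denseKron <- function(qnet, tnet) {
  B <- kronecker(as.matrix(adjacency(qnet)), as.matrix(adjacency(tnet)))
  d <- rowSums(B)
  dinv <- ifelse(d > 0, 1 / d, 0)
  list(B = B, d = d, Bbar = B %*% diag(dinv, nrow(B)))
}

denseBhatOracle <- function(qnet, tnet, sim = NULL, alpha = 1) {
  dk <- denseKron(qnet, tnet)
  if (alpha == 1) return(dk$Bbar)
  Nb <- numNodes(tnet)
  S <- numeric(nrow(dk$B))
  S[(sim@queryIndex - 1L) * Nb + sim@targetIndex] <- sim@score
  sbar <- S / sum(S)
  alpha * dk$Bbar + (1 - alpha) * sbar %*% t(rep(1, length(S)))
}

writeTempEdges <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

# deterministic full Frank-Wolfe on the residual objective, written
# independently of the package's solver loop (dense algebra throughout)
fullFWOracle <- function(Bhat, x0, nIter) {
  E <- Bhat - diag(nrow(Bhat))
  M <- t(E) %*% E
  x <- x0
  trace <- 0.5 * sum((E %*% x)^2)
  for (k in seq_len(nIter)) {
    g <- as.numeric(M %*% x)
    j <- which.min(g)
    s <- numeric(length(x)); s[j] <- 1
    p <- as.numeric(E %*% x); q <- as.numeric(E %*% s)
    denom <- sum((p - q)^2)
    gam <- if (denom < 1e-15) 0 else {
      gh <- (sum(p * p) - sum(p * q)) / denom
      if (gh <= 0) 0 else min(1, gh)
    }
    x <- x + gam * (s - x)
    trace <- c(trace, 0.5 * sum((E %*% x)^2))
  }
  list(x = x, trace = trace)
}
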