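# Independent oracles and small-instance generators shared across tests.

# Generic convex-programming oracle for the graph-guided fused lasso: ADMM on
# the generalized-lasso splitting z = M b, where M stacks the identity (for
# the l1 term) over the weighted signed edge-difference rows (for the fusion
# term). Implemented from the objective definition only -- it shares no code
# with the package solver.
admmOracle <- function(X, Y, edges, lambda, gamma, rho = 2, iters = 20000) {
  p <- ncol(X); k <- ncol(Y)
  A <- kronecker(diag(k), X)               # b = vec(B), column-major
  y <- as.vector(Y)
  Mi <- seq_len(p * k); Mj <- seq_len(p * k); Mx <- rep(1, p * k)
  nE <- if (is.null(edges)) 0L else nrow(edges)
  nRows <- p * k
  if (nE > 0 && gamma > 0) {
    r0 <- p * k
    for (e in seq_len(nE)) {
      w <- gamma * abs(edges$weight[e]); s <- sign(edges$weight[e])
      m <- edges$from[e]; l <- edges$to[e]
      for (j in seq_len(p)) {
        rr <- r0 + (e - 1) * p + j
        Mi <- c(Mi, rr, rr)
        Mj <- c(Mj, (m - 1) * p + j, (l - 1) * p + j)
        Mx <- c(Mx, w, -w * s)
      }
    }
    nRows <- p * k + nE * p
  }
  M <- matrix(0, nRows, p * k); M[cbind(Mi, Mj)] <- Mx
  H <- crossprod(A) + rho * crossprod(M)
  Hc <- chol(H)
  Aty <- crossprod(A, y)
  z <- numeric(nRows); u <- numeric(nRows)
  soft <- function(v, t) sign(v) * pmax(abs(v) - t, 0)
  for (it in seq_len(iters)) {
    b <- backsolve(Hc, forwardsolve(t(Hc), Aty + rho * crossprod(M, z - u)))
    Mb <- as.vector(M %*% b)
    v <- Mb + u
    z1 <- soft(v[1:(p * k)], lambda / rho)
    z2 <- if (nRows > p * k) soft(v[(p * k + 1):nRows], 1 / rho) else numeric(0)
    z <- c(z1, z2)
    u <- u + Mb - z
  }
  B <- matrix(b, p, k)
  obj <- 0.5 * sum((Y - X %*% B)^2) + lambda * sum(abs(B))
  if (nE > 0 && gamma > 0) {
    for (e in seq_len(nE)) {
      obj <- obj + gamma * abs(edges$weight[e]) *
        sum(abs(B[, edges$from[e]] - sign(edges$weight[e]) * B[, edges$to[e]]))
    }
  }
  list(B = B, objective = obj)
}

# support-recovery F1 over marker x trait index pairs
supportF1 <- function(est, truth) {
  tp <- sum(est & truth); fp <- sum(est & !truth); fn <- sum(!est & truth)
  if (tp == 0) return(0)
  2 * tp / (2 * tp + fp + fn)
}

# random small GFlasso instance for oracle-equivalence sweeps
randomSmallInstance <- function() {
  n <- sample(8:12, 1); p <- sample(2:8, 1); k <- sample(2:4, 1)
  X <- matrix(rnorm(n * p), n, p)
  Y <- matrix(rnorm(n * k), n, k)
  nE <- min(sample(1:6, 1), k * (k - 1) / 2)
  pairs <- t(combn(k, 2))
  pairs <- pairs[sample(nrow(pairs), nE), , drop = FALSE]
  edges <- data.frame(from = pairs[, 1], to = pairs[, 2],
                      weight = runif(nE, -1, 1))
  list(X = X, Y = Y, edges = edges,
       lambda = runif(1, 0.02, 0.8), gamma = runif(1, 0.02, 0.8))
}

# a small paired dataset written from plain matrices
toyPaired <- function(X, Y) {
  pairDatasets(GenotypeMatrix(X), TraitMatrix(Y))
}

# GFlasso sub-problem blocks (standardized X, centered trait groups, edges
# reindexed within each group) from a paired dataset and a network threshold
recoveryBlocks <- function(pd, threshold, seed) {
  net <- correlationNetwork(pd@traits, threshold = threshold)
  part <- traitPartition(net, cap = 250, seed = seed)
  X <- values(pd@genotype)
  b <- gfmap:::standardizeForGFlasso(X)
  blocks <- lapply(part@groups, function(g) {
    ed <- edges(net)
    keep <- ed$from %in% g & ed$to %in% g
    e <- ed[keep, , drop = FALSE]
    e$from <- match(e$from, g); e$to <- match(e$to, g)
    Yg <- scale(values(pd@traits)[, g, drop = FALSE], scale = FALSE)
    list(X = b$X, Y = Yg, edges = e, g = g)
  })
  blocks
}
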