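#' @include screen.R
#' @useDynLib gfmap, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

## spectral norm squared, computed on the smaller Gram matrix
specNorm2 <- function(X) {
  G <- if (nrow(X) <= ncol(X)) tcrossprod(X) else crossprod(X)
  max(eigen(G, symmetric = TRUE, only.values = TRUE)$values, 0)
}

#' Construct a graph-guided fused lasso sub-problem
#'
#' Bundles a standardized genotype submatrix, a trait block, the
#' trait-network edges restricted to the block, the two regularization
#' parameters and the solver controls. The fusion penalty couples the
#' coefficient columns of network-adjacent traits:
#' \deqn{F(B) = \tfrac12\|Y - XB\|_F^2 + \lambda\sum_{j,k}|B_{jk}|
#'   + \gamma\sum_{(m,l)\in E} |r_{ml}| \sum_j |B_{jm} - \mathrm{sign}(r_{ml})
#'   B_{jl}|.}
#'
#' @param X `n x p` genotype submatrix (standardize beforehand; the solver
#'   uses it as given).
#' @param Y `n x k` trait block.
#' @param edges data.frame (`from`, `to`, `weight`) with indices into the
#'   columns of `Y`; pass a zero-row frame for no fusion.
#' @param lambda,gamma sparsity and fusion penalties, `>= 0`.
#' @param mu fusion smoothing parameter; `NULL` (default) uses
#'   `tol / (2 * max(1, nEdges) * p)`, capped at 1e-2. Larger values trade
#'   accuracy for speed.
#' @param tol relative-objective convergence tolerance (default 1e-6).
#' @param maxIter iteration cap.
#' @return a \linkS4class{GFLassoProblem}.
#' @export
gflassoProblem <- function(X, Y, edges = NULL, lambda, gamma, mu = NULL,
                           tol = 1e-6, maxIter = 100000L) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (is.null(edges))
    edges <- data.frame(from = integer(), to = integer(), weight = numeric())
  if (is.null(mu)) mu <- min(tol / (2 * max(1L, nrow(edges)) * ncol(X)), 1e-2)
  new("GFLassoProblem", X = X, Y = Y, edges = edges, lambda = as.numeric(lambda),
      gamma = as.numeric(gamma), mu = as.numeric(mu), tol = as.numeric(tol),
      maxIter = as.integer(maxIter))
}

#' Graph-guided fused lasso objective value
#'
#' The unsmoothed objective of a \linkS4class{GFLassoProblem} at `B`: squared
#' Frobenius loss, the lambda-weighted l1 term, and the gamma-weighted fusion
#' term over network edges (see [gflassoProblem()] for the formula).
#'
#' @param B `p x k` coefficient matrix.
#' @param prob a \linkS4class{GFLassoProblem}.
#' @return the objective value.
#' @export
gflassoObjective <- function(B, prob) {
  B <- as.matrix(B)
  stopifnot(nrow(B) == ncol(prob@X), ncol(B) == ncol(prob@Y))
  loss <- 0.5 * sum((prob@Y - prob@X %*% B)^2)
  l1 <- prob@lambda * sum(abs(B))
  fuse <- 0
  e <- prob@edges
  if (nrow(e) && prob@gamma > 0) {
    for (i in seq_len(nrow(e)))
      fuse <- fuse + abs(e$weight[i]) *
        sum(abs(B[, e$from[i]] - sign(e$weight[i]) * B[, e$to[i]]))
    fuse <- prob@gamma * fuse
  }
  loss + l1 + fuse
}

#' Fit the graph-guided fused lasso by smoothing proximal gradient
#'
#' The non-smooth fusion penalty is Nesterov-smoothed with parameter `mu`
#' (dual variable clipped to `[-1, 1]`); the smoothed loss is minimized with
#' accelerated proximal-gradient steps (soft-threshold prox for the l1
#' term), backtracking line search seeded at `1 / sigma_max(X)^2`, and a
#' monotone acceptance rule, so the objective of accepted iterates never
#' increases. Iteration stops when the relative change of the true
#' (unsmoothed) objective falls below `tol`, or at `maxIter` (in which case
#' the solution is returned flagged `converged = FALSE`).
#'
#' With `gamma = 0` each column of the solution is the lasso for that trait
#' (note this objective has no `1/n` factor: it matches
#' [lassoFit()]`(..., lambda / n, standardize = FALSE)`); with
#' `lambda = gamma = 0` it is the least-squares fit.
#'
#' @param prob a \linkS4class{GFLassoProblem}.
#' @param warmStart optional `p x k` starting matrix.
#' @return a \linkS4class{GFLassoSolution}; entries of `B` below 1e-8 in
#'   magnitude are exactly zero.
#' @export
fitGFlasso <- function(prob, warmStart = NULL) {
  stopifnot(is(prob, "GFLassoProblem"))
  validObject(prob)
  p <- ncol(prob@X); k <- ncol(prob@Y)
  B0 <- if (is.null(warmStart)) matrix(0, p, k) else as.matrix(warmStart)
  stopifnot(nrow(B0) == p, ncol(B0) == k)
  e <- prob@edges
  hasE <- nrow(e) > 0 && prob@gamma > 0
  ef <- if (hasE) as.integer(e$from) - 1L else integer(0)
  et <- if (hasE) as.integer(e$to) - 1L else integer(0)
  ew <- if (hasE) prob@gamma * abs(e$weight) else numeric(0)
  es <- if (hasE) sign(e$weight) else numeric(0)
  sx2 <- specNorm2(prob@X)
  stepInit <- 1 / max(sx2, 1e-8)
  res <- .gflassoSPG(prob@X, prob@Y, ef, et, ew, es, prob@lambda, prob@mu,
                     prob@tol, prob@maxIter, B0, stepInit)
  new("GFLassoSolution", B = res$B, objective = res$objective,
      nIter = as.integer(res$nIter), converged = res$converged)
}

#' Cross-validation error of GFlasso at one (lambda, gamma)
#'
#' Splits the samples into `nFolds` seeded folds (or, with
#' `mode = "random"`, draws `nFolds` independent 90/10 splits), fits the
#' sub-problem on each training set and accumulates the held-out squared
#' error `||Y_test - X_test B_train||_F^2`. Errors are additive over
#' sub-network blocks: sum the returned values across blocks.
#'
#' @param X,Y,edges the block data (see [gflassoProblem()]).
#' @param lambda,gamma regularization parameters.
#' @param nFolds number of fits (default 10).
#' @param seed fold seed.
#' @param mode `"cv"` (default, a 10-fold partition) or `"random"`
#'   (independent 90/10 splits).
#' @param mu,tol,maxIter solver controls, see [gflassoProblem()].
#' @param warmStart optional starting matrix shared across folds.
#' @return total held-out squared error (non-negative scalar).
#' @export
cvErrorGFlasso <- function(X, Y, edges, lambda, gamma, nFolds = 10L, seed = 1L,
                           mode = c("cv", "random"), mu = NULL, tol = 1e-5,
                           maxIter = 20000L, warmStart = NULL) {
  mode <- match.arg(mode)
  n <- nrow(X)
  if (n < nFolds) gfStop("gfmap_spec_error", "need at least nFolds samples")
  testSets <- if (mode == "cv") {
    f <- makeFolds(n, nFolds, seed)
    lapply(sort(unique(f)), function(i) which(f == i))
  } else {
    set.seed(seed)
    lapply(seq_len(nFolds), function(i) sample.int(n, max(1L, round(0.1 * n))))
  }
  err <- 0
  for (te in testSets) {
    prob <- gflassoProblem(X[-te, , drop = FALSE], Y[-te, , drop = FALSE],
                           edges, lambda, gamma, mu = mu, tol = tol,
                           maxIter = maxIter)
    sol <- fitGFlasso(prob, warmStart = warmStart)
    err <- err + sum((Y[te, , drop = FALSE] -
                        X[te, , drop = FALSE] %*% sol@B)^2)
  }
  err
}

## pick the gamma-grid point nearest the log-scale midpoint
logMidpoint <- function(grid) {
  g <- sort(grid)
  mid <- exp(mean(log(range(g[g > 0]))))
  g[which.min(abs(log(pmax(g, min(g[g > 0]) / 10)) - log(mid)))]
}

#' Three-stage cross-validated (lambda, gamma) search
#'
#' The alternating linear search over the two GFlasso regularization
#' parameters: stage 1 scans `lambdaGrid` at `gamma = gammaInit`; stage 2
#' scans `gammaGrid` at the stage-1 best lambda; stage 3 scans a refined
#' lambda grid (the [refineGrid()] rule around the stage-1 best) at the
#' stage-2 best gamma. Each scan point is scored by the summed
#' cross-validation error over all sub-network blocks ([cvErrorGFlasso()],
#' `nFolds` fits per block per point). Ties in the argmin are broken toward
#' the more regularized (larger) value. Finally each block is refit on all
#' samples at the selected pair.
#'
#' @param blocks list of blocks, each a list with elements `X`, `Y`,
#'   `edges` (see [gflassoProblem()]).
#' @param lambdaGrid,gammaGrid positive scan grids.
#' @param gammaInit stage-1 gamma; defaults to the `gammaGrid` point nearest
#'   its log-scale midpoint (membership of the grid guarantees the stage-3
#'   best CV error is no worse than stage 1's).
#' @param nFolds fits per block per grid point (default 10).
#' @param seed fold seed (shared by all stages).
#' @param mode,mu,tol,maxIter see [cvErrorGFlasso()].
#' @param refinePoints size of the stage-3 lambda grid.
#' @return list with `records` (three \linkS4class{RegSearchRecord}s),
#'   `solutions` (one \linkS4class{GFLassoSolution} per block), and the
#'   selected `lambda` and `gamma`.
#' @export
stagedSearch <- function(blocks, lambdaGrid, gammaGrid, gammaInit = NULL,
                         nFolds = 10L, seed = 1L, mode = c("cv", "random"),
                         mu = NULL, tol = 1e-5, maxIter = 20000L,
                         refinePoints = 10L) {
  mode <- match.arg(mode)
  if (!length(lambdaGrid) || !length(gammaGrid))
    gfStop("gfmap_spec_error", "empty regularization grid")
  lambdaGrid <- sort(unique(as.numeric(lambdaGrid)), decreasing = TRUE)
  gammaGrid <- sort(unique(as.numeric(gammaGrid)), decreasing = TRUE)
  if (is.null(gammaInit)) gammaInit <- logMidpoint(gammaGrid)

  scan <- function(values, fixed, varying) {
    vapply(values, function(v) {
      lam <- if (varying == "lambda") v else fixed
      gam <- if (varying == "gamma") v else fixed
      sum(vapply(blocks, function(b)
        cvErrorGFlasso(b$X, b$Y, b$edges, lam, gam, nFolds = nFolds,
                       seed = seed, mode = mode, mu = mu, tol = tol,
                       maxIter = maxIter), 0))
    }, 0)
  }
  # grids are decreasing, so the first argmin is the more regularized value
  argbest <- function(errs) which(errs == min(errs))[1L]

  e1 <- scan(lambdaGrid, gammaInit, "lambda")
  b1 <- argbest(e1)
  rec1 <- new("RegSearchRecord", stage = 1L, parameter = "lambda",
              grid = lambdaGrid, fixedValue = gammaInit, cvError = e1,
              bestIndex = as.integer(b1))

  e2 <- scan(gammaGrid, lambdaGrid[b1], "gamma")
  b2 <- argbest(e2)
  rec2 <- new("RegSearchRecord", stage = 2L, parameter = "gamma",
              grid = gammaGrid, fixedValue = lambdaGrid[b1], cvError = e2,
              bestIndex = as.integer(b2))
  gammaBest <- gammaGrid[b2]

  state1 <- new("LambdaSearchState", grid = lambdaGrid, cvError = e1,
                bestIndex = as.integer(b1), stage = "coarse")
  fineGrid <- refineGrid(state1, nPoints = refinePoints)
  e3 <- scan(fineGrid, gammaBest, "lambda")
  b3 <- argbest(e3)
  rec3 <- new("RegSearchRecord", stage = 3L, parameter = "lambda",
              grid = fineGrid, fixedValue = gammaBest, cvError = e3,
              bestIndex = as.integer(b3))
  lambdaBest <- fineGrid[b3]

  solutions <- lapply(blocks, function(b) {
    prob <- gflassoProblem(b$X, b$Y, b$edges, lambdaBest, gammaBest, mu = mu,
                           tol = tol, maxIter = maxIter)
    fitGFlasso(prob)
  })
  list(records = list(rec1, rec2, rec3), solutions = solutions,
       lambda = lambdaBest, gamma = gammaBest)
}
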