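test_that("gflassoObjective matches hand arithmetic on a 2x2 problem", {
  X <- diag(2)
  Y <- matrix(c(1, 2, -1, 0.5), 2, 2)
  edges <- data.frame(from = 1L, to = 2L, weight = -0.5)
  prob <- gflassoProblem(X, Y, edges, lambda = 0.3, gamma = 2)
  B <- matrix(c(0.4, -0.2, 0.1, 0.3), 2, 2)
  loss <- 0.5 * sum((Y - B)^2)
  l1 <- 0.3 * (0.4 + 0.2 + 0.1 + 0.3)
  # edge (1,2) with r = -0.5: weight |r|, sign(r) = -1, summed over markers
  fuse <- 2 * 0.5 * (abs(0.4 - (-1) * 0.1) + abs(-0.2 - (-1) * 0.3))
  expect_equal(gflassoObjective(B, prob), loss + l1 + fuse, tolerance = 1e-12)
  # B = 0: objective is half the squared Frobenius norm of Y
  expect_equal(gflassoObjective(matrix(0, 2, 2), prob), 0.5 * sum(Y^2))
  # no edges: the fusion term vanishes for any B
  prob0 <- gflassoProblem(X, Y, NULL, lambda = 0.3, gamma = 2)
  expect_equal(gflassoObjective(B, prob0), loss + l1, tolerance = 1e-12)
})

test_that("the solver reaches the convex optimum found by an ADMM oracle", {
  set.seed(30)
  for (rep in 1:8) {
    ins <- randomSmallInstance()
    prob <- gflassoProblem(ins$X, ins$Y, ins$edges, ins$lambda, ins$gamma,
                           tol = 1e-9, maxIter = 200000L)
    sol <- fitGFlasso(prob)
    expect_true(sol@converged)
    ref <- admmOracle(ins$X, ins$Y, ins$edges, ins$lambda, ins$gamma)
    expect_lt(abs(sol@objective - ref$objective) / max(1, abs(ref$objective)),
              1e-4)
    # the reported objective is the objective of the reported coefficients
    expect_equal(sol@objective, gflassoObjective(sol@B, prob),
                 tolerance = 1e-10)
  }
})

test_that("gamma = 0 reduces to independent per-trait lassos", {
  set.seed(31)
  n <- 20; p <- 6; k <- 3
  X <- matrix(rnorm(n * p), n, p)
  Y <- matrix(rnorm(n * k), n, k)
  lambda <- 0.8
  prob <- gflassoProblem(X, Y, NULL, lambda = lambda, gamma = 0,
                         tol = 1e-13, maxIter = 300000L)
  sol <- fitGFlasso(prob)
  for (t in seq_len(k)) {
    b <- lassoFit(X, Y[, t], lambda / n, standardize = FALSE, thresh = 1e-14)
    expect_lt(max(abs(sol@B[, t] - b)), 1e-5)
  }
})

test_that("lambda = gamma = 0 reduces to least squares", {
  set.seed(32)
  n <- 25; p <- 5; k <- 2
  X <- matrix(rnorm(n * p), n, p)
  Y <- matrix(rnorm(n * k), n, k)
  prob <- gflassoProblem(X, Y, NULL, lambda = 0, gamma = 0,
                         tol = 1e-13, maxIter = 300000L)
  sol <- fitGFlasso(prob)
  ref <- qr.solve(X, Y)
  expect_equal(unname(sol@B), unname(ref), tolerance = 1e-5)
})

test_that("large gamma fuses the columns of positively linked traits", {
  set.seed(33)
  n <- 20; p <- 4
  X <- matrix(rnorm(n * p), n, p)
  b1 <- c(1.5, 0, -1, 0)
  Y <- cbind(X %*% b1 + rnorm(n, sd = 0.2),
             X %*% (b1 + c(0.4, 0, 0, -0.3)) + rnorm(n, sd = 0.2))
  edges <- data.frame(from = 1L, to = 2L, weight = 1)
  gap <- vapply(c(0.1, 1, 10, 100), function(g) {
    sol <- fitGFlasso(gflassoProblem(X, Y, edges, lambda = 0.05, gamma = g,
                                     tol = 1e-9, maxIter = 200000L))
    max(abs(sol@B[, 1] - sol@B[, 2]))
  }, 0)
  expect_true(all(diff(gap) <= 1e-6))
  expect_lt(gap[4], 1e-3)
})

test_that("a negative edge fuses columns up to sign", {
  set.seed(34)
  n <- 20; p <- 3
  X <- matrix(rnorm(n * p), n, p)
  b <- c(2, -1, 0)
  Y <- cbind(X %*% b + rnorm(n, sd = 0.2), -X %*% b + rnorm(n, sd = 0.2))
  edges <- data.frame(from = 1L, to = 2L, weight = -1)
  sol <- fitGFlasso(gflassoProblem(X, Y, edges, lambda = 0.05, gamma = 100,
                                   tol = 1e-9, maxIter = 200000L))
  expect_lt(max(abs(sol@B[, 1] + sol@B[, 2])), 1e-3)
})

test_that("the fit is invariant to trait ordering", {
  set.seed(35)
  n <- 15; p <- 4; k <- 3
  X <- matrix(rnorm(n * p), n, p)
  Y <- matrix(rnorm(n * k), n, k)
  edges <- data.frame(from = c(1L, 2L), to = c(2L, 3L), weight = c(0.8, -0.6))
  solA <- fitGFlasso(gflassoProblem(X, Y, edges, 0.2, 0.3,
                                    tol = 1e-10, maxIter = 200000L))
  perm <- c(3L, 1L, 2L)                      # new position of old trait i
  inv <- order(perm)
  # the fusion term is symmetric in (from, to) for |weight-sign| edges, so
  # renormalize to the stored from < to convention
  edgesP <- data.frame(from = pmin(perm[edges$from], perm[edges$to]),
                       to = pmax(perm[edges$from], perm[edges$to]),
                       weight = edges$weight)
  solB <- fitGFlasso(gflassoProblem(X, Y[, inv], edgesP, 0.2, 0.3,
                                    tol = 1e-10, maxIter = 200000L))
  expect_equal(solB@B[, perm], solA@B, tolerance = 1e-4)
  expect_equal(solB@objective, solA@objective, tolerance = 1e-8)
})

test_that("hitting maxIter reports converged = FALSE", {
  set.seed(36)
  X <- matrix(rnorm(40), 10, 4)
  Y <- matrix(rnorm(20), 10, 2)
  sol <- fitGFlasso(gflassoProblem(X, Y, NULL, 0.1, 0, tol = 1e-12,
                                   maxIter = 3L))
  expect_false(sol@converged)
  expect_lte(sol@nIter, 3L)
})

test_that("cvErrorGFlasso sums held-out errors over seeded folds", {
  set.seed(37)
  n <- 18; p <- 4; k <- 2
  X <- matrix(rnorm(n * p), n, p)
  Y <- matrix(rnorm(n * k), n, k)
  edges <- data.frame(from = 1L, to = 2L, weight = 0.7)
  err <- cvErrorGFlasso(X, Y, edges, 0.2, 0.1, nFolds = 3, seed = 5,
                        mu = 1e-4, tol = 1e-8, maxIter = 100000L)
  expect_gte(err, 0)
  # independent fold-loop recomputation
  folds <- gfmap:::makeFolds(n, 3, 5)
  ref <- 0
  for (f in sort(unique(folds))) {
    te <- folds == f
    sol <- fitGFlasso(gflassoProblem(X[!te, ], Y[!te, , drop = FALSE], edges,
                                     0.2, 0.1, mu = 1e-4, tol = 1e-8,
                                     maxIter = 100000L))
    ref <- ref + sum((Y[te, , drop = FALSE] - X[te, , drop = FALSE] %*% sol@B)^2)
  }
  expect_equal(err, ref, tolerance = 1e-10)
  expect_identical(err, cvErrorGFlasso(X, Y, edges, 0.2, 0.1, nFolds = 3,
                                       seed = 5, mu = 1e-4, tol = 1e-8,
                                       maxIter = 100000L))
})

test_that("stagedSearch with singleton grids selects those values", {
  set.seed(38)
  n <- 15; p <- 3; k <- 2
  blocks <- list(list(X = matrix(rnorm(n * p), n, p),
                      Y = matrix(rnorm(n * k), n, k),
                      edges = data.frame(from = 1L, to = 2L, weight = 0.6)))
  res <- stagedSearch(blocks, lambdaGrid = 0.5, gammaGrid = 0.2, nFolds = 3,
                      seed = 1, mu = 1e-3, tol = 1e-6, maxIter = 50000L,
                      refinePoints = 4L)
  expect_equal(res$gamma, 0.2)
  expect_length(res$records, 3L)
  expect_equal(res$records[[1]]@parameter, "lambda")
  expect_equal(res$records[[2]]@parameter, "gamma")
  expect_equal(res$records[[2]]@bestIndex, 1L)
  expect_true(res$lambda %in% res$records[[3]]@grid)
  expect_s4_class(res$solutions[[1]], "GFLassoSolution")
})

test_that("the stage-3 best CV error never exceeds stage 1's", {
  set.seed(39)
  n <- 20; p <- 4; k <- 3
  X <- matrix(rnorm(n * p), n, p)
  B <- matrix(0, p, k); B[1, ] <- 1.2; B[3, 1:2] <- -0.8
  Y <- X %*% B + matrix(rnorm(n * k, sd = 0.3), n, k)
  blocks <- list(list(X = X, Y = Y,
                      edges = data.frame(from = c(1L, 2L), to = c(2L, 3L),
                                         weight = c(0.8, 0.7))))
  res <- stagedSearch(blocks, lambdaGrid = c(4, 1, 0.25),
                      gammaGrid = c(2, 0.5, 0.125), nFolds = 4, seed = 2,
                      mu = 1e-3, tol = 1e-7, maxIter = 100000L,
                      refinePoints = 5L)
  e1 <- res$records[[1]]@cvError
  e2 <- res$records[[2]]@cvError
  e3 <- res$records[[3]]@cvError
  expect_lte(min(e2), min(e1) + 1e-8)
  expect_lte(min(e3), min(e1) + 1e-8)
  # gammaInit is the gamma-grid point nearest the log midpoint: 0.5 here, so
  # stage 2 at the stage-1 lambda reproduces the stage-1 best error
  expect_equal(e2[2], min(e1), tolerance = 1e-10)
})

test_that("mu defaults cap at 1e-2 and scale with tol and problem size", {
  X <- matrix(rnorm(40), 10, 4)
  Y <- matrix(rnorm(30), 10, 3)
  edges <- data.frame(from = c(1L, 2L), to = c(2L, 3L), weight = c(1, -1))
  prob <- gflassoProblem(X, Y, edges, 0.1, 0.1, tol = 1e-6)
  expect_equal(prob@mu, min(1e-6 / (2 * 2 * 4), 1e-2))
  probLoose <- gflassoProblem(X, Y, edges, 0.1, 0.1, tol = 1)
  expect_equal(probLoose@mu, 1e-2)
})
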