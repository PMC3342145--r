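#' @include io.R network.R
NULL

## seeded uniform random fold assignment, shared across trait blocks within a
## CV stage so held-out errors are comparable
makeFolds <- function(n, nFolds, seed) {
  if (nFolds < 2L) gfStop("gfmap_spec_error", "need at least 2 folds")
  set.seed(seed)
  f <- sample(rep_len(seq_len(nFolds), n))
  if (min(table(f)) < 2L || n - max(table(f)) < 2L)
    gfStop("gfmap_spec_error",
           "a fold has fewer than 2 samples (n = %d, folds = %d)", n, nFolds)
  f
}

#' Single-marker Wald test statistics
#'
#' For every (marker, trait) pair, the trait is regressed on the genotype by
#' simple linear regression; the Wald statistic is `slope / SE(slope)` with
#' a two-sided p-value from the t distribution on `n - 2` degrees of
#' freedom. Markers with fewer than two distinct genotype values have an
#' undefined statistic: their slope is set to 0 and p to 1, with a warning.
#' Zero-residual fits give a p-value clamped at the smallest positive
#' double rather than 0.
#'
#' `waldStats` returns the dense statistic matrices; [waldTest()] wraps them
#' into a sparse \linkS4class{AssociationResult} (weight = slope), keeping
#' entries with `p <= pCutoff`.
#'
#' @param pd a \linkS4class{PairedDataset} with at least 3 samples.
#' @return list of `p x k` matrices `slope`, `statistic`, `p`.
#' @export
waldStats <- function(pd) {
  X <- pd@genotype@values; Y <- pd@traits@values
  n <- nrow(X)
  if (n < 3) gfStop("gfmap_spec_error", "need at least 3 samples")
  Xc <- sweep(X, 2L, colMeans(X))
  Yc <- sweep(Y, 2L, colMeans(Y))
  Sxx <- colSums(Xc^2)
  Syy <- colSums(Yc^2)
  degenerate <- Sxx == 0
  if (any(degenerate))
    warning(sprintf("%d marker(s) with a single genotype value: statistic undefined, reported as 0 with p = 1",
                    sum(degenerate)))
  SxxSafe <- ifelse(degenerate, 1, Sxx)
  Sxy <- crossprod(Xc, Yc)                       # p x k
  slope <- Sxy / SxxSafe
  SSE <- pmax(rep(Syy, each = nrow(Sxy)) - slope * Sxy, 0)
  se2 <- SSE / ((n - 2) * SxxSafe)
  stat <- ifelse(se2 > 0, slope / sqrt(se2),
                 ifelse(slope == 0, 0, sign(slope) * Inf))
  p <- pmax(2 * stats::pt(-abs(stat), df = n - 2), .Machine$double.xmin)
  slope[degenerate, ] <- 0
  stat[degenerate, ] <- 0
  p[degenerate, ] <- 1
  list(slope = slope, statistic = stat, p = p)
}

#' @rdname waldStats
#' @param pCutoff keep entries with p-value at most this (default 1: all
#'   nonzero slopes).
#' @param adjust multiple-testing correction applied to the p-values before
#'   filtering: `"none"` (default, raw associations), `"bonferroni"` or
#'   `"BH"`.
#' @return `waldTest`: an \linkS4class{AssociationResult} with
#'   `methodTag = "wald"`.
#' @export
waldTest <- function(pd, pCutoff = 1, adjust = c("none", "bonferroni", "BH")) {
  adjust <- match.arg(adjust)
  st <- waldStats(pd)
  p <- st$p
  if (adjust != "none") p[] <- stats::p.adjust(p, method = adjust)
  keep <- which(st$slope != 0 & p <= pCutoff, arr.ind = TRUE)
  AssociationResult(markerIds(pd), traitIds(pd),
                    marker = keep[, 1], trait = keep[, 2],
                    weight = st$slope[keep], p_value = p[keep],
                    methodTag = "wald")
}

#' Wilcoxon rank-sum test of minor-allele carriers vs non-carriers
#'
#' Samples are split per marker into carriers (genotype > 0) and
#' non-carriers (genotype == 0). The rank-sum statistic uses mid-ranks for
#' ties. For small samples (`n <= 50`) and traits without tied values the
#' p-value is exact (the Mann-Whitney null distribution, equal to full
#' enumeration of carrier assignments); otherwise it comes from the normal
#' approximation with a tie-corrected variance and a continuity correction.
#' The reported weight is the signed standardized statistic. Markers for
#' which either group is empty are skipped with a warning (their entries are
#' `NA` in `wilcoxonStats`).
#'
#' @param pd a \linkS4class{PairedDataset}.
#' @return `wilcoxonStats`: list of `p x k` matrices `z` and `p` (`NA` for
#'   skipped markers).
#' @export
wilcoxonStats <- function(pd) {
  X <- pd@genotype@values; Y <- pd@traits@values
  n <- nrow(X); p <- ncol(X); k <- ncol(Y)
  G <- (X > 0) * 1
  n1 <- colSums(G); n2 <- n - n1
  skip <- n1 == 0 | n2 == 0
  if (any(skip))
    warning(sprintf("%d marker(s) with an empty carrier or non-carrier group: skipped",
                    sum(skip)))
  R <- apply(Y, 2L, rank)                         # mid-ranks per trait
  tieTerm <- apply(Y, 2L, function(y) {
    tt <- table(y)
    sum(tt^3 - tt) / ((n + 1) * n * (n - 1))
  })
  W1 <- crossprod(G, R)                           # p x k rank sums (carriers)
  mu <- n1 * (n + 1) / 2
  v <- outer(n1 * n2 / 12, (n + 1) * (1 - tieTerm))  # tie-corrected variance
  d <- W1 - mu
  d <- sign(d) * pmax(abs(d) - 0.5, 0)            # continuity correction
  z <- ifelse(v > 0, d / sqrt(v), 0)
  pv <- 2 * stats::pnorm(-abs(z))
  if (n <= 50L) {
    # exact Mann-Whitney p (equals enumeration of carrier assignments) for
    # traits without ties; grouped by carrier count so pwilcox vectorizes
    untied <- which(vapply(seq_len(k), function(t) !anyDuplicated(Y[, t]), TRUE))
    if (length(untied)) {
      for (m1 in unique(n1[!skip])) {
        rows <- which(n1 == m1 & !skip)
        if (!length(rows)) next
        m2 <- n - m1
        U <- W1[rows, untied, drop = FALSE] - m1 * (m1 + 1) / 2
        lo <- 2 * stats::pwilcox(U, m1, m2)
        hi <- 2 * stats::pwilcox(U - 1, m1, m2, lower.tail = FALSE)
        pv[rows, untied] <- pmin(ifelse(U > m1 * m2 / 2, hi, lo), 1)
      }
    }
  }
  z[skip, ] <- NA_real_
  pv[skip, ] <- NA_real_
  list(z = z, p = pv)
}

#' @rdname wilcoxonStats
#' @inheritParams waldTest
#' @return `wilcoxonTest`: an \linkS4class{AssociationResult} with
#'   `methodTag = "wilcoxon"` (weight = standardized statistic).
#' @export
wilcoxonTest <- function(pd, pCutoff = 1, adjust = c("none", "bonferroni", "BH")) {
  adjust <- match.arg(adjust)
  st <- wilcoxonStats(pd)
  p <- st$p
  if (adjust != "none") p[] <- stats::p.adjust(p, method = adjust)
  keep <- which(!is.na(st$z) & st$z != 0 & p <= pCutoff, arr.ind = TRUE)
  AssociationResult(markerIds(pd), traitIds(pd),
                    marker = keep[, 1], trait = keep[, 2],
                    weight = st$z[keep], p_value = p[keep],
                    methodTag = "wilcoxon")
}

#' The smallest lambda with an all-zero lasso solution
#'
#' With columns of `X` z-scored (population, 1/n, convention) and `y`
#' centered, the lasso solution is identically zero iff
#' `lambda >= max_j |x_j' y| / n`.
#'
#' @param X predictor matrix.
#' @param y response vector.
#' @param standardize use the z-scored-X / centered-y convention (default);
#'   otherwise `X` and `y` are used as given.
#' @return the critical lambda.
#' @export
lambdaMax <- function(X, y, standardize = TRUE) {
  n <- nrow(X)
  if (standardize) {
    Xc <- sweep(X, 2L, colMeans(X))
    s <- sqrt(colSums(Xc^2) / n)
    s[s == 0] <- 1
    X <- sweep(Xc, 2L, s, "/")
    y <- y - mean(y)
  }
  max(abs(crossprod(X, y))) / n
}

#' Lasso fit at a single regularization value
#'
#' Minimizes `(1/(2n)) ||y - X b||^2 + lambda ||b||_1` by cyclic coordinate
#' descent (via glmnet). With `standardize = TRUE` (default) columns of `X`
#' are z-scored and an intercept/centred `y` is used internally, with
#' coefficients reported on the original scale; with `standardize = FALSE`
#' the problem is solved on `X`, `y` exactly as given (no intercept).
#'
#' @param X `n x p` predictor matrix.
#' @param y length-`n` response.
#' @param lambda penalty, `>= 0`.
#' @param standardize see Description.
#' @param thresh coordinate-descent convergence threshold.
#' @return numeric coefficient vector of length `p` (no intercept).
#' @export
lassoFit <- function(X, y, lambda, standardize = TRUE, thresh = 1e-10) {
  p <- ncol(X)
  lmax <- lambdaMax(X, y, standardize = standardize)
  if (lambda >= lmax) return(numeric(p))         # KKT: all-zero solution
  if (lambda == 0) {                              # exact least-squares limit
    if (nrow(X) <= p)
      gfStop("gfmap_spec_error", "lambda = 0 requires n > p (full column rank)")
    fit <- if (standardize) stats::lm.fit(cbind(1, X), y)$coefficients[-1]
           else stats::lm.fit(X, y)$coefficients
    fit[is.na(fit)] <- 0
    return(as.numeric(fit))
  }
  if (p == 1L) {                                  # closed form, one predictor
    n <- nrow(X)
    if (standardize) {
      xc <- X[, 1] - mean(X[, 1]); yc <- y - mean(y)
      s <- sqrt(sum(xc^2) / n); if (s == 0) return(0)
      z <- sum(xc / s * yc) / n
      b <- sign(z) * max(abs(z) - lambda, 0) / (sum((xc / s)^2) / n)
      return(b / s)
    }
    z <- sum(X[, 1] * y) / length(y)
    return(sign(z) * max(abs(z) - lambda, 0) / (sum(X[, 1]^2) / length(y)))
  }
  path <- exp(seq(log(lmax), log(max(lambda, lmax * 1e-3)), length.out = 25L))
  if (lambda < path[length(path)]) path <- c(path, lambda)
  fit <- glmnet::glmnet(X, y, family = "gaussian", lambda = path,
                        standardize = standardize, intercept = standardize,
                        thresh = thresh, maxit = 10^6)
  idx <- which.min(abs(fit$lambda - lambda))
  as.numeric(fit$beta[, idx])
}

#' One cross-validated lambda search stage over trait blocks
#'
#' Traits are partitioned into blocks of at most `traitBlock` (the unit of
#' parallel work); within each block and fold, a lasso path over the whole
#' grid is fit per trait on the training folds and the held-out squared
#' error is accumulated for every grid value. Errors are summed over all
#' traits and folds, yielding one global best lambda (ties broken toward
#' the larger value). The fold assignment is seeded and shared across all
#' blocks, so the result is independent of the blocking.
#'
#' @param pd a \linkS4class{PairedDataset}.
#' @param lambdaGrid positive lambda values (any order; used in decreasing
#'   order).
#' @param nFolds number of CV folds (default 5).
#' @param traitBlock block size (default 250).
#' @param seed fold-assignment seed.
#' @param stage `"coarse"` or `"fine"` (recorded in the state).
#' @param markers optional integer subset of markers to use.
#' @return list with `state` (a \linkS4class{LambdaSearchState}),
#'   `coefficients` (sparse `p x k` [Matrix::sparseMatrix] of per-trait
#'   lasso coefficients refit on all samples at the best lambda) and
#'   `folds` (the fold assignment).
#' @export
lassoCVStage <- function(pd, lambdaGrid, nFolds = 5L, traitBlock = 250L,
                         seed = 1L, stage = c("coarse", "fine"),
                         markers = NULL) {
  stage <- match.arg(stage)
  if (!length(lambdaGrid)) gfStop("gfmap_spec_error", "empty lambda grid")
  grid <- sort(unique(as.numeric(lambdaGrid)), decreasing = TRUE)
  X <- pd@genotype@values
  if (!is.null(markers)) X <- X[, markers, drop = FALSE]
  Y <- pd@traits@values
  n <- nrow(X); k <- ncol(Y)
  folds <- makeFolds(n, nFolds, seed)
  bounds <- chunkBounds(k, traitBlock)
  cvError <- numeric(length(grid))
  for (b in seq_len(nrow(bounds))) {
    tr <- bounds$start[b]:bounds$end[b]
    cvError <- cvError + lassoCVBlock(X, Y[, tr, drop = FALSE], grid, folds)
  }
  best <- which(cvError == min(cvError))[1L]      # ties -> larger lambda
  state <- new("LambdaSearchState", grid = grid, cvError = cvError,
               bestIndex = as.integer(best), stage = stage)
  B <- lassoMatrix(X, Y, grid, grid[best])
  list(state = state, coefficients = B, folds = folds)
}

## held-out squared error per grid lambda for one trait block
lassoCVBlock <- function(X, Yb, grid, folds) {
  err <- numeric(length(grid))
  for (f in sort(unique(folds))) {
    te <- folds == f
    Xtr <- X[!te, , drop = FALSE]; Xte <- X[te, , drop = FALSE]
    for (t in seq_len(ncol(Yb))) {
      ytr <- Yb[!te, t]; yte <- Yb[te, t]
      fit <- glmnet::glmnet(Xtr, ytr, family = "gaussian", lambda = grid,
                            standardize = TRUE, intercept = TRUE)
      pred <- stats::predict(fit, newx = Xte, s = grid, exact = FALSE)
      err <- err + colSums((yte - pred)^2)
    }
  }
  err
}

## per-trait coefficients at bestLambda, refit on all samples
lassoMatrix <- function(X, Y, grid, bestLambda) {
  p <- ncol(X); k <- ncol(Y)
  bi <- list(); bj <- list(); bx <- list()
  for (t in seq_len(k)) {
    fit <- glmnet::glmnet(X, Y[, t], family = "gaussian", lambda = grid,
                          standardize = TRUE, intercept = TRUE)
    idx <- which.min(abs(fit$lambda - bestLambda))
    b <- fit$beta[, idx]
    nz <- which(b != 0)
    if (length(nz)) {
      bi[[t]] <- nz; bj[[t]] <- rep(t, length(nz)); bx[[t]] <- b[nz]
    }
  }
  Matrix::sparseMatrix(i = as.integer(unlist(bi)), j = as.integer(unlist(bj)),
                       x = as.numeric(unlist(bx)), dims = c(p, k))
}

#' Refine a lambda grid around the current best value
#'
#' Builds a new grid of `nPoints` log-spaced values spanning the interval
#' between the grid neighbors of the best point (the fine-tuned search of
#' the two-stage lambda selection). When the best value sits on a grid
#' boundary the span extends one coarse grid ratio beyond it. The best
#' lambda itself is always a member of the new grid.
#'
#' @param state a \linkS4class{LambdaSearchState} with computed errors.
#' @param nPoints size of the refined grid (default 10).
#' @return numeric vector, strictly decreasing.
#' @export
refineGrid <- function(state, nPoints = 10L) {
  g <- state@grid
  if (any(g <= 0)) gfStop("gfmap_spec_error", "refineGrid requires a positive grid")
  b <- state@bestIndex
  ratio <- if (length(g) >= 2L) g[1] / g[2] else 10
  upper <- if (b > 1L) g[b - 1L] else g[1] * ratio
  lower <- if (b < length(g)) g[b + 1L] else g[length(g)] / ratio
  newGrid <- exp(seq(log(upper), log(lower), length.out = nPoints))
  newGrid[which.min(abs(newGrid - g[b]))] <- g[b]  # keep the incumbent
  sort(unique(newGrid), decreasing = TRUE)
}

#' Default coarse lambda grid
#'
#' Ten log-spaced values from the critical `lambdaMax` of the dataset (the
#' smallest all-zero lambda, maximized over traits) down to 1% of it.
#'
#' @param pd a \linkS4class{PairedDataset}.
#' @param nPoints grid size.
#' @param markers optional marker subset.
#' @return decreasing numeric vector.
#' @export
defaultLambdaGrid <- function(pd, nPoints = 10L, markers = NULL) {
  X <- pd@genotype@values
  if (!is.null(markers)) X <- X[, markers, drop = FALSE]
  Y <- pd@traits@values
  lmax <- max(vapply(seq_len(ncol(Y)), function(t) lambdaMax(X, Y[, t]), 0))
  exp(seq(log(lmax), log(0.01 * lmax), length.out = nPoints))
}

#' Select markers for GFlasso from lasso prescreening results
#'
#' Markers are ranked by the number of traits with a nonzero lasso
#' coefficient (descending), ties by the total absolute coefficient mass
#' (descending), then by marker index (ascending). If fewer than `cap`
#' markers carry any nonzero coefficient, the remainder is filled with the
#' markers of largest maximum absolute marginal trait correlation, so that
#' exactly `min(n_markers, cap)` markers are returned.
#'
#' @param lassoB sparse `p x k` coefficient matrix (markers x traits).
#' @param cap maximum number of markers to pass on (default 4000).
#' @param pd the \linkS4class{PairedDataset}, required only when the fill
#'   rule is needed.
#' @return increasing integer vector of selected marker indices, of length
#'   `min(nrow(lassoB), cap)`.
#' @export
selectMarkers <- function(lassoB, cap = 4000L, pd = NULL) {
  if (cap < 1L) gfStop("gfmap_spec_error", "cap must be >= 1")
  p <- nrow(lassoB)
  nzCount <- Matrix::rowSums(lassoB != 0)
  mass <- Matrix::rowSums(abs(lassoB))
  active <- which(nzCount > 0)
  ord <- active[order(-nzCount[active], -mass[active], active)]
  target <- min(p, cap)
  sel <- utils::head(ord, target)
  if (length(sel) < target) {
    if (is.null(pd))
      gfStop("gfmap_spec_error",
             "fewer than %d markers with nonzero lasso coefficients; supply pd for the marginal-correlation fill rule",
             target)
    rest <- setdiff(seq_len(p), sel)
    X <- pd@genotype@values[, rest, drop = FALSE]
    R <- suppressWarnings(stats::cor(X, pd@traits@values))
    R[is.na(R)] <- 0
    score <- apply(abs(R), 1L, max)
    fill <- rest[order(-score, rest)]
    sel <- c(sel, utils::head(fill, target - length(sel)))
  }
  sort(as.integer(sel))
}
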