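#' @include io.R
NULL

## column-standardize with the sample (n-1) convention; zero-variance columns
## are flagged so their correlations can be defined as 0
standardizeCols <- function(Y) {
  n <- nrow(Y)
  mu <- colMeans(Y)
  Yc <- sweep(Y, 2L, mu)
  ss <- sqrt(colSums(Yc^2) / (n - 1))
  zero <- ss == 0
  ss[zero] <- 1
  list(Z = sweep(Yc, 2L, ss, "/"), zero = zero)
}

edgesFromR <- function(R, iOff, jOff, threshold, transform = identity) {
  W <- transform(R)
  keep <- which(abs(W) >= threshold & upperOnly(nrow(R), ncol(R), iOff, jOff),
                arr.ind = TRUE)
  if (!nrow(keep))
    return(data.frame(from = integer(), to = integer(), weight = numeric()))
  data.frame(from = keep[, 1] + iOff, to = keep[, 2] + jOff,
             weight = W[keep])
}

upperOnly <- function(nr, nc, iOff, jOff) {
  outer(seq_len(nr) + iOff, seq_len(nc) + jOff, `<`)
}

#' Build a thresholded trait correlation network
#'
#' Computes all pairwise Pearson (or Spearman) correlations between trait
#' columns and keeps an undirected edge `(m, l)` whenever
#' `|r_ml| >= threshold`, with the signed correlation as edge weight. The
#' computation is tiled into `sectionSize x sectionSize` blocks of traits --
#' the unit of parallel work for large trait sets -- and the result is
#' independent of the tiling.
#'
#' Zero-variance traits have all their correlations defined as 0 (no edges)
#' and trigger a warning.
#'
#' @param traits a \linkS4class{TraitMatrix} (at least 3 samples).
#' @param threshold absolute-correlation edge threshold in `[0, 1]`.
#' @param sectionSize tile width in traits (default 1000).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return a \linkS4class{TraitNetwork}.
#' @export
correlationNetwork <- function(traits, threshold = 0.5, sectionSize = 1000L,
                               method = c("pearson", "spearman")) {
  method <- match.arg(method)
  .corNetwork(traits, threshold, sectionSize, method, power = 1)
}

#' Build a soft-thresholded (scale-free style) trait network
#'
#' Correlations are raised element-wise to `power` (keeping the sign):
#' weights are `sign(r) * |r|^power`, and an edge is kept iff
#' `|r|^power >= threshold`. With `power = 1` this reduces to
#' [correlationNetwork()].
#'
#' @inheritParams correlationNetwork
#' @param power soft-thresholding exponent, `>= 1`.
#' @return a \linkS4class{TraitNetwork} whose weights are
#'   `sign(r) * |r|^power`.
#' @export
scaleFreeNetwork <- function(traits, power = 6, threshold = 0.5,
                             sectionSize = 1000L,
                             method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (power < 1) gfStop("gfmap_spec_error", "power must be >= 1")
  .corNetwork(traits, threshold, sectionSize, method, power = power)
}

.corNetwork <- function(traits, threshold, sectionSize, method, power) {
  stopifnot(is(traits, "TraitMatrix"))
  if (threshold < 0 || threshold > 1)
    gfStop("gfmap_spec_error", "threshold must be in [0, 1]")
  Y <- traits@values
  n <- nrow(Y); k <- ncol(Y)
  if (n < 3) gfStop("gfmap_spec_error", "need at least 3 samples")
  if (method == "spearman") Y <- apply(Y, 2L, rank)
  st <- standardizeCols(Y)
  if (any(st$zero))
    warning(sprintf("%d zero-variance trait(s); their correlations are defined as 0",
                    sum(st$zero)))
  Z <- st$Z
  Z[, st$zero] <- 0  # all correlations involving the degenerate trait vanish
  bounds <- chunkBounds(k, sectionSize)
  trans <- function(R) {
    R <- pmin(pmax(R, -1), 1)
    if (power == 1) R else sign(R) * abs(R)^power
  }
  pieces <- list()
  for (bi in seq_len(nrow(bounds))) {
    for (bj in bi:nrow(bounds)) {
      ri <- bounds$start[bi]:bounds$end[bi]
      rj <- bounds$start[bj]:bounds$end[bj]
      R <- crossprod(Z[, ri, drop = FALSE], Z[, rj, drop = FALSE]) / (n - 1)
      e <- edgesFromR(R, iOff = bounds$start[bi] - 1L,
                      jOff = bounds$start[bj] - 1L, threshold = threshold,
                      transform = trans)
      if (nrow(e)) pieces[[length(pieces) + 1L]] <- e
    }
  }
  e <- if (length(pieces)) do.call(rbind, pieces)
       else data.frame(from = integer(), to = integer(), weight = numeric())
  e <- e[order(e$from, e$to), , drop = FALSE]
  rownames(e) <- NULL
  new("TraitNetwork", traitIds = traits@traitIds, edges = e,
      threshold = threshold)
}

#' Connected components of a trait network
#'
#' @param net a \linkS4class{TraitNetwork}.
#' @return list of integer vectors (sorted trait indices), the maximal
#'   connected sets, in decreasing size with ties broken by the smallest
#'   contained index. Isolated traits form singleton components.
#' @export
connectedComponents <- function(net) {
  stopifnot(is(net, "TraitNetwork"))
  n <- length(net@traitIds)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(net@edges))
    g <- igraph::add_edges(g, rbind(net@edges$from, net@edges$to))
  memb <- igraph::components(g)$membership
  comps <- split(seq_len(n), memb)
  comps <- lapply(comps, sort)
  sizes <- lengths(comps)
  mins <- vapply(comps, `[[`, 0L, 1L)
  comps <- comps[order(-sizes, mins)]
  names(comps) <- NULL
  comps
}

## adjacency of |r| weights restricted to a node set
inducedAdjacency <- function(nodes, net) {
  n <- length(nodes)
  W <- matrix(0, n, n)
  e <- net@edges
  keep <- e$from %in% nodes & e$to %in% nodes
  if (any(keep)) {
    i <- match(e$from[keep], nodes); j <- match(e$to[keep], nodes)
    W[cbind(i, j)] <- abs(e$weight[keep])
    W[cbind(j, i)] <- abs(e$weight[keep])
  }
  W
}

## seeded k-means on the spectral embedding with deterministic fallbacks
seededClusters <- function(emb, k, seed) {
  key <- apply(emb, 1L, paste, collapse = ",")
  if (length(unique(key)) <= k) return(match(key, unique(key)))
  set.seed(seed)
  res <- tryCatch(stats::kmeans(emb, centers = k, nstart = 10L, iter.max = 100L),
                  error = function(e) NULL)
  if (is.null(res) || length(unique(res$cluster)) < 2L) {
    # fall back to an order split along the leading non-trivial coordinate
    o <- rank(emb[, ncol(emb) - 1L], ties.method = "first")
    return(as.integer(ceiling(o / (nrow(emb) / k))))
  }
  as.integer(res$cluster)
}

#' Split an oversized connected component by spectral clustering
#'
#' Components no larger than `cap` are returned unchanged. Larger ones are
#' embedded with the normalized symmetric Laplacian of the `|r|`-weighted
#' induced subgraph, clustered into `k = ceiling(size / cap)` groups by
#' seeded k-means on the bottom-`k` eigenvectors (rows normalized), and any
#' resulting part still exceeding the cap is split recursively (re-running
#' connected components on the induced subgraph first). Termination is
#' guaranteed: a part that cannot be split any other way is divided along
#' the embedding order.
#'
#' @param component integer vector of trait indices, connected in `net`.
#' @param net the \linkS4class{TraitNetwork}.
#' @param cap maximum part size (default 250).
#' @param seed integer seed for the k-means initialization; the split is
#'   deterministic given the seed.
#' @return list of integer vectors (sorted), each of size `<= cap`, that
#'   partition `component`.
#' @export
spectralSplit <- function(component, net, cap = 250L, seed = 1L) {
  component <- sort(as.integer(component))
  if (length(component) <= cap) return(list(component))
  W <- inducedAdjacency(component, net)
  n <- length(component)
  k <- ceiling(n / cap)
  deg <- rowSums(W)
  isolated <- which(deg == 0)
  if (length(isolated)) {
    # defensive: an unconnected node embeds degenerately; peel it off
    rest <- spectralSplit(component[-isolated], net, cap, seed)
    return(c(rest, as.list(component[isolated])))
  }
  dInv <- 1 / sqrt(deg)
  Lsym <- diag(n) - W * outer(dInv, dInv)
  ev <- eigen(Lsym, symmetric = TRUE)
  emb <- ev$vectors[, n:(n - k + 1L), drop = FALSE]  # bottom-k eigenvectors
  rn <- sqrt(rowSums(emb^2)); rn[rn == 0] <- 1
  emb <- emb / rn
  cl <- seededClusters(emb, k, seed)
  parts <- split(component, cl)
  if (length(parts) == 1L) {  # clustering failed to separate: order split
    o <- order(emb[, ncol(emb)])
    rk <- integer(n); rk[o] <- seq_len(n)
    parts <- split(component, ceiling(rk / cap))
  }
  out <- list()
  for (part in parts) {
    if (length(part) <= cap) {
      out[[length(out) + 1L]] <- sort(part)
    } else {
      sub <- subsetNetwork(net, part)
      for (comp in connectedComponents(sub)) {
        piece <- part[comp]
        out <- c(out, spectralSplit(piece, net, cap, seed + 1L))
      }
    }
  }
  out
}

## restrict a network to a node subset (indices remapped to 1..length(nodes))
subsetNetwork <- function(net, nodes) {
  e <- net@edges
  keep <- e$from %in% nodes & e$to %in% nodes
  e <- e[keep, , drop = FALSE]
  if (nrow(e)) {
    from <- match(e$from, nodes); to <- match(e$to, nodes)
    e <- data.frame(from = pmin(from, to), to = pmax(from, to),
                    weight = e$weight)
    e <- e[order(e$from, e$to), , drop = FALSE]
  }
  new("TraitNetwork", traitIds = net@traitIds[nodes], edges = e,
      threshold = net@threshold)
}

#' Pack bounded components into processing groups (first-fit decreasing)
#'
#' Combines components (each already of size `<= cap`, i.e. after
#' [spectralSplit()]) into groups of total size at most `cap` by first-fit
#' decreasing bin packing. Packing itself never severs an edge; `cutEdges`
#' reports the network edges whose endpoints fall in different final groups
#' (the edges dropped from the GFlasso fusion penalty), which is 0 whenever
#' no component had to be split.
#'
#' @param components list of integer vectors, each of size `<= cap`.
#' @param cap maximum group size (default 250).
#' @param net optional \linkS4class{TraitNetwork} used to count `cutEdges`.
#' @return a \linkS4class{SubnetworkPartition}.
#' @export
packSubnetworks <- function(components, cap = 250L, net = NULL) {
  sizes <- lengths(components)
  if (any(sizes > cap))
    gfStop("gfmap_contract_error",
           "component of size %d exceeds cap %d; apply spectralSplit first",
           max(sizes), cap)
  ord <- order(-sizes)  # stable: ties keep the given component order
  groups <- list(); room <- integer(0)
  for (ci in ord) {
    placed <- FALSE
    for (gi in seq_along(groups)) {
      if (room[gi] >= sizes[ci]) {
        groups[[gi]] <- c(groups[[gi]], components[[ci]])
        room[gi] <- room[gi] - sizes[ci]
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      groups[[length(groups) + 1L]] <- components[[ci]]
      room[length(groups)] <- cap - sizes[ci]
    }
  }
  groups <- lapply(groups, sort)
  cut <- 0L
  if (!is.null(net) && nrow(net@edges)) {
    gid <- integer(length(net@traitIds))
    for (gi in seq_along(groups)) gid[groups[[gi]]] <- gi
    cut <- sum(gid[net@edges$from] != gid[net@edges$to])
  }
  new("SubnetworkPartition", groups = groups, cap = as.integer(cap),
      cutEdges = as.integer(cut))
}

#' Decompose a trait network into bounded sub-networks
#'
#' Convenience wrapper chaining [connectedComponents()], [spectralSplit()]
#' on oversized components, and [packSubnetworks()].
#'
#' @param net a \linkS4class{TraitNetwork}.
#' @param cap maximum group size.
#' @param seed seed for the spectral splits.
#' @return a \linkS4class{SubnetworkPartition}.
#' @export
traitPartition <- function(net, cap = 250L, seed = 1L) {
  comps <- connectedComponents(net)
  parts <- list()
  for (comp in comps) parts <- c(parts, spectralSplit(comp, net, cap, seed))
  packSubnetworks(parts, cap = cap, net = net)
}

#' Chunking arithmetic for parallel jobs
#'
#' `chunkCount(n, b)` is the number of size-`b` jobs needed to cover `n`
#' items, `ceiling(n / b)`; `chunkBounds` returns the contiguous 1-based
#' inclusive index ranges of those jobs.
#'
#' @param nItems number of items, `>= 0`.
#' @param blockSize job size, `>= 1`.
#' @return `chunkCount`: an integer; `chunkBounds`: a data.frame with
#'   columns `start` and `end` covering `1..nItems`.
#' @examples
#' chunkCount(5637, 250)  # 23 parallel trait blocks
#' @export
chunkCount <- function(nItems, blockSize) {
  stopifnot(nItems >= 0, blockSize >= 1)
  as.integer(ceiling(nItems / blockSize))
}

#' @rdname chunkCount
#' @export
chunkBounds <- function(nItems, blockSize) {
  m <- chunkCount(nItems, blockSize)
  if (m == 0L) return(data.frame(start = integer(), end = integer()))
  start <- seq.int(1L, by = blockSize, length.out = m)
  data.frame(start = start, end = pmin(start + blockSize - 1L, as.integer(nItems)))
}
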