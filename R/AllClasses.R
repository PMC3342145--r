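#' @import methods
#' @importFrom GenomicRanges GRanges seqnames
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols
NULL

setClassUnion("characterOrNULL", c("character", "NULL"))

#' GenotypeMatrix: samples-by-markers numeric genotypes with genomic loci
#'
#' Holds a fully observed numeric genotype matrix (rows are samples, columns
#' are markers; a 0/1/2 minor-allele count encoding is recommended) together
#' with per-marker genomic coordinates stored as a \linkS4class{GRanges}.
#'
#' @slot values numeric matrix, `n_samples x n_markers`, finite, no missing
#'   entries.
#' @slot markerIds character vector of marker names, one per column.
#' @slot loci [GenomicRanges::GRanges] of width-1 positions, one per marker,
#'   in the same order as the columns of `values`.
#' @slot sampleIds optional character vector of sample labels (or `NULL`).
#'
#' @seealso [readGenotype()], [pairDatasets()]
#' @export
setClass("GenotypeMatrix",
  representation(
    values    = "matrix",
    markerIds = "character",
    loci      = "GRanges",
    sampleIds = "characterOrNULL"
  )
)

setValidity("GenotypeMatrix", function(object) {
  v <- object@values
  if (!is.numeric(v)) return("values must be numeric")
  if (anyNA(v) || any(!is.finite(v))) return("values must be finite with no missing entries")
  if (length(object@markerIds) != ncol(v))
    return(sprintf("markerIds length (%d) != number of markers (%d)",
                   length(object@markerIds), ncol(v)))
  if (length(object@loci) != ncol(v))
    return(sprintf("loci length (%d) != number of markers (%d)",
                   length(object@loci), ncol(v)))
  if (!is.null(object@sampleIds) && length(object@sampleIds) != nrow(v))
    return(sprintf("sampleIds length (%d) != number of samples (%d)",
                   length(object@sampleIds), nrow(v)))
  if (anyDuplicated(object@markerIds)) return("markerIds must be unique")
  TRUE
})

#' TraitMatrix: samples-by-traits real matrix with trait labels
#'
#' @slot values numeric matrix, `n_samples x n_traits`, finite.
#' @slot traitIds character vector of trait labels, one per column.
#' @slot sampleIds optional character vector of sample labels (or `NULL`).
#'
#' @seealso [readTraits()], [correlationNetwork()]
#' @export
setClass("TraitMatrix",
  representation(
    values    = "matrix",
    traitIds  = "character",
    sampleIds = "characterOrNULL"
  )
)

setValidity("TraitMatrix", function(object) {
  v <- object@values
  if (!is.numeric(v)) return("values must be numeric")
  if (anyNA(v) || any(!is.finite(v))) return("values must be finite with no missing entries")
  if (length(object@traitIds) != ncol(v))
    return(sprintf("traitIds length (%d) != number of traits (%d)",
                   length(object@traitIds), ncol(v)))
  if (!is.null(object@sampleIds) && length(object@sampleIds) != nrow(v))
    return("sampleIds length != number of samples")
  TRUE
})

#' PairedDataset: a genotype and a trait matrix over the same samples
#'
#' Rows of the two matrices refer to the same samples in the same order;
#' [pairDatasets()] enforces this, aligning by sample label when labels are
#' available on both sides.
#'
#' @slot genotype a \linkS4class{GenotypeMatrix}.
#' @slot traits a \linkS4class{TraitMatrix} with the same number of rows.
#' @export
setClass("PairedDataset",
  representation(genotype = "GenotypeMatrix", traits = "TraitMatrix")
)

setValidity("PairedDataset", function(object) {
  if (nrow(object@genotype@values) != nrow(object@traits@values))
    return("genotype and trait matrices have different sample counts")
  TRUE
})

#' TraitNetwork: thresholded weighted undirected graph over traits
#'
#' Edges carry the signed correlation `r_ml` between traits `m` and `l`;
#' only pairs with `|r_ml| >= threshold` are stored, each undirected edge
#' once with `from < to`.
#'
#' @slot traitIds character vector naming the nodes.
#' @slot edges data.frame with integer columns `from`, `to` (1-based trait
#'   indices, `from < to`) and numeric `weight` in `[-1, 1]`.
#' @slot threshold the absolute-correlation edge threshold in `[0, 1]`.
#' @export
setClass("TraitNetwork",
  representation(traitIds = "character", edges = "data.frame",
                 threshold = "numeric")
)

setValidity("TraitNetwork", function(object) {
  e <- object@edges
  if (!all(c("from", "to", "weight") %in% names(e)))
    return("edges must have columns from, to, weight")
  n <- length(object@traitIds)
  if (nrow(e)) {
    if (any(e$from < 1L) || any(e$to > n)) return("edge endpoints out of range")
    if (any(e$from >= e$to)) return("edges must satisfy from < to (no self-loops, stored once)")
    if (any(abs(e$weight) > 1 + 1e-12)) return("edge weights must lie in [-1, 1]")
    if (any(abs(e$weight) < object@threshold - 1e-12))
      return("all stored edges must meet the threshold")
    if (anyDuplicated(e[c("from", "to")])) return("duplicate edges")
  }
  if (object@threshold < 0 || object@threshold > 1)
    return("threshold must be in [0, 1]")
  TRUE
})

#' AssociationResult: sparse marker-trait association entries
#'
#' Only nonzero weights are stored, as a long-format table of
#' (marker index, trait index, weight, optional p-value).
#'
#' @slot markerIds character vector of marker names.
#' @slot traitIds character vector of trait names.
#' @slot entries data.frame with columns `marker`, `trait` (1-based integer
#'   indices), `weight` (nonzero numeric) and optionally `p_value` in `[0,1]`.
#' @slot methodTag short string naming the method that produced the result.
#' @export
setClass("AssociationResult",
  representation(markerIds = "character", traitIds = "character",
                 entries = "data.frame", methodTag = "character")
)

setValidity("AssociationResult", function(object) {
  e <- object@entries
  if (!all(c("marker", "trait", "weight") %in% names(e)))
    return("entries must have columns marker, trait, weight")
  if (nrow(e)) {
    if (any(e$marker < 1L) || any(e$marker > length(object@markerIds)))
      return("marker index out of range")
    if (any(e$trait < 1L) || any(e$trait > length(object@traitIds)))
      return("trait index out of range")
    if (any(e$weight == 0)) return("stored weights must be nonzero")
    if (!is.null(e$p_value) && (any(e$p_value < 0) || any(e$p_value > 1)))
      return("p_values must lie in [0, 1]")
  }
  TRUE
})

#' SubnetworkPartition: bounded trait groups for parallel GFlasso
#'
#' @slot groups list of integer vectors of trait indices; pairwise disjoint,
#'   jointly covering all traits, each of size at most `cap`.
#' @slot cap maximum group size.
#' @slot cutEdges number of network edges whose endpoints fall in different
#'   groups (edges severed when oversized components were split).
#' @export
setClass("SubnetworkPartition",
  representation(groups = "list", cap = "integer", cutEdges = "integer")
)

setValidity("SubnetworkPartition", function(object) {
  sizes <- lengths(object@groups)
  if (any(sizes > object@cap)) return("a group exceeds the cap")
  idx <- unlist(object@groups, use.names = FALSE)
  if (anyDuplicated(idx)) return("groups are not disjoint")
  if (object@cutEdges < 0L) return("cutEdges must be non-negative")
  TRUE
})

#' LambdaSearchState: one stage of the cross-validated lambda search
#'
#' @slot grid numeric vector of lambda values, strictly decreasing.
#' @slot cvError held-out squared error summed over all traits and folds,
#'   one value per grid point.
#' @slot bestIndex index of the grid minimum (ties broken toward larger
#'   lambda, i.e. the smaller index).
#' @slot stage `"coarse"` or `"fine"`.
#' @export
setClass("LambdaSearchState",
  representation(grid = "numeric", cvError = "numeric",
                 bestIndex = "integer", stage = "character")
)

setValidity("LambdaSearchState", function(object) {
  if (length(object@grid) != length(object@cvError))
    return("grid and cvError lengths differ")
  if (length(object@grid) > 1 && any(diff(object@grid) >= 0))
    return("grid must be strictly decreasing")
  if (any(!is.finite(object@cvError))) return("cvError must be finite")
  if (!object@stage %in% c("coarse", "fine")) return("stage must be coarse or fine")
  TRUE
})

#' GFLassoProblem: one graph-guided fused lasso sub-problem
#'
#' @slot X standardized `n x p` genotype submatrix (selected markers).
#' @slot Y `n x k` trait block.
#' @slot edges data.frame (`from`, `to`, `weight`) of trait-network edges
#'   restricted to the block, indices into columns of `Y`.
#' @slot lambda sparsity penalty, `>= 0`.
#' @slot gamma fusion penalty, `>= 0`.
#' @slot mu smoothing parameter for the fusion term, `> 0`.
#' @slot tol relative-objective convergence tolerance.
#' @slot maxIter iteration cap.
#' @export
setClass("GFLassoProblem",
  representation(X = "matrix", Y = "matrix", edges = "data.frame",
                 lambda = "numeric", gamma = "numeric", mu = "numeric",
                 tol = "numeric", maxIter = "integer")
)

setValidity("GFLassoProblem", function(object) {
  if (nrow(object@X) != nrow(object@Y)) return("X and Y sample counts differ")
  k <- ncol(object@Y)
  e <- object@edges
  if (nrow(e) && (any(e$from < 1L) || any(e$to > k) || any(e$from >= e$to)))
    return("edge endpoints out of range for the trait block")
  if (object@lambda < 0 || object@gamma < 0) return("lambda and gamma must be >= 0")
  if (object@mu <= 0) return("mu must be > 0")
  TRUE
})

#' GFLassoSolution: fitted coefficients for one sub-problem
#'
#' @slot B `p x k` coefficient matrix (entries below 1e-8 in absolute value
#'   are set to zero).
#' @slot objective the (unsmoothed) objective value at `B`.
#' @slot nIter accepted iterations taken.
#' @slot converged whether the relative objective change fell below `tol`.
#' @export
setClass("GFLassoSolution",
  representation(B = "matrix", objective = "numeric", nIter = "integer",
                 converged = "logical")
)

#' RegSearchRecord: one stage of the alternating (lambda, gamma) search
#'
#' @slot stage 1, 2 or 3 (lambda given gamma, gamma given lambda, refined
#'   lambda given gamma).
#' @slot parameter `"lambda"` or `"gamma"` -- which parameter was scanned.
#' @slot grid the scanned values.
#' @slot fixedValue the value of the other parameter during the scan.
#' @slot cvError cross-validation error per grid point.
#' @slot bestIndex argmin, ties broken toward the more regularized value.
#' @export
setClass("RegSearchRecord",
  representation(stage = "integer", parameter = "character", grid = "numeric",
                 fixedValue = "numeric", cvError = "numeric",
                 bestIndex = "integer")
)

setValidity("RegSearchRecord", function(object) {
  if (length(object@grid) != length(object@cvError))
    return("grid and cvError lengths differ")
  if (!object@parameter %in% c("lambda", "gamma"))
    return("parameter must be lambda or gamma")
  TRUE
})

## the S3 config list from pipelineConfig(), registered so it can live in the
## list-typed config slot below
setOldClass(c("PipelineConfig", "list"))

#' PipelineManifest: the checkpointed 14-step pipeline record
#'
#' Mirrors the on-disk `manifest.json` of a pipeline workspace: an ordered
#' list of steps with statuses (`pending`, `running`, `done`, `error`,
#' `paused`, `killed`), job counts and artifact paths, plus a frozen config
#' snapshot and the pipeline seed.
#'
#' @slot steps data.frame with columns `index`, `name`, `stage`, `status`,
#'   `n_jobs`, `jobs_done`, `artifact`, `error`, `started`, `finished`.
#' @slot config list, the pipeline configuration snapshot.
#' @slot seed integer master seed; all per-job seeds derive from it.
#' @slot workspace directory holding the manifest and step artifacts.
#' @export
setClass("PipelineManifest",
  representation(steps = "data.frame", config = "list", seed = "integer",
                 workspace = "character")
)

setValidity("PipelineManifest", function(object) {
  s <- object@steps
  need <- c("index", "name", "stage", "status", "n_jobs", "jobs_done")
  if (!all(need %in% names(s))) return("steps table missing required columns")
  if (nrow(s) != 14L) return("a GFlasso pipeline manifest has exactly 14 steps")
  if (!identical(s$index, 1:14)) return("step indices must be 1..14 in order")
  ok <- c("pending", "running", "done", "error", "paused", "killed")
  if (!all(s$status %in% ok)) return("invalid step status")
  # sequential gating: step i running implies all earlier steps done
  run <- which(s$status == "running")
  if (length(run) > 1L) return("at most one step may be running")
  if (length(run) == 1L && run > 1L && !all(s$status[seq_len(run - 1L)] == "done"))
    return("sequential gating violated: a running step requires all earlier steps done")
  TRUE
})
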