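#' @include AllClasses.R
NULL

#' Accessors for gfmap data containers
#'
#' Small accessor family used throughout the package instead of direct slot
#' access: dimensions, identifiers, the underlying numeric matrix, marker
#' loci and network edges.
#'
#' @param x a gfmap object (see Methods).
#' @return `nSamples`, `nMarkers`, `nTraits` return a single integer;
#'   `markerIds`, `traitIds`, `sampleIds` a character vector (or `NULL`);
#'   `values` the numeric matrix; `loci` a [GenomicRanges::GRanges];
#'   `edges` a data.frame of network edges; `entries` the long-format
#'   association table.
#' @name accessors
#' @aliases nSamples nMarkers nTraits markerIds traitIds sampleIds values
#'   loci edges entries methodTag
NULL

#' @rdname accessors
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))
#' @rdname accessors
#' @export
setGeneric("nMarkers", function(x) standardGeneric("nMarkers"))
#' @rdname accessors
#' @export
setGeneric("nTraits", function(x) standardGeneric("nTraits"))
#' @rdname accessors
#' @export
setGeneric("markerIds", function(x) standardGeneric("markerIds"))
#' @rdname accessors
#' @export
setGeneric("traitIds", function(x) standardGeneric("traitIds"))
#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))
#' @rdname accessors
#' @export
setGeneric("loci", function(x) standardGeneric("loci"))
#' @rdname accessors
#' @export
setGeneric("edges", function(x) standardGeneric("edges"))
#' @rdname accessors
#' @export
setGeneric("entries", function(x) standardGeneric("entries"))
#' @rdname accessors
#' @export
setGeneric("methodTag", function(x) standardGeneric("methodTag"))

#' @rdname accessors
#' @export
setMethod("nSamples", "GenotypeMatrix", function(x) nrow(x@values))
#' @rdname accessors
#' @export
setMethod("nSamples", "TraitMatrix", function(x) nrow(x@values))
#' @rdname accessors
#' @export
setMethod("nSamples", "PairedDataset", function(x) nrow(x@genotype@values))
#' @rdname accessors
#' @export
setMethod("nMarkers", "GenotypeMatrix", function(x) ncol(x@values))
#' @rdname accessors
#' @export
setMethod("nMarkers", "PairedDataset", function(x) ncol(x@genotype@values))
#' @rdname accessors
#' @export
setMethod("nTraits", "TraitMatrix", function(x) ncol(x@values))
#' @rdname accessors
#' @export
setMethod("nTraits", "PairedDataset", function(x) ncol(x@traits@values))
#' @rdname accessors
#' @export
setMethod("nTraits", "TraitNetwork", function(x) length(x@traitIds))
#' @rdname accessors
#' @export
setMethod("markerIds", "GenotypeMatrix", function(x) x@markerIds)
#' @rdname accessors
#' @export
setMethod("markerIds", "PairedDataset", function(x) x@genotype@markerIds)
#' @rdname accessors
#' @export
setMethod("markerIds", "AssociationResult", function(x) x@markerIds)
#' @rdname accessors
#' @export
setMethod("traitIds", "TraitMatrix", function(x) x@traitIds)
#' @rdname accessors
#' @export
setMethod("traitIds", "PairedDataset", function(x) x@traits@traitIds)
#' @rdname accessors
#' @export
setMethod("traitIds", "TraitNetwork", function(x) x@traitIds)
#' @rdname accessors
#' @export
setMethod("traitIds", "AssociationResult", function(x) x@traitIds)
#' @rdname accessors
#' @export
setMethod("sampleIds", "GenotypeMatrix", function(x) x@sampleIds)
#' @rdname accessors
#' @export
setMethod("sampleIds", "TraitMatrix", function(x) x@sampleIds)
#' @rdname accessors
#' @importFrom S4Vectors values
#' @export values
#' @export
setMethod("values", "GenotypeMatrix", function(x, ...) x@values)
#' @rdname accessors
#' @export
setMethod("values", "TraitMatrix", function(x, ...) x@values)
#' @rdname accessors
#' @export
setMethod("loci", "GenotypeMatrix", function(x) x@loci)
#' @rdname accessors
#' @export
setMethod("edges", "TraitNetwork", function(x) x@edges)
#' @rdname accessors
#' @export
setMethod("entries", "AssociationResult", function(x) x@entries)
#' @rdname accessors
#' @export
setMethod("methodTag", "AssociationResult", function(x) x@methodTag)

#' @rdname accessors
#' @param object object to display
#' @export
setMethod("show", "GenotypeMatrix", function(object) {
  cat(sprintf("GenotypeMatrix: %d samples x %d markers\n",
              nrow(object@values), ncol(object@values)))
  chr <- unique(as.character(GenomicRanges::seqnames(object@loci)))
  cat(sprintf("  chromosomes: %s\n",
              paste(utils::head(chr, 6), collapse = ", ")))
  if (!is.null(object@sampleIds)) cat("  sample labels: present\n")
  invisible(object)
})

#' @rdname accessors
#' @export
setMethod("show", "TraitMatrix", function(object) {
  cat(sprintf("TraitMatrix: %d samples x %d traits\n",
              nrow(object@values), ncol(object@values)))
  invisible(object)
})

#' @rdname accessors
#' @export
setMethod("show", "PairedDataset", function(object) {
  cat(sprintf("PairedDataset: %d samples, %d markers, %d traits\n",
              nSamples(object), nMarkers(object), nTraits(object)))
  invisible(object)
})

#' @rdname accessors
#' @export
setMethod("show", "TraitNetwork", function(object) {
  cat(sprintf("TraitNetwork: %d traits, %d edges (|r| >= %g)\n",
              length(object@traitIds), nrow(object@edges), object@threshold))
  invisible(object)
})

#' @rdname accessors
#' @export
setMethod("show", "AssociationResult", function(object) {
  cat(sprintf("AssociationResult [%s]: %d markers x %d traits, %d nonzero entries\n",
              object@methodTag, length(object@markerIds),
              length(object@traitIds), nrow(object@entries)))
  invisible(object)
})

#' @rdname accessors
#' @export
setMethod("show", "SubnetworkPartition", function(object) {
  cat(sprintf("SubnetworkPartition: %d groups (cap %d), sizes %s; %d cut edges\n",
              length(object@groups), object@cap,
              paste(utils::head(sort(lengths(object@groups), decreasing = TRUE), 8),
                    collapse = ","),
              object@cutEdges))
  invisible(object)
})

#' @rdname accessors
#' @export
setMethod("show", "GFLassoSolution", function(object) {
  cat(sprintf("GFLassoSolution: %d x %d, %d nonzero, objective %.6g, %s in %d iters\n",
              nrow(object@B), ncol(object@B), sum(object@B != 0),
              object@objective,
              if (object@converged) "converged" else "NOT converged",
              object@nIter))
  invisible(object)
})

#' @rdname accessors
#' @export
setMethod("show", "PipelineManifest", function(object) {
  cat(sprintf("PipelineManifest: workspace %s (seed %d)\n",
              object@workspace, object@seed))
  s <- object@steps
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %2d. %-34s [%s] %d/%d jobs\n", s$index[i], s$name[i],
                s$status[i], s$jobs_done[i], s$n_jobs[i]))
  invisible(object)
})
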