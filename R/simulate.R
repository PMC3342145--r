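#' @include io.R
NULL

#' Specification of a simulated association-mapping dataset
#'
#' Describes a seeded dataset with modular trait correlation structure and
#' sparse, module-fused true marker effects: genotypes are independent sites
#' drawn as `Binomial(2, maf)`, traits in the same module share a latent
#' factor (so within-module correlation is high), and each causal marker
#' contributes an additive effect to the traits of one module.
#'
#' @param nSamples,nMarkers,nTraits dataset dimensions (positive).
#' @param nModules number of correlated trait modules.
#' @param moduleSizes optional integer vector of module sizes (summing to at
#'   most `nTraits`); defaults to an even split of all traits.
#' @param mafRange minor-allele-frequency interval, a sub-interval of
#'   `(0, 0.5]`; each marker's MAF is drawn uniformly from it.
#' @param nCausal number of causal markers (at most `nMarkers`).
#' @param effectSize absolute additive effect per minor allele.
#' @param withinModuleSharing probability that a causal marker affects all
#'   traits of its module (the fused case); otherwise it affects a single
#'   random trait of the module.
#' @param latentLoading loading of the shared module factor on each member
#'   trait; 0 removes the latent structure.
#' @param noiseSd standard deviation of the independent trait noise, `>= 0`.
#' @param seed integer seed; the simulation is fully reproducible per seed.
#' @return a list of class `SimulationSpec`.
#' @seealso [simulateDataset()]
#' @export
simulationSpec <- function(nSamples, nMarkers, nTraits, nModules = 1L,
                           moduleSizes = NULL, mafRange = c(0.05, 0.5),
                           nCausal = 1L, effectSize = 1, withinModuleSharing = 1,
                           latentLoading = 1, noiseSd = 1, seed = 1L) {
  spec <- list(nSamples = as.integer(nSamples), nMarkers = as.integer(nMarkers),
               nTraits = as.integer(nTraits), nModules = as.integer(nModules),
               moduleSizes = moduleSizes, mafRange = as.numeric(mafRange),
               nCausal = as.integer(nCausal), effectSize = as.numeric(effectSize),
               withinModuleSharing = as.numeric(withinModuleSharing),
               latentLoading = as.numeric(latentLoading),
               noiseSd = as.numeric(noiseSd), seed = as.integer(seed))
  with(spec, {
    if (nSamples < 1L || nMarkers < 1L || nTraits < 1L || nModules < 1L)
      gfStop("gfmap_spec_error", "all counts must be positive")
    if (nCausal > nMarkers)
      gfStop("gfmap_spec_error", "infeasible: nCausal (%d) > nMarkers (%d)",
             nCausal, nMarkers)
    if (mafRange[1] <= 0 || mafRange[2] > 0.5 || mafRange[1] > mafRange[2])
      gfStop("gfmap_spec_error", "mafRange must lie within (0, 0.5]")
    if (noiseSd < 0) gfStop("gfmap_spec_error", "noiseSd must be >= 0")
    if (withinModuleSharing < 0 || withinModuleSharing > 1)
      gfStop("gfmap_spec_error", "withinModuleSharing must be a probability")
  })
  if (is.null(spec$moduleSizes)) {
    base <- spec$nTraits %/% spec$nModules
    extra <- spec$nTraits %% spec$nModules
    spec$moduleSizes <- as.integer(base + (seq_len(spec$nModules) <= extra))
  } else {
    spec$moduleSizes <- as.integer(moduleSizes)
    if (length(spec$moduleSizes) != spec$nModules ||
        sum(spec$moduleSizes) > spec$nTraits)
      gfStop("gfmap_spec_error", "moduleSizes must have nModules entries summing to <= nTraits")
  }
  class(spec) <- "SimulationSpec"
  spec
}

#' Simulate a genotype/trait dataset with known ground truth
#'
#' Genotypes are independent binomial(2, MAF) sites. Traits are assigned to
#' contiguous modules; each module has a standard-normal latent factor per
#' sample entering every member trait with loading `latentLoading`. Each
#' causal marker is assigned to a module and either affects all member
#' traits (probability `withinModuleSharing`, giving fused effects) or a
#' single random member trait. Finally
#' `Y = latent structure + X %*% trueB + noise`.
#'
#' @param spec a [simulationSpec()].
#' @return list with elements `genotype` (\linkS4class{GenotypeMatrix},
#'   markers placed on synthetic chromosomes), `traits`
#'   (\linkS4class{TraitMatrix}) and `truth` (list with sparse `trueB`
#'   ([Matrix::sparseMatrix]), `moduleAssignment` (0 = no module) and
#'   `causalMarkers`).
#' @examples
#' sim <- simulateDataset(simulationSpec(30, 20, 6, nModules = 2, nCausal = 2,
#'                                       seed = 7))
#' dim(values(sim$traits))
#' @export
simulateDataset <- function(spec) {
  stopifnot(inherits(spec, "SimulationSpec"))
  set.seed(spec$seed)
  n <- spec$nSamples; p <- spec$nMarkers; k <- spec$nTraits
  maf <- stats::runif(p, spec$mafRange[1], spec$mafRange[2])
  X <- matrix(stats::rbinom(n * p, 2L, rep(maf, each = n)), nrow = n)

  moduleAssignment <- integer(k)  # 0 = not in any module
  stops <- cumsum(spec$moduleSizes)
  starts <- c(1L, utils::head(stops, -1L) + 1L)
  for (m in seq_len(spec$nModules))
    moduleAssignment[starts[m]:stops[m]] <- m

  causal <- sort(sample.int(p, spec$nCausal))
  causalModule <- sample.int(spec$nModules, spec$nCausal, replace = TRUE)
  bi <- integer(0); bj <- integer(0); bx <- numeric(0)
  for (c in seq_len(spec$nCausal)) {
    members <- which(moduleAssignment == causalModule[c])
    sgn <- sample(c(-1, 1), 1L)
    hits <- if (stats::runif(1) <= spec$withinModuleSharing) members
            else sample(members, 1L)
    bi <- c(bi, rep(causal[c], length(hits)))
    bj <- c(bj, hits)
    bx <- c(bx, rep(sgn * spec$effectSize, length(hits)))
  }
  trueB <- Matrix::sparseMatrix(i = bi, j = bj, x = bx, dims = c(p, k))

  factors <- matrix(stats::rnorm(n * spec$nModules), nrow = n)
  latent <- matrix(0, n, k)
  for (m in seq_len(spec$nModules)) {
    members <- which(moduleAssignment == m)
    latent[, members] <- spec$latentLoading * factors[, m]
  }
  noise <- if (spec$noiseSd > 0) matrix(stats::rnorm(n * k, sd = spec$noiseSd), n, k)
           else matrix(0, n, k)
  Y <- latent + as.matrix(X %*% trueB) + noise

  # synthetic map: markers spread evenly over 16 chromosomes
  chrom <- paste0("chr", ((seq_len(p) - 1L) %% 16L) + 1L)
  pos <- 1000L * (((seq_len(p) - 1L) %/% 16L) + 1L)
  list(genotype = GenotypeMatrix(X, chrom = chrom, pos = pos,
                                 sampleIds = paste0("s", seq_len(n))),
       traits = TraitMatrix(Y, sampleIds = paste0("s", seq_len(n))),
       truth = list(trueB = trueB, moduleAssignment = moduleAssignment,
                    causalMarkers = causal, maf = maf))
}

#' Export a simulated dataset as the four-file import layout
#'
#' Writes `example_gen.txt` (genotype matrix, space-delimited, headerless),
#' `example_chrkey.txt` (marker key: chromosome, position, name),
#' `example_phen.txt` (trait matrix, no headers) and `example_phen_key.txt`
#' (one trait label per line), so the file-import path can be exercised
#' end-to-end on generated data.
#'
#' @param dataset a list as returned by [simulateDataset()] (elements
#'   `genotype` and `traits`).
#' @param directory output directory (created if needed; must be writable).
#' @return named character vector of the four file paths, invisibly.
#' @export
exportFixture <- function(dataset, directory) {
  if (!dir.exists(directory) &&
      !dir.create(directory, recursive = TRUE, showWarnings = FALSE))
    gfStop("gfmap_io_error", "cannot create directory %s", directory)
  if (file.access(directory, 2L) != 0L)
    gfStop("gfmap_io_error", "directory %s is not writable", directory)
  g <- dataset$genotype; t <- dataset$traits
  paths <- c(genotype = file.path(directory, "example_gen.txt"),
             key = file.path(directory, "example_chrkey.txt"),
             traits = file.path(directory, "example_phen.txt"),
             labels = file.path(directory, "example_phen_key.txt"))
  writeLines(apply(g@values, 1L, paste, collapse = " "), paths["genotype"])
  lc <- loci(g)
  writeLines(paste(as.character(GenomicRanges::seqnames(lc)),
                   GenomicRanges::start(lc), g@markerIds), paths["key"])
  writeLines(apply(t@values, 1L, function(r) paste(fmtReal(r), collapse = " ")),
             paths["traits"])
  writeLines(t@traitIds, paths["labels"])
  invisible(paths)
}
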