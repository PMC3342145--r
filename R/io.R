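#' @include AllClasses.R
NULL

## classed conditions so callers can distinguish import failures from bugs
gfStop <- function(class, fmt, ...) {
  stop(structure(class = c(class, "gfmap_error", "error", "condition"),
                 list(message = sprintf(fmt, ...), call = sys.call(-1))))
}

## split one line into tokens; delimiter "w" means any run of whitespace
splitTokens <- function(lines, delimiter) {
  if (identical(delimiter, "w")) {
    strsplit(trimws(lines), "[ \t\r]+")
  } else {
    if (nchar(delimiter) != 1L)
      gfStop("gfmap_import_error",
             "delimiter must be a single character or \"w\", got %s", delimiter)
    strsplit(sub("\r$", "", lines), delimiter, fixed = TRUE)
  }
}

## strict numeric parse: any non-numeric or missing-value token is an error;
## values are never silently imputed
parseNumericMatrix <- function(lines, delimiter, what) {
  toks <- splitTokens(lines, delimiter)
  ncols <- lengths(toks)
  if (length(unique(ncols)) > 1L)
    gfStop("gfmap_import_error",
           "%s: ragged rows (row 1 has %d columns, row %d has %d)",
           what, ncols[1], which(ncols != ncols[1])[1], ncols[ncols != ncols[1]][1])
  flat <- unlist(toks, use.names = FALSE)
  vals <- suppressWarnings(as.numeric(flat))
  bad <- which(is.na(vals) | !is.finite(vals) |
                 toupper(flat) %in% c("NA", "NAN", "INF", "-INF", ".", ""))
  if (length(bad)) {
    i <- bad[1]
    row <- ((i - 1L) %/% ncols[1]) + 1L
    col <- ((i - 1L) %% ncols[1]) + 1L
    gfStop("gfmap_import_error",
           "%s: non-numeric or missing value token \"%s\" at row %d, column %d; impute missing values before import",
           what, flat[i], row, col)
  }
  matrix(vals, nrow = length(lines), byrow = TRUE)
}

readNonEmptyLines <- function(path) {
  if (!file.exists(path))
    gfStop("gfmap_import_error", "file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines[nzchar(trimws(lines))]
}

#' Construct a GenotypeMatrix
#'
#' @param values numeric samples-by-markers matrix.
#' @param chrom,pos per-marker chromosome labels and 1-based positions, or
#'   pass `loci` directly.
#' @param markerIds optional marker names; defaults to `snp_<index>`.
#' @param sampleIds optional sample labels.
#' @param loci optional [GenomicRanges::GRanges] overriding `chrom`/`pos`.
#' @return a \linkS4class{GenotypeMatrix}.
#' @export
GenotypeMatrix <- function(values, chrom = NULL, pos = NULL, markerIds = NULL,
                           sampleIds = NULL, loci = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  p <- ncol(values)
  if (is.null(loci)) {
    if (is.null(chrom) || is.null(pos)) {
      chrom <- rep("chrUn", p)
      pos <- seq_len(p)
    }
    loci <- GenomicRanges::GRanges(as.character(chrom),
                                   IRanges::IRanges(as.integer(pos),
                                                    width = 1L))
  }
  if (is.null(markerIds)) markerIds <- paste0("snp_", seq_len(p))
  names(loci) <- markerIds
  new("GenotypeMatrix", values = unname(values), markerIds = as.character(markerIds),
      loci = loci, sampleIds = sampleIds)
}

#' Construct a TraitMatrix
#'
#' @param values numeric samples-by-traits matrix.
#' @param traitIds optional trait labels; defaults to `trait_<index>`.
#' @param sampleIds optional sample labels.
#' @return a \linkS4class{TraitMatrix}.
#' @export
TraitMatrix <- function(values, traitIds = NULL, sampleIds = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(traitIds)) traitIds <- paste0("trait_", seq_len(ncol(values)))
  new("TraitMatrix", values = unname(values), traitIds = as.character(traitIds),
      sampleIds = sampleIds)
}

#' Read a genotype matrix and its marker key
#'
#' The genotype file is a headerless numeric table: rows are samples, columns
#' are markers (a 0/1/2 minor-allele count encoding is recommended). The key
#' file has one line per marker with two or three whitespace-delimited
#' columns: chromosome, 1-based position, and an optional marker name
#' (absent names are generated as `snp_<index>`). Missing-value tokens
#' (`NA`, `.`, empty) and non-numeric cells are rejected outright: impute
#' before import.
#'
#' @param matrixPath path to the genotype matrix file.
#' @param keyPath path to the marker key file.
#' @param delimiter single character, or `"w"` for any run of whitespace
#'   (the default).
#' @param sampleLabelPath optional file with one sample label per line.
#' @return a \linkS4class{GenotypeMatrix}.
#' @examples
#' d <- tempfile(); k <- tempfile()
#' writeLines(c("0 1 2", "1 1 0"), d)
#' writeLines(c("chr1 100", "chr1 200", "chr2 50"), k)
#' g <- readGenotype(d, k)
#' nMarkers(g)
#' @export
readGenotype <- function(matrixPath, keyPath, delimiter = "w",
                         sampleLabelPath = NULL) {
  lines <- readNonEmptyLines(matrixPath)
  values <- parseNumericMatrix(lines, delimiter, "genotype matrix")
  key <- readNonEmptyLines(keyPath)
  if (length(key) != ncol(values))
    gfStop("gfmap_import_error", "marker count mismatch (%d vs %d)",
           ncol(values), length(key))
  ktoks <- splitTokens(key, "w")
  nk <- lengths(ktoks)
  if (any(nk < 2L))
    gfStop("gfmap_import_error",
           "marker key line %d has fewer than 2 columns", which(nk < 2L)[1])
  chrom <- vapply(ktoks, `[[`, "", 1L)
  pos <- suppressWarnings(as.integer(vapply(ktoks, `[[`, "", 2L)))
  if (anyNA(pos) || any(pos < 0L))
    gfStop("gfmap_import_error", "marker key positions must be non-negative integers")
  markerIds <- ifelse(nk >= 3L, vapply(ktoks, function(t) t[3], ""),
                      paste0("snp_", seq_along(ktoks)))
  sampleIds <- NULL
  if (!is.null(sampleLabelPath)) {
    sampleIds <- readNonEmptyLines(sampleLabelPath)
    if (length(sampleIds) != nrow(values))
      gfStop("gfmap_import_error", "sample label count mismatch (%d vs %d)",
             nrow(values), length(sampleIds))
  }
  GenotypeMatrix(values, chrom = chrom, pos = pos, markerIds = markerIds,
                 sampleIds = sampleIds)
}

#' Read a trait/expression matrix with a trait label file
#'
#' Supports four header layouts: `"none"` (pure numeric table),
#' `"row_headers"` (first column holds sample labels),
#' `"column_headers"` (first line holds trait labels), and `"both"`.
#' Labels from `labelPath` (one per trait) take precedence over any
#' in-file column headers.
#'
#' @param matrixPath path to the trait matrix file (rows are samples).
#' @param labelPath optional file with one trait label per line.
#' @param headerMode one of `"none"`, `"row_headers"`, `"column_headers"`,
#'   `"both"`.
#' @param delimiter single character or `"w"` (whitespace, the default).
#' @return a \linkS4class{TraitMatrix}.
#' @export
readTraits <- function(matrixPath, labelPath = NULL,
                       headerMode = c("none", "row_headers", "column_headers", "both"),
                       delimiter = "w") {
  headerMode <- match.arg(headerMode)
  lines <- readNonEmptyLines(matrixPath)
  colHeaders <- NULL
  if (headerMode %in% c("column_headers", "both")) {
    colHeaders <- splitTokens(lines[1], delimiter)[[1]]
    lines <- lines[-1]
  }
  sampleIds <- NULL
  if (headerMode %in% c("row_headers", "both")) {
    toks <- splitTokens(lines, delimiter)
    sampleIds <- vapply(toks, `[[`, "", 1L)
    lines <- vapply(toks, function(t) paste(t[-1], collapse = " "), "")
    delimiter <- "w"
    if (headerMode == "both" && length(colHeaders) > length(splitTokens(lines[1], "w")[[1]]))
      colHeaders <- colHeaders[-1]  # corner cell counted with the header row
  }
  values <- parseNumericMatrix(lines, delimiter, "trait matrix")
  traitIds <- colHeaders
  if (!is.null(labelPath)) {
    traitIds <- readNonEmptyLines(labelPath)
    if (length(traitIds) != ncol(values))
      gfStop("gfmap_import_error", "trait label count mismatch (%d labels vs %d columns)",
             length(traitIds), ncol(values))
  }
  TraitMatrix(values, traitIds = traitIds, sampleIds = sampleIds)
}

#' Pair a genotype matrix with a trait matrix over shared samples
#'
#' Pairing is accepted iff the sample counts agree. When both objects carry
#' sample labels the rows are aligned by label (so the two files may list
#' samples in different orders); otherwise the row order is assumed shared.
#'
#' @param genotype a \linkS4class{GenotypeMatrix}.
#' @param traits a \linkS4class{TraitMatrix}.
#' @return a \linkS4class{PairedDataset} whose rows are aligned.
#' @export
pairDatasets <- function(genotype, traits) {
  if (nSamples(genotype) != nSamples(traits))
    gfStop("gfmap_pairing_error", "sample count mismatch (%d vs %d)",
           nSamples(genotype), nSamples(traits))
  gIds <- sampleIds(genotype); tIds <- sampleIds(traits)
  if (!is.null(gIds) && !is.null(tIds)) {
    if (anyDuplicated(gIds) || anyDuplicated(tIds))
      gfStop("gfmap_pairing_error", "duplicate sample labels")
    ord <- match(sort(gIds), gIds)
    tOrd <- match(sort(gIds), tIds)
    if (anyNA(tOrd))
      gfStop("gfmap_pairing_error", "unmatched sample labels: %s",
             paste(utils::head(setdiff(gIds, tIds), 5), collapse = ", "))
    genotype <- new("GenotypeMatrix", values = genotype@values[ord, , drop = FALSE],
                    markerIds = genotype@markerIds, loci = genotype@loci,
                    sampleIds = gIds[ord])
    traits <- new("TraitMatrix", values = traits@values[tOrd, , drop = FALSE],
                  traitIds = traits@traitIds, sampleIds = tIds[tOrd])
  }
  new("PairedDataset", genotype = genotype, traits = traits)
}

#' Construct an AssociationResult
#'
#' @param markerIds,traitIds identifier vectors.
#' @param marker,trait,weight parallel vectors of 1-based indices and
#'   nonzero weights; zero weights are dropped (only nonzero values are
#'   stored).
#' @param p_value optional parallel vector of p-values in `[0, 1]`.
#' @param methodTag short string naming the producing method.
#' @return an \linkS4class{AssociationResult}.
#' @export
AssociationResult <- function(markerIds, traitIds, marker = integer(),
                              trait = integer(), weight = numeric(),
                              p_value = NULL, methodTag = "unknown") {
  keep <- weight != 0
  entries <- data.frame(marker = as.integer(marker[keep]),
                        trait = as.integer(trait[keep]),
                        weight = as.numeric(weight[keep]))
  if (!is.null(p_value)) entries$p_value <- as.numeric(p_value[keep])
  o <- order(entries$marker, entries$trait)
  new("AssociationResult", markerIds = as.character(markerIds),
      traitIds = as.character(traitIds), entries = entries[o, , drop = FALSE],
      methodTag = methodTag)
}

## 6-significant-digit decimal formatting; as.character() of the rounded
## double round-trips exactly, which pins down the file dialect
fmtReal <- function(x) as.character(signif(x, 6))

#' Write / read sparse association results as TSV
#'
#' The on-disk dialect is a tab-separated table with a header and columns
#' `marker_id`, `trait_id`, `weight` and, when present, `p_value`; only
#' nonzero entries are written, reals with 6 significant digits. A comment
#' line preserves the marker/trait universes and the method tag so the
#' round-trip is lossless.
#'
#' @param result an \linkS4class{AssociationResult}.
#' @param path output (input) file path.
#' @return `writeAssociation` returns `path` invisibly; `readAssociation`
#'   returns the reconstructed \linkS4class{AssociationResult}.
#' @export
writeAssociation <- function(result, path) {
  stopifnot(is(result, "AssociationResult"))
  e <- result@entries
  hasP <- !is.null(e$p_value)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# gfmap association\tmethod=%s", result@methodTag),
    sprintf("# markers\t%s", paste(result@markerIds, collapse = "\t")),
    sprintf("# traits\t%s", paste(result@traitIds, collapse = "\t")),
    paste(c("marker_id", "trait_id", "weight", if (hasP) "p_value"),
          collapse = "\t")), con)
  if (nrow(e)) {
    rows <- paste(result@markerIds[e$marker], result@traitIds[e$trait],
                  fmtReal(e$weight), sep = "\t")
    if (hasP) rows <- paste(rows, fmtReal(e$p_value), sep = "\t")
    writeLines(rows, con)
  }
  invisible(path)
}

#' @rdname writeAssociation
#' @export
readAssociation <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta <- lines[startsWith(lines, "# ")]
  body <- lines[!startsWith(lines, "# ")]
  getMeta <- function(tag) {
    ln <- meta[startsWith(meta, paste0("# ", tag))]
    if (!length(ln)) gfStop("gfmap_import_error", "missing '%s' metadata line", tag)
    strsplit(ln[1], "\t", fixed = TRUE)[[1]][-1]
  }
  methodTag <- sub("^method=", "", sub("^# gfmap association\t", "", meta[1]))
  markerIds <- getMeta("markers")
  traitIds <- getMeta("traits")
  if (!length(body)) gfStop("gfmap_import_error", "missing header row")
  hdr <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  hasP <- "p_value" %in% hdr
  rows <- body[-1]
  rows <- rows[nzchar(rows)]
  if (!length(rows))
    return(AssociationResult(markerIds, traitIds, methodTag = methodTag,
                             p_value = if (hasP) numeric() else NULL))
  toks <- strsplit(rows, "\t", fixed = TRUE)
  nt <- lengths(toks)
  if (any(nt != length(hdr)))
    gfStop("gfmap_import_error", "malformed association row %d", which(nt != length(hdr))[1])
  mk <- match(vapply(toks, `[[`, "", 1L), markerIds)
  tr <- match(vapply(toks, `[[`, "", 2L), traitIds)
  if (anyNA(mk) || anyNA(tr))
    gfStop("gfmap_import_error", "association row references unknown marker or trait")
  w <- as.numeric(vapply(toks, `[[`, "", 3L))
  pv <- if (hasP) as.numeric(vapply(toks, `[[`, "", 4L)) else NULL
  AssociationResult(markerIds, traitIds, marker = mk, trait = tr, weight = w,
                    p_value = pv, methodTag = methodTag)
}

#' Write / read a trait network as an edge-list TSV
#'
#' Edges are written once per undirected pair as `trait_a`, `trait_b`,
#' `weight` (6 significant digits). Comment lines preserve the node universe
#' and the edge threshold so isolated traits survive the round-trip.
#'
#' @param net a \linkS4class{TraitNetwork}.
#' @param path file path.
#' @return `writeNetwork` returns `path` invisibly; `readNetwork` the
#'   reconstructed \linkS4class{TraitNetwork}.
#' @export
writeNetwork <- function(net, path) {
  stopifnot(is(net, "TraitNetwork"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# gfmap trait network\tthreshold=%s", fmtReal(net@threshold)),
    sprintf("# traits\t%s", paste(net@traitIds, collapse = "\t")),
    "trait_a\ttrait_b\tweight"), con)
  e <- net@edges
  if (nrow(e))
    writeLines(paste(net@traitIds[e$from], net@traitIds[e$to],
                     fmtReal(e$weight), sep = "\t"), con)
  invisible(path)
}

#' @rdname writeNetwork
#' @export
readNetwork <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta <- lines[startsWith(lines, "# ")]
  body <- lines[!startsWith(lines, "# ")]
  thr <- as.numeric(sub(".*threshold=", "", meta[1]))
  traitIds <- strsplit(meta[startsWith(meta, "# traits")][1], "\t", fixed = TRUE)[[1]][-1]
  rows <- body[-1]
  rows <- rows[nzchar(rows)]
  if (length(rows)) {
    toks <- strsplit(rows, "\t", fixed = TRUE)
    if (any(lengths(toks) != 3L))
      gfStop("gfmap_import_error", "malformed network row")
    from <- match(vapply(toks, `[[`, "", 1L), traitIds)
    to <- match(vapply(toks, `[[`, "", 2L), traitIds)
    w <- as.numeric(vapply(toks, `[[`, "", 3L))
    e <- data.frame(from = pmin(from, to), to = pmax(from, to), weight = w)
    e <- e[order(e$from, e$to), , drop = FALSE]
  } else {
    e <- data.frame(from = integer(), to = integer(), weight = numeric())
  }
  new("TraitNetwork", traitIds = traitIds, edges = e, threshold = thr)
}
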