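#' TE annotation set with interval index
#'
#' Holds a normalized set of transposable-element loci as a [GRanges] with
#' locus metadata columns (`locus_id`, `subfamily`, `family`, `clazz`,
#' `milli_div`, `is_reference`), plus a genome build label. Coordinates are
#' stored in the usual Bioconductor 1-based closed convention; all text I/O
#' (BED, RepeatMasker) converts to/from 0-based half-open on the fly, and
#' `locus_id` uses BED-style coordinates
#' (`chrom|start0|end0|subfamily|strand`).
#'
#' @slot loci A `GRanges` of TE loci with the metadata columns above.
#' @slot genomeBuild Character label for the genome build (may be `""`).
#'
#' @seealso [parseRepeatMasker()], [readTeBed()], [mergeExtra()],
#'   [queryLoci()]
#' @export
setClass("TEAnnotation", representation(
  loci = "GRanges",
  genomeBuild = "character"
))

setValidity("TEAnnotation", function(object) {
  gr <- object@loci
  need <- c("locus_id", "subfamily", "family", "clazz", "milli_div",
            "is_reference")
  missing <- setdiff(need, colnames(mcols(gr)))
  if (length(missing))
    return(paste("missing metadata columns:", paste(missing, collapse = ", ")))
  if (anyDuplicated(gr$locus_id))
    return("duplicate locus_id in annotation set")
  s <- as.character(strand(gr))
  if (length(gr) && !all(s %in% c("+", "-")))
    return("locus strand must be '+' or '-'")
  TRUE
})

#' Construct a TEAnnotation from a GRanges
#'
#' @param loci `GRanges` with metadata columns `subfamily`, `family`, `clazz`,
#'   `milli_div`; `locus_id` and `is_reference` are filled in if absent.
#' @param genomeBuild Genome build label.
#' @return A [TEAnnotation-class] object.
#' @export
TEAnnotation <- function(loci, genomeBuild = "") {
  mc <- mcols(loci)
  if (is.null(mc$is_reference)) loci$is_reference <- rep(TRUE, length(loci))
  if (is.null(mc$locus_id)) loci$locus_id <- makeLocusId(loci)
  new("TEAnnotation", loci = loci, genomeBuild = genomeBuild)
}

#' Deterministic locus identifier
#'
#' `chrom|start0|end0|subfamily|strand` with 0-based half-open coordinates.
#'
#' @param gr A `GRanges` with a `subfamily` metadata column.
#' @return Character vector of locus ids.
#' @export
makeLocusId <- function(gr) {
  paste(as.character(seqnames(gr)), start(gr) - 1L, end(gr),
        gr$subfamily, as.character(strand(gr)), sep = "|")
}

#' @describeIn TEAnnotation-class number of loci
#' @param x,object A `TEAnnotation`.
#' @export
setMethod("length", "TEAnnotation", function(x) length(x@loci))

#' Extract the locus GRanges from a TEAnnotation
#'
#' @param x A [TEAnnotation-class].
#' @return The underlying `GRanges`.
#' @export
teLoci <- function(x) {
  stopifnot(is(x, "TEAnnotation"))
  x@loci
}

#' Genome build label of a TEAnnotation
#' @param x A [TEAnnotation-class].
#' @return Character scalar.
#' @export
genomeBuild <- function(x) {
  stopifnot(is(x, "TEAnnotation"))
  x@genomeBuild
}

setMethod("show", "TEAnnotation", function(object) {
  gr <- object@loci
  cat("TEAnnotation with", length(gr), "loci")
  if (nzchar(object@genomeBuild)) cat(" [", object@genomeBuild, "]", sep = "")
  cat("\n")
  if (length(gr)) {
    nref <- sum(!gr$is_reference)
    cat("  classes:", paste(sort(unique(gr$clazz)), collapse = ", "), "\n")
    if (nref) cat("  non-reference loci:", nref, "\n")
  }
})

#' Query loci overlapping an interval
#'
#' Returns the loci overlapping `[start, end)` (0-based half-open) on `chrom`.
#'
#' @param ann A [TEAnnotation-class].
#' @param chrom Chromosome/contig name.
#' @param start,end 0-based half-open interval.
#' @return `GRanges` of overlapping loci.
#' @export
queryLoci <- function(ann, chrom, start, end) {
  q <- GRanges(chrom, IRanges(start + 1L, end))
  gr <- teLoci(ann)
  gr[as.character(seqnames(gr)) == chrom &
       GenomicRanges::start(gr) <= end & GenomicRanges::end(gr) >= start + 1L]
}

#' Per-locus TE expression estimates
#'
#' Result container for [quantifyTE()]. One row of `estimates` per
#' (locus, orientation) with assigned counts, transcript span, effective
#' length, confidence score and FPKM; `subfamilies` holds the aggregated
#' subfamily table.
#'
#' @slot estimates `data.frame` of per-locus estimates (see
#'   [writeLocusTable()] for the column set).
#' @slot subfamilies `data.frame` of subfamily aggregates.
#' @slot libSize Number of fragments with at least one reported alignment
#'   (FPKM denominator).
#' @slot params List of quantification parameters actually used.
#' @slot nIter Number of EM iterations performed.
#' @slot converged Logical; `FALSE` if the auto loop hit the iteration cap.
#' @export
setClass("TECounts", representation(
  estimates = "data.frame",
  subfamilies = "data.frame",
  libSize = "numeric",
  params = "list",
  nIter = "integer",
  converged = "logical"
))

#' Per-locus estimate table of a TECounts
#' @param x A [TECounts-class].
#' @return `data.frame` of per-(locus, orientation) estimates.
#' @export
locusEstimates <- function(x) {
  stopifnot(is(x, "TECounts"))
  x@estimates
}

#' Subfamily aggregate table of a TECounts
#' @param x A [TECounts-class].
#' @return `data.frame` of subfamily totals.
#' @export
subfamilySummary <- function(x) {
  stopifnot(is(x, "TECounts"))
  x@subfamilies
}

#' Library size (fragments with >=1 alignment) of a TECounts
#' @param x A [TECounts-class].
#' @return Numeric scalar.
#' @export
librarySize <- function(x) {
  stopifnot(is(x, "TECounts"))
  x@libSize
}

setMethod("show", "TECounts", function(object) {
  est <- object@estimates
  cat("TECounts:", nrow(est), "locus/orientation rows,",
      nrow(object@subfamilies), "subfamilies\n")
  cat("  library size:", object@libSize, "fragments; EM iterations:",
      object@nIter, if (!object@converged) "(not converged)" else "", "\n")
  if (nrow(est)) {
    top <- head(est[order(-est$C_TE), c("locus_id", "orientation", "C_TE",
                                        "score", "fpkm")], 5L)
    print(top, row.names = FALSE)
  }
})
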