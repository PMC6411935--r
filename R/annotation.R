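## RepeatMasker-derived TE annotation: parsing, normalization, BED I/O.
## All external coordinates are BED-style 0-based half-open; internally loci
## live in a GRanges (1-based closed) inside a TEAnnotation.

.TE_CLASSES <- c("LINE", "SINE", "LTR", "DNA", "Retroposon", "RC",
                 "Unknown", "Other")

.stripQ <- function(x) sub("\\?$", "", x)

#' Parse RepeatMasker-derived TE annotation
#'
#' Reads either native RepeatMasker `.out` files (whitespace-delimited, three
#' header lines, 1-based inclusive coordinates, strand symbol `C` for minus)
#' or UCSC `rmsk` table dumps (TSV, 0-based half-open `genoStart`/`genoEnd`,
#' with or without the leading `#bin` column). All loci are normalized to a
#' single convention and, by default, filtered to transposable-element
#' classes (LINE, SINE, LTR, DNA, Retroposon, RC, Unknown, Other); set
#' `allRepeats = TRUE` to also keep simple repeats, low-complexity and
#' satellite annotation.
#'
#' @param path Annotation file.
#' @param dialect `"rm_out"`, `"ucsc_rmsk"`, or `"auto"` (detect from
#'   content: tab-separated 16/17-column rows are treated as `ucsc_rmsk`).
#' @param allRepeats Keep non-TE repeat classes too.
#' @param genomeBuild Optional build label stored on the result.
#' @return A [TEAnnotation-class].
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(paste(c(585, 1000, 115, 0, 0, "chr1", 100, 200, -1e6, "+",
#'   "AluYa5", "SINE", "Alu", 1, 100, 0, 1), collapse = "\t"), f)
#' ann <- parseRepeatMasker(f, "ucsc_rmsk")
#' teLoci(ann)
#' @export
parseRepeatMasker <- function(path, dialect = c("auto", "rm_out", "ucsc_rmsk"),
                              allRepeats = FALSE, genomeBuild = "") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  lines <- readLines(path)
  if (dialect == "auto") dialect <- .detectRmskDialect(lines)
  loci <- switch(dialect,
    rm_out = .parseRmOut(lines),
    ucsc_rmsk = .parseUcscRmsk(lines)
  )
  if (!allRepeats && nrow(loci))
    loci <- loci[.stripQ(loci$clazz) %in% .TE_CLASSES, , drop = FALSE]
  gr <- GRanges(loci$chrom,
                IRanges(loci$start + 1L, loci$end),
                strand = loci$strand)
  gr$subfamily <- loci$subfamily
  gr$family <- loci$family
  gr$clazz <- loci$clazz
  gr$milli_div <- loci$milli_div
  gr$is_reference <- rep(TRUE, nrow(loci))
  gr$locus_id <- makeLocusId(gr)
  TEAnnotation(gr, genomeBuild = genomeBuild)
}

.detectRmskDialect <- function(lines) {
  body <- lines[nzchar(trimws(lines))]
  if (!length(body)) return("ucsc_rmsk")  # empty: either parser yields 0 loci
  nf <- length(strsplit(body[1], "\t", fixed = TRUE)[[1]])
  if (nf %in% c(16L, 17L)) "ucsc_rmsk" else "rm_out"
}

.badLine <- function(i, dialect, why) {
  stop(sprintf("malformed line %d (%s dialect): %s", i, dialect, why),
       call. = FALSE)
}

.parseStrand <- function(sym, i, dialect) {
  out <- chartr("C", "-", sym)
  bad <- !(out %in% c("+", "-"))
  if (any(bad))
    .badLine(i[bad][1], dialect, paste0("unknown strand symbol '",
                                        sym[bad][1], "'"))
  out
}

.parseRmOut <- function(lines) {
  # native .out: 3 header lines (two column-name lines and a blank)
  keep <- seq_along(lines) > 3L & nzchar(trimws(lines))
  idx <- which(keep)
  if (!length(idx)) return(.emptyLocusFrame())
  toks <- strsplit(trimws(lines[idx]), "\\s+")
  nf <- lengths(toks)
  if (any(nf < 11L)) .badLine(idx[nf < 11L][1], "rm_out", "fewer than 11 fields")
  m <- t(vapply(toks, function(x) x[1:11], character(11)))
  begin <- suppressWarnings(as.integer(m[, 6]))
  end <- suppressWarnings(as.integer(m[, 7]))
  if (anyNA(begin) || anyNA(end))
    .badLine(idx[is.na(begin) | is.na(end)][1], "rm_out",
             "non-numeric coordinates")
  strand <- .parseStrand(m[, 9], idx, "rm_out")
  cf <- strsplit(m[, 11], "/", fixed = TRUE)
  clazz <- vapply(cf, `[`, "", 1L)
  family <- vapply(cf, function(x) if (length(x) > 1L) x[2] else x[1], "")
  data.frame(
    chrom = m[, 5],
    start = begin - 1L,           # 1-based inclusive -> 0-based half-open
    end = end,
    strand = strand,
    subfamily = m[, 10],
    family = family,
    clazz = clazz,
    milli_div = suppressWarnings(as.numeric(m[, 2])) * 10,  # percent -> per-mil
    stringsAsFactors = FALSE
  )
}

.parseUcscRmsk <- function(lines) {
  body <- which(nzchar(trimws(lines)) & !startsWith(lines, "#"))
  if (!length(body)) return(.emptyLocusFrame())
  toks <- strsplit(lines[body], "\t", fixed = TRUE)
  nf <- lengths(toks)
  if (!all(nf %in% c(16L, 17L)))
    .badLine(body[!(nf %in% c(16L, 17L))][1], "ucsc_rmsk",
             "expected 16 or 17 tab-separated fields")
  off <- ifelse(nf == 17L, 1L, 0L)  # leading bin column, autodetected per row
  g <- function(k) mapply(function(x, o) x[k + o], toks, off)
  gstart <- suppressWarnings(as.integer(g(6)))
  gend <- suppressWarnings(as.integer(g(7)))
  if (anyNA(gstart) || anyNA(gend))
    .badLine(body[is.na(gstart) | is.na(gend)][1], "ucsc_rmsk",
             "non-numeric genoStart/genoEnd")
  data.frame(
    chrom = g(5),
    start = gstart,               # already 0-based half-open
    end = gend,
    strand = .parseStrand(g(9), body, "ucsc_rmsk"),
    subfamily = g(10),
    family = g(12),
    clazz = g(11),
    milli_div = suppressWarnings(as.numeric(g(2))),
    stringsAsFactors = FALSE
  )
}

.emptyLocusFrame <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             strand = character(), subfamily = character(),
             family = character(), clazz = character(),
             milli_div = numeric(), stringsAsFactors = FALSE)
}

#' Taxonomy string for TE loci
#'
#' Formats the RepeatMasker taxonomy as `subfamily:family:class`
#' (e.g. `AluYa5:Alu:SINE`).
#'
#' @param x A [TEAnnotation-class] or a `GRanges` with `subfamily`, `family`,
#'   `clazz` metadata columns.
#' @return Character vector, one string per locus.
#' @export
taxonomyString <- function(x) {
  gr <- if (is(x, "TEAnnotation")) teLoci(x) else x
  stopifnot(all(nzchar(gr$subfamily)), all(nzchar(gr$family)),
            all(nzchar(gr$clazz)))
  paste(gr$subfamily, gr$family, gr$clazz, sep = ":")
}

#' Write a TE annotation as BED
#'
#' Six BED columns (chrom, start, end, locus_id, score = rounded milliDiv,
#' strand) followed by extra columns subfamily, family, clazz, milli_div,
#' is_reference. Tab-delimited, no header, 0-based half-open.
#'
#' @param ann A [TEAnnotation-class].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
writeTeBed <- function(ann, path) {
  gr <- teLoci(ann)
  dt <- data.table(
    chrom = as.character(seqnames(gr)),
    start = start(gr) - 1L,
    end = end(gr),
    name = gr$locus_id,
    score = pmin(1000L, as.integer(round(gr$milli_div))),
    strand = as.character(strand(gr)),
    subfamily = gr$subfamily,
    family = gr$family,
    clazz = gr$clazz,
    milli_div = gr$milli_div,
    is_reference = as.integer(gr$is_reference)
  )
  setorder(dt, chrom, start, end, name)
  .writeTsv(dt, path, col.names = FALSE)
  invisible(path)
}

#' Read a TE annotation written by [writeTeBed()]
#'
#' Also accepts plain BED6 (name column is then taken as the subfamily, with
#' family/class `"Unknown"`).
#'
#' @param path BED file.
#' @param genomeBuild Optional build label.
#' @return A [TEAnnotation-class].
#' @export
readTeBed <- function(path, genomeBuild = "") {
  dt <- tryCatch(
    suppressWarnings(
      data.table::fread(path, header = FALSE, sep = "\t",
                        data.table = TRUE)),
    error = function(e) data.table()
  )
  if (!nrow(dt)) {
    gr <- GRanges()
    gr$subfamily <- character()
    gr$family <- character()
    gr$clazz <- character()
    gr$milli_div <- numeric()
    gr$is_reference <- logical()
    gr$locus_id <- character()
    return(TEAnnotation(gr, genomeBuild))
  }
  if (ncol(dt) < 6L) stop("need at least 6 BED columns: ", path)
  full <- ncol(dt) >= 11L
  gr <- GRanges(as.character(dt[[1]]),
                IRanges(dt[[2]] + 1L, dt[[3]]),
                strand = as.character(dt[[6]]))
  gr$subfamily <- if (full) as.character(dt[[7]]) else as.character(dt[[4]])
  gr$family <- if (full) as.character(dt[[8]]) else "Unknown"
  gr$clazz <- if (full) as.character(dt[[9]]) else "Unknown"
  gr$milli_div <- if (full) as.numeric(dt[[10]]) else as.numeric(dt[[5]])
  gr$is_reference <- if (full) as.logical(dt[[11]]) else rep(TRUE, nrow(dt))
  gr$locus_id <- makeLocusId(gr)
  TEAnnotation(gr, genomeBuild)
}

#' Merge non-reference TE contigs into an annotation set
#'
#' Adds user-supplied TE loci living on extra contigs (e.g. an expression
#' vector or polymorphic-insertion sequences) to a reference annotation.
#' Extra loci are flagged `is_reference = FALSE` and become queryable like
#' any other locus.
#'
#' @param ann Reference [TEAnnotation-class].
#' @param extraBed BED file of loci on the extra contigs (BED6; name column
#'   is the subfamily, optional columns 7-8 are family and class).
#' @param extraFasta FASTA of the extra contig sequences.
#' @return A [TEAnnotation-class] containing both sets.
#' @export
mergeExtra <- function(ann, extraBed, extraFasta) {
  fa <- readDNAStringSet(extraFasta)
  names(fa) <- sub("\\s.*$", "", names(fa))
  ref <- teLoci(ann)
  clash <- intersect(names(fa), as.character(seqlevels(ref)))
  if (length(clash))
    stop("extra contig name collides with reference chromosome: ",
         paste(clash, collapse = ", "))
  dt <- tryCatch(
    suppressWarnings(
      data.table::fread(extraBed, header = FALSE, sep = "\t",
                        data.table = TRUE)),
    error = function(e) data.table()
  )
  if (!nrow(dt)) return(ann)
  if (ncol(dt) < 6L) stop("extra BED needs at least 6 columns")
  bad <- !(as.character(dt[[1]]) %in% names(fa))
  if (any(bad))
    stop("extra BED interval on contig absent from FASTA: ",
         as.character(dt[[1]])[bad][1])
  over <- dt[[3]] > setNames(width(fa), names(fa))[as.character(dt[[1]])]
  if (any(over))
    stop("extra BED interval exceeds contig length on: ",
         as.character(dt[[1]])[over][1])
  gx <- GRanges(as.character(dt[[1]]), IRanges(dt[[2]] + 1L, dt[[3]]),
                strand = as.character(dt[[6]]))
  gx$subfamily <- as.character(dt[[4]])
  gx$family <- if (ncol(dt) >= 7L) as.character(dt[[7]]) else gx$subfamily
  gx$clazz <- if (ncol(dt) >= 8L) as.character(dt[[8]]) else "Unknown"
  gx$milli_div <- rep(0, nrow(dt))
  gx$is_reference <- rep(FALSE, nrow(dt))
  gx$locus_id <- makeLocusId(gx)
  combined <- suppressWarnings(c(ref, gx))
  TEAnnotation(combined, genomeBuild = genomeBuild(ann))
}

.writeTsv <- function(dt, path, col.names = TRUE) {
  data.table::fwrite(dt, path, sep = "\t", col.names = col.names,
                     quote = FALSE, scipen = 50)
}
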