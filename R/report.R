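## Output writers: locus/subfamily TSV tables, transcript-span BED6, and a
## minimal strand-splittable coverage bedGraph (unique vs multi tracks).

.LOCUS_COLS <- c("chrom", "tx_start", "tx_end", "locus_id", "score",
                 "tx_strand", "orientation", "subfamily", "family", "clazz",
                 "milli_div", "C_U", "C_TE_float", "C_TE_int", "R_TE",
                 "L_TE", "l_TE", "fpkm", "passed_score")

#' Write the per-locus estimate table
#'
#' Tab-separated with a header, one row per (locus, orientation), sorted by
#' (chrom, tx_start); floating-point columns rounded to 6 decimals.
#'
#' @param x A [TECounts-class] or its estimate `data.frame`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
writeLocusTable <- function(x, path) {
  est <- as.data.table(if (is(x, "TECounts")) locusEstimates(x) else x)
  if (nrow(est)) {
    out <- est[, .(chrom, tx_start, tx_end, locus_id,
                   score = round(score, 6), tx_strand, orientation,
                   subfamily, family, clazz, milli_div, C_U,
                   C_TE_float = round(C_TE, 6), C_TE_int, R_TE,
                   L_TE = round(L_TE, 6), l_TE = round(l_TE, 6),
                   fpkm = round(fpkm, 6), passed_score)]
    setorder(out, chrom, tx_start, locus_id, orientation)
  } else {
    out <- setNames(
      data.table(character(), integer(), integer(), character(), numeric(),
                 character(), character(), character(), character(),
                 character(), numeric(), integer(), numeric(), integer(),
                 integer(), numeric(), numeric(), numeric(), logical()),
      .LOCUS_COLS)
  }
  .writeTsv(out, path, col.names = TRUE)
  invisible(path)
}

#' Read back a table written by [writeLocusTable()]
#' @param path File written by [writeLocusTable()].
#' @return A `data.table`.
#' @export
readLocusTable <- function(path) {
  data.table::fread(path, sep = "\t", header = TRUE, data.table = TRUE,
                    colClasses = list(character = c("chrom", "locus_id",
                                                    "tx_strand",
                                                    "orientation")))
}

#' Write the subfamily aggregate table
#' @param x A [TECounts-class] or a subfamily `data.frame`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
writeSubfamilyTable <- function(x, path) {
  subf <- as.data.table(if (is(x, "TECounts")) subfamilySummary(x) else x)
  if (nrow(subf)) {
    subf <- subf[, .(subfamily, family, clazz,
                     total_count = round(total_count, 6),
                     total_fpkm = round(total_fpkm, 6), n_loci_expressed)]
  }
  .writeTsv(subf, path, col.names = TRUE)
  invisible(path)
}

#' Write transcript spans as BED6
#'
#' One record per (locus, orientation): observed transcript span, locus id,
#' integer score (confidence score, 0-100 scaled to BED's 0-1000 range is
#' unnecessary; the raw 0-100 score is written) and transcript strand.
#'
#' @param x A [TECounts-class] or estimate `data.frame`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
writeTranscriptBed <- function(x, path) {
  est <- as.data.table(if (is(x, "TECounts")) locusEstimates(x) else x)
  if (!nrow(est)) {
    writeLines(character(), path)
    return(invisible(path))
  }
  out <- est[, .(chrom, tx_start, tx_end, locus_id,
                 score = as.integer(round(score)), tx_strand)]
  setorder(out, chrom, tx_start, locus_id)
  .writeTsv(out, path, col.names = FALSE)
  invisible(path)
}

.rleToBedgraph <- function(cov) {
  recs <- lapply(names(cov), function(ch) {
    r <- cov[[ch]]
    v <- S4Vectors::runValue(r)
    l <- S4Vectors::runLength(r)
    e <- cumsum(as.numeric(l))
    s <- e - as.numeric(l)
    keep <- v >= 1e-6
    data.table(chrom = ch, start = as.integer(s[keep]),
               end = as.integer(e[keep]), value = v[keep])
  })
  rbindlist(recs)
}

.chromOfLocus <- function(locus_id) {
  vapply(strsplit(locus_id, "|", fixed = TRUE), `[`, "", 1L)
}

.bedgraphFromSpans <- function(dt, path, label) {
  lines <- sprintf("track type=bedGraph name=\"%s\"", label)
  if (nrow(dt)) {
    gr <- GRanges(dt$chrom, IRanges(dt$span_start + 1L, dt$span_end))
    cov <- coverage(gr, weight = dt$w)
    recs <- .rleToBedgraph(cov)
    if (nrow(recs)) {
      setorder(recs, chrom, start)
      lines <- c(lines, sprintf("%s\t%d\t%d\t%s", recs$chrom, recs$start,
                                recs$end, format(recs$value, digits = 15,
                                                 trim = TRUE,
                                                 scientific = FALSE)))
    }
  }
  writeLines(lines, path)
  path
}

#' Write coverage bedGraphs of assigned fragments
#'
#' Two UCSC bedGraph tracks per (optional) strand: a "unique" track where
#' every whole-count fragment (unique or rescued) adds 1 over its aligned
#' span, and a "multi" track where each multi-mapped fragment adds its
#' assigned fraction — so stacked multi-read heights are inversely related
#' to the number of loci sharing the read. 0-based half-open records;
#' values below 1e-6 are omitted.
#'
#' @param candidates Candidate table from [candidateLoci()].
#' @param fractions Final fraction table (e.g. `runEM(...)$fractions`).
#' @param prefix Output path prefix; files are
#'   `<prefix>.unique.bedgraph` / `<prefix>.multi.bedgraph`, with an
#'   additional `.plus` / `.minus` infix when `strandSplit`.
#' @param strandSplit Split tracks by fragment strand.
#' @return Character vector of files written, invisibly.
#' @export
writeBedgraph <- function(candidates, fractions, prefix, strandSplit = FALSE) {
  cand <- .ensureN(candidates)
  fr <- as.data.table(fractions)
  uni <- cand[N == 1L, .(chrom = .chromOfLocus(locus_id), span_start,
                         span_end, w = 1, fstr)]
  mul <- merge(fr[f > 0], cand,
               by = c("frag_id", "locus_id", "orientation"))
  mul <- mul[, .(chrom = .chromOfLocus(locus_id), span_start, span_end,
                 w = f, fstr)]
  strata <- if (strandSplit) list(plus = "+", minus = "-") else list(all = NULL)
  files <- character()
  for (nm in names(strata)) {
    sel <- strata[[nm]]
    infix <- if (is.null(sel)) "" else paste0(".", nm)
    u <- if (is.null(sel)) uni else uni[fstr == sel]
    m <- if (is.null(sel)) mul else mul[fstr == sel]
    files <- c(files,
      .bedgraphFromSpans(u, paste0(prefix, infix, ".unique.bedgraph"),
                         paste0("unique", infix)),
      .bedgraphFromSpans(m, paste0(prefix, infix, ".multi.bedgraph"),
                         paste0("multi", infix)))
  }
  invisible(files)
}
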