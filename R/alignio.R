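## SAM/BAM fragment streaming, unique/multi classification with mate rescue,
## and candidate-locus determination (50%-overlap rule, strandedness).
## Internal coordinates: 0-based half-open reference spans.

#' Read all reported alignments, grouped per fragment
#'
#' Loads every mapped record of a SAM or BAM file (including secondary
#' alignments) into a table keyed by read name. NH and HI tags are captured
#' when present; uniqueness is later decided from the observed placements,
#' not the NH tag.
#'
#' @param path SAM or BAM file. SAM input is converted on the fly.
#' @return A `data.table` with one row per alignment record: `qname`, `mate`
#'   (1/2, or 0 for single-end), `chrom`, `start`/`end` (0-based half-open),
#'   `strand`, `hi`, `nh`, `pnext`, `paired`.
#' @export
readFragmentAlignments <- function(path) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile()
    bam <- Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                            indexDestination = FALSE)
  }
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "strand", "pos", "cigar", "mpos"),
    tag = c("NH", "HI"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE)
  )
  x <- Rsamtools::scanBam(bam, param = param)[[1]]
  n <- length(x$qname)
  if (!n) {
    return(data.table(qname = character(), mate = integer(),
                      chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      hi = integer(), nh = integer(), pnext = integer(),
                      paired = logical()))
  }
  flag <- x$flag
  refw <- GenomicAlignments::cigarWidthAlongReferenceSpace(x$cigar)
  dt <- data.table(
    qname = x$qname,
    mate = ifelse(bitwAnd(flag, 1L) == 0L, 0L,
                  ifelse(bitwAnd(flag, 64L) > 0L, 1L, 2L)),
    chrom = as.character(x$rname),
    start = x$pos - 1L,
    end = x$pos - 1L + refw,
    strand = as.character(x$strand),
    hi = if (is.null(x$tag$HI)) rep(NA_integer_, n) else as.integer(x$tag$HI),
    nh = if (is.null(x$tag$NH)) rep(NA_integer_, n) else as.integer(x$tag$NH),
    pnext = ifelse(is.na(x$mpos), NA_integer_, x$mpos - 1L),
    paired = bitwAnd(flag, 1L) > 0L
  )
  nhbad <- dt[!is.na(nh), .(obs = .N, nh = nh[1]), by = .(qname, mate)][obs != nh]
  if (nrow(nhbad))
    warning(nrow(nhbad), " mate(s) with NH tag contradicting observed ",
            "record count; trusting observed records")
  dt
}

#' Classify fragments as unique, rescued, multi or discordant
#'
#' Applies the mate-rescue rules: a pair with both mates uniquely placed is
#' unique; a multi-mapping mate paired with a unique mate makes the pair
#' unique and its other placements are discarded; a pair with both mates
#' multi-mapping but exactly one concordant placement contributes a full
#' count ("rescued") without counting as unique evidence; otherwise all
#' concordant placements are kept as a multi-mapping fragment. Pairs with no
#' concordant placement at all are classified discordant and excluded.
#' Single-end fragments are unique iff they have exactly one placement.
#'
#' @param records Alignment table from [readFragmentAlignments()].
#' @param concordantMax Maximum fragment span (bp) for two mates on the same
#'   chromosome, opposite strands, to count as concordant.
#' @return List with `placements` (kept placements; paired placements share a
#'   `placement_id` within a fragment) and `fragments` (`frag_id`,
#'   `uniqueness` in unique/rescued/multi/discordant).
#' @export
classifyFragments <- function(records, concordantMax = 1e6) {
  rec <- unique(as.data.table(records),
                by = c("qname", "mate", "chrom", "start", "end", "strand", "hi"))
  se <- rec[paired == FALSE]
  pe <- rec[paired == TRUE & mate %in% c(1L, 2L)]
  if (nrow(pe)) {
    cnt <- pe[, .(h1 = sum(mate == 1L), h2 = sum(mate == 2L)), by = qname]
    orphan <- cnt[h1 == 0L | h2 == 0L, qname]
    if (length(orphan)) {
      warning(length(orphan),
              " paired fragment(s) missing a mate; kept as single-end")
      se <- rbind(se, pe[qname %in% orphan])
      pe <- pe[!qname %in% orphan]
    }
  }

  pl <- list(); fr <- list()

  if (nrow(se)) {
    sd <- unique(se, by = c("qname", "chrom", "start", "end", "strand"))
    sd[, placement_id := seq_len(.N), by = qname]
    pl$se <- sd[, .(frag_id = qname, placement_id, mate = 0L, chrom, start,
                    end, strand)]
    fr$se <- sd[, .(uniqueness = fifelse(.N == 1L, "unique", "multi")),
                by = .(frag_id = qname)]
  }

  if (nrow(pe)) {
    m1 <- pe[mate == 1L]
    m2 <- pe[mate == 2L]
    hiOk <- pe[, .(ok = all(!is.na(hi))), by = qname][ok == TRUE, qname]
    mkPairs <- function(a, b, byCols) {
      merge(a[, .(qname, hi, chrom1 = chrom, s1 = start, e1 = end,
                  str1 = strand, pn1 = pnext)],
            b[, .(qname, hi, chrom2 = chrom, s2 = start, e2 = end,
                  str2 = strand, pn2 = pnext)],
            by = byCols, allow.cartesian = TRUE)
    }
    P <- mkPairs(m1[qname %in% hiOk], m2[qname %in% hiOk], c("qname", "hi"))
    rest1 <- m1[!qname %in% hiOk]; rest2 <- m2[!qname %in% hiOk]
    if (nrow(rest1)) {
      Px <- merge(rest1[, .(qname, chrom1 = chrom, s1 = start, e1 = end,
                            str1 = strand, pn1 = pnext)],
                  rest2[, .(qname, chrom2 = chrom, s2 = start, e2 = end,
                            str2 = strand, pn2 = pnext)],
                  by = "qname", allow.cartesian = TRUE)
      # prefer position-cross-matched pairs (RNEXT/PNEXT semantics)
      Px[, ok := !is.na(pn1) & !is.na(pn2) & s2 == pn1 & s1 == pn2]
      Px[, ok := ok | !any(ok), by = qname]
      Px <- Px[ok == TRUE][, ok := NULL]
      Px[, hi := NA_integer_]
      P <- rbind(P, Px, use.names = TRUE)
    }
    P <- unique(P, by = c("qname", "chrom1", "s1", "str1",
                          "chrom2", "s2", "str2"))
    nplace <- rbind(
      unique(m1, by = c("qname", "chrom", "start", "strand"))[, .(n1 = .N),
                                                              by = qname],
      unique(m2, by = c("qname", "chrom", "start", "strand"))[, .(n2 = .N),
                                                              by = qname],
      fill = TRUE
    )[, .(n1 = sum(n1, na.rm = TRUE), n2 = sum(n2, na.rm = TRUE)), by = qname]
    P <- merge(P, nplace, by = "qname")
    P[, span := pmax(e1, e2) - pmin(s1, s2)]
    P[, concordant := chrom1 == chrom2 & str1 != str2 & span <= concordantMax]
    P[, nc := sum(concordant), by = qname]
    P[, cls := fifelse(n1 == 1L & n2 == 1L, "unique",
               fifelse(xor(n1 == 1L, n2 == 1L), "unique_one",
               fifelse(nc == 1L, "rescued",
               fifelse(nc >= 2L, "multi", "discordant"))))]
    keep <- rbind(
      P[cls == "unique"],
      P[cls == "unique_one"][order(qname, !concordant, span),
                             .SD[1], by = qname],
      P[cls %in% c("rescued", "multi") & concordant == TRUE]
    )
    if (nrow(keep)) {
      keep[, placement_id := seq_len(.N), by = qname]
      long <- rbind(
        keep[, .(frag_id = qname, placement_id, mate = 1L, chrom = chrom1,
                 start = s1, end = e1, strand = str1)],
        keep[, .(frag_id = qname, placement_id, mate = 2L, chrom = chrom2,
                 start = s2, end = e2, strand = str2)]
      )
      pl$pe <- long
    }
    fr$pe <- unique(P[, .(frag_id = qname,
                          uniqueness = fifelse(cls %in% c("unique", "unique_one"),
                                               "unique", cls))],
                    by = "frag_id")
  }

  placements <- if (length(pl)) rbindlist(pl) else
    data.table(frag_id = character(), placement_id = integer(),
               mate = integer(), chrom = character(), start = integer(),
               end = integer(), strand = character())
  fragments <- if (length(fr)) rbindlist(fr) else
    data.table(frag_id = character(), uniqueness = character())
  setorder(placements, frag_id, placement_id, mate)
  list(placements = placements, fragments = fragments)
}

.flipStrand <- function(s) chartr("+-", "-+", s)

#' Candidate TE loci per fragment
#'
#' A kept placement nominates a locus when at least one of its mates
#' overlaps the locus by at least half of that mate's aligned length
#' (rounded up), i.e. up to 50% of the read may hang over into flanking
#' sequence. In stranded modes the sense and antisense directions of a TE
#' are treated as separate transcripts: the candidate key is
#' (locus, orientation) with the fragment strand inferred from mate 1
#' (`fr`: mate-1 strand; `rf`: its opposite). Unstranded data always uses
#' orientation `"sense"`.
#'
#' @param classified Output of [classifyFragments()].
#' @param ann A [TEAnnotation-class].
#' @param strandMode `"none"`, `"rf"` or `"fr"`.
#' @return A `data.table` with one row per (fragment, locus, orientation)
#'   candidacy: aligned span (`span_start`, `span_end`), mean aligned
#'   fragment length `frag_len`, fragment `uniqueness` and the fragment's
#'   candidate count `N`. Fragments with zero candidates are absent.
#' @export
candidateLoci <- function(classified, ann, strandMode = c("none", "rf", "fr")) {
  strandMode <- match.arg(strandMode)
  pl <- classified$placements
  loci <- teLoci(ann)
  empty <- data.table(frag_id = character(), locus_id = character(),
                      orientation = character(), span_start = integer(),
                      span_end = integer(), frag_len = numeric(),
                      uniqueness = character(), N = integer())
  if (!nrow(pl) || !length(loci)) return(empty)

  grm <- GRanges(pl$chrom, IRanges(pl$start + 1L, pl$end))
  hits <- findOverlaps(grm, loci)
  if (!length(hits)) return(empty)
  q <- queryHits(hits); s <- subjectHits(hits)
  ovw <- pmin(pl$end[q], end(loci)[s]) - pmax(pl$start[q], start(loci)[s] - 1L)
  matelen <- pl$end[q] - pl$start[q]
  pass <- ovw >= ceiling(0.5 * matelen)
  q <- q[pass]; s <- s[pass]
  if (!length(q)) return(empty)

  cand <- data.table(frag_id = pl$frag_id[q], placement_id = pl$placement_id[q],
                     locus_id = loci$locus_id[s],
                     locus_strand = as.character(strand(loci))[s])
  cand <- unique(cand)

  pinfo <- pl[, .(
    fstr = if (any(mate != 2L)) strand[mate != 2L][1] else
      .flipStrand(strand[1]),
    p_start = min(start), p_end = max(end)
  ), by = .(frag_id, placement_id)]
  cand <- merge(cand, pinfo, by = c("frag_id", "placement_id"))

  cand[, orientation := switch(strandMode,
    none = "sense",
    fr = fifelse(fstr == locus_strand, "sense", "antisense"),
    rf = fifelse(.flipStrand(fstr) == locus_strand, "sense", "antisense")
  )]

  out <- cand[, .(span_start = min(p_start), span_end = max(p_end),
                  frag_len = mean(p_end - p_start), fstr = fstr[1]),
              by = .(frag_id, locus_id, orientation)]
  out <- merge(out, classified$fragments, by = "frag_id")
  out[, N := .N, by = frag_id]
  setorder(out, frag_id, locus_id, orientation)
  out[]
}
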