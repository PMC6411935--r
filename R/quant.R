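## Core quantifier: unique statistics, unique-informed initial assignment of
## multi-mapped fragments, transcribed/effective lengths, EM refinement with
## zeroing and auto-convergence, confidence score, FPKM, subfamily rollup.
##
## Keys are (locus_id, orientation) throughout; in unstranded mode the
## orientation is always "sense".

.keyCols <- c("locus_id", "orientation")

.ensureN <- function(cand) {
  cand <- as.data.table(cand)
  if (!"N" %in% names(cand)) cand[, N := .N, by = frag_id]
  cand
}

#' Unique-read statistics per (locus, orientation)
#'
#' `C_U` counts fragments that are both uniquely placed and candidates of a
#' single locus; `L_U` counts their distinct leftmost start positions (the
#' uniquely alignable length); `C_fixed` additionally includes fragments
#' that contribute a whole count without unique evidence: rescued pairs
#' (both mates multi-mapping, concordant at exactly one location) and
#' fragments whose placements all collapse onto one candidate key. Rescued
#' fragments are deliberately excluded from `C_U` and `L_U`.
#'
#' @param candidates Candidate table from [candidateLoci()] (needs
#'   `uniqueness` and per-fragment candidate count `N`; `N` is computed if
#'   absent).
#' @return `data.table` keyed by (locus_id, orientation) with `C_U`, `L_U`,
#'   `C_fixed` and the unique span (`us_min`, `us_max`).
#' @export
uniqueStats <- function(candidates) {
  cand <- .ensureN(candidates)
  keys <- unique(cand[, .keyCols, with = FALSE])
  fixed <- cand[N == 1L]
  cu <- fixed[uniqueness == "unique",
              .(C_U = .N, L_U = data.table::uniqueN(span_start),
                us_min = min(span_start), us_max = max(span_end)),
              by = .keyCols]
  cf <- fixed[, .(C_fixed = .N), by = .keyCols]
  out <- merge(keys, cu, by = .keyCols, all.x = TRUE)
  out <- merge(out, cf, by = .keyCols, all.x = TRUE)
  out[is.na(C_U), `:=`(C_U = 0L, L_U = 0L)]
  out[is.na(C_fixed), C_fixed := 0L]
  setkeyv(out, .keyCols)
  out[]
}

#' Initial assignment of multi-candidate fragments
#'
#' For each fragment with N > 1 candidate keys, the n candidates without
#' unique evidence each receive 1/N of the fragment; the remainder
#' (1 - n/N) is split among candidates with unique reads in proportion to
#' their unique count normalized by uniquely alignable length,
#' (C_U/L_U) / sum(C_s/L_s). Per-fragment fractions sum to one.
#'
#' @param candidates Candidate table (see [candidateLoci()]); only rows of
#'   fragments with `N >= 2` are assigned.
#' @param ustats Output of [uniqueStats()].
#' @return `data.table` with `frag_id`, key columns and the fraction `f`.
#' @export
initialAssignment <- function(candidates, ustats) {
  cand <- .ensureN(candidates)
  multi <- cand[N >= 2L, c("frag_id", .keyCols), with = FALSE]
  if (!nrow(multi))
    return(data.table(frag_id = character(), locus_id = character(),
                      orientation = character(), f = numeric()))
  us <- as.data.table(ustats)[, c(.keyCols, "C_U", "L_U"), with = FALSE]
  multi <- merge(multi, us, by = .keyCols, all.x = TRUE)
  multi[is.na(C_U), `:=`(C_U = 0L, L_U = 0L)]
  multi[, `:=`(N = .N, n0 = sum(C_U == 0L)), by = frag_id]
  multi[, w := fifelse(C_U > 0L, C_U / L_U, 0)]
  multi[, wsum := sum(w), by = frag_id]
  multi[, f := fifelse(C_U == 0L, 1 / N, (1 - n0 / N) * w / wsum)]
  out <- multi[, c("frag_id", .keyCols, "f"), with = FALSE]
  setorderv(out, c("frag_id", .keyCols))
  out[]
}

#' Effective transcript length
#'
#' The transcribed length minus the average aligned fragment length plus
#' one (the number of distinct start positions a transcript admits),
#' clamped below at 1.
#'
#' @param L_TE Transcribed length(s), bp.
#' @param l_avg Mean aligned fragment length(s), bp.
#' @return Numeric effective length(s), `>= 1`.
#' @examples
#' effectiveLength(6000, 250)  # 5751
#' @export
effectiveLength <- function(L_TE, l_avg) pmax(L_TE - l_avg + 1, 1)

#' Transcript spans from assigned fragments
#'
#' The transcript of a locus is delimited by the outermost aligned bases of
#' the fragments attributed to it: single-candidate fragments plus
#' multi-candidate fragments holding a nonzero fraction. The transcribed
#' length may exceed the annotation (read-through) or fall short of it
#' (partial transcription).
#'
#' @param candidates Candidate table.
#' @param fractions Fraction table (e.g. from [initialAssignment()]).
#' @return `data.table` per key: `tx_start`, `tx_end`, `L_TE`, `l_avg`
#'   (mean aligned fragment length over all candidate fragments at the
#'   locus) and `l_TE`.
#' @export
transcriptSpans <- function(candidates, fractions) {
  cand <- .ensureN(candidates)
  fr <- as.data.table(fractions)
  contrib <- rbind(
    cand[N == 1L, c("frag_id", .keyCols), with = FALSE],
    fr[f > 0, c("frag_id", .keyCols), with = FALSE]
  )
  contrib <- merge(contrib,
                   cand[, c("frag_id", .keyCols, "span_start", "span_end"),
                        with = FALSE],
                   by = c("frag_id", .keyCols))
  span <- contrib[, .(tx_start = min(span_start), tx_end = max(span_end)),
                  by = .keyCols]
  lavg <- cand[, .(l_avg = mean(frag_len)), by = .keyCols]
  out <- merge(span, lavg, by = .keyCols, all = TRUE)
  out[, L_TE := tx_end - tx_start]
  out[, l_TE := effectiveLength(L_TE, l_avg)]
  setkeyv(out, .keyCols)
  out[]
}

.totalCounts <- function(ustats, fractions) {
  us <- as.data.table(ustats)[, c(.keyCols, "C_fixed"), with = FALSE]
  fsum <- as.data.table(fractions)[, .(fmass = sum(f)), by = .keyCols]
  out <- merge(us, fsum, by = .keyCols, all = TRUE)
  out[is.na(C_fixed), C_fixed := 0L]
  out[is.na(fmass), fmass := 0]
  out[, C_TE := C_fixed + fmass]
  setkeyv(out, .keyCols)
  out[, c(.keyCols, "C_TE"), with = FALSE]
}

#' One expectation step of the EM refinement
#'
#' Reassigns each multi-candidate fragment in proportion to the relative
#' length-normalized total count C/l of its candidate loci. Loci whose
#' running total count has fallen below one fragment are judged unlikely to
#' have produced any read: they are zeroed and dropped from the fragment's
#' denominator. If every candidate of a fragment is zeroed, the fragment
#' falls back to an equal 1/N split.
#'
#' @param fractions Current fraction table.
#' @param counts `data.table` per key with `C_TE` (current totals).
#' @param lengths `data.table` per key with `l_TE` (frozen effective
#'   lengths).
#' @param zero Apply the below-one-count zeroing rule.
#' @return Updated fraction table.
#' @export
emStep <- function(fractions, counts, lengths, zero = TRUE) {
  fr <- as.data.table(fractions)[, c("frag_id", .keyCols), with = FALSE]
  fr <- merge(fr, as.data.table(counts)[, c(.keyCols, "C_TE"), with = FALSE],
              by = .keyCols, all.x = TRUE)
  fr <- merge(fr, as.data.table(lengths)[, c(.keyCols, "l_TE"), with = FALSE],
              by = .keyCols, all.x = TRUE)
  fr[is.na(C_TE), C_TE := 0]
  fr[, elig := if (zero) C_TE >= 1 else rep(TRUE, .N)]
  fr[, w := fifelse(elig, C_TE / l_TE, 0)]
  fr[, `:=`(wsum = sum(w), N = .N), by = frag_id]
  fr[, f := fifelse(wsum > 0, w / wsum, 1 / N)]
  out <- fr[, c("frag_id", .keyCols, "f"), with = FALSE]
  setorderv(out, c("frag_id", .keyCols))
  out[]
}

#' Run the EM refinement loop
#'
#' Alternates maximization (per-locus totals C = fixed counts + assigned
#' fractions) and expectation ([emStep()]) until a fixed iteration count,
#' or in `"auto"` mode until every locus with at least 10 counts changes by
#' less than 1% relative (|dC| / max(C_prev, 1) < 0.01), with a hard cap of
#' `maxIter` iterations. `iterations = 0` returns the initial-assignment
#' totals unchanged.
#'
#' @param ustats Output of [uniqueStats()].
#' @param fractions Initial fraction table from [initialAssignment()].
#' @param lengths Per-key effective lengths (`l_TE`), e.g. from
#'   [transcriptSpans()].
#' @param iterations `"auto"` or a non-negative integer.
#' @param maxIter Iteration cap for `"auto"`.
#' @param zeroing `"per-step"` applies the below-one-count rule at every
#'   expectation step; `"final"` only once after the loop ends.
#' @return List: `counts` (per-key `C_TE`), `fractions` (final), `nIter`,
#'   `converged` (FALSE only when `"auto"` hit the cap).
#' @export
runEM <- function(ustats, fractions, lengths, iterations = "auto",
                  maxIter = 100L, zeroing = c("per-step", "final")) {
  zeroing <- match.arg(zeroing)
  auto <- identical(iterations, "auto")
  if (!auto) {
    iterations <- as.integer(iterations)
    stopifnot(iterations >= 0L)
  }
  fr <- as.data.table(fractions)
  C <- .totalCounts(ustats, fr)
  it <- 0L
  converged <- TRUE
  perStep <- zeroing == "per-step"
  while ((auto && it < maxIter) || (!auto && it < iterations)) {
    Cprev <- C
    fr <- emStep(fr, C, lengths, zero = perStep)
    C <- .totalCounts(ustats, fr)
    it <- it + 1L
    if (auto) {
      cmp <- merge(Cprev, C, by = .keyCols, suffixes = c("_prev", ""))
      watch <- cmp[C_TE_prev >= 10]
      done <- !nrow(watch) ||
        all(abs(watch$C_TE - watch$C_TE_prev) /
              pmax(watch$C_TE_prev, 1) < 0.01)
      if (done) break
    }
  }
  if (auto && it >= maxIter) {
    converged <- FALSE
    warning("EM did not converge within ", maxIter, " iterations")
  }
  if (zeroing == "final" && it > 0L) {
    fr <- emStep(fr, C, lengths, zero = TRUE)
    C <- .totalCounts(ustats, fr)
  }
  list(counts = C, fractions = fr, nIter = it, converged = converged)
}

#' Confidence score
#'
#' `100 * C_TE / R_TE`, where `R_TE` is the number of fragments with any
#' candidate placement at the locus. 100 means every touching fragment was
#' attributed to the locus; low values flag loci whose reads are largely
#' explained by other loci.
#'
#' @param C_TE Assigned count(s).
#' @param R_TE Touching-fragment count(s), `>= 1`.
#' @return Numeric score(s) in \[0, 100\].
#' @export
computeScore <- function(C_TE, R_TE) {
  stopifnot(all(R_TE >= 1))
  100 * C_TE / R_TE
}

#' Fragments per kilobase of transcript per million fragments
#'
#' Uses the empirically transcribed length rather than the annotated locus
#' length, so partially transcribed or read-through loci are normalized by
#' what was actually expressed.
#'
#' @param C_TE Assigned count(s).
#' @param length_bp Transcript length(s), bp (`>= 1`).
#' @param libraryFragments Fragments with at least one reported alignment.
#' @return Numeric FPKM value(s).
#' @export
computeFpkm <- function(C_TE, length_bp, libraryFragments) {
  stopifnot(all(length_bp >= 1), libraryFragments >= 1)
  C_TE / ((length_bp / 1000) * (libraryFragments / 1e6))
}

#' Aggregate locus estimates to subfamilies
#'
#' Sums counts and FPKM per subfamily over member loci, collapsing the two
#' orientations, and counts member loci whose (orientation-summed) count
#' reaches `countMin`.
#'
#' @param estimates Per-locus estimate `data.frame` (from
#'   [locusEstimates()]).
#' @param ann Optional [TEAnnotation-class] used to verify that every
#'   `locus_id` resolves.
#' @param countMin Expression threshold for `n_loci_expressed`.
#' @return `data.table`: subfamily, family, clazz, total_count, total_fpkm,
#'   n_loci_expressed.
#' @export
aggregateSubfamilies <- function(estimates, ann = NULL, countMin = 10) {
  est <- as.data.table(estimates)
  if (!nrow(est))
    return(data.table(subfamily = character(), family = character(),
                      clazz = character(), total_count = numeric(),
                      total_fpkm = numeric(), n_loci_expressed = integer()))
  if (!is.null(ann)) {
    unknown <- setdiff(est$locus_id, teLoci(ann)$locus_id)
    if (length(unknown))
      stop("locus_id not present in annotation: ", unknown[1])
  }
  perLocus <- est[, .(C = sum(C_TE)), by = .(subfamily, family, clazz,
                                             locus_id)]
  out <- est[, .(total_count = sum(C_TE), total_fpkm = sum(fpkm)),
             by = .(subfamily, family, clazz)]
  nx <- perLocus[, .(n_loci_expressed = sum(C >= countMin)),
                 by = .(subfamily, family, clazz)]
  out <- merge(out, nx, by = c("subfamily", "family", "clazz"))
  setorder(out, -total_count)
  out[]
}

#' Flag or drop loci below a score threshold
#'
#' @param estimates Per-locus estimate table.
#' @param threshold Score threshold in \[0, 100\] (a threshold of at least
#'   50 is a good default for separating reliably attributed loci).
#' @param drop Remove failing rows instead of flagging them.
#' @return The table with a logical `passed_score` column (or filtered).
#' @export
applyScoreThreshold <- function(estimates, threshold = 50, drop = FALSE) {
  stopifnot(threshold >= 0, threshold <= 100)
  est <- as.data.table(estimates)
  if (nrow(est)) est[, passed_score := score >= threshold]
  else est[, passed_score := logical()]
  if (drop) est <- est[passed_score == TRUE]
  est[]
}

#' Quantify TE expression at locus resolution
#'
#' End-to-end quantification: stream and classify fragments, determine
#' candidate loci (50%-overlap rule, strand-aware), compute unique
#' statistics, assign multi-mapped fractions by unique-informed initial
#' assignment, refine with the EM loop using transcribed effective lengths,
#' and report per-locus counts, transcript spans, confidence scores, FPKM
#' and subfamily aggregates.
#'
#' @param alignments SAM/BAM path, a record table from
#'   [readFragmentAlignments()], or a classified list from
#'   [classifyFragments()].
#' @param ann A [TEAnnotation-class].
#' @param strandMode `"none"`, `"rf"` or `"fr"`.
#' @param emIterations `"auto"` (iterate to convergence) or an integer
#'   (0 = initial assignment only).
#' @param maxIter Cap for `"auto"`.
#' @param zeroing See [runEM()].
#' @param scoreThreshold Score below which loci are flagged.
#' @param dropBelowScore Drop flagged loci from the output tables.
#' @param concordantMax See [classifyFragments()].
#' @return A [TECounts-class].
#' @export
quantifyTE <- function(alignments, ann, strandMode = c("none", "rf", "fr"),
                       emIterations = "auto", maxIter = 100L,
                       zeroing = c("per-step", "final"), scoreThreshold = 50,
                       dropBelowScore = FALSE, concordantMax = 1e6) {
  strandMode <- match.arg(strandMode)
  zeroing <- match.arg(zeroing)
  if (is.character(alignments) && length(alignments) == 1L)
    alignments <- readFragmentAlignments(alignments)
  if (is.data.frame(alignments)) {
    libSize <- data.table::uniqueN(as.data.table(alignments)$qname)
    classified <- classifyFragments(alignments, concordantMax = concordantMax)
  } else {
    classified <- alignments
    libSize <- max(1L, data.table::uniqueN(classified$fragments$frag_id))
  }
  cand <- candidateLoci(classified, ann, strandMode = strandMode)
  if (!nrow(cand)) {
    return(new("TECounts", estimates = .emptyEstimates(),
               subfamilies = as.data.frame(aggregateSubfamilies(
                 .emptyEstimates())),
               libSize = as.numeric(libSize),
               params = list(strandMode = strandMode,
                             emIterations = emIterations),
               nIter = 0L, converged = TRUE))
  }
  us <- uniqueStats(cand)
  fr0 <- initialAssignment(cand, us)
  spans <- transcriptSpans(cand, fr0)
  em <- runEM(us, fr0, spans, iterations = emIterations, maxIter = maxIter,
              zeroing = zeroing)

  est <- merge(em$counts, us, by = .keyCols)
  est <- merge(est, spans, by = .keyCols)
  rte <- cand[, .(R_TE = data.table::uniqueN(frag_id)), by = .keyCols]
  est <- merge(est, rte, by = .keyCols)

  loci <- teLoci(ann)
  li <- data.table(locus_id = loci$locus_id,
                   chrom = as.character(seqnames(loci)),
                   locus_strand = as.character(strand(loci)),
                   subfamily = loci$subfamily, family = loci$family,
                   clazz = loci$clazz, milli_div = loci$milli_div)
  est <- merge(est, li, by = "locus_id")
  est[, tx_strand := fifelse(orientation == "antisense",
                             .flipStrand(locus_strand), locus_strand)]
  est[, score := computeScore(C_TE, R_TE)]
  est[, fpkm := computeFpkm(C_TE, pmax(L_TE, 1), libSize)]
  est[, C_TE_int := as.integer(floor(C_TE + 0.5))]
  est <- est[, .(chrom, tx_start, tx_end, locus_id, score, tx_strand,
                 orientation, subfamily, family, clazz, milli_div, C_U,
                 C_TE, C_TE_int, R_TE, L_TE, l_TE, fpkm)]
  est <- applyScoreThreshold(est, threshold = scoreThreshold,
                             drop = dropBelowScore)
  setorder(est, chrom, tx_start, locus_id, orientation)
  subf <- aggregateSubfamilies(est, ann)
  new("TECounts",
      estimates = as.data.frame(est),
      subfamilies = as.data.frame(subf),
      libSize = as.numeric(libSize),
      params = list(strandMode = strandMode, emIterations = emIterations,
                    maxIter = maxIter, zeroing = zeroing,
                    scoreThreshold = scoreThreshold,
                    concordantMax = concordantMax),
      nIter = em$nIter, converged = em$converged)
}

.emptyEstimates <- function() {
  data.frame(chrom = character(), tx_start = integer(), tx_end = integer(),
             locus_id = character(), score = numeric(),
             tx_strand = character(), orientation = character(),
             subfamily = character(), family = character(),
             clazz = character(), milli_div = numeric(), C_U = integer(),
             C_TE = numeric(), C_TE_int = integer(), R_TE = integer(),
             L_TE = numeric(), l_TE = numeric(), fpkm = numeric(),
             passed_score = logical(), stringsAsFactors = FALSE)
}
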