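# candidate-table row shorthand for abstract quantifier tests
crow <- function(frag, locus, uniq = "unique", s = 0L, e = 250L,
                 len = 250, ori = "sense") {
  data.table::data.table(frag_id = frag, locus_id = locus,
                         orientation = ori, span_start = as.integer(s),
                         span_end = as.integer(e), frag_len = len,
                         uniqueness = uniq)
}

# the worked three-locus instance: A has 4 unique fragments at 2 start
# positions, B one unique fragment, C none; 4 multi fragments hit all three
fig2cand <- function() {
  data.table::rbindlist(c(
    list(crow("uA1", "A", s = 100L, e = 350L),
         crow("uA2", "A", s = 100L, e = 350L),
         crow("uA3", "A", s = 400L, e = 650L),
         crow("uA4", "A", s = 400L, e = 650L),
         crow("uB1", "B", s = 5000L, e = 5250L)),
    lapply(sprintf("m%d", 1:4), function(f) {
      data.table::rbindlist(list(
        crow(f, "A", uniq = "multi", s = 800L, e = 1050L),
        crow(f, "B", uniq = "multi", s = 5400L, e = 5650L),
        crow(f, "C", uniq = "multi", s = 9000L, e = 9250L)))
    })))
}

test_that("unique statistics count fragments and distinct start positions", {
  us <- uniqueStats(fig2cand())
  a <- us[locus_id == "A"]
  expect_equal(a$C_U, 4L)
  expect_equal(a$L_U, 2L)   # duplicate starts collapse
  expect_equal(a$C_fixed, 4L)
  expect_equal(us[locus_id == "B", .(C_U, L_U)], data.table::data.table(
    C_U = 1L, L_U = 1L))
  expect_equal(us[locus_id == "C", .(C_U, L_U, C_fixed)],
               data.table::data.table(C_U = 0L, L_U = 0L, C_fixed = 0L))
})

test_that("rescued whole-count fragments are excluded from C_U and L_U", {
  cand <- data.table::rbindlist(list(
    crow("u1", "A", s = 0L),
    crow("r1", "A", uniq = "rescued", s = 300L),
    crow("r2", "A", uniq = "rescued", s = 600L)))
  us <- uniqueStats(cand)
  expect_equal(us$C_U, 1L)
  expect_equal(us$L_U, 1L)
  expect_equal(us$C_fixed, 3L)  # all three add whole counts
})

test_that("initial assignment reproduces the worked-example fractions", {
  cand <- fig2cand()
  us <- uniqueStats(cand)
  # normalized unique counts: A = 4/2 = 2, B = 1/1 = 1
  expect_equal(us[locus_id == "A", C_U / L_U], 2)
  expect_equal(us[locus_id == "B", C_U / L_U], 1)
  fr <- initialAssignment(cand, us)
  expect_equal(nrow(fr), 12L)
  expect_equal(unique(fr[locus_id == "C", f]), 1 / 3, tolerance = 1e-12)
  expect_equal(unique(fr[locus_id == "A", f]), 4 / 9, tolerance = 1e-12)
  expect_equal(unique(fr[locus_id == "B", f]), 2 / 9, tolerance = 1e-12)
  expect_equal(fr[, sum(f), by = frag_id]$V1, rep(1, 4))
})

test_that("initial assignment handles the degenerate candidate patterns", {
  # all candidates without unique evidence: equal 1/N split
  us0 <- data.table::data.table(locus_id = c("X", "Y"),
                                orientation = "sense", C_U = 0L, L_U = 0L,
                                C_fixed = 0L)
  cand0 <- data.table::rbindlist(list(
    crow("f", "X", uniq = "multi"), crow("f", "Y", uniq = "multi")))
  expect_equal(initialAssignment(cand0, us0)$f, c(0.5, 0.5))
  # single-candidate fragments are not fractional at all
  expect_equal(nrow(initialAssignment(crow("g", "X"), us0)), 0L)
})

test_that("effective length follows L_TE - l_avg + 1 with a floor of 1", {
  expect_equal(effectiveLength(6000, 250), 5751)
  expect_equal(effectiveLength(250, 250), 1)
  expect_equal(effectiveLength(200, 250), 1)  # clamped
})

test_that("transcript spans come from assigned fragments, not annotation", {
  cand <- fig2cand()
  us <- uniqueStats(cand)
  fr <- initialAssignment(cand, us)
  spans <- transcriptSpans(cand, fr)
  a <- spans[locus_id == "A"]
  expect_equal(a$tx_start, 100L)
  expect_equal(a$tx_end, 1050L)   # extends to the multi-read placements
  expect_equal(a$L_TE, 950)
  expect_equal(a$l_avg, 250)
  expect_equal(a$l_TE, 701)
  c_ <- spans[locus_id == "C"]
  expect_equal(c_$L_TE, 250)      # only the multi placements
})

test_that("the expectation step zeroes unsupported loci and renormalizes", {
  fr <- data.table::data.table(frag_id = "f", locus_id = c("A", "B", "C"),
                               orientation = "sense", f = 1 / 3)
  lens <- data.table::data.table(locus_id = c("A", "B", "C"),
                                 orientation = "sense", l_TE = 100)
  cnt <- function(a, b, c) data.table::data.table(
    locus_id = c("A", "B", "C"), orientation = "sense", C_TE = c(a, b, c))
  # one survivor: everything goes to it
  out <- emStep(fr, cnt(10, 0.4, 0.4), lens)
  expect_equal(out[order(locus_id), f], c(1, 0, 0))
  # symmetric C/l: equal split among the eligible
  out <- emStep(fr, cnt(5, 5, 0.2), lens)
  expect_equal(out[order(locus_id), f], c(0.5, 0.5, 0))
  # all below one: fall back to the equal split
  out <- emStep(fr, cnt(0.3, 0.3, 0.3), lens)
  expect_equal(out$f, rep(1 / 3, 3))
  # without zeroing the weights are pure C/l ratios
  out <- emStep(fr, cnt(6, 3, 1), lens, zero = FALSE)
  expect_equal(out[order(locus_id), f], c(0.6, 0.3, 0.1))
})

test_that("zero EM iterations return the initial-assignment totals", {
  cand <- fig2cand()
  us <- uniqueStats(cand)
  fr <- initialAssignment(cand, us)
  em <- runEM(us, fr, transcriptSpans(cand, fr), iterations = 0)
  C <- stats::setNames(em$counts$C_TE, em$counts$locus_id)
  expect_equal(unname(C["A"]), 4 + 4 * 4 / 9, tolerance = 1e-12)  # 5.778
  expect_equal(unname(C["B"]), 1 + 4 * 2 / 9, tolerance = 1e-12)  # 1.889
  expect_equal(unname(C["C"]), 4 / 3, tolerance = 1e-12)          # 1.333
  expect_equal(em$nIter, 0L)
})

test_that("a single-locus dataset is a fixed point reached at iteration 1", {
  cand <- data.table::rbindlist(list(
    crow("u1", "A", s = 0L), crow("u2", "A", s = 300L)))
  # two multi fragments whose candidates collapsed to one key count whole
  us <- uniqueStats(cand)
  fr <- initialAssignment(cand, us)
  em <- runEM(us, fr, transcriptSpans(cand, fr), iterations = "auto")
  expect_equal(em$counts$C_TE, 2)
  expect_equal(em$nIter, 1L)
  expect_true(em$converged)
})

test_that("auto EM stops once well-supported loci settle below 1% change", {
  set.seed(42)
  inst <- randomInstance(42)
  tabs <- instToTables(inst)
  fr0 <- initialAssignment(tabs$cand, tabs$ustats)
  em <- runEM(tabs$ustats, fr0, tabs$lengths, iterations = "auto")
  expect_true(em$converged)
  expect_lte(em$nIter, 100L)
  # running one more fixed iteration changes >=10-count loci by < 1%
  emPlus <- runEM(tabs$ustats, fr0, tabs$lengths,
                  iterations = em$nIter + 1L)
  big <- em$counts[C_TE >= 10]
  cmp <- merge(big, emPlus$counts, by = c("locus_id", "orientation"),
               suffixes = c("", "_next"))
  expect_true(all(abs(cmp$C_TE_next - cmp$C_TE) / pmax(cmp$C_TE, 1) < 0.01))
})

test_that("score and FPKM follow their definitions", {
  expect_equal(computeScore(10, 10), 100)  # all fragments retained
  expect_equal(computeScore(5, 10), 50)
  expect_error(computeScore(1, 0))
  expect_equal(computeFpkm(10, 1000, 1e6), 10)
  expect_equal(computeFpkm(0, 1000, 1e6), 0)
  expect_equal(computeFpkm(10, 1000, 2e6), computeFpkm(10, 1000, 1e6) / 2)
})

test_that("subfamily aggregation conserves locus totals", {
  est <- data.table::data.table(
    locus_id = c("l1", "l2", "l3", "l3"),
    orientation = c("sense", "sense", "sense", "antisense"),
    subfamily = c("S1", "S1", "S2", "S2"),
    family = "F", clazz = "K",
    C_TE = c(3, 7, 12, 4), fpkm = c(1, 2, 3, 0.5))
  subf <- aggregateSubfamilies(est)
  expect_equal(subf[subfamily == "S1", total_count], 10)
  expect_equal(subf[subfamily == "S2", total_count], 16)
  expect_equal(sum(subf$total_count), sum(est$C_TE))
  expect_equal(sum(subf$total_fpkm), sum(est$fpkm))
  # l3 is expressed (12 + 4 >= 10, orientations collapsed); l1/l2 are not
  expect_equal(subf[subfamily == "S2", n_loci_expressed], 1L)
  expect_equal(subf[subfamily == "S1", n_loci_expressed], 0L)
  expect_equal(nrow(aggregateSubfamilies(est[0])), 0L)
})

test_that("aggregation refuses locus ids missing from the annotation", {
  ann <- toyAnnotation(0L, 1000L)
  est <- data.table::data.table(locus_id = "nope", orientation = "sense",
                                subfamily = "S", family = "F", clazz = "K",
                                C_TE = 1, fpkm = 1)
  expect_error(aggregateSubfamilies(est, ann), "nope")
})

test_that("score thresholding flags or drops, and the extremes behave", {
  est <- data.table::data.table(score = c(100, 60, 33), C_TE = 1, fpkm = 1,
                                locus_id = c("a", "b", "c"))
  expect_true(all(applyScoreThreshold(est, 0)$passed_score))
  expect_equal(applyScoreThreshold(est, 100)$passed_score,
               c(TRUE, FALSE, FALSE))
  expect_equal(applyScoreThreshold(est, 50, drop = TRUE)$locus_id,
               c("a", "b"))
})

test_that("identical inputs give byte-identical output tables", {
  fx <- exampleThreeTE()
  ann <- readTeBed(fx$bed)
  f1 <- tempfile(); f2 <- tempfile()
  writeLocusTable(quantifyTE(fx$sam, ann), f1)
  writeLocusTable(quantifyTE(fx$sam, ann), f2)
  expect_identical(readLines(f1), readLines(f2))
})
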