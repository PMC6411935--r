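# Small construction helpers for alignment-record tables and SAM text.

rec <- function(qname, mate, chrom, start, end, strand, hi = NA_integer_,
                nh = NA_integer_, pnext = NA_integer_) {
  data.table::data.table(qname = qname, mate = as.integer(mate),
                         chrom = chrom, start = as.integer(start),
                         end = as.integer(end), strand = strand,
                         hi = as.integer(hi), nh = as.integer(nh),
                         pnext = as.integer(pnext), paired = mate != 0L)
}

recs <- function(...) data.table::rbindlist(list(...))

# single-chromosome annotation from 0-based half-open intervals
toyAnnotation <- function(starts, ends, strands = "+",
                          subfam = sprintf("S%d", seq_along(starts)),
                          chrom = "chr1") {
  gr <- GenomicRanges::GRanges(
    chrom, IRanges::IRanges(starts + 1L, ends),
    strand = rep_len(strands, length(starts)))
  gr$subfamily <- subfam
  gr$family <- rep("FamX", length(starts))
  gr$clazz <- rep("LTR", length(starts))
  gr$milli_div <- rep(100, length(starts))
  gr$is_reference <- rep(TRUE, length(starts))
  gr$locus_id <- makeLocusId(gr)
  TEAnnotation(gr)
}

samHeader <- function(chrom = "chr1", len = 100000L) {
  c("@HD\tVN:1.6\tSO:unsorted", sprintf("@SQ\tSN:%s\tLN:%d", chrom, len))
}

samLine <- function(qname, flag, chrom, pos1, cigar = "100M", rnext = "*",
                    pnext1 = 0L, seq = strrep("A", 100L), nh = NULL,
                    hi = NULL) {
  tags <- c(if (!is.null(nh)) paste0("NH:i:", nh),
            if (!is.null(hi)) paste0("HI:i:", hi))
  paste(c(qname, flag, chrom, pos1, 255L, cigar, rnext, pnext1, 0L, seq,
          strrep("I", nchar(seq)), tags), collapse = "\t")
}
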