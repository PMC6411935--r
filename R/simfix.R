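## Synthetic genome / read / alignment generation and evaluation against
## truth. Everything is generated in code under a single integer seed, so the
## whole quantifier is testable end to end with no downloads and no external
## aligner.

#' Simulation configuration
#'
#' Defaults emulate a stranded paired-end short-read TE experiment: 100 bp
#' mates, fragment lengths ~ Normal(250, 25) truncated at the read length,
#' a uniform 0.5% per-base sequencing error rate, and 20x mean per-locus
#' read coverage. Divergence levels are assigned per locus, evenly spaced
#' across `divergenceRange` within each subfamily, so every subfamily spans
#' young (hard-to-map) to old (easy) copies.
#'
#' @param seed Integer seed; all downstream sampling derives from it.
#' @param readLength Mate length, bp.
#' @param fragMean,fragSd Fragment length distribution, bp.
#' @param errorRate Per-base substitution error probability.
#' @param coverageMean Mean fold read coverage of expressed loci.
#' @param nSubfamilies,lociPerSubfamily Annotation layout.
#' @param divergenceRange Per-base substitution probability range from the
#'   subfamily consensus (c(min, max)).
#' @param consensusLength Length of each subfamily consensus, bp.
#' @param genomeBackgroundLength Random background genome length, bp.
#' @param flankExtension Transcripts extend this many bp beyond the locus on
#'   both sides (read-through into unique flanking sequence).
#' @return A `SimConfig` list.
#' @export
simConfig <- function(seed = 1L, readLength = 100L, fragMean = 250,
                      fragSd = 25, errorRate = 0.005, coverageMean = 20,
                      nSubfamilies = 5L, lociPerSubfamily = 20L,
                      divergenceRange = c(0.02, 0.25),
                      consensusLength = 1000L,
                      genomeBackgroundLength = 300000L,
                      flankExtension = 0L) {
  stopifnot(errorRate >= 0, errorRate <= 1,
            all(divergenceRange >= 0), all(divergenceRange <= 1),
            fragMean >= readLength, coverageMean >= 0)
  cfg <- list(seed = as.integer(seed), readLength = as.integer(readLength),
              fragMean = fragMean, fragSd = fragSd, errorRate = errorRate,
              coverageMean = coverageMean,
              nSubfamilies = as.integer(nSubfamilies),
              lociPerSubfamily = as.integer(lociPerSubfamily),
              divergenceRange = divergenceRange,
              consensusLength = as.integer(consensusLength),
              genomeBackgroundLength = as.integer(genomeBackgroundLength),
              flankExtension = as.integer(flankExtension))
  class(cfg) <- "SimConfig"
  cfg
}

.randomDna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.mutateSeq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(ch)) < rate)
  if (length(hit)) {
    for (i in hit) {
      alt <- setdiff(c("A", "C", "G", "T"), ch[i])
      ch[i] <- alt[sample.int(3L, 1L)]
    }
  }
  paste(ch, collapse = "")
}

.revcompChar <- function(x) {
  as.character(reverseComplement(DNAStringSet(x)))
}

#' Build a synthetic genome with divergent TE subfamilies
#'
#' Draws one random consensus per subfamily, derives each locus from its
#' consensus by substitution-only mutation at a per-locus divergence, and
#' inserts the loci at non-overlapping random positions (random strand; a
#' minus-strand locus is inserted as the reverse complement) into a random
#' background contig. Deterministic for a given config seed.
#'
#' @param cfg A [simConfig()].
#' @return List: `genome` (`DNAStringSet`, one contig `"chrS"`),
#'   `annotation` ([TEAnnotation-class] with `milli_div` = divergence x
#'   1000), `consensi` (`DNAStringSet`), `divergence` (named per-locus
#'   vector), `config`.
#' @export
makeGenome <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  set.seed(cfg$seed)
  nloc <- cfg$nSubfamilies * cfg$lociPerSubfamily
  total <- nloc * cfg$consensusLength
  slack <- cfg$genomeBackgroundLength - total
  if (slack < nloc + 1L)
    stop("infeasible packing: ", nloc, " loci of ", cfg$consensusLength,
         " bp do not fit in ", cfg$genomeBackgroundLength, " bp background")

  background <- .randomDna(cfg$genomeBackgroundLength)
  consensi <- vapply(seq_len(cfg$nSubfamilies),
                     function(i) .randomDna(cfg$consensusLength), "")
  names(consensi) <- sprintf("SIM%d", seq_len(cfg$nSubfamilies))
  clazzes <- rep(c("LINE", "SINE", "LTR"), length.out = cfg$nSubfamilies)

  div <- rep(seq(cfg$divergenceRange[1], cfg$divergenceRange[2],
                 length.out = cfg$lociPerSubfamily), cfg$nSubfamilies)
  subfam <- rep(names(consensi), each = cfg$lociPerSubfamily)
  strandv <- sample(c("+", "-"), nloc, replace = TRUE)

  # random non-overlapping placement: gaps are a random composition of slack
  gapu <- diff(sort(c(0, runif(nloc), 1)))
  gaps <- floor(gapu * slack)
  starts0 <- cumsum(gaps[seq_len(nloc)]) +
    (seq_len(nloc) - 1L) * cfg$consensusLength  # 0-based locus starts

  pieces <- character(2L * nloc + 1L)
  seqs <- character(nloc)
  cursor <- 0L
  for (i in seq_len(nloc)) {
    s <- .mutateSeq(consensi[[subfam[i]]], div[i])
    if (strandv[i] == "-") s <- .revcompChar(s)
    seqs[i] <- s
    pieces[2L * i - 1L] <- substr(background, cursor + 1L, starts0[i])
    pieces[2L * i] <- s
    cursor <- starts0[i] + cfg$consensusLength
  }
  pieces[2L * nloc + 1L] <- substr(background, cursor + 1L,
                                   cfg$genomeBackgroundLength)
  genome <- DNAStringSet(paste(pieces, collapse = ""))
  names(genome) <- "chrS"

  gr <- GRanges("chrS", IRanges(starts0 + 1L, starts0 + cfg$consensusLength),
                strand = strandv)
  gr$subfamily <- subfam
  gr$family <- sub("[0-9]+$", "", subfam)
  gr$clazz <- clazzes[match(subfam, names(consensi))]
  gr$milli_div <- div * 1000
  gr$is_reference <- rep(TRUE, nloc)
  gr$locus_id <- makeLocusId(gr)
  GenomeInfoDb::seqlengths(gr) <- setNames(width(genome), "chrS")

  list(genome = genome,
       annotation = TEAnnotation(gr, genomeBuild = "synthetic"),
       consensi = DNAStringSet(consensi),
       divergence = setNames(div, gr$locus_id),
       config = cfg)
}

#' Simulate stranded paired-end reads from expressed loci
#'
#' Fragments are drawn uniformly along each expressed locus's transcript
#' (the locus extended by `flankExtension`), with Normal(fragMean, fragSd)
#' lengths truncated at the read length, substitution errors applied at
#' `errorRate`, and mates emitted in transcript orientation (mate 1 on the
#' transcript strand — an `fr` library). The expected fragment count per
#' locus is coverage x transcript length / (2 x read length).
#'
#' @param sim Output of [makeGenome()].
#' @param expression Named per-locus coverage vector (names = locus ids);
#'   default: every locus at `coverageMean`.
#' @param cfg Config; defaults to `sim$config`.
#' @return List: `reads1`, `reads2` (named character vectors; read names
#'   encode fragment serial, origin locus and 0-based genomic fragment
#'   start as `f<serial>;<locus_id>;<start>`), and `truth` (`data.table`
#'   with per-locus simulated fragment counts, the expressed flag at
#'   the 10-fragment convention, divergence and coordinates).
#' @export
simulateReads <- function(sim, expression = NULL, cfg = sim$config) {
  set.seed(cfg$seed + 1L)
  gr <- teLoci(sim$annotation)
  glen <- width(sim$genome)[1]
  gseq <- as.character(sim$genome[[1]])
  if (is.null(expression))
    expression <- setNames(rep(cfg$coverageMean, length(gr)), gr$locus_id)

  RL <- cfg$readLength
  r1 <- list(); r2 <- list()
  truth <- data.table(locus_id = gr$locus_id,
                      n_frags = 0L,
                      divergence = gr$milli_div / 1000,
                      chrom = as.character(seqnames(gr)),
                      start = start(gr) - 1L, end = end(gr),
                      strand = as.character(strand(gr)))
  serial <- 0L
  for (i in seq_along(gr)) {
    cov <- expression[gr$locus_id[i]]
    if (is.na(cov) || cov <= 0) next
    txs <- max(1L, start(gr)[i] - cfg$flankExtension)
    txe <- min(glen, end(gr)[i] + cfg$flankExtension)
    txlen <- txe - txs + 1L
    tx <- substr(gseq, txs, txe)
    minus <- as.character(strand(gr))[i] == "-"
    if (minus) tx <- .revcompChar(tx)
    nfrag <- rpois(1L, cov * txlen / (2 * RL))
    if (nfrag == 0L) next
    flen <- pmin(pmax(round(rnorm(nfrag, cfg$fragMean, cfg$fragSd)), RL),
                 txlen)
    fpos <- floor(runif(nfrag) * (txlen - flen + 1L))  # 0-based in transcript
    m1 <- substr(rep(tx, nfrag), fpos + 1L, fpos + RL)
    m2 <- .revcompChar(substr(rep(tx, nfrag), fpos + flen - RL + 1L,
                              fpos + flen))
    if (cfg$errorRate > 0) {
      m1 <- vapply(m1, .mutateSeq, "", rate = cfg$errorRate,
                   USE.NAMES = FALSE)
      m2 <- vapply(m2, .mutateSeq, "", rate = cfg$errorRate,
                   USE.NAMES = FALSE)
    }
    gstart <- if (minus) (txe - 1L) - (fpos + flen - 1L) else (txs - 1L) + fpos
    nm <- sprintf("f%06d;%s;%d", serial + seq_len(nfrag), gr$locus_id[i],
                  gstart)
    serial <- serial + nfrag
    names(m1) <- nm; names(m2) <- nm
    r1[[length(r1) + 1L]] <- m1
    r2[[length(r2) + 1L]] <- m2
    truth[i, n_frags := nfrag]
  }
  truth[, expressed := n_frags >= 10L]
  list(reads1 = unlist(r1), reads2 = unlist(r2), truth = truth)
}

#' Write simulated reads as paired FASTQ
#' @param reads Output of [simulateReads()].
#' @param prefix Path prefix; writes `<prefix>_1.fastq`, `<prefix>_2.fastq`.
#' @return The two paths, invisibly.
#' @export
writeSimFastq <- function(reads, prefix) {
  paths <- paste0(prefix, c("_1.fastq", "_2.fastq"))
  for (k in 1:2) {
    rd <- if (k == 1) reads$reads1 else reads$reads2
    con <- file(paths[k], "w")
    writeLines(paste0("@", names(rd), "/", k, "\n", rd, "\n+\n",
                      strrep("I", nchar(rd))), con)
    close(con)
  }
  invisible(paths)
}

.samEscape <- function(x) gsub("[ \t]", "_", x)

#' Exhaustively align paired reads against a small genome
#'
#' Reports every ungapped placement of each mate on both strands with at
#' most `maxMismatches` mismatches (complete by pigeonhole-seeded scanning),
#' pairs mates into all concordant combinations (same contig, opposite
#' strands, fragment span at most `pairMax`), and writes a SAM file with NH
#' (number of reported pairs) and HI (pair index) tags. Fragments with no
#' concordant combination are omitted. Intended as a desk-scale oracle
#' replacing an external spliced aligner; genomes beyond a few megabases
#' are refused.
#'
#' @param reads Output of [simulateReads()], or a list with named `reads1`,
#'   `reads2` character vectors.
#' @param genome `DNAStringSet` genome.
#' @param samPath Output SAM path.
#' @param maxMismatches Mismatch tolerance per mate.
#' @param pairMax Maximum concordant fragment span, bp.
#' @return `samPath`, invisibly; attribute `"placements"` holds the raw
#'   per-mate placement table.
#' @export
oracleAlign <- function(reads, genome, samPath, maxMismatches = 3L,
                        pairMax = 1e6) {
  stopifnot(sum(as.numeric(width(genome))) <= 5e6)
  contigs <- as.character(genome)
  nm1 <- names(reads$reads1)
  stopifnot(identical(nm1, names(reads$reads2)))

  scan <- function(rd) {
    d <- as.data.table(cpp_scan_reads(contigs, unname(rd),
                                      as.integer(maxMismatches)))
    d[, `:=`(qname = nm1[read], len = nchar(rd)[read],
             chrom = names(genome)[contig])]
    d
  }
  p1 <- scan(reads$reads1)
  p2 <- scan(reads$reads2)

  pairs <- merge(
    p1[, .(qname, chrom, s1 = pos, e1 = pos + len, str1 = strand, len1 = len,
           seq1 = unname(reads$reads1)[read])],
    p2[, .(qname, chrom, s2 = pos, e2 = pos + len, str2 = strand, len2 = len,
           seq2 = unname(reads$reads2)[read])],
    by = c("qname", "chrom"), allow.cartesian = TRUE)
  pairs <- pairs[str1 != str2 & pmax(e1, e2) - pmin(s1, s2) <= pairMax]
  if (nrow(pairs)) {
    pairs[, `:=`(nh = .N, hi = seq_len(.N) - 1L), by = qname]
  } else {
    pairs[, `:=`(nh = integer(), hi = integer())]
  }

  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", names(genome), width(genome)))
  lines <- character()
  if (nrow(pairs)) {
    mkLine <- function(qn, flag, chrom, pos0, len, seqc, neg, mpos0, tlen,
                       nh, hi) {
      sq <- ifelse(neg, .revcompChar(seqc), seqc)
      paste(qn, flag, chrom, pos0 + 1L, 255L, paste0(len, "M"), "=",
            mpos0 + 1L, tlen, sq, strrep("I", len),
            paste0("NH:i:", nh), paste0("HI:i:", hi), sep = "\t")
    }
    span <- pmax(pairs$e1, pairs$e2) - pmin(pairs$s1, pairs$s2)
    tlen1 <- ifelse(pairs$s1 <= pairs$s2, span, -span)
    sec <- ifelse(pairs$hi > 0L, 256L, 0L)
    f1 <- 1L + 2L + 64L + ifelse(pairs$str1 == "-", 16L, 0L) +
      ifelse(pairs$str2 == "-", 32L, 0L) + sec
    f2 <- 1L + 2L + 128L + ifelse(pairs$str2 == "-", 16L, 0L) +
      ifelse(pairs$str1 == "-", 32L, 0L) + sec
    qn <- .samEscape(pairs$qname)
    lines <- c(
      mkLine(qn, f1, pairs$chrom, pairs$s1, pairs$len1, pairs$seq1,
             pairs$str1 == "-", pairs$s2, tlen1, pairs$nh, pairs$hi),
      mkLine(qn, f2, pairs$chrom, pairs$s2, pairs$len2, pairs$seq2,
             pairs$str2 == "-", pairs$s1, -tlen1, pairs$nh, pairs$hi))
  }
  writeLines(c(header, lines), samPath)
  placements <- rbind(p1[, .(qname, mate = 1L, chrom, pos, strand, mm)],
                      p2[, .(qname, mate = 2L, chrom, pos, strand, mm)])
  attr(samPath, "placements") <- placements
  invisible(samPath)
}

#' Compare estimates to simulated truth
#'
#' Per truth-expressed locus, %Observed/Expected = 100 x reported count /
#' simulated fragment count (orientations collapsed). The true positive
#' rate is the percentage of truth-expressed loci (>= `countMin` simulated
#' fragments) reported with >= `countMin` counts; the positive predictive
#' value is the percentage of reported (>= `countMin`) loci that are
#' truth-expressed.
#'
#' @param x A [TECounts-class] or per-locus estimate `data.frame`.
#' @param truth Truth table from [simulateReads()].
#' @param countMin Expression convention (default 10 fragments).
#' @return List: `perLocus` table (with `oe`), `meanOE`, `meanOE_by_bin`
#'   (divergence < 10% vs >= 10%), `TPR`, `PPV`.
#' @export
evaluateEstimates <- function(x, truth, countMin = 10) {
  est <- as.data.table(if (is(x, "TECounts")) locusEstimates(x) else x)
  obs <- if (nrow(est)) est[, .(observed = sum(C_TE)), by = locus_id] else
    data.table(locus_id = character(), observed = numeric())
  tab <- merge(as.data.table(truth), obs, by = "locus_id", all.x = TRUE)
  tab[is.na(observed), observed := 0]
  tab[, oe := fifelse(n_frags > 0, 100 * observed / n_frags, NA_real_)]
  expressedTab <- tab[n_frags >= countMin]
  reported <- tab[observed >= countMin]
  bins <- expressedTab[, .(meanOE = mean(oe), n = .N),
                       by = .(bin = fifelse(divergence < 0.10,
                                            "div<10%", "div>=10%"))]
  list(perLocus = tab[],
       meanOE = if (nrow(expressedTab)) mean(expressedTab$oe) else NA_real_,
       meanOE_by_bin = bins[],
       TPR = if (nrow(expressedTab))
         100 * mean(expressedTab$observed >= countMin) else NA_real_,
       PPV = if (nrow(reported))
         100 * mean(reported$n_frags >= countMin) else NA_real_)
}

#' Worked three-locus example dataset
#'
#' Builds the canonical didactic instance used throughout the
#' documentation and tests: TE A with 4 uniquely aligned fragments at 2
#' distinct start positions, TE B with 1 unique fragment, TE C with none,
#' plus 4 multi-mapping fragments that each align to all three loci. Under
#' the unique-informed initial assignment each multi fragment contributes
#' 1/3 to C and splits the remaining 2/3 between A and B as 2:1 (4/9 and
#' 2/9).
#'
#' @param dir Directory to write `loci.bed` and `reads.sam` into.
#' @return List: `bed`, `sam` paths and the `annotation`.
#' @export
exampleThreeTE <- function(dir = tempfile("threeTE")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gr <- GRanges("chr1", IRanges(c(1001L, 10001L, 20001L),
                                c(7000L, 14000L, 23000L)), strand = "+")
  gr$subfamily <- c("TEA", "TEB", "TEC")
  gr$family <- "SimFam"
  gr$clazz <- "LTR"
  gr$milli_div <- c(120, 150, 60)
  gr$is_reference <- rep(TRUE, 3L)
  gr$locus_id <- makeLocusId(gr)
  ann <- TEAnnotation(gr, genomeBuild = "toy")
  bed <- file.path(dir, "loci.bed")
  writeTeBed(ann, bed)

  line <- function(qn, flag, pos0, nh, hi) {
    paste(qn, flag, "chr1", pos0 + 1L, 255L, "100M", "*", 0L, 0L,
          strrep("A", 100L), strrep("I", 100L),
          paste0("NH:i:", nh), paste0("HI:i:", hi), sep = "\t")
  }
  uni <- c(line("uA1", 0L, 1100L, 1L, 0L), line("uA2", 0L, 1100L, 1L, 0L),
           line("uA3", 0L, 1400L, 1L, 0L), line("uA4", 0L, 1400L, 1L, 0L),
           line("uB1", 0L, 10100L, 1L, 0L))
  multiPos <- c(3000L, 11000L, 20500L)
  multi <- unlist(lapply(1:4, function(i) {
    vapply(seq_along(multiPos), function(j) {
      line(paste0("m", i), if (j == 1L) 0L else 256L, multiPos[j], 3L,
           j - 1L)
    }, "")
  }))
  sam <- file.path(dir, "reads.sam")
  writeLines(c("@HD\tVN:1.6\tSO:unsorted", "@SQ\tSN:chr1\tLN:30000",
               uni, multi), sam)
  list(bed = bed, sam = sam, annotation = ann, dir = dir)
}
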