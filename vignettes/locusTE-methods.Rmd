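---
title: "Locus-level TE quantification: model, parameters and design"
author: "locusTE authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locus-level TE quantification: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(locusTE)
```

## The problem

Transposable elements (TEs) are interspersed repeats: loci of one subfamily
descend from a shared consensus and can be nearly identical in sequence.
Short RNA-seq reads originating from a young TE locus therefore often align
equally well to many loci ("multi-mapped reads"), while reads from older,
diverged loci align uniquely. Discarding multi-mapped reads underestimates
expression of exactly the loci of greatest biological interest; aggregating
them to the subfamily level discards the genomic context. locusTE assigns
fractional counts of multi-mapped fragments to individual loci so that
expression can be quantified per locus.

## The model

Quantification works per *key*, a (locus, orientation) pair: with a stranded
library the sense and antisense directions of a TE are treated as separate
transcripts; unstranded data collapses to a single orientation.

**Classification.** Every reported placement of a fragment is read from
SAM/BAM (secondary alignments included; uniqueness is decided from the
observed placements, not the NH tag). A paired fragment is *unique* if both
mates have a single placement, or if one mate is unique — then the pair
containing the unique mate is kept and the multi-mate's other placements
are discarded. If both mates are multi-mapping but concordant (same
chromosome, opposite strands, span below a configurable bound, default
1 Mb) at exactly one location, the fragment contributes a whole count there
but is *not* unique: it is excluded from unique counts and from the
uniquely alignable length. With two or more concordant locations the
fragment is *multi* and its discordant placements are dropped; with none it
is excluded altogether (the upstream aligner's concordance policy defines
such fragments, and we have no principled way to place them).

**Candidacy.** A placement nominates a locus when at least one mate
overlaps it by at least half of that mate's aligned reference span (rounded
up) — up to 50% of a read may hang into flanking sequence, which recovers
unique evidence at TE boundaries. A fragment with one candidate key counts
wholly there; a fragment with N ≥ 2 candidates is assigned fractionally.
Co-located (nested) loci are kept distinct, so even a uniquely *placed*
fragment can have several candidates; it is then resolved by the same
fractional machinery, and only fragments with a single candidate key enter
the unique statistics.

**Initial assignment.** For each locus the unique count $C_U$ is normalized
by the uniquely alignable length $L_U$, the number of distinct unique-
fragment start positions (duplicate starts collapse — the literal reading
of "unique read start positions"; unique mappable bases would be an
alternative unit). Among the N candidates of a multi-mapped fragment, the
n candidates without unique reads each receive $1/N$; the remainder
$1 - n/N$ is split among the others proportionally to
$(C_U/L_U) / \sum_{s \in T} C_s/L_s$. Per fragment the fractions sum to 1.

**Lengths.** The transcribed length $L_{TE}$ is the span from the leftmost
to the rightmost aligned base of the fragments attributed to the locus
(whole-count fragments plus multi fragments with a nonzero initial
fraction); it may exceed the annotation (read-through) or fall short of it
(partial transcription). The effective length is
$l_{TE} = \max(L_{TE} - l_{avg} + 1,\, 1)$, with $l_{avg}$ the mean aligned
fragment length over all fragments touching the locus — the number of
distinct start positions the transcript admits, clamped at 1 so it can
stand in a denominator. Both are frozen after the initial assignment: the
EM objective stays fixed, and recomputing them inside the loop is not part
of the procedure.

**EM refinement.** Each expectation step reassigns every multi fragment
proportionally to the current length-normalized totals
$(C_{TE}/l_{TE}) / \sum_{t \in T} C_t/l_t$; each maximization step re-sums
$C_{TE}$ = whole counts + fractions. A locus whose running total has
dropped below one fragment is unlikely to have produced any read: it is
zeroed and removed from the fragment's denominator (per-locus totals are
the only non-degenerate reading of the below-one rule, since per-read
fractions are almost always < 1). If all of a fragment's candidates are
zeroed it falls back to an equal 1/N split. Zeroing is applied at every
E-step by default; `zeroing = "final"` defers it to a single pass after the
loop, since the procedure's description leaves the schedule open.
In `"auto"` mode the loop stops when every locus with at least 10 counts
changes by less than 1% relative ($|\Delta C| / \max(C_{prev}, 1) < 0.01$),
with a hard cap of 100 iterations (accuracy does not degrade with more
iterations, so the cap is safe); a fixed iteration count can be requested
instead, and 0 returns the initial assignment.

**Outputs.** Per key: the confidence score $100 \cdot C_{TE}/R_{TE}$, where
$R_{TE}$ counts fragments (pairs once) with any candidate placement at the
locus — 100 means every touching fragment stayed; a default threshold of
50 flags loci likely to carry misattributed reads. FPKM uses the
*transcribed* length (annotation-length normalization underestimates
transcripts shorter than their annotation) and a library size equal to the
number of fragments with at least one reported alignment anywhere — the
standard per-million denominator. Counts are reported as floats with an
additional half-up-rounded integer column for count-based downstream
tools. Subfamily tables sum counts and FPKM over member loci with
orientations collapsed.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `strandMode` | `none` | `fr`/`rf` library orientation; mate 1 carries (`fr`) or opposes (`rf`) the fragment strand |
| `emIterations` | `auto` | convergence-driven; integer for fixed count, 0 for initial assignment only |
| `maxIter` | 100 | hard cap for `auto` |
| `zeroing` | `per-step` | when the below-one-count rule is applied |
| `scoreThreshold` | 50 | flagging threshold on the 0–100 confidence score |
| `concordantMax` | 1e6 bp | concordance span bound, mirroring the wide defaults of splice-aware aligners |

## The synthetic data generator

`simConfig()` / `makeGenome()` / `simulateReads()` / `oracleAlign()` build
a fully synthetic, truth-tracked test bed: one random consensus per
subfamily; each locus is the consensus mutated by substitution only at its
per-locus divergence (evenly spaced across 2–25% within a subfamily, so
each subfamily spans hard young copies to easy old ones) and inserted at a
random position and strand in a random background contig. Reads are 100 bp
stranded pairs with Normal(250, 25) fragment lengths, a uniform 0.5%
per-base error rate and 20x mean coverage; the per-locus fragment count is
Poisson around coverage x transcript length / (2 x read length). The
default benchmark uses 5 subfamilies x 20 loci of 1 kb in 300 kb of
background — small enough that the whole pipeline (generation, exhaustive
alignment, quantification) runs in well under a minute on one CPU, while
still producing ~10,000 fragments across 100 loci.

The oracle aligner reports *every* ungapped placement of each mate with at
most 3 mismatches (complete by pigeonhole seeding: a read split into
max_mm + 1 segments must contain an error-free 16-mer at a known offset),
then pairs mates into all concordant combinations with NH/HI tags. Three
mismatches cover essentially all sequencing errors at 0.5% per base
(P(>3 errors in 100 bp) ≈ 2e-5). Substitution-only divergence keeps the
oracle exhaustive and ungapped; it is sufficient to create the
unique/multi structure the quantifier adjudicates.

What the simulation does *not* emulate: splicing, indels, quality-score
structure, GC and positional coverage bias, genes overlapping TEs, and
genome-scale annotation density. Passing the synthetic benchmark therefore
demonstrates the correctness of the assignment arithmetic and the
direction of the EM benefit, not performance on real libraries aligned
with a spliced aligner.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open externally (BED convention; native
  RepeatMasker `.out` rows are converted on ingest) and ordinary
  Bioconductor 1-based GRanges internally; locus ids are
  `chrom|start0|end0|subfamily|strand`.
* Every RepeatMasker row is one locus; fragments of one interrupted
  element are not re-joined, which may split old elements into several
  loci.
* Proportional splits need no tie-breaking: equal weights split equally by
  construction.
* A locus with no aligned fragment is not reported; a fragment with no
  candidate locus is excluded from TE quantification (not an error).
* Non-TE repeat classes (simple repeats, satellites, low complexity) are
  filtered at parse time by default since TEs are the object of
  quantification; `allRepeats = TRUE` keeps them.
* Score thresholding *flags* by default rather than dropping, so
  downstream filtering stays reversible.
* Deterministic throughout: identical inputs and seed give byte-identical
  tables; every CLI run writes its parameters to a manifest.

## Known limitations

* No splice-aware placement: the package consumes aligner output and the
  built-in oracle is ungapped; intron-spanning TE reads are out of scope.
* The uniquely alignable length counts unique start positions, not unique
  bases; for very short loci with clustered unique reads this can
  overweight them in the initial assignment.
* Rescued concordant-single-location pairs add whole counts without unique
  evidence, so a locus supported only by rescued pairs is treated as
  zero-unique in the initial assignment.
* Subfamily aggregation sums locus estimates; it does not re-run
  assignment at the subfamily level.
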