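---
title: "Discovering plant miRNA genes from small-RNA read clouds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering plant miRNA genes from small-RNA read clouds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plantmir)
```

## The problem

A plant miRNA gene betrays itself twice in an sRNA-seq experiment. At the
sequence level, the locus folds into a stem-loop precursor whose free
energy is far lower than its base composition alone would predict. At the
read level, Dicer-like processing leaves a two-peak footprint: a dominant
stack of identical ~21-nt reads (the guide miRNA) and a smaller stack on
the opposite arm (the passenger, miRNA\*), staggered by the 2-nt 3′
overhangs that RNase III cleavage produces. Neither signal is sufficient
alone — genomes are full of hairpins, and degradation or siRNA loci
produce read peaks — but their conjunction is highly specific. `plantmir`
operationalises this conjunction as a pipeline ending in a 0–6 star
score, so that downstream users can choose their own trade-off between
sensitivity and precision rather than inherit a hard cutoff.

## Pipeline stages and their parameters

### Prefiltering

Reads overlapping annotated CDS, tRNA, rRNA or snoRNA features are
masked (any ≥ 1 bp overlap, on either strand), because degradation
products of structured or abundant transcripts are the dominant source
of false hairpin candidates. Reads mapping to more than
`max_genomic_hits = 5` loci are removed: transposon-derived siRNA
families map promiscuously, and their clouds are not interpretable as
single-locus expression. Reads inside user-supplied known precursor
coordinates (same strand, ≥ 1 bp) are tallied per precursor and set
aside, so de novo discovery reports only new loci. When a read record
qualifies for several bins the priority is known-miRNA > mask >
multimapper, which makes the filter report an exact partition of the
input — a property the test suite checks on random read sets.

Masking is strand-agnostic by design: the annotations we mask against are
primarily a contamination filter, and degradation fragments map to both
strands of an expressed feature.

### Peak calling

Reads separated by at most `cluster_gap = 30` nt are merged into
clusters. The gap is intentionally smaller than the span of a full
precursor arm-loop-arm so the two duplex peaks of a short-looped hairpin
may merge into one cluster — the partner search below tolerates that.
Cluster total copy counts are then split into background and signal by an
exact 1-D 2-means: on sorted log10 counts the optimal 2-partition is a
single split point, found by minimising the within-group sum of squares
over all splits. This removes any seed or initialisation dependence that
an iterative k-means would introduce. Clusters in the high group become
peaks, as does any cluster with at least `peak_floor = 10` copies — the
absolute floor protects moderately expressed loci in libraries dominated
by one very tall peak. If all clusters have equal counts the split is
undefined and everything is kept for the downstream filters to sort out.

### Duplex partner search

A read peak can only come from a miRNA precursor if nearby sequence can
base-pair with it. Windows of peak length are slid across ± 350 nt of
genomic context (windows lie fully inside that range, and near-identical
windows — ≥ 90% overlap with the peak — are excluded as the peak itself).
Each window is scored by `pairing_matrix()`: a free-end-gap alignment of
the peak against the reversed window counting C-G, A-U and G-U pairs,
allowing at most 2 internal bulges of ≤ 2 nt each, implemented as a small
dynamic program in C++ and cross-checked in the tests against an
exhaustive enumeration oracle on short strings. A peak survives when some
window reaches `min_paired = 14` pairs. With 21-nt peaks this asks for
roughly two-thirds of positions paired, which canonical duplexes with up
to ~4 mismatches clear comfortably while random windows rarely do; both
ends of the threshold are exercised by the boundary tests.

### Folding and hairpin selection

Candidate loci (peak ∪ best partner window, extended by
`fold_margin = 30` nt of context, since precursor ends usually extend
past the read-covered interval) are folded with RNALfold under a 350-nt
span cap, matching the search radius. Every locally stable structure is
reduced to its single stem-loop components: for each terminal loop we
take the maximal enclosing run of non-branching pairs, which dissolves
multiloops without discarding their arms. Components must be 60–350 nt
long with at least 50% of bases paired — permissive bounds, chosen
because plant precursors vary greatly in size; all four numbers are
exposed in `pipeline_config()`. The surviving component with the lowest
RNAeval energy becomes the precursor.

Thermodynamics are summarised as MFE (kcal/mol, nearest-neighbor model),
AMFE (MFE per 100 nt, making loci of different length comparable) and
MFEI (AMFE divided by GC percentage — with GC expressed in percent, e.g.
50 not 0.5, so that the conventional −0.6 and −0.8 thresholds apply).
The optional prefilter `mfei < -0.6` (strict) reflects the observation
that the vast majority of genuine plant precursors fall below −0.6 while
pseudo-hairpins generally do not.

The dinucleotide-shuffle significance test implements the
Altschul–Erickson Eulerian-path method, preserving all 16 dinucleotide
counts and both terminal nucleotides exactly; the empirical p-value uses
the standard pseudocount correction (k+1)/(n+1) so it is never zero. The
default pipeline leaves it off (`shuffle_n = 0`) because folding 100
shuffles per candidate dominates runtime and the score does not use it;
it is available per sequence via `shuffle_significance()`.

### Scoring

The six criteria are evaluated on the precursor plus its read cloud
(reads intersecting the precursor, with local 5′→3′ offsets; a read
belongs to the arm containing the majority of its span, loop-majority
reads count toward totals but no arm):

* **C1** MFEI < −0.8 (strict).
* **C2** ≥ 10 copies on each arm, or ≥ 100 copies in total. Copy counts,
  not unique reads, everywhere: the worked 71/114 = 62% example only
  works on copies.
* **C3** the most common unique read is the guide if its copy frequency
  is ≥ 1/3 (exact fraction, displayed as 33%; ties break to the 5′-most
  start, then lexicographically, making guide choice deterministic).
* **C4** ≥ 75% of copies start within [−3,+3] of the guide start or
  [−5,+5] of the expected passenger start. Read 5′ starts only — 3′ ends
  of plant sRNA reads are more ragged.
* **C5** at least one copy starts in that passenger window.
* **C6** duplex geometry: ≥ 75% of guide bases paired, implied 3′
  overhangs of 2 ± 1 nt at both duplex ends, no internal loop > 3 nt.
  This rule is deliberately pluggable (`criterion_funs` /
  `duplex_rule` arguments accept any predicate), so a learned classifier
  can replace it; the built-in rule encodes the published duplex
  geometry directly.

The expected passenger start maps the guide base two positions upstream
of its 3′ end through the structure's pair table — the 2-nt 3′ overhang
geometry — extrapolating linearly from the nearest paired base when the
anchor is unpaired. A guide spanning the terminal loop has no opposite
arm; criteria 4–6 then fail gracefully (C4 falls back to the guide
window alone, C5 and C6 are false).

Because C4–C6 are gated on C3, a locus without a defined miRNA can score
at most 2, and a locus whose passenger window is empty at most 5; the
acceptance sweeps verify these bounds over 1000 random loci each, and a
stub-injection test verifies score = Σ criteria over all 64 boolean
combinations.

### Annotation

Duplication: exact occurrences of the guide and its reverse complement
are counted across the genome with Biostrings. Occurrences inside the
prediction's own precursor (every hairpin contains a near-complement of
its guide on the star arm) count as the locus itself, so a single-copy
miRNA has `n_genomic_occurrences = 1` and weight = guide copies. The
weight divides read support among the loci that could have produced it.

Conservation: each known mature sequence is aligned to the precursor by
a semiglobal edit-distance DP allowing at most 3 mismatches + indels and
no two adjacent indel columns (the operative definition used for
conservation calls in this field). Hits overlapping the guide are
flagged and surface as "double-checked" in the summary table.

## The synthetic-data generator

`make_hairpin()`, `make_planted_locus()`, `make_read_cloud()`,
`make_genome()` and `make_dataset()` produce genomes and read sets with
known truth. The emulated features are: perfect or mismatched inverted
repeats (stems of 28 bp with 10-nt loops by default, comfortably inside
the 60–350 nt precursor bounds); two-peak read clouds with exact copy
totals (dominant guide, passenger at the 2-nt-overhang position, sparse
background with Poisson-distributed copies); optional isomiR-like guide
jitter; multi-copy repeat insertions whose reads exceed the multimapping
threshold; CDS mask features; uniform degradation reads for negative
controls. The canonical fixture reproduces a 114-copy locus with 7
unique reads (71 guide + 27 passenger + 16 background).

What the generator does **not** emulate: sequencing errors, ligation and
PCR biases, isomiR 3′ heterogeneity, multi-locus miRNA families with
near-identical members, and chromosome-scale genome structure. Passing
tests therefore demonstrate the correctness of the method's logic and
its behaviour at every documented threshold, not its sensitivity or
false-discovery rate on real libraries — the latter depend on library
depth and genome content in ways a desk-scale fixture cannot represent.

All generators take explicit seeds and restore the caller's RNG state,
so the test suite is byte-reproducible and the pipeline itself is
deterministic given its inputs.

## Numerical and design choices

* Coordinates are 0-based half-open everywhere inside the package;
  conversion to 1-based inclusive happens only at the GFF boundary. BED
  columns are: chrom, start, end, read sequence, copy count, strand, and
  an optional 7th column with the read's genome-wide hit count.
* Reads are stored in read orientation (the 5′→3′ sequence of the small
  RNA); the strand column records the genomic strand, and minus-strand
  SAM records are reverse-complemented back on import.
* Tie-breaks are deterministic everywhere (guide selection, stem-loop
  choice by lowest energy, export ordering by position), so identical
  inputs give byte-identical exports.
* Two peaks frequently rediscover the same hairpin (one per arm);
  precursors overlapping by ≥ 30 bp on one strand are deduplicated,
  keeping the most stable.
* Percentages in reports round half away from zero (62.28% → 62%).
* Degenerate inputs: empty read sets, empty annotation, contig-edge
  peaks and GC-free sequences (MFEI undefined → candidate rejected with
  a warning) are all handled and tested.
* Problem sizes in the suite: unit fixtures use 4–9 kb genomes with 1–2
  planted loci; the score-bound sweeps use 1000 random loci per bound
  over a pool of 20 folded precursors; end-to-end recovery uses 20
  seeded datasets plus 20 noise-only negatives. These sizes give stable
  pass/fail behaviour while keeping the whole suite in minutes on one
  CPU.

## Known limitations

* Criterion 6 is a geometric rule, not a trained classifier; borderline
  duplexes that a random-forest model might accept can be rejected (and
  vice versa). The pluggable predicate interface exists precisely so a
  learned model can be swapped in.
* The duplex partner search scores windows of exactly peak length; a
  partner arm much longer than the peak (asymmetric clouds) is found
  through its best-matching sub-window, which slightly understates the
  pairing of long arms.
* Known-miRNA quantification reports raw copy totals only; there is no
  normalisation or differential analysis.
* The conservation aligner reports the single best hit per database
  sequence per region; overlapping paralogue hits are collapsed.
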