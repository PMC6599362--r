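# plantmir

Identification of microRNA (miRNA) genes in plant genomes from small-RNA
sequencing alignments.

Plant miRNAs are ~21-nt regulatory RNAs excised from hairpin (stem-loop)
precursors. Finding the genes that produce them from an sRNA-seq library
is harder in plants than in animals: precursors vary widely in length and
shape, 24-nt heterochromatic siRNAs flood the libraries, and degradation
products of abundant transcripts mimic expression peaks. `plantmir`
addresses this by combining two orthogonal signals — where the reads
stack, and whether the locus folds into a thermodynamically credible
stem-loop — and by reporting an explicit 0–6 quality score instead of a
yes/no call.

## Method

Starting from genome-mapped reads (BED, or SAM/BAM via the built-in
converter):

1. **Prefilter.** Reads overlapping annotated CDS/tRNA/rRNA/snoRNA
   features are masked; reads mapping to more than 5 genomic loci
   (customisable) are removed; reads inside already-annotated miRNA
   precursors are reported separately.
2. **Peak calling.** Reads separated by ≤ 30 nt are merged into clusters;
   an exact 1-D 2-means on log10 cluster counts separates expression
   peaks from background.
3. **Duplex partner search.** Each peak must base-pair (C-G, A-U, G-U) with
   a window within 350 nt — the read-level signature of a stem-loop — via
   a banded alignment allowing two bulges of ≤ 2 nt.
4. **Folding.** Candidate loci are folded with RNALfold; the best single
   stem-loop of 60–350 nt with ≥ 50% paired bases is kept, and
   MFE, AMFE = MFE/len·100 and MFEI = AMFE/GC% are computed with RNAeval.
   Optionally, only candidates with MFEI < −0.6 are retained, and a
   dinucleotide-preserving shuffle test gives an empirical stability
   p-value.
5. **Scoring.** Six criteria, one star each:
   * C1 — MFEI < −0.8;
   * C2 — ≥ 10 read copies on each arm, or ≥ 100 in total;
   * C3 — the most common read reaches ≥ 33% of copies (it becomes the
     guide miRNA);
   * C4 — ≥ 75% of copies start within [−3,+3] of the guide start or
     [−5,+5] of the pairing position on the opposite arm;
   * C5 — at least one read in that passenger (miRNA\*) window;
   * C6 — the implied miRNA:miRNA\* duplex is geometrically sound
     (extensive pairing, 2-nt 3′ overhangs).

   A locus with no defined guide can score at most 2; a locus without
   passenger-strand evidence at most 5; 6 stars means both strands of the
   duplex are expressed from a consistent hairpin.
6. **Annotation.** Each guide is scanned for exact duplications across the
   genome (weight = guide copies / genomic occurrences) and aligned
   against a database of known mature miRNAs (≤ 3 mismatches/indels, no
   two consecutive indels); a conservation hit overlapping the guide is
   flagged "double-checked".

Exports: CSV summary table, GFF3, dot-bracket FASTA, ORG-mode report and
text read clouds.

## Worked example

The package ships a generator for read-cloud fixtures with known ground
truth. The canonical example is a locus with 114 read copies in 7 unique
reads: a 21-nt guide with 71 copies, a passenger read with 27 copies, and
16 background copies.

```r
library(plantmir)

fx  <- canonical_locus_fixture()
gen <- make_genome(list(fx$planted), length = 4000, seed = 2,
                   keep_positions = TRUE)
run <- run_pipeline(fx$reads, gen$genome)
print(run)
#> miRNA prediction run
#>   reads: 7 records in, 7 retained (0 known-miRNA, 0 masked, 0 multimapped)
#>   predictions: 1
#>   score distribution (0-6 stars): 1 / 0 / 0 / 0 / 0 / 0 / 0 (6 first)

build_summary(tidy(run))
#> # A tibble: 1 x 13
#>   name             position      strand quality_score reads reads_flag
#> 1 chr1__980-1094_+ chr1:981-1094 +                  6   114 TRUE
#>   reads_distribution  mfei mfei_flag mirna_sequence        mirna_length weight
#> 1                  3 -1.16 TRUE     AGAUAUUAGUGCGGUUCAAUC           21      71
```

The locus earns all six stars: its structure is stable (MFEI −1.16 <
−0.8), it has 114 > 100 reads, the top read holds 71/114 = 62% of copies
and becomes the guide, 98/114 = 86% of copies start in the two processing
windows, the passenger window holds 27 copies, and the duplex has clean
2-nt overhangs. The weight of 71 means the guide sequence is unique in
the genome. The text read cloud shows the precursor, its structure, the
duplex (square brackets) and each unique read with its depth:

```r
cat(render_read_cloud(tidy(run)[1, ]), sep = "\n")
#> GAUUCUAGGUUCAUAAUCUAAAGAUUUAGAUAUUAGUGCGGUUCAAUCAUGUGCAUCC...
#> ((((.(((.((...(((((.((((((((((((((((((((((((((((..........
#> ...........................[===================]...........[===================]...
#> ...........................AGAUAUUAGUGCGGUUCAAUC...........  length=21 depth=71
#> ............................................................*********************  length=21 depth=27
```

`plot_read_cloud(run)` and `autoplot(run)` give ggplot2 versions of the
read cloud and the score distribution; `tidy(run)` and `glance(run)`
return the per-locus table and the one-row run summary.

A command-line driver wraps the same functions:

```sh
Rscript exec/plantmir fixtures --out fx --n-loci 2 --seed 3
Rscript exec/plantmir predict --genome fx/genome.fa --bed fx/reads.bed --out out --seed 1
Rscript exec/plantmir bam2bed --in aln.sam --out reads.bed
```

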