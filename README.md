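# crestreg

Tools for characterising *cis*-regulatory elements from stage-resolved
chromatin accessibility (ATAC-seq) data in developing embryos, of the kind
used to study neural-crest gene-regulatory networks. The package is aimed
at computational biologists who have per-stage peak calls, accessibility
signal, gene/transcript models and a differential-expression table, and
want a tested, scriptable re-implementation of four analysis stages that
are usually stitched together from one-off scripts:

1. **Peak annotation.** Per-stage peak sets are merged into a consensus
   peakset (union of overlapping or abutting intervals) and classified
   with priority *promoter > exonic > intronic > intergenic*, where the
   promoter window is the strand-aware 2 kb upstream of a TSS,
   `[TSS − 2000, TSS)`. Intergenic peaks overlapping promoter windows of a
   second, curated annotation are moved to the promoter set, and the
   intergenic/intronic sets are filtered to peaks whose gene-body distance
   to a stage-enriched gene (adjusted *p* < 0.05, log2FC > 0) is strictly
   below 50 kb.
2. **Accessibility dynamics.** Signal is binned around each peak centre
   (±1500 bp in 15 bp bins, 200 bins per stage), profiles are concatenated
   across stages and clustered by Euclidean *k*-means. Dynamically opening
   ("EMT") clusters are detected by an early-vs-late offset test: per peak
   the paired log-ratio `log2((s_late + 1)/(s_early + 1))` of total
   windowed signal, tested per cluster with a two-sided Wilcoxon
   signed-rank test against 0, Bonferroni-corrected across clusters; a
   cluster is flagged when the corrected *p* < 0.05 **and** the mean fold
   is ≥ 1.5. The Pearson correlation of early vs late totals is reported
   alongside.
3. **Motif co-occurrence.** Sequences are scanned on both strands with
   position weight matrices scored as natural-log odds
   `ln((p + εb)/(b(1 + ε)))` against a background composition; a binary
   presence matrix records, per region and motif, whether a hit starts
   within ±250 bp of the peak centre. For every unordered motif pair the
   joint-presence counts in a target cluster and a control cluster form a
   2×2 table tested with the 1-df chi-squared statistic
   `N(ad − bc)² / (r₁r₂c₁c₂)`; with *m* tested pairs, a pair is retained
   when *p* < α/m (α = 0.05) and the pair is enriched in the target
   (18 motifs ⇒ m = 153, threshold ≈ 3.27 × 10⁻⁴). Per-motif enrichment
   against control regions uses a one-sided hypergeometric test with
   Benjamini–Hochberg correction.
4. **lncRNA cascade.** Assembled transcripts are filtered, in order:
   remove same-strand overlap with coding genes; remove transcripts with a
   protein hit of > 30 % identity at e-value ≤ 10⁻²; remove unspliced
   (single-exon) transcripts; keep transcripts whose *nearest* coding gene
   is within 5 kb on the opposite strand; remove transcripts shorter than
   200 bp (summed exon length). Every step emits an audit record, and the
   fraction of survivors overlapping accessible regions is reported.

A synthetic-data generator (`synth_config()`, `generate_dataset()`)
produces a complete internally consistent dataset — genome annotation,
stage-wise peaks and signal with planted profile clusters and a planted
EMT fold, sequences with planted motif co-occurrences, and transcripts
with true lncRNAs plus decoys each violating exactly one rule — with
ground-truth labels for every object, so that each stage of the pipeline
can be validated end to end.

## Worked example

```r
library(crestreg)

cfg <- synth_config(seed = 7)      # 4 x 2 Mb genome, 120 genes, 120 peaks
ann <- generate_annotation(cfg)
sp  <- generate_peaks_and_signal(cfg, ann)

# classify the planted peaks against the generated annotation
cls <- classify_peaks(sp$peaks[, 1:6], ann$transcripts, ann$genes)
table(planted = sp$peaks$category, recovered = cls$category)
#>             recovered
#> planted      intergenic intronic promoter
#>   intergenic         40        0        0
#>   intronic            0       40        0
#>   promoter            0        0       40

# cluster accessibility profiles and test for dynamic opening
cl  <- cluster_profiles(sp$profiles, k = 2, clustering_config(seed = 11))
emt_offset_test(cl, sp$profiles, clustering_config())
#> Early-vs-late offset test (1 EMT cluster(s) of 2)
#>  cluster  n pearson_r mean_log2_ratio  fold        p p_bonferroni emt_flag
#>        1 42     0.991         1.31858 2.494 4.55e-13     9.09e-13     TRUE
#>        2 78     0.994        -0.00788 0.995 1.51e-01     3.03e-01    FALSE

# lncRNA cascade on the planted transcript fixture
stx <- generate_transcripts_for_lncrna(cfg, ann)
run_cascade(stx$transcripts, ann$genes, stx$hits)
#> lncRNA filter cascade:
#>                step n_in n_removed n_out
#>      coding_overlap   15         2    13
#>  protein_similarity   13         2    11
#>           unspliced   11         2     9
#>  antisense_proximal    9         2     7
#>              length    7         2     5
#> final candidates: 5
```

The EMT table reads: cluster 1 (the planted dynamic cluster, 42 member
peaks) has a mean late/early fold of 2.49 with a Bonferroni-corrected
Wilcoxon *p* of 9.1 × 10⁻¹³ and is flagged; cluster 2 is static. The
cascade removes
exactly the two planted decoys at each rule and returns the five true
antisense lncRNAs.

A thin command-line wrapper over the same functions is installed at
`inst/cli/crestreg.R` with subcommands `synth`, `classify`, `cluster`,
`motifs`, `cooccur` and `lncrna`.

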