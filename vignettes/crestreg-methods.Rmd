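---
title: "Methods: regulatory element dynamics, motif co-occurrence and the lncRNA cascade"
author: "crestreg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: regulatory element dynamics, motif co-occurrence and the lncRNA cascade}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crestreg)
```

This vignette documents the models, rules and numerical choices behind
each analysis stage, what the synthetic-data generator does and does not
emulate, and the design decisions taken where more than one reasonable
option existed.

## Coordinates and interval arithmetic

All coordinates are 0-based half-open (the BED convention); GFF3/GTF
input is converted once at the boundary (`start' = start − 1`,
`end' = end`), an exact bijection on valid records. A single internal
convention removes the whole class of off-by-one bugs that arise when
1-based inclusive and half-open coordinates mix.

Interval distance is the gap between nearest ends, zero for overlap *and*
for abutment (`(100,200)` and `(200,300)` abut), infinite across
sequences. Merging is strand-blind and fuses abutting intervals, matching
the default behaviour of the standard merging tool this step emulates.
Note that gap distance does not satisfy the plain triangle inequality (an
interval spanning the gap between two others is at distance 0 from both);
the inequality holds with the middle interval's length added, which is
what the test suite asserts.

Nearest-gene lookups break ties by smaller distance, then lexicographic
gene id, so every result is deterministic. A peak's distance to a gene is
measured to the gene *body*, not the TSS — conventional for annotation
tools, and stated in the documentation because the proximity filter
(below) inherits it.

## Peak annotation

The consensus peakset is the merged union of per-stage peak calls; each
consensus peak records which stages contributed an overlapping or
abutting call.

Classification uses priority **promoter > exonic > intronic >
intergenic**. The promoter window is strand-aware, half-open and excludes
the TSS base itself: `[TSS − flank, TSS)` on the plus strand,
`(TSS, TSS + flank]` on the minus strand, with `flank = 2000` bp — the
flank semantics of the upstream-window tool the rule mirrors
(`-l 2000 -r 0 -s`). Genes with a body span below 1500 bp (span, not
summed exon length) are discarded before classification, together with
their transcripts. Exonic peaks are kept as a fourth label so that the
categories partition the peakset exactly; downstream stages consume only
the three named sets.

Intergenic peaks that overlap a promoter window of a second, curated gene
annotation are relabelled promoter. Reassignment only changes labels —
coordinates and total peak count are conserved, and the audit column
`reassigned` records every move.

The proximity filter retains a peak iff its gene-body distance to the
nearest *enriched* gene (adjusted p below 0.05 and positive log fold
change, both configurable) is **strictly** below 50 000 bp: a peak at
49 999 bp survives, one at exactly 50 000 bp does not. Whether the
published rule measured to the gene body or the TSS is not stated
anywhere we could check; gene body was chosen for consistency with the
nearest-gene convention, and the choice is surfaced in the function
documentation.

## Accessibility dynamics

Profiles are built over ±1500 bp around the peak centre in 15 bp bins
(200 bins per stage). The centre is the floor midpoint — for even-length
peaks this biases the window by at most 1 bp. Bin values are summed
signal; windows that run past a contig end are zero-padded and the peak
is flagged rather than dropped. "Linear" normalisation divides each
stage's values by that stage's total profiled signal (library-size
style); the exact normalisation of the desktop tool this emulates is not
published, so the simplest scale-removing choice was taken and the raw
profiles are kept available, because the offset test below wants raw
counts.

Clustering runs Euclidean *k*-means on the per-stage profiles
concatenated per peak (peaks × bins·stages). Whether the original
analysis clustered stages jointly or on a reference stage is not
documented; joint concatenation uses all the information and makes the
cluster assignment a single object. `stats::kmeans` (Hartigan–Wong) is
used with `n_init` random restarts under a fixed seed, keeping the best
inertia; with well-separated profile templates the restart scheme is
insensitive to the seeding rule, so no bespoke seeding was implemented.
Clusters are relabelled in descending order of total mean signal so ids
are stable across runs. *k* defaults to 6 for intergenic and 5 for
intronic sets in the command-line wrapper, echoing the cluster indices
that studies of this kind report; the true *k* of any given dataset is
unknown and the parameter is fully configurable.

The "dynamically opening" (EMT) call is an operationalisation of a
qualitative published claim — clusters visibly offset from the early-vs
late diagonal. Per member peak we take total windowed signal at the early
and late stages, form `log2((s_late + c)/(s_early + c))` with pseudocount
`c = 1` on raw binned counts, and per cluster test the log-ratios against
0 with a two-sided Wilcoxon signed-rank test, Bonferroni-corrected across
clusters. A cluster is flagged iff the corrected p-value is below 0.05
**and** the mean fold `2^mean(log-ratio)` is at least 1.5. The fold gate
keeps large clusters with statistically significant but biologically
trivial offsets from being flagged; the signed-rank test keeps the
procedure distribution-light. The Pearson correlation between early and
late totals is reported per cluster as a descriptive statistic. Clusters
with fewer than 5 members report statistics but are never flagged (with a
warning): a signed-rank test on fewer than 5 pairs cannot reach p < 0.05.

## Motif scanning and co-occurrence

PWMs store per-position base probabilities; scores are natural-log odds
with a background-proportional pseudocount,
`ln((p + εb)/(b(1 + ε)))`, ε = 10⁻³ by default. The published analyses
print log-odds scores without stating the base; natural log was fixed and
no attempt is made to reproduce another tool's numeric scale. The default
scan threshold is 80 % of the maximum attainable score; windows
containing `N` never score. Both strands are scanned; a minus-strand hit
at offset *i* means the reverse complement of the motif matches the
forward sequence at *i*. The scanner is vectorised over positions and is
checked in the test suite against a naive per-position rescoring oracle.

The presence matrix is strictly binary: region × motif, 1 iff at least
one hit *starts* within ±250 bp (inclusive) of the peak centre.

Co-occurrence testing takes two presence matrices — a target cluster and
a control cluster — and for each unordered pair forms the 2×2 table
(target with-both / target rest; control with-both / control rest). The
statistic is the 1-df Pearson chi-squared (cross-product form, no Yates
correction by default); the p-value is the upper tail. "Two-tailed" in
the published description is honoured by testing deviation in either
direction while only *enriched* pairs are retainable, matching how the
results are used. Retention is strict: `p < α/m`. `m` counts pairs
actually tested — pairs among motifs present in at least one region
overall — which equals C(18, 2) = 153 whenever all 18 motifs occur
somewhere. When any expected cell falls below 1 the two-sided Fisher
exact p-value is substituted and the row flagged. An alternative
contingency construction (marginal-independence expectation within the
target cluster alone) was considered and rejected as the default because
the published procedure explicitly names a control cluster.

Per-motif enrichment against a control region set uses the one-sided
hypergeometric tail on the pooled population with Benjamini–Hochberg
correction across motifs, and control regions can be sampled uniformly
from the non-coding, non-peak genome under a seed.

## lncRNA cascade

Five rules in a fixed order, each emitting an audit record
(`n_in − n_removed = n_out`, chained):

1. remove transcripts with ≥ 1 bp same-strand exon overlap with a coding
   gene body (antisense overlap is allowed);
2. remove transcripts with any protein hit of identity > 30 % and
   e-value ≤ 10⁻². The published description prints the e-value
   inequality the other way (`> 10⁻²`), which would remove only
   *insignificant* hits; since the rule's purpose is to exclude
   protein-coding transcripts, significant similarity must drive removal.
   The literal reading remains available via `literal_evalue = TRUE`;
3. remove unspliced (single-exon) transcripts;
4. keep transcripts whose *nearest* coding gene (gene-body distance,
   deterministic tie-break) is within 5 kb (inclusive) **and** on the
   opposite strand. Only the single nearest gene is consulted, exactly as
   the rule is worded, even if a farther gene within range is antisense;
5. remove transcripts with summed exon length strictly below 200 bp.

On the synthetic fixture the final set is invariant to rule order (each
decoy violates exactly one rule), asserted as a regression test; on real
data order can matter and the published order is used.

`atac_overlap_fraction()` reports the strand-blind fraction of surviving
transcripts with ≥ 1 bp exon overlap with an accessible region.

## The synthetic-data generator

The generator emulates the statistical structure the pipeline is designed
to detect, not the biology of any genome. Defaults define the study
conditions used throughout the tests: 4 chromosomes × 2 Mb (large enough
to place intergenic elements freely, small enough to generate in
seconds), 120 coding genes packed with 3–20 kb gaps, a 40 % enriched
fraction in the DE table (drawn with padj < 0.05 and log2FC > 1),
three stages, lognormal multiplicative noise with σ = 0.25 on per-cluster
template profiles (no noise model is published for this kind of signal; a
multiplicative lognormal is the standard light-tailed choice for
coverage ratios, and a negative-binomial option provides count realism),
and a planted EMT fold of 2.5 between the first and later stages.

Peaks are placed to make the planted category unambiguous: promoter peaks
strictly inside a gene's upstream window, intronic peaks inside introns
clear of exons and of every promoter window, intergenic peaks clear of
gene bodies and windows, and all peak centres at least one full profile
window apart so that rendered bedGraph tracks never overlap. Cluster
shapes are deterministic multi-bump templates whose bump positions differ
between clusters, so cluster identity is carried by profile *shape* and
survives the per-peak depth noise.

Motif plantings insert the motif's consensus string at a uniform offset
within ±250 bp of the peak centre on a random strand — guaranteeing a
hit at any sensible threshold while exercising strand handling. The
default motif set is 18 synthetic 8-mer PFMs (main base probability
0.85) labelled after transcription-factor families typical of this
field; at the default threshold only the exact consensus (or its reverse
complement) scores, which makes planted-versus-chance hits easy to
reason about.

Two planting routes exist for co-occurrence studies. The sequence route
(`generate_sequences_with_motifs()`) literally inserts the pair into
target-cluster peaks at rate `p_joint_target` and control-cluster peaks
at `p_joint_control`, and is exercised end to end (plant → scan →
presence → test) at small scale. The presence route
(`generate_presence()`) simulates the binary matrices directly and is
used for the large calibration and power studies (hundreds of simulated
datasets), where scanning sequences would dominate runtime without
changing what is being tested — the co-occurrence statistics consume
only the presence matrix. The presence route additionally equalises each
pair motif's *marginal* rate across the two groups (by raising the
singleton rate in the lower-joint group): joint planting inflates
marginals, and without this compensation every pair sharing one planted
motif has a genuinely different joint rate between groups, which is a
property of the planting, not a false positive of the test. With
marginals matched, the planted pair is the only non-null pair, which is
exactly what a power/specificity analysis needs. The extreme
`p_joint_target = 1, p_joint_control = 0` corner used by the
sequence-route example is not marginal-matchable and the sequence route
deliberately does not compensate.

lncRNA planting places each true candidate antisense to an isolated
anchor gene at ~1 kb, spliced, 300 bp. Decoys violate exactly one rule
each; the same-strand-overlap decoy is placed in the shared span of an
antisense gene pair chosen so that the tie-break at distance 0 resolves
to the opposite-strand gene, making it fail only the overlap rule. The
annotation generator guarantees such pairs by relocating every sixth gene
to overlap the preceding plus-strand gene on the minus strand.

What the generator does **not** emulate: realistic genome composition
(repeats, isochores, GC structure), read-level sampling noise,
correlated replicate structure, motif degeneracy beyond the PFM itself,
and genes with alternative isoforms. Tests passing on this generator
therefore demonstrate the correctness and calibration of the *methods*
under their stated models — not performance on real chromatin data,
where signal-to-noise, peak-width variation and motif degeneracy are all
less favourable.

## Determinism and problem sizes

Every stochastic stage derives its stream from a single integer seed
(generators use fixed offsets from the configured seed so each stage is
individually reproducible); identical configurations produce
byte-identical output files. The test-suite and acceptance problem sizes
were chosen to estimate each property with comfortable margins while
keeping a full run in minutes: 2.5 × 10⁵ exhaustive contingency tables;
1000 PWM–sequence scan comparisons; 200 simulated datasets for
family-wise error and 50 for power (500 + 500 regions, 18 motifs); 50
datasets per EMT condition with 200-peak planted clusters; 1000 peaks
across 4 planted clusters for recovery. Larger runs change none of the
conclusions, only the confidence-interval widths.
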