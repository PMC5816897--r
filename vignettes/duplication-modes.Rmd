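---
title: "Classifying gene duplication modes and measuring duplicate divergence"
author: "ParalogModes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying gene duplication modes and measuring duplicate divergence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ParalogModes)
```

## The problem

Plant genomes accumulate duplicate genes through qualitatively different
mechanisms: whole-genome duplication (WGD, polyploidization), tandem
duplication (TD, unequal crossing over producing adjacent copies), proximal
duplication (PD, copies separated by a handful of genes), retrotransposition
(RD, an mRNA reverse-transcribed and reinserted, producing an intronless
daughter), DNA-based transposition (DD, relocation with introns intact) and
dispersed duplication (DSD, homologous pairs fitting none of those
patterns).  Because the generating mechanisms differ, the copies' subsequent
evolution — sequence divergence, expression divergence, promoter turnover,
gene conversion — differs too, and analysing duplicates without separating
the modes conflates those signals.

ParalogModes implements the full classification and divergence-measurement
pipeline for a single annotated genome plus one or more outgroup genomes,
together with a synthetic-genome simulator that plants every event type with
a machine-readable truth set, so each stage can be validated against ground
truth rather than against circular re-use of its own output.

## The classification procedure

Input is an all-vs-all within-genome protein homology table (BLAST m8
format; E ≤ 1e-5, top 5 subjects per query by default), the genome
annotation, and homology against the outgroup(s).  Genes on each chromosome
are ranked by position; rank difference, not base pairs, is the distance
used throughout.

1. **Collinear blocks.** Hits are chained in rank space per chromosome pair
   by a score-maximising dynamic programme (score = anchors −
   0.05·Σ rank gaps; strict monotonicity on both axes, per-step gap ≤ 25,
   minimum 5 anchors per block; chains extracted greedily in descending
   score).  Anchor pairs of intra-genome blocks are **WGD** pairs.  On the
   chromosome self-comparison, pairs separated by ≤ `max_gap` ranks are
   excluded from chaining: local duplicates otherwise chain along the rank
   diagonal into spurious blocks.
2. **Rank rules.** Remaining same-chromosome pairs with rank difference 1
   are **TD**; rank difference strictly between 1 and 20 (configurable;
   `proximal_rank`) are **PD**.
3. **Ancestral loci.** Focal genes that are anchors of focal-vs-outgroup
   blocks (union over outgroups) sit at ancestral loci.  A residual pair
   with exactly one ancestral member is a transposed candidate; the
   ancestral gene with the highest percent identity (ties: E-value, bit
   score, id) is the parent.  Parent with ≥ 3 exons and an intronless
   daughter → **RD**; both single-exon → set aside; otherwise → **DD**.
4. **Dispersed.** Everything left is **DSD**.
5. **Gene level.** Each gene takes the highest-priority mode among its
   pairs, WGD > TD > PD > RD > DD > DSD; genes without hits are singletons.

The proximal window default follows the operational rank-difference < 20
definition; the run report records the definition used so a 10-gene window
variant is an explicit, visible choice.

## Sequence divergence

Ka and Ks are estimated with the Nei–Gojobori (1986) pathway-counting
method after global protein alignment (BLOSUM62, affine gaps) back-translated
to codons.  Two conventions are fixed deliberately: substitutions creating a
stop codon count toward the nonsynonymous site total, so S + N = 3 × codon
columns exactly; and substitution pathways through stop-codon intermediates
are excluded from the difference averaging.  Proportions are corrected with
the Jukes–Cantor formula; pairs with a proportion ≥ 3/4 are flagged
saturated and their Ka/Ks left missing.  A model-averaged estimator over
many codon models would shift the Ks scale; every Ks window in the package
(recent WGD 0.15–0.25, ancient 1.2–1.5 by default) is therefore a
configurable parameter rather than a constant.

Ks distributions from successive WGDs are decomposed with a two-component
Gaussian mixture on log-Ks, fitted by a hand-rolled EM with ten seeded
restarts (quantile-split initialisation, jittered).  The per-iteration
log-likelihood is retained so the non-decreasing property is testable.
Values above `ks_cap = 5` are excluded as saturated.

## Expression and promoter divergence

Expression input is a genes × samples TPM matrix.  The expression threshold
is data-derived: the per-sample median TPM of intergenic regions, averaged
over samples; a gene is expressed if it exceeds that background in at least
one sample, and only pairs with both copies expressed are scored.  Pair
similarity is the Pearson correlation r across all samples jointly; the
divergence cutoff is the 95% quantile of r over 10,000 random non-duplicate
gene pairs.  A pair has diverged when r is strictly below the cutoff;
zero-variance profiles yield a missing r rather than 0.

Promoters are the 1000 bp upstream of the TSS (5′-most coordinate on the
gene's strand, truncated at chromosome ends).  Promoter similarity s_LS is
the fraction of positions covered by maximal exact shared substrings of
length ≥ 16 bp, averaged over the two sequences (a position is covered
exactly when some 16-mer window containing it occurs in the partner, so
coverage reduces to k-mer set matching); the shared-motif divergence is
d_SM = 1 − s_LS.  The published tool behind this statistic does not print
its exact formula, so coverage-by-shared-substrings is this package's
operational definition, with `min_len` exposed.  The conservation cutoff
s_LS ≥ 0.60 mirrors the null-quantile construction and both cutoffs can be
recomputed from data (`randomPairCutoff`).

## Gene conversion

For each duplicate pair with orthologs in the outgroup, a quartet (A, B,
A′, B′) is built; syntenic-anchor orthologs are preferred over best-hit
ones.  Because duplication predates the species split, conversion is
signalled by Ks(A, B) < min(Ks(A, A′), Ks(B, B′)).  Significance comes from
1000 codon-column bootstrap replicates, resampling columns with replacement
independently within each pairwise alignment (the resampling unit is a
deliberate choice; the source procedure does not state one), implemented as
multinomial column weights against per-column NG86 count profiles.  A pair
is called converted when the signal holds on the original data and in ≥ 95%
of replicates; saturated or undefined Ks values make the quartet
untestable.  Only whole-gene conversion is modelled — partial tracts are out
of scope.

## Enrichment

Term enrichment per mode uses the one-sided hypergeometric tail (identical
to Fisher's exact test with `alternative = "greater"`; implemented via
`phyper` so exhaustive verification against table enumeration is cheap)
with Benjamini–Hochberg correction at q < 0.05.  Terms are used as flat
labels without ontology propagation.  Family membership assigns a gene to
every family whose query hits it at E ≤ 1e-10, and per-family mode
composition tabulates gene-level modes within each family.

## What the simulator emulates — and what it does not

`simulateDuplicatome()` builds a multi-chromosome genome (default 2 × 300
genes, 100–300 random sense codons per CDS, 1–6 exons, ≥ 2.2 kb intergenic
gaps), applies a WGD by appending copies of each chromosome with per-gene
retention sampling (default 0.8), and plants the configured single-gene
events.  Sequence divergence is a uniform codon-substitution process:
proposals are uniform over positions and alternative bases, synonymous
changes are always accepted, nonsynonymous ones with probability equal to
the target Ka/Ks (0.3 by default), stops rejected, until the synonymous
change count reaches target Ks × synonymous sites.  The Jukes–Cantor
correction inside NG86 then recovers the target on average, which is the
estimator-recovery oracle used in the tests.  Planted divergences default to
Ks 0.2 for WGD pairs (a recent-WGD peak), 0.1 for young single-gene events
and 0.3 for dispersed pairs, with the outgroup at Ks 0.3 — inside the
windows the block-selection defaults expect.

Two design points deserve emphasis.  First, dispersed events are planted by
overwriting the CDS of a distant gene whose WGD copy was not retained with a
diverged copy of the source, so both members sit at ancestral loci — a new
insertion would satisfy the one-ancestral/one-novel transposed rule and be
mislabelled by construction.  Second, the emitted homology table contains
the true pairs (plus optional high-E-value decoys) rather than the output of
a search tool, which removes the aligner dependency and makes planted-truth
recovery exact.

The simulator does not model indels, transposable-element sequence,
GC-content heterogeneity, tandem arrays larger than two, read-level RNA-seq
noise, or partial conversion tracts.  Passing tests therefore demonstrate
the correctness of the procedures under the stated generative model, not
robustness to every artefact of real annotation pipelines.

Expression profiles are bivariate normal per pair around gene-specific
means (≈ 40–80 TPM, SD 10) with the pair's target correlation, floored at
zero; intergenic background rows are exponential with per-sample median
≈ 0.715, emulating a low-transcription background so the data-derived
threshold behaves like one estimated from real intergenic quantification.
Promoter pairs carry identical blocks (≥ 16 bp, default ≈ 50 bp) at shared
positions covering the target fraction of sites.

## Numerical choices and degenerate inputs

* Rank ties (equal starts) break by end, then id; ranks are a permutation
  of 1..n per chromosome by construction.
* Chain extraction stops when the best remaining chain has fewer than
  `min_block_size` anchors; a block whose anchors all lack finite Ks gets a
  missing mean rather than an error.
* EM variances are floored at 1e-8 on the log scale; single-component data
  fitted with k = 2 produce two near-identical components, reported, not an
  error.
* `smooth.spline` degrees of freedom are capped at the number of unique x
  values minus one, and the fit is evaluated on a fixed 100-point grid.
* All stochastic steps take explicit seeds; stage seeds are derived from the
  master seed so a single integer reproduces every table byte for byte.

## Problem sizes used in the test-suite

The reference recovery experiment uses 2 chromosomes × 300 genes with WGD
retention 0.8 and 20/20/10/10/20 planted TD/PD/RD/DD/DSD events; estimator
recovery uses 200 replicate pairs of 300 codons per Ks target; conversion
error control uses 200 quartets per condition at 1000 bootstraps; the
mixture check uses 1000 Ks values.  These sizes give Monte-Carlo error
comfortably inside the asserted tolerances while keeping the default
check fast on a laptop.

## Known limitations

* The Jukes–Cantor correction is undefined once a difference proportion
  reaches 3/4, so NG86 saturates at high divergence; the ancient-WGD window
  (1.2–1.5) sits below saturation, but the estimator shows a positive bias
  there under the uniform substitution process, which the recovery tests
  tolerate explicitly (mean within ±15% of target).
* Chance collinearity of unrelated single-gene duplicates can occasionally
  phenocopy a short block and relabel a handful of RD/DD/DSD pairs as WGD;
  with default parameters this affects ≲ 2% of genes in simulation and is
  the main reason gene-level recovery is asserted at ≥ 95% rather than
  100% (TD/PD/WGD themselves recover at 100%).
* The transposed-parent rule relies on outgroup synteny; genomes without a
  usable outgroup reduce the cascade to WGD/TD/PD/DSD with a warning.

## A minimal run

```{r example, eval = FALSE}
report <- runPipeline(list(
    simulate = list(
        n_chroms = 2L, genes_per_chrom = 120L,
        n_events = c(TD = 8L, PD = 8L, RD = 4L, DD = 4L, DSD = 8L),
        seed = 11L
    ),
    out_dir = "run1",
    params = list(seed = 11L)
))
report$stages$classification$gene_mode_counts
report$stages$recovery$gene_mode_accuracy
```
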