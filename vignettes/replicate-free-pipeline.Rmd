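---
title: "Methods: differential analysis of a replicate-free two-genotype transcriptome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential analysis of a replicate-free two-genotype transcriptome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ucptx)
```

## The design this package serves

ucptx implements the statistics of a common but awkward experimental design:
a single pooled wild-type RNA-seq library compared against two independent
transgenic overexpressor (OE) lines, each also a single pooled library. There
is no within-genotype replication, so dispersion-estimating DE models
(DESeq2, edgeR, limma-voom) are not applicable; instead, each OE library is
compared with the WT library by a two-proportion test on read counts, and the
two OE lines — independent transformation events showing the same phenotype —
act as each other's biological replicas through an intersection rule: only
genes called in the same direction in both comparisons count as differentially
expressed. The downstream layers (GO enrichment, pathway scoring, metabolite
selection, qPCR concordance) are the standard companions of such a study.

## Gene-level model

**RPKM and normalization.** Expression is reads per kilobase per million
library reads. RPKM removes length and depth effects but leaves
distributional differences between libraries, so samples are quantile
normalized before fold changes are computed: every column's sorted values are
replaced by the across-sample mean of sorted values (ties averaged). The
implementation delegates to `limma::normalizeQuantiles()`; the postconditions
(identical sorted columns, preserved within-column ranks) are property-tested.

**The test runs on counts, the fold change on normalized expression.** The
pooled two-proportion Z-statistic is only defined on count proportions, so
`call_degs()` applies it to raw counts with the library totals, while the
fold-change threshold is applied to the quantile-normalized RPKM. Stated
cutoffs: `|log2FC| >= 1` (boundary inclusive) and raw two-sided `p <= 0.001`.
The p-values are deliberately *not* multiplicity-adjusted at this stage —
the stringent raw cutoff plus the across-line intersection is the error
control of this design; BH adjustment lives in the enrichment layer.

**Zeros.** Genes with zero counts in both compared libraries carry no
information for the proportion test and are excluded from testing. For fold
changes, a pseudo-count of 1 expression unit is added to *both* sides only
when one side is exactly zero (`log2_ratio()`), keeping the ratio finite
without perturbing well-supported genes. The same policy is reused verbatim
for the EC-level fold changes so the two layers cannot disagree.

**Library totals.** Column sums of the count table are the default `N`;
`read_count_table(totals =)` accepts externally determined totals (e.g.
total mapped reads including features outside the table) since either
convention occurs in practice and the choice is not recoverable from a count
table alone.

## GO enrichment and category summaries

Enrichment of the up- and down-regulated common-DEG sets is the exact
hypergeometric upper tail against the expressed-gene universe
(`stats::phyper`; an enumeration oracle checks it exhaustively for all
universes up to 25 genes), BH-adjusted, flagged at adjusted `p < 0.05`.
Two choices worth making explicit:

* **No GO-graph propagation.** A gene annotated with a descendant term does
  not implicitly carry its ancestors; enrichment is on the literal term sets
  of the annotation file. Propagation would require an ontology snapshot and
  silently changes every `K`; users who want it should propagate their
  annotation before reading it in.
* **No minimum term size.** Terms with a single carrier in the universe are
  still tested; BH adjustment handles the multiplicity.

Category summaries (`summarize_go_categories()`) report per-term transcript
counts and percentages of the selected set **truncated** (toward zero) to two
decimals. Truncation, not rounding, is the convention of the published
category histograms this mirrors: 15/239 = 6.276% prints as 6.27, and
66/577 = 11.438% as 11.43 — values a rounding rule cannot produce. A small
epsilon (1e-9) guards exact decimal boundaries against binary floating-point
representation.

## The resampling pathway Z-score

The pathway layer asks whether the enzymes of a pathway moved together. Each
EC number inherits the unweighted mean log2 fold change of its coding genes;
pathways with at least five fold-change-bearing ECs are retained (below five,
a mean over ECs is too noisy to interpret). For a retained pathway of `k`
ECs, the observed mean fold change is compared with the means of random
k-subsets drawn from the pool of ECs, giving

```
Z = (observed − mean(null means)) / sd(null means),   p = 2·Φ(−|Z|)
```

Design choices, each genuinely open:

* **The pool is the union of distinct mapped ECs over all retained
  pathways.** An EC belonging to several pathways enters the pool once;
  weighting by pathway multiplicity would make the null depend on pathway
  bookkeeping rather than on enzyme regulation.
* **Sampling is without replacement within a set; sets are independent.**
  With replacement within a set would allow degenerate subsets that no real
  pathway could be.
* **The p-value is normal-theory from Z, with the empirical rank p reported
  alongside** (`p_empirical`, the `(1+r)/(1+n)` estimator). With the default
  100 sets an empirical p cannot resolve below ~0.01, while the Z-score is
  reported to finer precision; the normal approximation of a mean of five or
  more fold changes is adequate and both numbers are in the output so the
  reader can compare.
* **`n_sets = "exhaustive"`** enumerates every k-subset when the pool is
  small; the test suite uses this to check the sampled statistic against an
  exact C(8,5) null.

Degenerate cases are defined, not patched: if the null sd is zero and the
observed mean equals the null mean (a constant pool), Z = 0 and p = 1; if the
sd is zero otherwise the pool is broken and the function errors. A pool not
larger than `k` cannot produce a null and errors.

Null calibration is part of the acceptance suite: pathways drawn uniformly
from their own pool flag `p < 0.05` at a rate measured within [0.03, 0.07]
over 2,000 simulated pathways — slightly liberal tails are expected because
the null sd is estimated from 100 draws.

## Metabolite statistics

The scaling chain is median normalization, then log10, then Pareto scaling,
in that order (the chain is not commutative and a test asserts a permuted
chain differs). Median "centering" of raw intensities is implemented as
*division* by the sample median, the row-normalization convention of the
web portal this chain mirrors: subtraction can produce non-positive values
that the subsequent log10 step cannot accept, so division is the only
reading under which the stated chain is well defined. Pareto scaling divides
the centred column by the square root of its standard deviation, leaving
each column with mean 0 and variance equal to its pre-scaling sd (property
tested to 1e-9).

Volcano selection combines an unpaired equal-variance two-sided t-test on
the scaled values with a fold-change criterion computed on the *raw* group
means (the scaled values are dimensionless and centred, so a fold change
there would be meaningless). The fold-change threshold of the original
volcano is not stated anywhere; the default is 2, the common portal default,
and it is configurable — so the headline "two significant metabolites"
behavior is emulated on synthetic data rather than reproduced.

## qPCR concordance

Relative expression is `2^−ΔΔCt` with an assumed ideal amplification
efficiency of 2 (no efficiency values being available, the comparative-Ct
default), the reference gene measured in every sample and the WT as
calibrator. Concordance correlates RNA-seq log2 fold change against qPCR
log2 relative expression — both log-scale effect measures against the same
WT baseline; correlating mixed scales (linear fold vs log) would build in
curvature that the Pearson coefficient penalizes spuriously.

## What the simulator emulates — and what it does not

`simulate_counts()` generates the three-library design directly: long-tailed
log-normal baseline abundances scaled to the library size (default 5×10^5
reads, within the 10^5–10^6 range typical of the MiSeq libraries this design
uses), negative-binomial counts, and a spiked fraction of genes (default 5%)
whose means are multiplied by `2^±de_log2fc` identically in both OE samples.
Gene lengths are uniform on 197–5386 bp, the contig-length range of a
short-read de novo assembly. Defaults of 2,000–5,000 genes keep test runs in
seconds; they are study-condition choices, not statements about real
transcriptome sizes (the assembly this mirrors had ~34k contigs).

Overdispersion deserves a note: the real experiment has no replicates, so
its test is exactly a Poisson-proportion comparison, and any extra-Poisson
variation between libraries inflates its false-positive rate. The simulator
therefore defaults to negative-binomial counts (`dispersion = 0.1`) to show
that anti-conservativeness honestly — the worked example calls ~150 common
DEGs where 100 were spiked — while the null-calibration tests use
`dispersion = 0` (Poisson), where the p ≤ 0.001 rate is verified to sit
inside its binomial band. Passing tests on this generator demonstrate the
arithmetic and the operating characteristics under the stated model; they do
not demonstrate that a single-library contrast controls errors on real
overdispersed tissue, which no statistic computed from these data could.

`simulate_annotations()` attaches background GO terms at random (Poisson
mean 2 per gene), spikes one extra term onto true DE genes with probability
0.9, and maps the ECs of one pathway onto up-regulated spiked genes so the
pathway layer has a true positive with known per-EC shifts; all other ECs
map to null genes. `simulate_metabolites()` uses log-normal intensities
(baseline log10 levels uniform on 2–5, within-group sd 0.15) with a default
panel of 125 metabolites, 6 samples per group and 2 metabolites shifted by
0.6 log10 units — a size at which the volcano criteria recover both true
positives while the false-positive count stays within its binomial bound.
`simulate_qpcr()` constructs Ct values whose expected `2^−ΔΔCt` *equals* the
simulated fold change (one cycle per doubling, reference gene constant), so
at zero noise the ΔΔCt chain is checked exactly, and concordance degrades
monotonically as Ct noise grows.

None of the generators simulate reads, mapping ambiguity, annotation error,
or correlated metabolite blocks; they are ground-truth harnesses for the
statistics, not data look-alikes.

## Numerical and testing notes

* All randomized functions take explicit seeds and are bit-reproducible for
  a fixed seed.
* `kal_z_test()` is checked against an independent pooled two-proportion
  computation (`prop.test` without continuity correction, signed square root
  of X²) to 1e-10 over 1,000 random inputs.
* Problem sizes in the test and acceptance runs — 2,000 genes × 20 seeds for
  null calibration, 2,000 resampled null pathways, 125-metabolite panels —
  were chosen to put each measured rate inside usefully narrow binomial
  bands while keeping the full suite in a few minutes on one core.
* Known limitation: with very small counts the proportion test's p-values
  are discrete, so the null p ≤ 0.001 rate is a band, not a point; the
  calibration test uses exact binomial bounds rather than a point equality.
* The sign convention is fixed throughout: positive Z / positive log2FC
  means higher in the OE line; negating every fold change negates every
  pathway Z and swaps the up/down lists (tested).
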