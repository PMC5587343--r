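---
title: "Screening for passage-dependent methylation drift: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening for passage-dependent methylation drift: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methdrift)
```

## The problem

Human pluripotent stem cells accumulate selectable changes during prolonged
culture. Beyond the well-known genetic routes (trisomies of chromosomes 1,
12, 17, X; focal amplifications), promoter CpG-island hypermethylation can
silence a gene heritably — an epimutation — and be selected for exactly like
a loss-of-function mutation. `methdrift` screens matched methylation and
expression profiles of cell lines sampled at known passage numbers for
genes showing this signature: methylation that rises with time in culture,
coupled with loss of expression.

## The screening model

Samples are split by passage *p* into a low group (*p* ≤ 25) and a high
group (*p* ≥ 50, the *strict* design; the *permissive* design takes
*p* > 25 as high when very-high-passage samples are scarce — e.g. for
validation compendia assembled from public expression profiles). For every
gene-linked methylation probe the screen computes

* Δβ = aggregate(β, high) − aggregate(β, low),
* FC = aggregate(2^e, low) / aggregate(2^e, high) for the linked gene's
  expression e (FC > 1 means downregulated at high passage),
* Pearson r between β and e across all matched samples,

and flags candidates by Δβ > 0.2 and FC > 1.5, both strict. The cutoffs are
parameters (`delta_beta_cutoff`, `fold_cutoff`); their defaults correspond
to changes large enough to be rare genome-wide (a few percent of probes at
most in typical compendia). Strictness at the boundary matters only for
constructed data but is fixed here for determinism.

Two aggregate conventions circulate for this kind of screen: differences of
group means, and ratios of group medians. We default to **means for Δβ**
and **medians (of linearized values) for the expression fold**, and expose
both (`beta_aggregate`, `expr_aggregate`); the two agree exactly on
symmetric noise-free data, which the tests assert. When a gene carries
several expression probes, the probe with the highest mean expression
represents the gene — the most reliably measured signal. The
methylation–expression correlation is computed across *all* matched
samples, not within groups: the quantity of interest is the coupling along
the whole passage trajectory. Probes with fewer than `min_samples = 3`
usable samples in either group are reported but marked unevaluable.

### Pre-screen filters

Sex-chromosome probes are removed (X inactivation and Y dosage make their
methylation/expression uninterpretable in mixed-sex compendia). A gene is
dropped when it is unexpressed in more than 80% of samples in *both*
groups; "unexpressed" is operationalized as sitting exactly at the
expression floor, since flooring is the only notion of non-expression the
pipeline introduces. The floor itself is a config parameter (default log2
value 4 for the simulated arrays, 0.5 linear for FPKM data): public array
pipelines differ in their noise thresholds, so no universal constant is
claimed. Methylation probes missing more than 50% of values in either
group are dropped; remaining missing values are excluded pairwise
everywhere downstream.

β matrices coming from raw exports can be rescaled against control DNA:
`range_scale_betas` maps the unmethylated control to 0 and the fully
methylated control to 1, clips to [0,1], flags probes whose control
dynamic range is below 0.2 as unusable, and *reports* (never enforces) how
far a half-methylated control lands from 0.5 — a calibration diagnostic,
not a validity condition.

## Sample QC: simplified e-karyotyping

Chromosome-scale copy-number changes shift the expression of hundreds of
adjacent genes by roughly the dosage ratio (log2 1.5 ≈ 0.585 for a
trisomy). `ekaryotype_scan` centers each gene at its cross-sample median,
orders genes by position, and slides a 100-gene window (step 1) along each
chromosome; a sample fails when any window mean reaches 0.3 in absolute
value, or when the MAD of its centered values reaches 0.8 (a noisy
transcriptome). The published e-karyotyping method this emulates has its
own tuned parameters that are not reproduced here; ours are package
defaults chosen so that a 100-gene window averages array noise
(sd ≈ 0.5 log2) down to ≈ 0.05 — six standard errors below the trisomy
signal — while the noise threshold sits at roughly the 99th percentile of
simulated diploid dispersion under the generator's default noise model.
All three are configurable. Chromosomes with fewer genes than the window
are skipped with a warning rather than scanned with an unstable window.

## Methylation dynamics

`fit_methylation_slopes` fits per-probe OLS of β on passage and keeps the
slope (β units per passage): near zero for stable probes, positive for
progressive gain. The fit is closed-form on masked sums, so missing values
cost nothing; probes with fewer than 3 samples or fewer than 2 distinct
passages get `NA`. Each sample is one observation — no pooling of
replicates of a line — because replicate structure is rarely annotated in
public compendia. `rank_slopes` ranks gene-linked probes by descending
slope. Ties share the *worst* (largest) position — conservative for any
"top x%" claim — while the deterministic row order breaks ties by probe id.
Percentile is 100·rank/universe, so "top 1%" means percentile ≤ 1.
`variability_ranking` does the analogous descending ranking of unbiased
cross-sample variances (log2 scale for expression, raw β for CpG-island
methylation probes) and tests candidate enrichment in the top decile with
the hypergeometric machinery below.

## Concordance statistics

**Overlap.** `intersect_candidates` computes the upper-tail hypergeometric
probability P(X ≥ k) of the observed intersection of two candidate sets.
The tail is evaluated with `phyper(log.p = TRUE)`, so genome-scale screens
whose overlap probabilities underflow doubles (10⁻²⁰ and beyond) still get
an exact `log10_p`. The universe is a required argument: the defensible
choice, used by `run_pipeline`, is the number of genes evaluable on *both*
platforms after filtering, and the run report records it. Tests verify the
tail against exact enumeration on small universes and an independent
log-gamma implementation to 6 significant digits.

**Clustering.** Samples are clustered with complete linkage on
1 − Pearson r (or Euclidean distance); the "two main branches" are the two
children of the dendrogram root — no tree-cut height parameter exists, by
design. Their passage composition is tested with a two-tailed Fisher exact
test (sum of the probabilities of all tables with the observed margins not
exceeding the observed table's probability), verified against full
enumeration for every 2×2 table up to n = 20. A degenerate margin (all
samples one group) reports p = 1 with a warning instead of failing, so
stratified runs on unbalanced strata stay usable. `stratified_clustering`
repeats the analysis within sample strata (sex, by default) to show the
separation is not an artifact of sample composition.

## Validation-side computations

`validate_expression_compendium` applies a two-sided Wilcoxon rank-sum
test per expression probe of each candidate gene (permissive grouping by
default), Benjamini–Hochberg across tested probes, and calls a gene
validated when some probe has q < 0.05 *and* a lower high-passage mean.

`de_filter` implements the knockdown filter: floor at 0.5 FPKM, then mean
fold > 2 and both knockdown-replicate folds > 1.5, direction-consistent.
"Fold over the two controls" is ambiguous between each-replicate-vs-control-
mean and all-four-pairwise comparisons; the former is the default, the
latter available as `replicate_mode = "each_vs_each"` (and is the exactly
arm-symmetric variant, which the tests exercise).

`mcrbc_quantify` converts McrBC-digestion qPCR into methylation calls:
ΔCt = Ct(digested) − Ct(mock); a digested reaction that fails to amplify
while the mock amplifies is complete digestion, i.e. methylated; a failed
mock makes the sample unevaluable. The default call threshold of 3 cycles
(~8-fold template loss) is a package choice — ΔCt is usually plotted, not
thresholded — and is a parameter.

## The synthetic-data generator

`simulate_dataset` emulates the statistical structure the screen assumes,
with every planted effect recorded as ground truth:

* CpG-island baselines from Beta(2, 18) (mean ≈ 0.1), open-sea baselines
  from Beta(17, 3) (mean ≈ 0.85) — the bimodal β landscape of promoters vs
  gene bodies, with support guaranteed in [0,1];
* drift genes: island probes follow β(p) = clip(β₀ + 0.004·p) plus
  N(0, 0.05) measurement noise, re-clipped; open-sea probes stay flat;
* expression: gene baselines N(8, 1.5) on log2 scale with N(0, 0.5) noise;
  a drift gene's expression drops in proportion to that sample's *realized*
  island β gain, scaled so the expected loss between the strict passage
  groups is 3 log2 units (8-fold) — methylation–expression correlation is
  therefore negative by construction, and exactly −1 in noise-free runs;
* design: 6 lines × passages {5,10,15,20,25,70,80,90,100,110} → 30 low- and
  30 high-passage samples, populating both group designs; mean passage
  spread 75 × slope 0.004 gives a planted group Δβ of 0.30;
* optional trisomy-like samples: one autosome (default "12", a recurrent
  hPSC trisomy) shifted by log2(1.5) in expression; drift genes are kept
  off that chromosome so the two planted effects never mix;
* `simulate_second_platform`: fresh samples, fresh noise, distinct probe
  ids, sharing exactly `round(overlap_fraction · n_genes)` genes with the
  first platform (drift genes always shared);
* `simulate_knockdown`: a two-replicate FPKM table where a chosen number
  of genes passes the DE filter and a band of boundary genes sits just
  below each rule (mean fold 1.95; one replicate fold 1.4).

Defaults were chosen once to represent a realistic compendium of this
kind — passage ranges as reported for long-term hPSC culture, array-like
noise levels, effect sizes large enough to be biologically meaningful —
and are the conditions under which the acceptance checks run.

What the generator does **not** emulate: probe-level Infinium chemistry
(type I/II bias), cross-reactive or SNP-affected probes, batch effects,
cell-line relatedness (samples are exchangeable within a line), copy-number
effects on *methylation*, and realistic covariance among neighboring genes.
Passing tests therefore demonstrate correctness of the computations and
recoverability under the stated generative model, not robustness to every
artifact of real array data — inputs are assumed normalized (the pipeline
deliberately contains no SWAN/RMA/batch steps).

## Numerical and design choices

* Determinism: every generator call runs in a private RNG stream seeded
  from its config and restores the caller's RNG state; the second platform
  derives its stream from seed + 10⁶. `run_pipeline` reruns byte-identical
  for identical config + seed.
* The hypergeometric tail and its log10 are the only quantities computed
  in log space; everything else is safe in doubles.
* Tie-breaks: ranking ties share the worst position (percentiles), and
  probe-id lexicographic order fixes row order.
* Degenerate inputs error early and name the offender: empty passage
  groups, constant profiles under Pearson distance, all-identical
  passages, universes smaller than the set union, malformed TSV cells.
* Chromosome names are accepted with or without a "chr" prefix and
  normalized to bare names; positions are 1-based (array-annotation
  convention).
* Package shape: rather than a single monolithic fit function, each
  analysis stage returns a small classed S3 object (`drift_screen`,
  `drift_slopes`, `ekaryo_scan`, `overlap_result`, `cluster_test`) with
  print/summary/plot/coef methods, and `run_pipeline` composes them — the
  screen is a pipeline of estimators, not one model, and this keeps every
  stage independently testable. Internals are base R; file interfaces are
  plain TSV/JSON. The orchestration layer is the R API itself plus
  `run_pipeline` over a declarative config; no shell binary is shipped.

## Problem sizes

The test suite validates the full default conditions (10,000 genes,
60 samples) across 10 generator seeds for the recovery, QC and
null-control properties, and uses smaller configurations (300–4,000 genes)
for structural and invariance checks. `scripts/acceptance.R` re-measures
the headline quantities at the default scale with 3–5 replicate seeds
derived from its `--seed`.

## Known limitations

* The overlap universe of any published two-screen intersection is rarely
  recoverable; reported overlap probabilities are only as meaningful as
  the universe supplied.
* The slope model is plain OLS per probe: no line-nested random effects,
  so pseudo-replication of heavily resampled lines inflates confidence in
  real data.
* The e-karyotype scan detects chromosome-arm-scale dosage shifts only; it
  is not a CNV caller and estimates no breakpoints.
* The screen's cutoffs are marginal (per-probe); no joint or region-level
  (DMR) model is fitted.
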