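---
title: "Methods: time-resolved phosphoproteomic analysis with phosphoflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: time-resolved phosphoproteomic analysis with phosphoflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phosphoflux)
```

## The design and its assumptions

`phosphoflux` analyses a paired two-condition phosphoproteomic time
course in insulin-secreting beta cells: for each time point (5, 30,
60 min of glucose stimulation) a matched control kept at resting glucose
is processed in the same multiplexed run, in five independent replicates.
The unit of quantification is the p-site — a specific phospho-acceptor
residue (S/T/Y plus position) on a protein, canonically written
`ACCESSION_S123`, with multi-phosphorylated features written
`ACCESSION_S519/S523` and treated as a single key. The paired design is
the central assumption: replicate *i* under high glucose is compared to
replicate *i* under low glucose at the same time point, which removes
shared run effects (e.g. phosphorylation drift during incubation in the
assay buffer) from every downstream statistic.

Input tables carry log2 quantitative values (a flag log2-transforms raw
intensities on read), a localization probability per site, and the
peptide sequence window. Three filters are applied on ingestion, in
order: localization probability >= 0.95; pairwise blanking, so that
within a time point the replicate indices with data are identical between
conditions (a pair with a missing member is dropped as a pair); and a
presence filter requiring at least two complete pairs per time point.
Missing values are never zero-imputed — zero is a legal log2 value.

## Differential regulation

For each p-site and time, the effect estimate is the mean of paired
differences `log2FC = mean(high_i - low_i)` and significance is a
two-sided paired t-test on those differences. A site is *regulated* iff
`p <= 0.05` **and** `|log2FC| > 0.3`. The two gates are deliberately
independent: a strongly significant site at log2FC 0.25 is not called.
The 0.3 gate equals a 23% change (`100*(2^0.3 - 1)` = `r
round(lfc_percent_equivalent(0.3), 1)`), and `lfc_percent_equivalent()`
exposes the conversion. Raw p-values are the calling criterion for
fidelity with the published analysis; a Benjamini-Hochberg column is
emitted for users who want FDR control. The unpaired (Welch) variant is
available via `paired = FALSE` because the source tables' legends are
ambiguous between paired and unpaired; paired is the default as it
matches the stated design.

Degenerate variance is handled explicitly rather than propagating NaN:
all differences exactly zero gives p = 1; identical non-zero differences
give the smallest representable double as p plus a `degenerate` flag,
since the t statistic is unbounded there and the direction is certain
while the magnitude of evidence is not estimable.

Protein-level data (the non-enriched fraction) run through the same code
path keyed by accession; `reconcile_protein_level()` then reports, per
time, the fraction of p-site-regulated proteins that are also regulated
in total abundance — such sites are annotated protein-confounded because
their apparent phospho-change may be an abundance change.

## Trajectory clustering

Kinetic archetypes are found by clustering descriptive measures of each
regulated site's fold-change trajectory, not the raw series. Design
choices here, in order of consequence:

* **Baseline augmentation.** The three log2FC values are prepended with
  an exact 0 at t = 0: before stimulation the glucose-relative change is
  zero by construction. This gives four points, so second-difference
  measures are well defined. Clustering the raw three-point series
  instead was evaluated on planted-archetype data and recovers the
  transient class markedly worse than the baseline-augmented series, so
  augmentation is the default.
* **The measure catalogue** covers level (mean, SD, CV, range), change
  (total, per unit time, relative to first and to mean), trend
  (least-squares slope, R^2), first differences and second differences
  with their ratios. First differences are computed per unit time
  (interval slopes) because the grid is uneven — a 5-min and a 30-min
  interval are not comparable steps — and second differences are
  differences of consecutive interval slopes, so a linear-in-time
  trajectory has exactly zero second differences. The *mean of second
  differences* is computed but excluded from clustering by default; the
  exclusion is specified by name, not index, so it survives any
  reordering of the catalogue.
* **Factor reduction.** Measures are standardized; principal factors
  with eigenvalue > 1 are retained and varimax-rotated.
  `stats::varimax()` is restarted from a fixed set of random orthogonal
  rotations because its identity start can be a stationary saddle for
  symmetric loading patterns. Two routes leave the reduction:
  `select_informative_measures()` names the top-loading measure per
  factor (useful for reporting and interpretation), while the pipeline
  clusters on the rotated **factor scores**. The scores aggregate each
  correlated measure block into one denoised axis; on planted-archetype
  benchmarks the score space separates the early-sustained and
  intermediate classes reliably, whereas single representative measures
  (e.g. range instead of mean as a level proxy) intermittently merge
  them.
* **Clustering** is k-medoids (PAM) under the Manhattan distance
  (k = 4 by default), the 1-norm analogue of k-means; 50 seeded random
  restarts on top of the deterministic PAM build keep reruns
  bit-identical. Cluster labels come from an onset rule on the cluster
  mean trajectory: timing is the first grid point where |mean| reaches
  50% of its peak (early / intermediate / late), an early cluster whose
  final value has fallen back within 50% of peak is early-transient, and
  direction is the sign at onset. An onset-on-values rule is used rather
  than largest-step timing because a transient profile's recovery step
  can rival its onset step under noise, which mislabels the class.

Heatmap row ordering uses complete-linkage hierarchical clustering on
Gower dissimilarities (`cluster::daisy`), which for all-quantitative
input is the Manhattan metric after per-variable range scaling;
zero-range variables drop out. Subtree orientation is canonicalized by
the leaves' dissimilarity row sums, making the displayed order a function
of the dissimilarity matrix alone.

## KSEA

Substrate groups are built by joining quantified p-sites to a
kinase-substrate table on uppercase gene symbol plus site position
(accession-exact mode available; the gene-symbol default exists because
cross-species joins — a rat dataset against human-centric databases —
rarely share accessions). Motif groups match a regular expression against
the +/-7-residue window, accepted only when a match ends at the window
centre, i.e. at the phospho-residue. A multi-site feature joins a group
once, no matter how many of its sites match.

The enrichment score for a group of size m is
`z = (s_bar - p_bar) * sqrt(m) / delta`, where `s_bar` is the mean
substrate fold change, and `p_bar` and `delta` are the mean and SD of
*all* quantified fold changes in that replicate and time point. The
background is the full dataset, not the regulated subset, because the
score asks whether an enzyme's substrates move relative to everything
measured. z is exactly invariant to affine transforms of the fold
changes, and the full background scored as a group gives z = 0. The
two-sided normal p neglects the finite-population correction
`sqrt((N-m)/(N-1))` of subset sampling, so it is slightly conservative
for small backgrounds; `ksea_permutation_p()` provides the exact
subset-resampling reference, and at dataset scale (thousands of
quantified sites) the two agree within Monte-Carlo error. Significance is
reported only for m >= 2 — with site-level matching many groups are tiny
and a one-substrate z is a single site's standardized residual, not an
enrichment. BH adjustment is applied across enzymes within each
(time, replicate).

Replicate scores are averaged per enzyme and time; scores beyond +/-2
are highlighted, and activity classes assign each enzyme a direction and
an onset (early/intermediate/late) from its largest consecutive score
change with an implicit 0 before stimulation. For phosphatases the
activity interpretation is inverted: hyper-phosphorylation of a
phosphatase's substrates means the phosphatase is *less* active.

## Enrichment and respirometry

Gene-set over-representation is the upper-tail hypergeometric probability
`P(X >= k)` with BH FDR across the collection. The universe defaults to
the quantified proteins, not the genome: enrichment against a whole-genome
universe would mostly re-discover what is detectable in beta cells. The
cross-time ranking scores each set by the SD of −log10 p across the
per-time enrichments (a set missing in a group counts as p = 1, flagged)
and truncates to 30 terms for display.

Respirometry traces are reduced to a basal rate — the arithmetic mean OCR
over pre-injection cycles — and a signed trapezoidal integral of
OCR − basal from the injection to trace end, on actual timestamps so
skipped cycles do no harm. Below-basal excursions are not clipped;
inhibition is information. Treatment effects are folds versus the mean
mock AUC with Welch t-tests across wells, and any compound whose
pre-stimulus rates already differ from mock (Welch p < 0.05) is flagged,
since its response fold conflates basal and stimulated effects. The AUC
window runs to trace end by default; a fixed endpoint is configurable as
the choice is not dictated by the assay.

## The synthetic generator

`generate_phospho_dataset()` emulates the study conditions: paired
low/high log2 values at 5/30/60 min in five replicates, planted enzymes
with disjoint substrate groups (m = 10 by default), archetype effect
profiles that are piecewise-constant on the time grid (early-sustained
= effect at all times, early-transient = 5 min only, intermediate =
30 and 60, late = 60 only), alternating up/down directions, effect size
0.8 log2 and homoscedastic Gaussian noise of SD 0.2 on the paired
difference — numbers chosen to mirror the regulated effect sizes and
replicate scatter typical of TMT phosphoproteomics at this depth. Null
sites receive no effect, so their paired differences are exactly
Gaussian and the t-test's type-I error is measurable. A configurable
fraction of regulated proteins is co-shifted at the protein level to
exercise the reconciliation step.

What the generator does *not* emulate: intensity-dependent variance
(available as an option but off by default), peptide-level missingness
beyond missing-completely-at-random, shared-peptide ambiguity, batch
effects, and compositional TMT artefacts such as ratio compression.
Passing recovery tests therefore demonstrates correctness of the
statistical machinery under the stated model, not robustness to every
real-data pathology.

Benchmarks used in the test suite and acceptance script (sizes chosen to
keep the full suite in minutes on one CPU): type-I calibration on 2000
null sites; enzyme-direction recovery over 20 seeds at effect 0.8, noise
0.2, m = 10, five replicates (sign concordance >= 95%); archetype
recovery over 20 seeds at trajectory noise one tenth of the effect,
summarized as the mean adjusted Rand index (>= 0.9; single seeds can dip
to ~0.89, i.e. two to three ambiguous assignments out of 48, which is
inherent to measure-space clustering at that noise); permutation
validation of the KSEA normal p at a 3000-site background.

## Numerical conventions

P-values of 0 are capped at −log10 p = 300 in volcano exports. Ratios
with zero denominators yield flagged missing values and such measures are
dropped before factoring. k-medoids ties are resolved by the seeded
restart with the lowest total cost; identical seeds reproduce every
assignment bit-for-bit. Config files are flat key/value text; every
output of the pipeline carries the configuration hash in its run log.

## Known limitations

Site-level database matching is conservative: sites that moved position
between species orthologues will not join their group. The KSEA variant
implemented is the mean-based z-score; delta-count and median variants
are out of scope. No moderated-variance (empirical Bayes) test is
offered; with five replicates the paired t is serviceable but
lower-powered than shrinkage estimators. Enrichment p-values depend
strongly on the universe choice, which is surfaced as an explicit
parameter rather than hidden.
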