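# phosphoflux

Time-resolved phosphoproteomic signaling analysis for glucose-stimulated
insulin-secreting beta cells.

Pancreatic beta cells couple glucose metabolism to insulin secretion
through fast, time-structured phosphorylation signaling. `phosphoflux`
implements the downstream statistical analysis of a paired two-condition
phosphoproteomic time course — resting (2.5 mM) versus stimulating
(16.7 mM) glucose at 5, 30 and 60 min with five replicates per condition —
for researchers who quantify phosphosites (p-sites) with TMT-style
multiplexed MS and want to know *which* sites respond, *when* they
respond, and *which kinases and phosphatases* drive the response.

## What it computes

**Differential regulation.** For each p-site and time point, the paired
log2 fold change (high − low glucose, replicate-matched) and a two-sided
paired t-test. A site is *regulated* iff p ≤ 0.05 and |log2FC| > 0.3
(a 23% change, since 100·(2^0.3 − 1) ≈ 23). Cross-time overlap (Venn)
analysis and volcano exports follow, plus a reconciliation step that flags
regulated p-sites whose parent protein changes in total abundance.

**Trajectory clustering.** The log2FC series of every regulated site
(prepended with 0 at t = 0) is summarized by a catalogue of descriptive
measures (range, mean, SD, CV, total change, slope and fit, first- and
second-difference statistics and their ratios; the *mean of second
differences* is computed but excluded by default). Principal factors with
eigenvalue > 1 are varimax-rotated and the trajectories are partitioned by
k-medoids (k = 4) under the Manhattan (1-norm) distance, then labelled
with the four kinetic archetypes: early-sustained, early-transient,
intermediate, late.

**Kinase-substrate enrichment (KSEA).** Quantified p-sites are arranged
into substrate groups per kinase/phosphatase from a kinase-substrate
relationship table (PhosphoSitePlus/Signor-style export) and optional
phospho-motifs. For each enzyme, replicate and time point,

    z = (mean(substrate FCs) − mean(all FCs)) · sqrt(m) / sd(all FCs)

with a two-sided normal p (validated against a permutation null).
High z reads as kinase activation; for phosphatases the reading is
inverted. Replicate-averaged enzyme × time matrices, top/bottom-30
listings and direction/timing activity classes are produced.

**Gene-set enrichment.** Upper-tail hypergeometric over-representation of
regulated proteins against a GMT collection (universe = quantified
proteins), with BH FDR, and a cross-time differential ranking by the SD of
−log10 p across time points.

**Respirometry.** Oxygen-consumption traces (6-min cycles) are reduced to
a basal rate (pre-injection mean) and the signed trapezoidal *area under
the curve over basal* from glucose injection to trace end; treatment
effects are expressed as fold versus mock wells with Welch t-tests and a
flag for compounds that already perturb basal respiration.

**Synthetic data.** `generate_phospho_dataset()` and
`generate_ocr_plate()` produce ground-truthed inputs with planted enzyme
effects, trajectory archetypes and additive log-scale noise, so every
stage is testable without raw study data.

## Worked example

```r
library(phosphoflux)

sim <- generate_phospho_dataset(n_sites = 300, n_enzymes = 8,
                                m_per_enzyme = 10, effect_size = 0.8,
                                noise_sd = 0.2, seed = 42)
bundle <- run_time_course_analysis(sim$quant, run_config(),
                                   protein = sim$protein, ksdb = sim$ksdb)
bundle$overlap
#> <overlap_counts> sizes: t5=40, t30=41, t60=60 | common: 20 | union: 81 | shared: 24.7%
bundle$archetypes
#> # A tibble: 4 x 4
#>   cluster archetype       direction     n
#>     <int> <chr>           <chr>     <int>
#> 1       1 early-sustained up           22
#> 2       2 early-transient down         21
#> 3       3 intermediate    up           17
#> 4       4 late            down        21
head(bundle$activity_classes, 4)
#> # A tibble: 4 x 5
#>   enzyme class       direction timing       interpreted_activity
#> 1 ENZ01  kinase      positive  early        activated
#> 2 ENZ02  phosphatase negative  early        activated
#> 3 ENZ03  kinase      positive  intermediate activated
#> 4 ENZ04  phosphatase negative  late         activated
```

Of the 300 simulated sites, 80 carry planted enzyme-driven effects; the
pipeline calls 40/41/60 sites regulated at 5/30/60 min (false positives
at the nominal 5% are expected among the 220 null sites), 20 sites are
regulated at every time point (24.7% of the union of 81), the four
planted kinetic archetypes are recovered as the four clusters, and each
planted enzyme is classified with its planted direction and onset — note
`ENZ02`/`ENZ04` are phosphatases whose negative scores read as
*activation* under the sign inversion.

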