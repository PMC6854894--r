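---
title: "Methods: droplet calling, Poisson quantification and two-of-three panel scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: droplet calling, Poisson quantification and two-of-three panel scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trimeth)
```

## The problem this package addresses

Colorectal cancer (CRC) sheds DNA into the bloodstream. A small
fraction of the circulating cell-free DNA (cfDNA) of a patient —
often well below 1% — is tumour-derived (ctDNA), and it carries the
tumour's aberrant DNA methylation. A blood test for CRC can therefore
be built from a handful of CpG regions that are consistently
hypermethylated in CRC tissue yet essentially unmethylated in the
blood cells that dominate cfDNA. This package implements the complete
computational chain of such a test:

1. **Discovery filtering** of candidate CpGs on 450K-style β-value
   matrices (β = fraction methylated, in [0, 1]).
2. **Assay triage** through an ordered PBL → tumour-tissue → plasma
   funnel.
3. **Droplet digital PCR (ddPCR) calling**: a plate-wise threshold
   derived from a kernel density fit to a fully methylated positive
   control, additive normalization of test wells, and Poisson
   quantification of copies per well.
4. **Quality control**: bisulfite recovery, spike-in purification
   efficiency, lymphocyte-contamination flagging, and input planning.
5. **Panel scoring**: the locked two-of-three rule over the markers
   *C9orf50*, *KCNQ5* and *CLIP4*, with cohort sensitivity,
   specificity, stage stratification and per-marker ROC.

A synthetic-data module generates every input the chain consumes, so
all of it is testable without clinical samples.

## Discovery filtering

`filter_candidates()` operationalizes the discovery funnel on a
`beta_matrix`:

* **Blood exclusion.** A CpG is discarded when the fraction of
  peripheral-blood-leukocyte (PBL) samples with β above `pbl_beta_max`
  (default 0.05) exceeds `pbl_frac_max` (default 0 — markers must be
  blank in blood). The published funnel excludes "CpG sites methylated
  in blood cells" without printing its numeric cut; these defaults are
  configurable design choices, not reproductions.
* **CRC hypermethylation.** A CpG is discarded when fewer than
  `crc_frac_min` (default 0.97) of CRC samples exceed `beta_hyper`
  (default 0.35). The winning markers were described as
  hypermethylated (β > 0.35) in > 97% of tumours, which anchors both
  defaults.
* **Ranking.** Survivors are ordered by
  `crc_sensitivity × cross_cancer_specificity`, where cross-cancer
  specificity is one minus the mean hypermethylation fraction across
  the other cancer types in the matrix. The published ranking is
  stated only as "CRC sensitivity and specificity against other
  cancers"; the product is symmetric and monotone in both, and ties
  break by lower PBL positivity, then CpG id, so the ranking is
  deterministic. Normal-mucosa methylation is reported but never used
  for exclusion, since intestinal DNA is not found in healthy
  circulation.

`assay_funnel()` applies the printed triage cut-offs with their strict
inequalities: > 7.5% PBL positivity excludes, > 93% tumour-tissue
sensitivity retains, > 70% plasma sensitivity at 100% plasma
specificity selects. The funnel is order-dependent and idempotent on
its survivors.

## Droplet calling

Each ddPCR plate carries a fully methylated positive control whose
droplets form two fluorescence populations: empty (negative) and
template-bearing (positive). `fit_control_density()` estimates the
control's amplitude density with a Gaussian kernel at the **smallest
bandwidth for which the density has exactly two maxima and one
minimum**. The amplitude at that minimum is the classification
threshold for every well on the plate; the median of control droplets
below it is the normalization reference.

Numerical choices:

* The density is evaluated on a fixed 512-point grid spanning the
  amplitude range plus three bandwidths on each side (the `stats::density`
  convention). 512 points are ample at fluorescence scale and keep the
  search fast.
* The number of maxima of a Gaussian KDE is non-increasing in the
  bandwidth, so the smallest two-mode bandwidth is found by bisection
  between an under-smoothed bracket (> 2 maxima) and an over-smoothed
  one (≤ 2), over 1%–100% of the control amplitude standard deviation,
  to a relative tolerance of 10⁻³. The returned fit records the lower
  bracket so the tolerance can be audited.
* Discrete plateaus count as a single extremum at their midpoint.
* **Bimodality guard.** "Exactly two maxima" alone cannot reject a
  genuinely unimodal control: as smoothing increases, the discrete
  mode count can transiently pass through two via shallow ripples. The
  fit therefore additionally requires the density at the minimum to be
  below `dip_frac` (default 0.5) of the lower maximum. Real two-
  population controls have an essentially empty valley and pass by a
  wide margin; unimodal controls fail deterministically with a
  control-failure error naming the well.

`normalize_well()` shifts each test well additively so that the median
of its negative population (its droplets below the control-defined
minimum, before shifting) matches the control's. Wells in which fewer
than 5% of droplets fall below the minimum have no identifiable
negative population; they are flagged and left unshifted. The additive
(rather than multiplicative) correction is an interpretation of the
plate-alignment scheme, which matches negative-population medians
across wells; whether the original pipeline also corrected gain is not
stated, and gain drift is out of scope here.

`call_droplets()` counts droplets strictly above the threshold. Adding
a constant to every amplitude of a test well leaves its call unchanged
(exact shift invariance), because the shift estimate absorbs the
constant.

## Quantification and QC

With `N` droplets of which `P` are positive, Poisson partitioning of
molecules among droplets gives the per-well copy estimate

> c = −N · ln(1 − P/N),

implemented in `poisson_concentration()`. It is exact for the
partitioning model the simulator uses, strictly increasing in `P`, and
reduces to `c ≈ P` in the dilute limit. A saturated well (`P = N`) is
an explicit error instructing dilution — the formula diverges, and
silent clipping would fabricate a number. An optional interval from
the standard partition variance is available but off by default.

The QC operations are deliberately plain arithmetic with guarded
units: `bs_recovery()` (CF assay after/before bisulfite conversion, as
percent), `purification_efficiency()` (percent CPP1 spike-in
recovered), `contamination_flag()` (positivity of the B-cell IGH assay
flags, never excludes), `native_quantity()` (mean of the CF and Chr3
reference assays), and `copies_per_ml()` (copies per well over eluate
fraction and plasma volume). `plan_input()` computes the detection
limit implied by a fixed input — at 4500 copies per reaction one
methylated molecule corresponds to a ctDNA fraction of
100/4500 ≈ 0.02% — and checks the per-reaction input against the
5000-copy minimum used to justify negative calls.

## Panel scoring

`call_trimeth()` applies the locked rule: a marker is positive if it
detected **any** methylated DNA (strictly > 0 copies; no floor — this
is asserted in the tests), and a sample is positive if at least two of
the three markers are. `cohort_metrics()` turns a scored sample table
into sensitivity, specificity, stage-stratified sensitivity and
per-marker metrics.

* **Confidence intervals.** The published work does not state its CI
  method; this package defaults to Clopper–Pearson exact intervals
  (conservative and standard for diagnostic studies), with Wilson
  intervals available by configuration. Both exact percentages and
  half-up-rounded integer percentages (the printed style) are always
  reported.
* **Count-level input.** `samples_from_stage_counts()` and
  `positives_from_printed_pct()` let published stage-level counts flow
  through the same metrics path as sample-level data, which is how the
  pooled headline numbers are recomputed in `scripts/acceptance.R`.
* **ROC.** `marker_roc()` traces the empirical curve over all score
  thresholds with ties collapsed; the trapezoidal AUC then equals the
  normalized Mann–Whitney U statistic exactly, which the tests verify
  against an exhaustive pairwise oracle and an established
  implementation. Constant scores yield AUC 0.5 with a degenerate-score
  warning. The any-methylated-DNA operating point is annotated.
* **Medians.** `summarize_methylated_load()` reports group medians
  with seeded bootstrap percentile intervals (2000 resamples); the
  published work gives median CIs without a method, so the bootstrap is
  a documented package choice.

## The synthetic-data module

The generators define the study conditions under which everything is
tested; their defaults are fixed and documented here.

* **β matrices** (`generate_beta_matrix()`): marker CpGs draw from
  Beta distributions with mean 0.65 in CRC and 0.005 (tightly
  concentrated) in PBL, so that planted markers behave like the real
  ones — hypermethylated in essentially all tumours, blank in blood.
  Background CpGs have mean β 0.3 in every group and are blood-excluded.
  Beta distributions are parameterized by mean and concentration
  (shape1 = m·k, shape2 = (1−m)·k).
* **Droplet plates** (`generate_plate()`): molecules are assigned to
  droplets by actual Poisson partitioning (uniform multinomial
  assignment), the same model the concentration formula inverts, so the
  occupied fraction concentrates around 1 − exp(−k/N). Amplitudes are
  Gaussian around modes 2000 (empty) and 8000 (occupied) with spread
  300 — amplitude units are arbitrary fluorescence counts — and the
  droplet count defaults to 16,218, the observed median partition
  number. Per-well plate effects are additive offsets drawn from
  ±600; multiplicative gain drift is not simulated. **Rain** is modeled
  as partial amplification: a `rain_fraction` (default 1%) of the
  *occupied* droplets lands uniformly between the modes and is
  classified by the same threshold as every other droplet. Tying rain
  to occupied droplets reflects its physical origin and keeps the
  caller's recovery interpretable (a rain model that relabeled a
  percentage of *all* droplets would inject hundreds of false positives
  per well and swamp low-copy wells, which contradicts the observed
  behaviour of these assays at 8-copy inputs).
* **Cohorts** (`generate_cohort()`): cfDNA copies/ml are log-normal
  with median 968 and log-sd 0.85, spanning roughly the reported
  210–23,798 range over a few hundred samples. The number of
  methylated template molecules a reaction receives is Poisson with
  mean `input × tumour_fraction × marker indicator`, where the marker
  indicator is Bernoulli with the marker's tissue-level sensitivity
  (default 0.97 each). Stage-wise tumour-fraction distributions are
  **free parameters** — they are not reported in the source data — set
  to log-normal with median 0.05%, 0.1%, 0.2%, 0.5% for stages I–IV
  (log-sd 1.2), values in the range liquid-biopsy studies typically
  observe; they make detection rise with stage but are documented
  choices, not calibrated claims. Control false positives are
  independent across markers with rates 0.09, 0.05, 0.01 — the
  complements of the reported single-marker specificities 91%, 95%,
  99%. Both input designs are supported: fixed 4500-copy input, or a
  fixed 16 ml plasma volume whose per-reaction input varies with the
  sample's cfDNA level (bisulfite recovery 0.541).

All randomness flows from one master seed; `derive_seed(seed, tag)`
keys independent streams so modules can be simulated and tested in
isolation while a full pipeline run stays byte-reproducible.

### What passing tests do and do not show

The simulators emulate the *statistical* structure the analysis
assumes: bimodal amplitude clouds with additive plate shifts, Poisson
occupancy, group-structured β distributions, independent control false
positives. They do not emulate probe cross-hybridization, bisulfite
conversion failure, multiplex competition, amplitude gain drift,
correlated marker failures, or the biology linking tumour size to
shedding. Recovery of planted markers and unbiased copy estimates on
synthetic data therefore validate the *algorithms* under their own
model assumptions; they are not evidence about clinical performance.
The published patient-level AUCs and per-marker plasma sensitivities
cannot be recomputed without the clinical samples; only the
count-level arithmetic (pooled and per-cohort sensitivities,
specificity, stage stratification, detection-limit arithmetic) is
reproduced exactly, and the synthetic cohort — whose generator the
published rates seed — covers the rest at the property level.

## Problem sizes

The test suite and the acceptance script scale their simulations to
what the checks need statistically: 10,000 Monte-Carlo partitioning
replicates per occupancy level for the Poisson cross-check; 300–4000
replicate wells per copy level (16,218 droplets each) for caller bias;
100 random controls for the bandwidth-search contract; 100,000
synthetic controls for the two-of-three null; cohorts of 256 cases +
178 controls (the pooled published size) for end-to-end runs, with
2500–8000 droplets per well where full droplet resolution adds nothing.

## Known limitations

* The additive normalization and the per-well negative-median
  definition are interpretations of a scheme the source describes only
  graphically; a gain-correcting variant would need a different
  reference.
* The bandwidth search assumes mode-count monotonicity on the
  evaluation grid; pathological amplitude distributions that violate it
  numerically raise an explicit error rather than returning a fit.
* Duplex reactions are treated per channel with channel-matched
  controls; cross-channel compensation is not modeled.
* `positives_from_printed_pct()` assumes half-up rounding of printed
  percentages, and verifies its reconstruction re-prints identically.
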