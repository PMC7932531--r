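---
title: "Statistical determination of plantar risk regions from in-shoe pressure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical determination of plantar risk regions from in-shoe pressure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 5,
                      fig.height = 7)
library(qsfoot)
library(dplyr)
```

## The problem

Elevated plantar pressure during walking is a major, modifiable risk factor
for ulceration in the neuropathic diabetic foot. Custom-made insoles
redistribute ("offload") that pressure, and in-shoe pressure measurement is
the natural instrument for judging whether an insole actually works. The
commonly cited clinical target is to bring peak plantar pressure below
200 kPa.

A direct comparison of a single pressure map against 200 kPa ignores the
defining feature of gait: it is cyclic but never identical. Consecutive
steps differ in duration and in foot–floor loading, so the peak pressure in
any one location varies step to step. qsfoot implements a
quantitative-statistical treatment of that variability: risk regions are
determined not from one map but from the distribution of per-stance peak
pressures, cell by cell.

## The analysis pipeline

For one foot in one insole condition:

1. **Acquisition.** An in-shoe recording of many mid-walk steps. The raw
   device format is emulated by an open text dialect (PressureCSV) over an
   irregular layout of 99 unequal rectangular sensors sampled at 50 Hz in
   the 20–600 kPa measurement range. Values below the 20 kPa device floor
   are set to zero (the device cannot resolve them, and zeros keep per-cell
   maxima well defined); values above 600 kPa are clipped and counted.
2. **Resampling.** Sensor frames are resampled onto a regular 5 mm grid
   (0.25 cm² per cell). The default `area_weighted` scheme assigns each
   cell the overlap-area-weighted mean of the sensors covering it: it is
   well defined for unequal sensor sizes, preserves constant fields, and
   conserves total force wherever sensors tile the grid. A
   `centroid_bilinear` alternative interpolates sensor-centroid values and
   is defined for layouts whose centroids form a complete rectilinear
   lattice (true of the emulated insole); a general scattered-data scheme
   is deliberately out of scope.
3. **Stance segmentation.** A frame is "in contact" when at least 4 cells
   read ≥ 20 kPa; maximal contact runs lasting 10–120 frames (0.2–2.4 s at
   50 Hz) become stance phases, and the first and last stance of each
   walkway pass are trimmed so only steady mid-walk steps remain. Contact
   area rather than total force is used because the 20 kPa floor makes an
   area criterion robust to baseline drift.
4. **Peak maps and the MPPM.** Each stance yields a peak pressure map (the
   per-cell maximum over its frames); averaging these maps cell-wise gives
   the mean peak pressure map with its per-cell sample SD (n − 1
   denominator, feeding t statistics with n − 1 degrees of freedom).
5. **R-ROI determination.** Every cell of the MPPM — with no anatomical
   masking, so no region is excluded a priori — is tested against the
   200 kPa threshold. Connected risk cells (8-connectivity by default, so
   diagonal neighbours merge) form clusters, and the total risk area in
   cm² is the per-foot outcome measure.
6. **Redistribution and group analysis.** Step-paired cell-wise t-tests
   between two conditions map where an insole significantly lowers or
   raises pressure; per-foot areas across ≥ 2 conditions are compared with
   Friedman and pairwise Wilcoxon signed-rank tests under Bonferroni
   family control.

## The per-cell decision rule

The per-cell statistic is $t = (\bar{x} - 200)/(s/\sqrt{n})$ with $n - 1$
degrees of freedom. What exactly to do with it is a genuinely open design
point, because a cell mean slightly below 200 kPa with large step-to-step
SD is still clinically worrying. Four rules are implemented
(`rroi_config(rule = ...)`):

* `not_significantly_below` (default): a cell stays in the risk region
  *unless* the test shows its mean significantly below the threshold
  ($t < -t_{1-\alpha,\,n-1}$). This is the conservative reading: high
  variability keeps near-threshold cells flagged. It always contains the
  naive mask (see below).
* `significantly_above`: only cells proven above threshold.
* `direct_threshold`: the literature's plain $\bar{x} \ge 200$ cut-off,
  kept as the baseline the statistical rules improve on.
* `dispersion_band`: $\bar{x} \ge 200$ or deficit within
  $t_{1-\alpha,\,n-1} \cdot s$ (SD, not SEM) — an SD-banded variant some
  practitioners use.

Zero-variance cells are decided by direct mean comparison under every rule
(the $t$ limit). No multiple-testing correction is applied across cells by
default — each cell is read as its own clinical question — but any
`p.adjust` method can be switched on for sensitivity analysis.

A provable relation between the rules: the `direct_threshold` mask is a
subset of the `not_significantly_below` mask for every MPPM, since a mean
at or above threshold can never test significantly below it. The test suite
asserts this on 1,000 randomised maps.

In paired redistribution maps, a cell whose step differences are *all
identically zero* carries no evidence and is reported not significant,
while an identical non-zero shift on every step is treated as the
$t \to \pm\infty$ limit (significant). Both degenerate cases occur in
noise-free synthetic data.

## Power analysis: why 24 steps

The number of stances *is* the sample size of every per-cell test, so it is
set by a priori power analysis on the noncentral t distribution
(power $= P(T'_{n-1,\,d\sqrt{n}} > t_{\mathrm{crit}})$; both rejection
regions are counted for two-tailed tests, which matters at large effect
sizes):

* one-sample test against 200 kPa, one tail, d = 0.6, α = 0.05, power
  0.80 → **19 steps**;
* paired test between conditions, two tails, same d → **24 steps** (the
  binding requirement);
* recording 24 steps instead of 19 lowers the detectable one-tailed
  one-sample effect from d = 0.6 to **d = 0.52** (solved by bisection to
  |Δpower| ≤ 1e−6).

```{r power}
required_n_t(d = 0.6, alpha = 0.05, power = 0.8, tails = 1,
             family = "one_sample_t")
required_n_t(d = 0.6, alpha = 0.05, power = 0.8, tails = 2,
             family = "paired_t")
detectable_d(24, alpha = 0.05, power = 0.8, tails = 1)
```

Fewer steps produce a warning, not an error: the requirement is a power
property, and exploratory runs on short recordings remain useful.

For cohort design, a repeated-measures ANOVA power calculator
(noncentral F, within-factor parameterisation with explicit mean
correlation ρ and nonsphericity ε) is provided. Conventions for this
design differ across software — in particular the assumed ρ and the d→f
conversion — so both parameters must be stated explicitly; no single
published cohort size can be reproduced without knowing them. The +15%
rule of thumb (`nonparametric_inflate()`) sizes the nonparametric Friedman
analysis from the parametric requirement.

## Group-level statistics

Per-foot total R-ROI areas contain many exact zeros (feet whose risk
region an insole removes entirely — the "optimal" outcome), so they are
far from normal and full of ties. Consequently:

* the Friedman test applies midranks within feet and, in `approx` mode,
  the tie-corrected chi-square. Because the chi-square approximation is
  only good to a few hundredths in p even at 60 feet, the default computes
  the **exact** permutation p for up to three conditions: the statistic
  depends only on the rank column sums, whose exact null distribution is
  obtained by convolving the per-foot rank arrangements (doubled ranks
  keep midranks on an integer grid). The exact mode is verified against
  full $(3!)^n$ enumeration in the tests.
* pairwise Wilcoxon signed-rank tests drop zero differences and midrank
  ties (the classic policy; the policy is stated in the output since
  conventions differ across tools), using exact enumeration for n ≤ 25
  without ties and the continuity-corrected normal approximation
  otherwise. Family-wise control is Bonferroni: each of the three pairwise
  tests runs at α = 0.05/3 ≈ 0.016667.
* mean per-pair area differences are reported next to the rank-based
  p-values — note these are differences of means, not rank statistics.

## The synthetic gait generator

Because clinical recordings cannot be redistributed, every stage is
validated against a simulator with known ground truth. It models the
plantar field as a baseline load over a foot-shaped mask plus isotropic
Gaussian loci at the clinically typical sites (heel, five metatarsal
heads, hallux), each with a timing window so loading progresses heel to
forefoot within a stance (trapezoidal activation: 30% ramp, 40% plateau).
Defaults describe a plausible high-risk neuropathic foot: several loci
with expected peaks of 240–420 kPa (plus ~90 kPa baseline), stance
duration 0.7 ± 0.05 s at 50 Hz, per-step amplitude CV 0.1, 2 mm spatial
jitter. The 600 kPa ceiling is applied after noise so its truncation
effect on means is exercised. An offloading intervention scales locus
amplitudes by 1 − r and can reroute a fraction of the removed amplitude
to a midfoot/arch locus, mimicking how insoles redistribute rather than
destroy load.

```{r sim, warning = FALSE}
tpl <- foot_template()
walk <- simulate_walk(tpl, variability_model(), n_steps = 26, seed = 7)
fit <- qsf_analyze(walk)
fit
glance(fit$rroi)
```

The asymptotic ground-truth mask is the expected (noise-free) peak map
thresholded by the configured rule — all statistical rules converge to
`mean >= threshold` as $n \to \infty$, while the dispersion band keeps its
SD allowance (approximated as `amplitude_cv * mean`). Validation
properties (run in the test suite, at the sizes quoted): detected masks
reach Jaccard ≥ 0.9 against ground truth with 100 usable steps across 20
seeds; a 40% offload shrinks the detected area versus the flat condition
in ≥ 95% of seeds; noise-free walks are bit-reproducible from the seed and
realise the template peaks exactly.

What the simulator does **not** emulate: anisotropic or crescent-shaped
callus loci, shear stress, speed drift within a session, sensor
calibration error and cross-talk, or the contact mechanics of real foam
insoles. Passing recovery tests therefore demonstrates that the pipeline's
statistics behave as designed under a controlled gait-like process — not
that any particular clinical effect size will be observed in patients.

## Numerical and degenerate-input choices

* Grid origins snap down to multiples of the cell size so cell boundaries
  are stable across layouts; cells with no sensor support read 0, not NA,
  keeping downstream maxima and means total.
* Text round-trips (grid sequences, PressureCSV) write the shortest
  decimal that parses back to the identical double.
* An MPPM needs ≥ 2 maps (the SD needs a denominator); single-foot
  descriptives report SD as NA rather than 0.
* An empty *reference* risk region makes a reduction report meaningless
  (`residual_reduction()` errors; the comparison pipeline reports "not
  applicable"); an empty *alternative* region is the optimal outcome and
  reports the lower bound `mean(ref R-ROI) − 200` that holds whenever
  residual cells are all significantly below threshold.
* Simulated stance durations are truncated at 0.3 s so a pathological draw
  cannot produce a stance shorter than the detector's gate.

## Problem sizes used in the shipped checks

The validation suite works at deliberately modest sizes chosen to keep the
statistical properties sharp: enumeration oracles at n ≤ 10 (sign flips)
and n ≤ 6 feet (row permutations), 1,000 randomised maps for the mask
superset property, 20 simulator seeds at 100 usable steps for recovery,
and a synthetic 60-foot cohort (30 subjects × 2 feet × 3 conditions) for
the group-level machinery. The synthetic cohort is a structural stand-in:
published per-foot areas are not bundled, and no published group statistic
is asserted against it.

## Known limitations

* The PressureCSV dialect is this package's own convention; vendor-native
  binary exports need a user-written adapter to `sensor_layout()` +
  `read_pressure_csv()` semantics.
* Pressure–time integrals and time-over-threshold are not computed; risk
  is assessed on peak pressure only.
* The exact Friedman mode covers k ≤ 3 conditions; larger designs fall
  back to the tie-corrected chi-square.
* Pairing of steps across conditions is by step order. Steps from
  different walks are not physically matched pairs; the Welch option
  exists for exactly that reason, and the paired default reflects the
  design's power analysis rather than a physical pairing.
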