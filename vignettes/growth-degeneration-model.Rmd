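---
title: "Modeling brain growth and degeneration from cross-sectional group means"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling brain growth and degeneration from cross-sectional group means}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(braintraj)
library(dplyr)
```

## The scientific problem

Mouse models of Christianson syndrome (loss of the endosomal Na+/H+
exchanger NHE6) show two superimposed processes in the postnatal brain:
*undergrowth* — brain regions never reach wild-type size — and
*neurodegeneration* — tissue that was built is later lost, most severely in
the cerebellum, where Purkinje cells die progressively. Because each animal
is measured once (perfusion is terminal), the trajectory of a brain region
is cross-sectional: a sequence of group means at postnatal day 0 and 1, 2,
6 and 23 months, not a longitudinal record of any one animal.

braintraj asks of such a trajectory: how much of the mutant's deficit is a
growth problem, and how much is a degeneration problem?

## The kinetic model

Area (a 2-D proxy for regional volume) is modeled as

$$\frac{dA(t)}{dt} = G\,A(t) - D\,A(t)$$

with a growth coefficient $G$ and a degeneration coefficient $D$, both in
month$^{-1}$ and both piecewise constant over the intervals between
measurement ages (0–1, 1–2, 2–6, 6–23 months). One interval supplies one
net rate, so $G$ and $D$ are not separately identifiable without
assumptions. The baseline fit uses the two identifying assumptions of the
source analysis for wild-type animals:

1. degeneration is negligible during the growth phase: $D = 0$ for
   $t \le 6$ months;
2. growth is negligible afterwards: $G = 0$ for $t \ge 6$ months.

`growth_phase_end` (default 6 months) is configurable, but intervals may
not straddle it: the boundary must be a measurement age, otherwise neither
assumption applies to the interval.

### Discretization

The differential equation must be discretised to be fitted to two anchors
per interval, and more than one convention is defensible. We use the
**end-anchored** rule

$$k = \frac{(A_{end}-A_{start})/\Delta t}{A_{end}}, \qquad k = G - D,$$

i.e. the net coefficient for which the interval's average rate equals
$k\,A_{end}$. The exact exponential solution would instead give
$k = \log(A_{end}/A_{start})/\Delta t$. For slow intervals the two agree;
for the steep first month they differ a lot (for the wild-type cerebellum,
0.856 vs 1.93 month$^{-1}$). The end-anchored rule is the package default
because it is the convention the published coefficient tables for this
mouse model are consistent with; the continuous form remains available in
`simulate_trajectory(mode = "continuous")` for forward simulation.
`simulate_trajectory(mode = "discrete")` inverts the fitting rule exactly
($A_{end} = A_{start}/(1 - k\Delta t)$, requiring $k\Delta t < 1$), which
gives the package a machine-precision round-trip test of the whole fitting
path.

### Counterfactual variants

Two single-mechanism hypotheses are fitted for the mutant against the
wild-type baseline:

* **undergrowth-only** — the deficit is entirely a growth problem. During
  the growth phase $D$ is held at the control value (zero under the
  baseline assumptions) and $G$ absorbs the mutant's net coefficient. After
  `growth_phase_end` the no-growth assumption still pins $G = 0$, so $D$ is
  solved from the mutant's own decline — the convention of the published
  table this analysis reproduces, rather than holding $D$ at the control
  value there.
* **degeneration-only** — the deficit is entirely accelerated loss. $G$ is
  held at the control value in every phase and $D = G_{control} - k$.

A hypothesis that cannot explain an interval produces a *negative* fitted
coefficient. These are deliberately reported verbatim and flagged
`feasible = FALSE` instead of being truncated at zero: the infeasibility is
the scientific conclusion (for the cortex at 2–6 months, the
degeneration-only model demands negative degeneration, i.e. it is rejected,
which is the quantitative argument for a mixed
undergrowth-plus-degeneration interpretation).

Whatever the variant, $G - D$ always equals the data's net coefficient for
the interval — the variants repartition the net rate, never change it —
and the test suite asserts this invariant on every fit.

### Atrophy percentages

`percent_decrease()` summarises a pair of (mean, SEM, n) cells as
$100\,(\bar A_{ref} - \bar A_{test})/\bar A_{ref}$. Its default
uncertainty is $100\,\mathrm{SEM}_{test}/\bar A_{ref}$ — the convention the
published "x% ± y%" values for this model follow, which ignores the
reference group's SEM. First-order propagation of both SEMs is available
with `method = "delta"`; it is systematically wider when the reference
group is noisy.

## Inference from summary cells

Published tables carry (mean, SEM, n) per group, not raw animals, so every
test in the package runs from either raw vectors or summary cells. A group
SD is reconstructed as $\mathrm{SEM}\sqrt{n}$; since every statistic used
here (pooled and Welch t, one- and two-way ANOVA F, Tukey HSD q, two-point
regression slopes) depends on the data only through these sufficient
statistics, summary mode and raw mode agree to machine precision whenever
the raw data realize the summaries — an equivalence the tests check
directly, with `realize_values()` producing exact realizations.

Conventions, each chosen to match the source analyses and each overridable:

* the two-sample t test pools variances with $n_a + n_b - 2$ df (Welch is a
  flag), two-tailed;
* one-way ANOVA uses between/within sums of squares from the cell
  statistics; Tukey HSD p values come from the studentized range
  distribution (`stats::ptukey`) with the Tukey–Kramer harmonic correction
  for unbalanced pairs;
* balanced two-way ANOVA uses the classical cell-means decomposition;
  unbalanced designs use Type III sums of squares with sum-to-zero
  contrasts (via `car::Anova` on exactly-realized data) to emulate the
  commercial software behind the published tables. Each term also reports
  its percent of total variance; for unbalanced Type III these shares need
  not sum to 100.
* slope comparisons fit OLS per group and test
  $t = (b_1-b_2)/\sqrt{SE_1^2+SE_2^2}$ on the summed residual df. With two
  age clusters the slope reduces exactly to
  $\Delta\bar{y}/\Delta\mathrm{age}$, which is what makes published slopes
  recomputable from group means.
* p values are never binned inside analyses; `p_stars()` applies the
  figure-style thresholds (0.05, 0.01, 0.001, 0.0001) in the report layer
  only.

## Morphometry operators

The histology readouts are implemented as geometric operators over
detections (or generator ground truth) and simple thresholded images; there
is deliberately no segmentation of real stained tissue (no stain
normalisation, no learned nucleus detection) — see Limitations.

* **Purkinje-cell linear density**: cell bodies within a capture distance
  of the layer polyline, divided by the measured layer length, per 100 µm.
  The capture distance defaults to 12 µm, 1.5× a typical 8-µm soma radius.
* **Signal area fraction**: percent of pixels at or above a threshold. The
  default rule emulates thresholding "against the dark background": the
  background population (a supplied mask, or by default the pixels below an
  Otsu cut) sets the threshold at mean + k·SD with k = 3. With an exactly
  constant background the rule degenerates, so the threshold is nudged just
  above the constant — "positive" then means strictly above background.
  Otsu's criterion plateaus across an empty gap between intensity modes;
  ties are broken at the plateau centre (mid-gap).
* **Tile-based cell counts**: square fields are laid from the image's
  top-left corner and the first `n_fields` complete fields are counted in
  raster order; membership of a centroid is half-open (top/left edge in,
  bottom/right out) so nothing is double-counted. The source protocol
  describes "228-µm²" counting regions while reporting tens-to-hundreds of
  microglia per region set — a 228 µm² square is a 15-µm box that holds at
  most one cell, so the geometry is interpreted as square fields 228 µm on
  a side, and the field size is a parameter.
* **Puncta size**: connected components of the thresholded puncta channel
  (8-connected by default, as in common ImageJ practice; 4-connectivity is
  an option), kept only where they overlap a positive cell mask, with a
  2-pixel minimum size; areas are pixel counts × pixel_size². An image with
  no mask-positive cells returns an empty result with a warning rather
  than an error, mirroring regions where too few marker-positive cells
  exist to analyse.

Pixel coordinates are 0-based and row-major throughout, and puncta areas
scale quadratically with the pixel size — both properties are pinned by
tests.

## What the synthetic generators emulate

`gen_cohort()` draws animal-level records around known piecewise
trajectories; the defaults are the study conditions the package targets:
ages {0, 1, 2, 6, 23} months, 8 animals per age, multiplicative normal
noise with CV 5% (published gross-area SEM/mean ratios are mostly 1–8%), and
true trajectories obtained by fitting the packaged published group means.
A lognormal noise option guarantees positivity at large CV. Truth tables
are emitted alongside the records, and at CV = 0 the pipeline reproduces
the generating coefficients to machine precision.

`gen_pc_layer_image()` places soma disks along a sinusoidal folium-like
path at a target linear density with a deterministic dropout fraction
(survivors = round((1 − dropout)·n)), so a degeneration phenotype has an
exactly known ground truth. `gen_cell_field_image()` draws microglia-like
cells from a homogeneous Poisson process and per-cell puncta with
gamma-distributed areas; puncta placement retries to avoid merging, and a
punctum that cannot be placed after bounded retries is dropped from both
image and truth.

All randomness flows through R's Mersenne–Twister under one master seed;
per-group substreams are derived as `seed + 10007·k` (`substream_seed()`),
and every generated object records its seed, so runs are deterministic
across platforms.

What the generators do **not** emulate: staining gradients, sectioning
artifacts, anisotropic point-spread, cell-shape variation, or spatial
clustering of microglia. Passing recovery tests on these scenes therefore
demonstrates the correctness of the measurement operators and the fitting
pipeline, not robustness to real histology.

## Numerical choices and degenerate inputs

* Interval fits require strictly increasing ages and positive end-anchor
  areas; the discrete simulator refuses $k\Delta t \ge 1$ (singular
  inversion).
* A zero pooled variance with unequal means reports p = 0 with a warning
  (constant data contradict the null); equal means give t = 0, p = 1.
* Summary cells with n = 1 have no within-group variance: they are flagged
  in `summarize_groups()` and rejected by the ANOVA routines.
* SEMs use the sample SD (n − 1 denominator) throughout — the standard of
  mainstream statistical software; whether the published tables used n or
  n − 1 cannot be determined from printed values, and the difference is
  absorbed by comparison tolerances.
* The 23–26-month pooled age group is encoded as age 23; the 11–13-month
  group as 12, with the label kept alongside.

## Problem sizes used by the test suite

The package's own verification runs at desk scale: 200 replicate cohorts
for Monte-Carlo parameter recovery, 2000 null replicates for type-I-error
calibration of the t test and one-way ANOVA, and single synthetic images of
about 10^5–10^6 pixels for the morphometry recovery checks. At these sizes
the full suite runs in a few minutes on one CPU. One caveat the suite makes
explicit: with 200 cohorts at CV 5% and n = 8, the Monte-Carlo standard
error of the mean fitted coefficient for the near-plateau 2–6-month phase
is about 6% of its (small) true value, so the recovery of that one
coefficient is noise-limited rather than bias-limited at this replicate
count; the steep growth phases and the decline phase recover to well under
1%.

## Limitations

* The model is descriptive kinetics on group means: no likelihood, no
  uncertainty intervals on $G$ and $D$, and no mixed-effects structure for
  animal-level variation (the design is cross-sectional).
* Reproductions from published tables inherit the rounding of those
  tables. Coefficients formed as differences of near-equal numbers (the
  degeneration-only $D$ during fast growth) are dominated by that rounding
  and can deviate by their own magnitude even when every input matches to
  print precision.
* The morphometry operators assume detections are given or obtainable by
  global thresholding; they are not a segmentation method.
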