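---
title: "Quantifying stroke recovery from longitudinal SPECT/MRI: models and design"
author: "strokeflow authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying stroke recovery from longitudinal SPECT/MRI: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strokeflow)
```

## The measurement problem

After transient middle cerebral artery occlusion (MCAO) in the rat, the
questions a longitudinal imaging study must answer are quantitative: how much
tissue is hypoperfused, where, how does perfusion in the initially ischemic
territory evolve over three weeks, which functional brain regions return to
normal flow, and how large is the edema/infarct on T2 MRI. `strokeflow`
implements that analysis chain for co-registered, skull-stripped volumes:
[⁹⁹ᵐTc]-HMPAO SPECT activity maps (MBq/ml, ~0.33 mm isovoxels), T2 MRI
(~0.46 mm voxels), an integer atlas labelling 77 regions per hemisphere, and
a healthy reference cohort. Registration, reconstruction and skull stripping
are upstream of this package and out of scope; volumes must be congruent
(same lattice) and masked-out voxels are `NaN`, excluded from every
statistic.

## Relative rCBF and Lassen's correction

HMPAO retention is a saturating function of flow, so uptake ratios
underestimate flow ratios. With the contralesional (right) hemisphere as the
reference region, each voxel's uptake ratio \(R = A / \bar A_{\mathrm{ref}}\)
is linearized with Lassen's correction

\[ F \;=\; \frac{\alpha R}{1 + (\alpha - 1) R}, \qquad \alpha = 0.5
   \text{ for HMPAO,} \]

which fixes \(F(1) = 1\) (the reference anchor), is strictly increasing on
its domain, and reduces to the identity at \(\alpha = 1\). Without an
arterial input function all values are *relative* rCBF (reference ≡ 1).
\(\alpha\) is recorded in every `ParametricMap` and maps with different
\(\alpha\) must not be pooled. For \(\alpha < 1\) the transform has a pole at
\(R = 1/(1-\alpha)\); ratios at or beyond it are clamped just below the pole
and counted, since physiological ratios live well inside the domain.

## Classification against the healthy reference

For every atlas region and hemisphere the healthy cohort provides mean, SD
and n of region rCBF. A voxel is **hypoperfused** if its rCBF falls below
`mean - 2*SD` of *its own region*, **hyperperfused** above `mean + 2*SD`
(the 95% normality band); the bands derive only from the healthy reference,
never from study data. The three classes partition the brain mask, a
conservation property the tests enforce on every map. Two numerical details:

* band comparisons carry a 1e-8 absolute tolerance so the degenerate
  zero-SD bands that arise in noise-free validation data classify values
  numerically equal to the mean as normal; against any real band
  (half-width ~0.1) this is invisible;
* voxels outside every region, and `NaN` voxels, are classed `outside` and
  excluded from all volumes.

Longitudinal tracking fixes each animal's day-0 ipsilesional hypoperfused
volume as a 3-D mask and applies it to all later timepoints of the same
animal. Mean rCBF inside the mask is computed **voxel-wise** (average the
parametric-map voxels) and **roi-wise** (average the raw SPECT activity,
form one uptake ratio, apply Lassen once). The two agree exactly on
homogeneous masks (the transform of a constant equals the constant's
transform) and closely on real masks; both are always reported.

## Region recovery

A region is *affected* when its group day-0 mean lies outside the healthy
band. At later timepoints an affected region is *recovered* when its group
values are no longer significantly below the healthy cohort — a Welch
two-sample t-test against the cohort summary statistics at α = 0.05 by
default. Choices worth stating explicitly:

* the test is computed from (mean, SD, n) summaries because that is all a
  healthy reference table carries; the implementation is cross-checked in
  the tests against `t.test()` on raw cohort draws;
* a region whose mean moves *above* the upper band is flagged
  `hyper_after_recovery` and still counts as recovered — flow was restored
  and overshot, which is how hyperperfusion after recanalization presents;
* a pure band criterion (`method = "band"`) is available; no
  multiple-testing correction is applied by default, with
  Benjamini–Hochberg behind `adjust = "BH"`;
* "affected" is decided on group means, not any-animal criteria, and the
  day-0 affected call is re-used unchanged at every later timepoint, so
  recovered ⊆ affected always holds.

Recovery is also profiled spatially: voxels are binned by the Euclidean
distance of their centres from the injection site (voxel centres at
`origin + (index + 0.5) * spacing`, making shell distances unambiguous), and
per 1-mm shell the affected (hypo ∪ hyper) and total volumes are reported.
Shells partition the brain, so the profile conserves both totals; the
treated-minus-control difference localises where treatment recovered
tissue.

## Edema volumetry on T2 MRI

The contralesional hemisphere's intensity histogram is fitted with a free
amplitude Gaussian \(A e^{-(x-\mu)^2 / 2\sigma^2}\) by nonlinear least
squares (Freedman–Diaconis binning by default; the fit is invariant to
histogram normalisation and equivariant under affine intensity transforms).
The absolute edema threshold is \(\mu + 2\sigma\), keeping voxels *above*
it: on a pure Gaussian hemisphere this excludes \(\Phi(2) = 97.7\%\) of
voxels, and the bright remainder is ventricular CSF. (A published
description of this procedure words the threshold as the mean with two SDs
"subtracted"; only the bright-side threshold is consistent with both the
97.7% exclusion and with edema/CSF being T2-hyperintense, so that is the
default, with the literal dark-side reading available via
`direction = "below"`.) The infarct estimate then applies two corrections,
each reported separately:

1. **ventricles** — the contralesional above-threshold volume is
   subtracted, because ipsilesional ventricles cannot be isolated inside
   the edema; this also cancels the symmetric Gaussian-tail false-positive
   volume;
2. **space-occupying effect** — vasogenic edema swells the ipsilesional
   hemisphere, so the hemispheric volume excess
   \(\max(0, V_{ipsi} - V_{contra})\) is removed. The correction operates
   on volumes, not per-slice areas, since a single corrected size is
   reported.

The corrected volume is clamped at zero with a flag; a missing
contralesional ventricle signal produces a warning and zero subtraction,
also flagged.

## Behavioural scoring

General deficit is posture (0–4) + activity (0–4) + hair (0–2), range 0–10;
the eyes item (0–4) is recorded but never enters the cumulative score
because eye condition normalises by day 8 in both arms. Focal deficit sums
body symmetry, gait, forelimb symmetry, compulsory circling and whisker
response (each 0–4; range 0–20). Epileptic-behaviour, circling-behaviour
and climbing items are structurally absent from the scheme. The cylinder
test reports the unimpaired-forelimb use fraction (0.5 = symmetric use)
with raw counts preserved so any other index is recomputable; zero-touch
sessions are flagged undefined, not dropped. Group contrasts use Welch's
unpaired t-test with Shapiro–Wilk normality checks, mean ± SEM.

## The phantom: what it emulates, and how the designed truth is exact

No animal data ship with the package, so every stage is validated on a
seeded phantom whose defaults are the study conditions themselves: 0.33 mm
SPECT isovoxels on a 48×56×32 grid, 0.46 mm MRI voxels, a 77-region atlas
(3 regions carry no data, 2 incomplete data — 72 analysable), 15 healthy
animals, 6 per arm, imaging at days 0–21, injection at bregma-relative
(AP +0.3, ML −4.0, DV +4.8) mm in the left hemisphere. The brain is an
ellipsoid (≈0.9 cm³) with mirrored hemispheres; bregma maps to the dorsal
midline point.

Healthy region means sit near 1 with deterministic region-specific offsets
(±0.06, a golden-angle sequence); between-animal variability is a
per-animal, per-region Gaussian effect (SD 0.05, typical inter-subject
rCBF variability) plus small voxel noise (SD 0.01) and a ±20% injected-dose
factor that the ratio normalisation must remove. Activity is synthesised by
inverting Lassen's correction, so the analysis pipeline — not a shortcut —
reconstructs the designed rCBF.

The `reference_mcao` scenario encodes the paper-matched design as *realised*
truth, not expectation:

* the ipsilesional hemisphere is carved into regions in order of distance
  from the injection site: 30 core regions (non-recovering in either arm),
  8 tiny penumbral regions (5 recover in both arms, 3 only in control),
  27 large penumbral regions (recover only under treatment, 3 of them
  overshooting into hyperperfusion), 2 regions affected only in the
  control arm, 5 unaffected, and the 5 excluded-bookkeeping regions
  distally. Region sizes are solved so recovered-region volume shares
  equal the designed hypoperfused-volume shrinkages (67% treated, 1%
  control);
* affected regions start at 0.45× their healthy mean (a typical MCAO
  deficit); recovery follows an exponential-shaped curve anchored at day 0
  and day 7 with group-specific half-times (2 d treated, 3.5 d control),
  because every headline quantity is a day-0/day-7 anchor; after day 7
  levels hold (an optional relapse term exists and is off by default);
* the treated arm's non-recovered day-7 level is solved numerically so the
  day-7 mask-mean contrast is exactly the designed +41%;
* study-arm animal effects are drawn and then centred within each
  group × region, and ipsilesional activity is anchored to each animal's
  own contralesional mean, so realised group means equal designed targets
  to machine precision. This is what makes "the classifier must recover
  the designed truth" a sharp test: 65/67 affected and 32/8 recovered are
  deterministic outcomes, not averages. The healthy cohort and the
  `lesion_free` scenario draw *uncentred* effects, so null calibration
  (≈4.55% of voxels outside the 2σ bands) remains honest.

On the MRI side, parenchyma is Gaussian (100 ± 10), ventricles a bright
(200) component occupying 2.4% of each hemisphere, edema a 60 mm³
hyperintense sphere at the injection site from day 3 on, and the
ipsilesional hemisphere swells by 12 mm³ (stretching its lateral
semi-axis). All achieved values are stored in the ground-truth record.

What the phantom deliberately does **not** emulate: photon transport,
collimator blur, partial-volume effects, motion, registration error,
inter-regional covariance of healthy rCBF, heavy-tailed noise, or real
anatomy (regions are distance-ordered blocks, and the non-recovering core
spans ~0–3 mm rather than the sub-millimetre core of a real infarct).
Passing tests therefore demonstrate that the *analysis* is correct and
calibrated under the stated statistical structure, not that it is robust to
real-world imaging physics.

## Numerical choices and degenerate inputs

* Congruence (shape, spacing, origin within 1e-6 mm) is required, never
  repaired by resampling.
* The reference mean uses all finite contralesional voxels (median
  available); an empty or non-positive reference is an error.
* The Gaussian fit falls back from `nls` to Nelder–Mead on the identical
  objective if the former fails to converge; a non-positive fitted σ, a
  constant hemisphere, or fewer than 1000 contralesional voxels are
  errors.
* Welch tests with zero pooled variance compare means with a 1e-8 absolute
  tolerance (noise-free designs then classify exactly); group sizes below
  2 are errors, as is a labelled region without a reference row (named in
  the message).
* Zero-noise validation asserts exact recovery of designed region means,
  day-0/day-7 hypoperfused volumes and all recovery counts; day-7 hyper
  overshoot is degenerate at zero noise (the overshoot is defined in units
  of the empirical SD) and is therefore asserted only in noisy runs.
* Desk-scale problem sizes: module tests run on a 32×36×24 grid with
  3–4 animals per group; the full-conditions checks (default grid, 15
  healthy, 6 per arm) generate and analyse a complete study in well under
  a minute.

## Reproducing the headline numbers

`runFullStudy()` executes the whole chain on a phantom scenario and
serialises a report bundle whose configuration is stored with a hash
(`validateBundle()` re-checks it). `scripts/acceptance.R` in the source
repository recomputes the headline quantities — threshold calibration,
recovery counts, volume shrinkages, mask-mean contrast — from scratch on a
fresh phantom for any seed.

```{r, eval = FALSE}
bundle <- runFullStudy(list(scenario = "reference_mcao", seed = 1))
bundle$counts$groups$treated$recovered   # 32 of 65 affected regions
bundle$shrinkPct                         # ipsilesional hypo-volume shrink
bundle$maskContrast$contrastPct          # day-7 treated-vs-control, ~+41%
```

## Known limitations

Atlas region ids are synthetic: they follow the bookkeeping of the real
atlas (77 regions, the same five exclusions) but carry no anatomy, so
region-level findings cannot be mapped onto named structures. The edema
module quantifies a single timepoint per call and does no longitudinal
edema modelling; absolute CBF is out of scope (no arterial input
function); and the recovery test treats regions independently, as the
source analysis does — a correlated-region model would need the covariance
the healthy summary table does not carry.
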