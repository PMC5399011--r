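---
title: "Dual-timepoint PET texture analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-timepoint PET texture analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petex)
```

## The problem

Radiomic texture features promise imaging biomarkers beyond what the eye
can read off an ^18^F-FDG PET scan, but they are only comparable between
scans acquired under the same conditions. One condition that is easy to
overlook is the uptake time: tracer distribution in a tumour keeps
evolving for hours after injection, so a feature computed at ~100 min
post-injection need not equal the same feature at ~250 min. `petex`
implements the full analysis needed to quantify this effect in a paired
design: per-scan extraction of a 99-feature signature from a segmented
tumour volume, and a nonparametric paired comparison of early versus
late acquisitions across a cohort, with benign and malignant subgroups.

Because clinical dual-timepoint cohorts are rarely shareable, the
package ships a synthetic paired-phantom generator that reproduces the
statistical structure the analysis assumes, so the whole pipeline can be
exercised, calibrated and regression-tested without any patient data.

## Per-scan feature model

Each scan contributes one `FeatureVector` of 99 named values (see
`feature_catalog()`), in four families.

**First order (37).** "ROI" statistics are computed on the raw
activity-concentration values inside the tumour volume of interest
(VOI), decay-corrected to injection time by $2^{\Delta t/T_{1/2}}$ with
$T_{1/2} = 109.77$ min for ^18^F. Moments are population moments
(divisor $N$); kurtosis is non-excess, so a Gaussian scores 3;
percentiles interpolate linearly between order statistics. Histogram
entropy and energy use 64 equally spaced bins over the VOI min-max
range, giving entropy in bits bounded by $\log_2 64 = 6$. Three further
entropies are taken on the Laplacian-of-Gaussian response at
$\sigma = 1.5, 2.0, 2.5$ mm. The volume descriptors are the metabolic
active volume $\mathrm{MAV} = N\,s_x s_y s_z$ and the equal-volume
sphere diameter $(6\,\mathrm{MAV}/\pi)^{1/3}$. "SUV" statistics repeat
the 13 moments plus entropy/energy on body-weight SUV,
$\mathrm{SUV} = c \,/\, (A\,2^{-\Delta t/T_{1/2}} / W)$, together with
total lesion glycolysis $\mathrm{TLG} = \mathrm{SUV}_{mean}\cdot
\mathrm{MAV}$ and $\mathrm{SUV}_{peak}$, the hottest 1 cm^3 sphere mean
(radius 6.2 mm, clipped to the VOI).

**Second order (25).** The VOI is quantized to 64 equally spaced bins
(`quantize()`: $b = 1 + \lfloor 64 (v - v_{min})/(v_{max} -
v_{min})\rfloor$, maximum clamped, constants mapping to bin 1). Grey
level co-occurrence matrices are built symmetrically per offset, and
grey-level difference histograms from the same pairs; 21 GLCM and 4
GLDM features are averaged over 7 directions $\times$ 2 distances = 14
offsets. All logs are base 2 with $0\log 0 = 0$.

**High order (31).** Run-length matrices (13 features, averaged over
the 7 directions at step 1 — a run with stride above 1 is not well
defined), size-zone matrices over 26-connected equal-bin zones (13
features, orientation-free, computed once) and the neighbourhood
grey-tone difference table over 26-neighbourhoods (5 Amadasun–King
features).

**Fractal (6).** Local differential box counting on 8-voxel windows
tiling the VOI bounding box (intensities rescaled to 64 grey levels;
box ladder 2, 4, 8; dimension = slope of $\log N_s$ vs $\log 1/s$),
summarised as window mean, population SD, and reciprocal mean;
gliding-box lacunarity $M_2/M_1^2 - 1$ averaged over the same ladder;
the Peleg blanket dimension ($3 - $ slope of $\log A(e)$ vs $\log e$,
windowed and averaged); and a Hurst exponent from the isotropic
variogram (half the log-log slope of mean squared increments over lags
1–4 voxels, in mm).

### Choices where the method was genuinely open

* **Direction set.** Seven directions are the canonical reduction of
  the 13 unique 3D neighbour directions: three axes, three face
  diagonals, one body diagonal, with distances 1 and 2. Any consistent
  set preserves the algebraic structure of the features; absolute
  values of directional features do depend on the choice.
* **Symmetry.** This 7-set is *not* closed under 90° rotations about
  any axis (the face diagonal $(1,1,0)$ maps outside the set), so
  averaged features are only guaranteed invariant under the set's
  actual stabilizer — axis swap of $x$/$y$ and full inversion — which
  is what the test suite asserts.
* **Redundant definitions.** Within the difference-histogram family the
  implementation keeps the classical redundancies exact: GLCM
  dissimilarity $\equiv$ GLDM mean, GLCM contrast $\equiv$ GLCM
  difference variance (defined as the second moment $\sum d^2 p_d$)
  $\equiv$ GLDM contrast, GLCM difference entropy $\equiv$ GLDM
  entropy, and homogeneity $\equiv$ inverse difference moment (both
  weighted $1/(1+(i-j)^2)$). These identities are enforced at $10^{-9}$
  on random inputs.
* **"Variability" features.** Run-length/size-zone "intensity
  variability" and "run length/size zone variability" are implemented
  as the population variance of the marginal count vectors — over all
  64 grey levels for the intensity marginal, and over lengths/sizes up
  to the longest observed for the length marginal (so the statistic
  does not depend on the allocated matrix width).
* **Bin edges** are recomputed independently per scan from the VOI
  min–max of that scan; early and late scans are not harmonised. This
  is the most literal reading of per-scan resampling and makes every
  binned feature invariant to positive affine intensity maps.
* **LoG entropies** filter the *full* volume before masking (filtering
  a cut-out would manufacture edge response), then re-quantize the VOI
  response to 64 bins. Filters use per-axis sigma in voxels
  ($\sigma_{mm}/s_{axis}$), mirror boundaries and derivative kernels
  corrected to exactly zero DC gain, so a constant volume has exactly
  zero response. A note on direction: on white-noise simulations the
  re-quantized response entropy is flat-to-slightly-increasing in
  $\sigma$ (the band-pass *power* decreases, but the 64-bin histogram
  entropy is scale-free); the test suite therefore asserts the power
  decrease, not an entropy decrease.
* **Hurst estimator.** Reported dual-timepoint values of this feature
  in the clinical literature exceed 1, which rules out the usual
  bounded rescaled-range reading; the variogram slope estimator used
  here is the standard one for image fields, recovers $H$ on synthetic
  fractional fields, and is affine-invariant, but numeric agreement
  with any particular in-house implementation is not expected.
* **SUV~peak~** uses the 1 cm^3 EANM-style sphere; on the clinical
  4.7 × 4.7 × 3.27 mm grid the sphere contains 15 voxel centres
  (≈1.08 cm^3).

## Preprocessing contracts

SUV conversion assumes tissue density 1 g/ml; decay correction refers
measured activity back to injection time using per-scan actual uptake
times (not nominal protocol times). CT-space masks are mapped onto the
PET grid by nearest-neighbour lookup at voxel centres under an
assumed-perfect co-registration; no partial-volume threshold is applied
so masks stay strictly binary. Grids are axis-aligned
(position = origin + index × spacing); oblique orientations are out of
scope.

## The paired statistical layer

Per feature and per group (all patients, benign, malignant — subgroups
require ≥ 5 patients), the package reports medians and ranges per time
point, a two-sided related-samples Wilcoxon signed-rank test, Spearman
correlation between time points, and a direction arrow (set only when
p < 0.05, from the sign of the median paired difference). Zero
differences are discarded before ranking (the classical and default
choice in mainstream statistics packages; Pratt handling is available
via `wilcoxon_zeros = "pratt"`). The p value is exact — from the
signed-rank null distribution — for up to 25 tie-free pairs, and
otherwise uses the normal approximation with tie-corrected variance and
continuity correction; both branches agree to better than 0.01 at the
switchover in tests. No multiplicity correction is applied, matching
common practice for exploratory feature screens; the comparison object
records `n_tests` so the family-wise exposure is explicit.
Inter-observer agreement uses ICC(2,1) — two-way random effects,
absolute agreement, single measure — the conservative reading when the
ICC variant is unspecified.

## What the phantom emulates — and what it does not

`phantom_spec()` defaults encode the emulated study: 54 patients with a
30/24 benign/malignant split, ellipsoidal tumours (semi-axes 10–26 mm)
on a 4.7 × 4.7 × 3.27 mm grid, scans at 101.5 and 251.7 min
post-injection of 350 MBq for a 70 kg body, 6 mm FWHM Gaussian
post-filtering. Heterogeneous uptake is lognormal: base SUV 1.4
modulated by a unit-variance Gaussian random field with 10 mm
correlation length (mean-preserving $e^{\sigma Z - \sigma^2/2}$,
dispersion 0.3), background SUV 0.3. Kinetics are multiplicative:
benign lesions wash out to $w = 0.8$ of their early SUV; malignant
lesions intensify their hottest decile of voxels by $g = 1.5$,
reproducing the qualitative dual-timepoint behaviour of these tumours
(mean uptake falls in benign lesions; the maximum rises in malignant
ones) while also increasing skewness and kurtosis. Noise is Gaussian
with variance proportional to local activity times the decay factor,
so later, count-poorer scans are noisier ($\kappa = 2$ in Bq/ml units,
giving roughly 3% early and 9% late relative noise at lesion level);
noise is added before the 6 mm post-filter, as reconstruction noise
would be.

Deliberate simplifications: no tracer kinetic modelling (the analysis
measures differences, not kinetics), no sinogram/Poisson/reconstruction
physics, no anatomical background, a single segmentation shared by both
time points (real studies re-segment per scan, so volume features can
vary there), and perfect co-registration. Passing tests on these
phantoms therefore validate the *pipeline and its statistics* — not
scanner physics, segmentation variability, or the clinical magnitude of
any feature shift.

## Numerical conventions and degeneracies

Degenerate inputs are flagged, never fatal: zero-variance VOIs return
skewness/kurtosis 0 with a flag, an all-zero difference vector returns
p = 1, zero-variance GLCM marginals return correlation 0,
neighbourless NGTDM voxels are excluded (coarseness capped at $10^{12}$
with $\varepsilon = 10^{-12}$), offsets along which a thin VOI admits
no pair are excluded from the directional average, and a failed fractal
regression yields flagged `NA` features rather than aborting a cohort
run. Tie-breaks: the direction arrow falls back to "none" when the
median paired difference is exactly zero.

## Problem sizes used for validation

The test suite chooses sizes so each property is tested at full
strength in minutes on one core: oracle equivalence of every texture
matrix against naive triple-loop enumeration on 200 random 4×4×3
grids; the feature-identity suite on 200 random small VOIs at
$10^{-9}$; type-I calibration of the paired test over 400 null phantom
cohorts of 20 patients each (small 14×14×12 grids, matched scan times
so the null holds exactly), checking the per-feature rejection rate
against its binomial band around the nominal 5%; and directional
parameter recovery (benign mean down, malignant maximum up) on 20
full-size 54-patient cohorts at the study defaults. Some features
cannot reach the nominal level by construction and are asserted
conservative instead: mask-derived volume features are
deterministically equal across time points under the
shared-segmentation design (they never reject), and the
fractal-dimension SD is identically zero at both time points whenever
a small lesion's bounding box fits a single analysis window, so its
paired differences vanish and the zero-difference convention (p = 1)
applies.

## Known limitations

Absolute values of directional texture features depend on the direction
set and bin count and are not comparable across implementations without
harmonising those choices; only the algebraic identities and invariances
are implementation-independent. The Hurst and blanket estimators are
window/lag-parameterised and should be treated as relative measures.
The phantom's shared mask makes volume features uninformative in
simulation. DICOM input, oblique grids, partial-volume correction and
benign-versus-malignant discrimination are out of scope.
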