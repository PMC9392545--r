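---
title: "Methods: virtual-line profiling of adjacent category-selective regions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: virtual-line profiling of adjacent category-selective regions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cortexline)
```

## The scientific question

Category-selective patches in ventral temporal cortex — the fusiform face
area (FFA) for faces, the parahippocampal place area (PPA) for houses and
scenes — sit next to each other on the cortical sheet. Whether the
transition between them is a sharp functional border or a gradual,
asymmetric gradient is informative about how object representations are
organized: strictly modular accounts predict symmetric, mirror-image
changes in face- versus house-selectivity across the boundary, while
distributed or hybrid accounts allow the two regions to behave
qualitatively differently.

`cortexline` implements the analysis that addresses this question: sample a
*virtual line* of small ROIs running from the face-selective peak to the
house-selective peak on the cortical surface, characterize each ROI's
response to a factorial set of face/house stimuli at two contrasts, and
quantify (i) selectivity, (ii) invariance to contrast and to a concurrently
presented nonpreferred category, and (iii) the asymmetry of response
changes across the boundary — univariately through beta profiles and
slopes, and multivariately through classification accuracy.

Because the analysis has no public dataset attached, the package pairs it
with a generative stand-in cortex whose ground truth is known. All tests
and examples run end to end on that synthetic cortex; what a passing test
demonstrates is that the *statistical machinery* behaves correctly on data
with known structure, not that any particular real brain behaves this way.

## The divisive-normalization generator

The simulator's response model is divisive normalization: a unit's drive is
divided by a semisaturation constant plus the pooled drive of its
neighborhood,

$$R(v) = \frac{D(v)}{\sigma + \overline{D}_{\mathrm{pool}(v)}},\qquad
D(v) = w_{\mathrm{face}}(v)\,g_{\mathrm{face}}(c) +
       w_{\mathrm{house}}(v)\,g_{\mathrm{house}}(c),$$

where $\mathrm{pool}(v)$ is the set of vertices within `pool_radius` of $v$
by geodesic distance and $\overline{D}$ its mean drive. Tuning weights are
geodesic Gaussians around two planted centers. This is the textbook account
of why a region embedded in a *homogeneous* neighborhood (the face patch:
nothing nearby responds to houses) is contrast-invariant and robust to
clutter, while a region with a *heterogeneous* neighborhood (the house
patch: face-responsive cortex within pool reach) inherits sensitivity to
contrast and to concurrently presented faces through its normalization
pool.

Two gain asymmetries complete the model:

* face gain is contrast-saturated: `g_face_low = g_face_high = 1`;
* house gain grows with contrast: `g_house_low = 0.5`, `g_house_high = 1`.

With these, four structural properties hold at the patch centers in the
noiseless model, each asserted as a direct inequality in the tests: the
face response is identical across face contrasts; the high-contrast house
response exceeds the low-contrast one by more than 20%; a concurrent
low-contrast face suppresses the low-contrast house response; and the
high-contrast house response is unchanged (within 5%) by a concurrent
face. The last two together are the signature the multivariate analyses
should recover: decoding of *low*-contrast houses is hurt by an overlaid
face, decoding of *high*-contrast houses is not.

### Choosing the frozen geometry

The normalization constants above are fixed by design. The remaining free
parameters — mesh scale, patch separation, and patch widths — were chosen
once, before any statistical test was written, by evaluating the noiseless
model over a small grid and keeping the first configuration that satisfied
every structural property with margin:

| parameter | value | why |
|---|---|---|
| mesh | icosphere, radius 40 mm, 3 subdivisions (642 vertices) | closed surface at desk scale; 4 subdivisions (2562 vertices, ~2.6 mm edges) for searchlight work |
| patch separation | ~22.5 mm geodesic | close enough that the face patch reaches the house patch's 12 mm pool (suppression exists), far enough that the centers are outside each other's tuning cores |
| `face_sigma` | 6 mm | narrow face patch |
| `house_sigma` | 18 mm | wide house patch; with pool saturation this flattens the house profile over the boundary window (house/face slope-magnitude ratio 0.20 in the noiseless model) |
| `peak` | 2 | drive at a patch center, response units |
| `sigma`, `pool_radius` | 1, 12 mm | semisaturation constant and pool size |
| `beta_sd` | 0.4 | block-beta noise placed so that anchor-ROI decoding sits on the informative part of its psychometric range (accuracies ~0.8–0.98 rather than pinned at 1.0), which is where the suppression effect is visible in accuracy |
| `ts_sd`, `ar1_rho` | 1, 0.3 | AR(1) time-series noise; roughly doubles beta-estimation noise after the GLM |

The suppression effect deserves a note: the requirement that high-contrast
houses be *immune* to an overlaid face caps how much face drive may reach
the house pool, which in turn caps the low-contrast suppression at roughly
6–7% of the response. It is a genuinely small effect — which is faithful to
the phenomenon being modelled — so detecting it in classification
accuracies needs either many subjects or many runs; the tests use 12
simulated subjects with 40 runs for that one comparison and the
study-scale 9 runs everywhere else.

One qualitative feature of real data is deliberately not modelled: the
house-selectivity profile in real brains can show a double peak on the
house side. A single geodesic Gaussian cannot produce it, and nothing
downstream depends on it.

Also not modelled: hemodynamic nonlinearity, motion or physiological
noise, volumetric geometry, between-subject anatomical variability (all
subjects share one mesh; only noise differs). Passing tests therefore say
nothing about robustness to those factors.

## Design choices in the analysis itself

**One GLM per run, one regressor per block.** Blocks are 16 s apart and
their HRF-convolved regressors nearly orthogonal (tested: |r| < 0.05 for
separated blocks), so iterative single-block estimation would buy nothing.
The HRF is the canonical double-gamma (peak 5 s, undershoot near 15 s,
ratio 1/6, unit peak) — the analysis consumes relative beta patterns, so
the exact kernel shape is not critical, but it is fixed and documented.
Nuisance model: intercept plus linear drift; the simulation contains no
motion, so no motion regressors exist.

**The virtual line is straight in 3-D.** Line coordinates interpolate (and
beyond the peaks, extrapolate) linearly between the two peak coordinates;
each coordinate adopts its 5 Euclidean-nearest vertices as an ROI. On a
locally near-planar inflated surface the straight segment and the geodesic
path differ little; off-surface coordinates are harmless because
membership is by nearest vertices. Adjacent ROIs may share vertices when
the spacing is finer than the mesh edge length — the constructor reports
the overlap fraction rather than forbidding it. ROI indices are 1-based in
every user-facing table; mesh vertex indices are 1-based in R and 0-based
in on-disk JSON/OFF, converted at the boundary.

**Condition means feed the univariate statistics; block betas feed MVPA.**
Block betas are averaged within condition per run, then across runs, before
profiles, selectivity, and slopes; classifiers see individual block
patterns.

**"Corrected" means Bonferroni throughout.** The correction family is the
set of ROIs on the line for profile-wise tests, the set of planned
contrasts (3) for the slope-asymmetry tests, and all 15 cell pairs for
ANOVA post-hocs. No sphericity correction is applied by default to the
3-level factor; Greenhouse–Geisser is available via `gg = TRUE`.

**Repeated-measures ANOVA error terms.** Each within-subject effect is
tested against its own subject-interaction stratum (A vs A×S, B vs B×S,
A×B vs A×B×S) — the classical univariate partition. The implementation
delegates to `aov()` with an `Error(subject/(a*b))` term; tests verify it
against an independent hand-written sum-of-squares decomposition. Exactly
zero effect sums of squares are reported as F = 0, p = 1 rather than 0/0.

**Two classifiers, deliberately.** ROI-level classification uses a linear
maximum-margin SVM (cost 1, unscaled features); the searchlight uses ridge
regression with regularization strength 10, classifying by the sign of the
prediction against ±1 class codes (ties called "face"). These mirror the
two tools conventionally used for the two jobs and are kept distinct on
purpose. Cross-validation folds group runs (never splitting a run between
training and test) and are seeded. Overlapping-image samples, which have no
true face/house label, are labelled by every fold's classifier and merged
by majority vote, ties to "face" — a documented, configurable convention.

**Searchlight disks are geodesic** (Euclidean available as a flag), radius
5 mm, accuracy stored at the center vertex; the group map is a per-vertex
one-sample t against chance 0.5, thresholded at p < .001 uncorrected.
Zero-variance vertices are flagged degenerate and never significant.

**Gaussian-process smoothing** (for display) uses a squared-exponential
kernel; length-scale and noise variance are fitted per subject profile by
marginal-likelihood maximization (signal variance profiled as the data
variance), with a fixed fallback length-scale of 3 ROI steps if the
optimizer fails. Smoothing happens per subject before group averaging, and
is never used in inference.

## Numerical and degenerate-input conventions

* RMS contrast is the population SD of normalized pixel values with the
  mean preserved; when reaching the target would push pixels outside
  [0, 1], pixels are clipped and the scale re-estimated iteratively (≤ 50
  rounds) until the post-clip RMS is within 1e-3 of the target. Constant
  images are rejected.
* Image overlay is the unweighted pixelwise mean with no re-normalization:
  the contrast of an overlapping condition is emergent, so "low face on
  high house" genuinely has a less visible face.
* Peak finding breaks ties toward the lowest vertex index.
* Paired tests with zero-variance differences return t = 0, p = 1 and a
  degeneracy flag instead of failing.
* All simulator randomness descends from one master seed via deterministic
  per-(subject, run) derivation, so any subject or run can be regenerated
  in isolation; an identical seed gives bit-identical output, and reusing a
  seed across conditions reuses the identical noise draw.

## Problem sizes used by the shipped tests

Simulation-backed tests run at the scale a desk machine handles comfortably:
the 642-vertex mesh for profile and slope work (50 simulated studies of 12
subjects × 9 runs for the slope-asymmetry recovery, via the full
time-series → GLM path), the 2562-vertex mesh for the searchlight
specificity check (12 subjects), and 20 label permutations of 12 subjects
on the coarser mesh for the false-positive calibration. The suppression
comparison uses 12 subjects × 40 runs of block betas, for the power reasons
given above.

## Known limitations

* The generator shares one mesh and one tuning field across subjects;
  between-subject variability is noise-only, so group statistics are
  better-behaved than on real data.
* The equal-spacing of line coordinates is measured along the straight 3-D
  segment, not along the surface; a geodesic-spacing variant would differ
  on strongly curved meshes.
* The ANOVA implementation assumes complete balanced designs, which the
  pipeline guarantees but arbitrary user data may not.
* Accuracy granularity with few runs makes the group t-test on searchlight
  maps slightly anti-conservative below ~10 subjects; the false-positive
  calibration test documents the regime (12 subjects) where the nominal
  rate holds.
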