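---
title: "Methods: MRI-based endothelial profiling with a synthetic phantom cohort"
author: "endoprofile"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MRI-based endothelial profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(endoprofile)
```

## The measurement problem

Endothelial dysfunction precedes overt atherosclerosis. Two in-vivo MRI
readouts capture it in the mouse brachiocephalic artery (BCA):

1. **Vasomotor response.** Acetylcholine (Ach) dilates a healthy artery via
   endothelium-derived NO; with a dysfunctional endothelium the smooth-muscle
   muscarinic response dominates and the vessel *constricts*. The endpoint is
   the percent change of end-diastolic BCA lumen volume between cine 3D
   gradient-echo scans acquired before and after Ach. Untreated
   atherosclerotic (ApoE/LDLR-deficient) animals respond with constriction of
   a few percent; effective vasoprotective treatment restores a dilatation of
   similar magnitude.

2. **Endothelial permeability.** An albumin-binding gadolinium contrast agent
   stays intravascular across an intact endothelium. Where the endothelium is
   leaky the agent accumulates in and around the vessel wall and shortens the
   local longitudinal relaxation time T1. Comparing per-pixel T1 maps
   acquired before and ~30 min after contrast, the endpoint **Npx50** counts
   the pixels around the lumen whose T1 decreased by *more than 50%*. The
   fixed relative-change criterion makes the statistic operator-independent:
   no hand-drawn ROI boundary decides which pixels count.

Both readouts are joined with a plasma panel — nine angiotensin peptides
(fmol/ml) quantifying the ACE/Ang II (detrimental) versus
ACE2/Ang-(1–7)/Ang-(1–9) (protective) axes, and L-arginine-pathway
metabolites (µmol/L) including ADMA, whose ratio L-Arg/ADMA proxies NO
bioavailability — and correlated animal-by-animal (Spearman).

No imaging or plasma raw data accompany the study this package emulates, so
a synthetic phantom/cohort generator with known ground truth stands in for
the animals. Every analysis stage is exercised end-to-end against that
ground truth.

## Models

### Spoiled gradient-echo signal and VFA T1 estimation

The steady-state magnitude of an ideally spoiled gradient echo at flip angle
$\alpha$ is

$$S(\alpha) = M_0 \sin\alpha \, \frac{1 - E_1}{1 - E_1\cos\alpha},
\qquad E_1 = e^{-TR/T_1}.$$

`spgr_signal()` implements this forward model; a Bloch-iteration oracle
(repeated rotation + relaxation to convergence) verifies it in the test
suite. The variable flip angle (VFA) method samples $S$ at several nominal
angles — the permeability protocol uses 2, 4, 6, 8, 14, 20, 30, 50 degrees at
TR = 10 ms — and estimates $(M_0, T_1)$ per pixel:

* **Linear step** (`method = "linear"`): the model linearizes to
  $S/\sin\alpha = E_1\,(S/\tan\alpha) + M_0(1-E_1)$; ordinary least squares
  on $(S/\tan\alpha, S/\sin\alpha)$ gives $E_1$ from the slope and
  $T_1 = -TR/\log E_1$.
* **Nonlinear refinement** (default): a vectorized Levenberg–Marquardt pass
  minimizes the untransformed squared residuals starting from the linear
  estimate, and is kept only where it does not increase the residual. On
  noiseless data the two agree to $10^{-4}$ relative; the nonlinear fit has
  the smaller variance under noise (the linearization re-weights errors by
  $1/\sin\alpha$).

**Failed-fit policy.** All-zero signals, slopes outside $(0,1)$ (non-physical
$E_1$) and estimates above `t1_max` (default 10 s) are *undefined*, carry a
coded reason, and propagate as missing values. They are never clamped and
never become zeros: a zero would masquerade as a 100% T1 drop and corrupt
Npx50 downstream. B1 inhomogeneity is not modeled; angles are taken as
nominal. This is a documented limitation, acceptable here because both maps
of a pre/post pair share the same miscalibration and Npx50 uses their ratio.

### Npx50

Given co-registered pre/post maps, the per-pixel relative change is
$(T_1^{pre} - T_1^{post})/T_1^{pre}$, positive for the T1 *decrease* the
agent produces (an absolute-change mode exists; decrease is the default and
the natural reading of the endpoint). Npx50 is the count of analysis-region
pixels whose change **strictly exceeds** the threshold (default 0.50). The
analysis region is the perivascular rim: the morphological dilation of the
lumen mask minus the lumen (default thickness 2 pixels, 4-connectivity).
Pixels undefined in either map are excluded from both the region size and
the count, and the exclusion count is logged. Group-level summaries of Npx50
use the median, matching the non-parametric treatment of this endpoint.
Npx50 is reported summed over the acquired slice stack.

### Vasomotion

The cine stack (256 × 256 × 30 voxels over 30 × 30 × 5 mm, 7 cardiac frames
in the full protocol) is analysed at end-diastole: the frame minimizing the
total segmented lumen area (ties break to the lowest index). Five contiguous
slices ending strictly before the bifurcation — detected as the first slice
whose thresholded lumen splits into two connected components — are segmented
slice-wise. The threshold sits halfway between the background level (slice
median) and the lumen level (median of a 7 × 7 window around a seed point
tracked slice-to-slice via the component centroid); the seeded connected
component is kept and holes are filled. Volume is the rectangular rule
(area × slice thickness), and the endpoint is
$100\,(V_{post} - V_{pre})/V_{pre}$. The slice range is determined on the
pre-Ach scan and reused for the post scan, exploiting the 3D acquisition's
retrospective repositioning. Otsu thresholding is available as an
alternative; thresholds are computed per slice.

## The synthetic phantom

`default_geometry()` emulates the imaged arch segment as a branched vessel
along the slice axis: lumen radius 1.21 mm at the first slice, tapering
1.6% per slice, wall 0.12 mm, bifurcating at slice 12, with a sub-pixel
in-plane centerline drift per slice. Cardiac pulsation modulates the radius
by a raised cosine (default amplitude 12%) with its minimum at the diastolic
frame (4 of 7). The Ach response is encoded by a **dilation factor** $d$
multiplying end-diastolic lumen *volume* between states (radii scale by
$\sqrt d$): $d = 0.9282$ encodes the −7.18% untreated response, $d = 1.045$
a +4.5% dilatation.

Two deliberate design choices matter for accuracy:

* **Partial-volume rendering.** Cine intensities mix per-compartment levels
  with a one-pixel linear edge ramp (a point-spread-function stand-in), so
  threshold segmentation sees realistic partial-volume edges rather than
  binary discs.
* **Slant and taper.** Pixel-count volumetry of an axis-aligned cylinder is
  quantized: every slice commits the same sub-pixel rounding and the error
  does not average out. The default slant (~0.5 px per slice) and taper
  spread the boundary phase across the five analysed slices. A noiseless
  design study over dilation factors 0.90–1.093 fixed these defaults so the
  end-to-end recovery error stays below ~0.2 percentage points; they are
  study conditions, not tuning knobs.

The paper behind this package reports no vessel dimensions or tissue
relaxation times, so compartment T1/M0 defaults (blood 1900 → 400 ms
post-contrast, wall 1200 ms, perivascular rim 1400 → 500 ms where leaky,
background 900 ms, at 9.4 T) are plausible placeholders, all configurable
via `tissue_params()`. Cine compartment intensities encode inflow-enhanced
bright blood (100) over wall (30) and background (10) — the spoiled
steady-state would render slowly relaxing blood dark, which is not what a
gated FLASH angiogram shows.

**Noise.** Magnitude images get Rician noise: independent Gaussian
perturbations of scale $\sigma$ in two quadrature channels, then the
modulus. The background is then Rayleigh, which the test suite verifies by
goodness of fit. SNR is quoted as signal over $\sigma$ — blood cine
intensity for the vasomotor stage, the largest-angle SPGR signal for the VFA
stage. A Gaussian option exists for debugging. Every stochastic output is
bit-reproducible given (inputs, seed).

**Contrast leak.** In the post-contrast state exactly
`round(leak_fraction × n_rim)` rim voxels (chosen reproducibly from the
seed) switch to the leaky post-contrast T1. A rim T1 drop of
1400 → 500 ms (64%) clears the 50% criterion, so on a noiseless phantom
Npx50 equals the planted leak count exactly — the worked examples with 15
(untreated median) and 6 (treated median) leaking voxels reproduce the
published medians and their 60% treatment difference by construction of the
pipeline, not by assignment.

## The synthetic plasma cohort

`study_group_specs()` parameterizes untreated, MNA-treated and
perindopril-treated groups at the published group sizes (plasma: 6/5/5 after
one month, 6/7/8 after two). Where the study prints group means ± SEM
(Ang II 119.8 ± 11.3 → 85.5 ± 5.4 / 50.2 ± 4.1 fmol/ml; Ang III
206.2 ± 15.5 → 130.4 ± 10.0 / 96.2 ± 8.7), those numbers are used verbatim.
Analytes reported only as percent effects apply those percentages to
literature-plausible untreated baselines (e.g. L-Arg 80 µmol/L, ADMA
0.8 µmol/L); the percent-change endpoints are invariant to the baseline
choice. Unprinted SEMs are set small enough that the reported group
separations are statistically significant at the published group sizes,
mirroring the significance markers of the source figures.

One internal inconsistency of the source had to be resolved: the abstract
reports the 2-month L-Arg/ADMA ratio increase as +107% (MNA) and +140%
(perindopril), while the results text reports +34%/+46% after one month,
"maintained" at two. The 2-month calibration follows the abstract: ADMA
declines by the printed −15%/−20% and L-Arg is scaled so the mean ratio
shift is 2.07×/2.40×.

Per-animal concentrations are drawn from a zero-truncated normal with
SD = SEM × √n (the SEM being the between-animal SD over √n). Truncation is
by deterministic redraw; at the concentrations and dispersions used it is
essentially never active, so the mean is unbiased in practice.

`simulate_study_cohort()` additionally generates per-animal imaging
endpoints with a latent endothelial score coupling volume response
(positively) and Npx50 (negatively) within groups; together with the
group-level effects this reproduces the published correlation sign pattern
(volume change positive with both protective ratios, Npx50 negative with
everything).

## Statistics

Group comparisons follow the study's scheme: Kruskal–Wallis (tie-corrected,
via `stats::kruskal.test`) for the non-parametric imaging endpoints, one-way
ANOVA with Tukey HSD for analyte concentrations, with per-group
Lilliefors/Kolmogorov–Smirnov normality recorded where n ≥ 5. The study
names no post-hoc test after Kruskal–Wallis; this package uses Dunn's
pairwise z-tests on mean ranks with the tie-corrected variance and Holm
adjustment, implemented directly from the standard formula. Correlations
are Spearman (Pearson on average ranks, tie-robust) or Pearson, two-sided.
Degenerate inputs (all values identical) return a null result (statistic 0,
p = 1) rather than NaN; constant vectors make a correlation an error.

## Problem sizes and determinism

Default test and acceptance problem sizes were chosen as desk-scale
workloads: full-protocol phantoms (256 × 256 × 30 × 7) for the acceptance
recoveries at 20 noise seeds per condition, reduced grids (96 × 96 and
48 × 48) for unit tests, 50-seed plasma replications, 200-seed
direction/bias checks. The end-to-end pipeline demo
(`inst/extdata/demo_config.yaml`) runs the complete per-animal chain for 21
animals in about a minute. All randomness flows from explicit integer seeds
through a single splitting function, so any result in this package is
reproducible bit-for-bit from (inputs, seed); re-running a pipeline
configuration reproduces the report exactly.

## What passing tests do and do not show

The generator emulates the geometry, contrast, partial-volume and noise
structure relevant to the analysis contracts — not cardiac/respiratory
motion residuals, B1 inhomogeneity, flow artefacts, reconstruction filters,
wall plaque, or inter-animal anatomical variability. Recovery of ground
truth here validates the *analysis* (segmentation, fitting, counting and
statistics are internally consistent and unbiased under the stated model);
it does not certify accuracy on scanner data, where sequence-specific
effects enter upstream of this pipeline. The LC-MS/MS side is consumed as
finished concentration tables; quantification chemistry is out of scope.
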