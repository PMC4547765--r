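---
title: "Methods: diffusion kurtosis estimation and longitudinal ROI statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diffusion kurtosis estimation and longitudinal ROI statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dkiblast)
```

`dkiblast` implements the analysis chain of a serial preclinical
diffusion-MRI study: voxelwise diffusion kurtosis estimation from
multi-shell data, ROI summarization into a longitudinal table, a balanced
split-plot ANOVA with Fisher's LSD post-hoc tests, quality gating of
spectroscopy metabolite tables, and percent-area quantification of
fluorescence micrographs. This vignette records the models, the estimator
choices, and the places where the design was genuinely open — and what the
synthetic test bench does and does not demonstrate about real data.

## The signal model and its estimator

Along a unit gradient direction $\mathbf{n}$ with diffusion weighting $b$,
the kurtosis model for the log-signal ratio is

$$\ln\frac{S(b)}{S_0} = -b\,D_{app} + \tfrac{1}{6} b^2 D_{app}^2 K_{app},$$

with $D_{app} = \mathbf{n}^\mathsf{T} D \mathbf{n}$ and
$K_{app} = (\mathrm{MD}^2/D_{app}^2)\sum_{ijkl} n_i n_j n_k n_l W_{ijkl}$.
Setting the kurtosis tensor $W = 0$ recovers the mono-exponential tensor
model, so Gaussian diffusion is the exact null case of the fitter — a
property the test suite exercises directly.

The default estimation pathway is **per-direction**: for every acquired
direction the two parameters $(x_1, x_2) = (D_{app},\, D_{app}^2 K_{app})$
are solved by linear least squares over the shells (the model is linear in
these variables), then $K_{app} = x_2/x_1^2$. MK is the arithmetic mean of
$K_{app}$ over all measured directions, which is exactly what a
per-direction estimator yields naturally; the diffusion tensor for MD and
FA is fitted by linear least squares of $D_{app} = \mathbf{n}^\mathsf{T} D
\mathbf{n}$ to the kurtosis-corrected per-direction diffusivities. A joint
21-parameter weighted-linear mode (6 tensor + 15 kurtosis-tensor
components per voxel) is available behind `fit_mode = "joint"`; both modes
must and do pass the same forward/inverse round-trip tests, and they agree
to about $10^{-6}$ on noise-free phantoms.

Numerical guards, each recorded per voxel in an exhaustive failure code
(ok / negative-signal / degenerate / clamped):

- **S0** is the arithmetic mean of the $b=0$ volumes. Voxels with
  $S_0 \le 0$ are excluded as `negative-signal`.
- **Positivity floor**: signals below $\varepsilon S_0$ (default
  $\varepsilon = 10^{-6}$) are raised to it before the log — magnitude data
  can reach zero after smoothing near the volume edge.
- **$K_{app}$ clamp**: apparent kurtosis is clamped to $[0, 3]$. The lower
  bound removes unphysical negative kurtosis produced by noise; the upper
  bound prevents blow-up where $D_{app} \to 0$. Clamped voxels remain in
  the maps but are flagged, so ROI summaries can audit them.
- A direction whose fitted $D_{app} \le 0$ is `degenerate` and excluded
  from the MK average (with the exclusion count reported); a voxel is
  degenerate only if every direction fails.
- Tensor eigenvalues are sorted descending; negative eigenvalues are
  clamped to zero before MD/FA (and the clamp recorded).

Pre-smoothing uses a separable Gaussian with FWHM 0.3 mm (SD = FWHM/2.3548
converted to voxels per axis, so anisotropic voxels are honoured — at the
native 0.234 × 0.234 × 1 mm grid the through-plane blur is intentionally
negligible). Convolution is edge-renormalized: the kernel mass falling
outside the volume is redistributed, so constant images are preserved
exactly. Smoothing precedes masking and fitting, mirroring the processing
order of the acquisition pipelines this package emulates.

## The gradient scheme

The acquisition emulated by the defaults is 30 encoding directions at
three shells ($b = 1000/1500/2000$ s/mm²) after 5 non-weighted volumes,
with gradient timing $\delta = 4$ ms, $\Delta = 23$ ms carried as
metadata. Since no published direction table is available, direction sets
are generated by electrostatic repulsion on the sphere — inverse-square
forces between every pair of points *and their antipodes* (diffusion
encoding is symmetric under $\mathbf{n} \to -\mathbf{n}$), iterated from a
seeded random start with a decaying step. Any externally supplied unit-norm
set is accepted on input. The same direction block is reused on every
shell, and the reader reorders arbitrary on-disk volume orders into this
canonical layout, which makes all maps invariant to volume permutation.

## The synthetic test bench

The generator produces every input class with known ground truth:

- **DWI phantoms** obey the forward model exactly, voxel by voxel. Kurtosis
  ground truth may be a full 15-component $W$ or a single isotropic
  $K$; the isotropic case uses
  $W = (K/\mathrm{MD}^2)\,\mathrm{sym}(D \otimes D)$, which makes
  $K_{app}(\mathbf{n}) = K$ along *every* direction for *any* positive
  definite $D$ — so even the anisotropic "tract" phantom has a flat
  directional kurtosis profile with a known value. Rician noise
  ($\sqrt{(s+\epsilon_1)^2 + \epsilon_2^2}$) is the default, matching
  magnitude MR data; Gaussian noise exists for analytic tests. The $b=0$
  volume is replicated 5 times with independent noise, as acquired.
- **Cohort tables** draw `cell mean + subject effect + residual` —
  compound symmetry, which is precisely the covariance structure the
  split-plot ANOVA assumes. Defaults are the study design: 2 arms × 6
  subjects × 5 times. Between-subject and residual SDs both default to
  0.05 on the baseline-normalized scale, a realistic magnitude for ROI
  summaries whose group-mean standard errors sit at a few percent.
- **Metabolite tables** are generated at the fitted-concentration level
  (name, concentration, CRLB%), always with a tCr reference row; no
  spectral simulation is attempted.
- **Micrographs** place exactly `round(fraction × n)` pixels at
  `multiple × background`, making the percent-area ground truth exact by
  construction.

What passing these tests shows: the estimator inverts its own forward
model exactly, degrades gracefully under the nominal noise level (median
MK error < 0.1 at SNR 20 through the standard smoothing), and the ANOVA is
correctly calibrated (null type-I rate within the binomial interval of
0.05 over 2000 cohorts). What it does not show: robustness to motion, eddy
currents, susceptibility distortion, imperfect masks, or spatially
correlated physiological noise — none of which the generator simulates.

## Statistics

For $g$ groups, $s$ subjects per group and $t$ times, the balanced
split-plot partition is

$$SS_{total} = SS_{group} + SS_{subj(group)} + SS_{time} +
  SS_{group\times time} + SS_{resid},$$

with the group effect tested against $MS_{subj(group)}$ (df $g-1$,
$g(s-1)$) and the within-subject effects against $MS_{resid}$ (df $t-1$
resp. $(g-1)(t-1)$ over $g(s-1)(t-1)$). The implementation is the
closed-form balanced decomposition (cross-checked in the tests against
`aov()` with an `Error(subject)` stratum); unbalanced or incomplete input
is rejected with the offending cells named, because the closed-form
partition is only valid for complete balanced layouts —
`complete_case_filter()` enforces the study's own inclusion rule (subjects
must be observed at every time point). No sphericity correction is applied
by default, matching the convention of the reports this package
reproduces; the usual corrections can be layered on by the user.

**Time-level convention.** The analysis variable is the
baseline-normalized value, and the baseline level itself is *included* as
one of the five within-subject levels by default. That choice is not
arbitrary: for a two-arm, six-per-group design, interaction F statistics
carry df (4, 40) with five levels but (3, 30) with four, and recomputing
p from a published F under both conventions identifies which one produced
it — for the study this package re-implements, every printed interaction
F/p pair is consistent with df (4, 40) and inconsistent with (3, 30), so
five levels is the default and `include_baseline_level = FALSE` provides
the four-level alternative. Note that with baseline included the baseline
cells are identically 1, which only reduces the residual; the partition
remains valid.

**Fisher's LSD.** The post-hoc comparison of the two groups at a fixed
time mixes both error strata, so the default error term is the combined
mean square $MS_{cell} = (MS_{subj(group)} + (t-1) MS_{resid})/t$ with
Satterthwaite degrees of freedom; this is the standard between-group-at-
within-level contrast for split-plot designs. Because the source reports
do not state their error term, a plain per-time pooled t-test mode
(`error = "per_time"`) is provided; with a single time level the combined
term reduces exactly to the unpaired t-test, which the tests verify. LSD
p-values are deliberately unadjusted, and no correction is applied across
regions or measures.

Rank transformation (midranks, NAs preserved) is available for ordinal
outcomes and makes the ANOVA invariant to any strictly increasing
transform of the data. Histology endpoints use the classical
pooled-variance unpaired t-test with explicit degenerate-case handling
(zero pooled variance: p = 1 for equal means, flagged p = 0 otherwise).

## MRS quality control and histology

Metabolite records pass a strict CRLB gate (`CRLB < threshold`, default
20%: a record at exactly the threshold is excluded) before
metabolite-to-total-creatine ratios are formed. The gate is applied per
time point: a metabolite failing it at one scan yields a missing cell
there rather than being dropped study-wide, preserving the longitudinal
design; the missing cells are then handled by the same complete-case rule
as the imaging data. If tCr itself is absent or fails the gate the voxel
is unusable and an error is raised rather than silently imputing.

Micrograph quantification thresholds each analysis ROI at
`multiplier × background` (default 2×), where the background level is the
median — robust to stray bright pixels; a mean switch exists — of a
user-supplied unlabeled reference ROI on the *same image* (per-image
backgrounds, so batch-level intensity drift cannot bias a group
comparison). Percent ROI is `100 × n(labeled)/n(pixels)`; the measure is
invariant under global intensity rescaling and monotone non-increasing in
the multiplier. ROI geometry is specified in pixels; physical rectangle
sizes (e.g. 450 × 360 µm) convert via the microscope's µm-per-pixel
calibration.

## Problem sizes and determinism

The test suite and the acceptance script regenerate all inputs at
run time: the full 95-volume scheme on phantoms up to $32^3$ voxels for
the exact-limit checks, 600 voxels for the noise study, and 2000 synthetic
cohorts for the null calibration — sizes chosen so the whole bench runs in
a few minutes on one core while keeping the Monte-Carlo intervals tight.
Every stochastic component takes an explicit integer seed and restores the
caller's RNG state; identical configuration and seed give byte-identical
CSV outputs, which the pipeline tests assert literally.

## Known limitations

- Axial/radial kurtosis and kurtosis-tensor invariants beyond MK are out
  of scope, as are tractography and distortion/motion correction.
- The per-direction estimator needs at least two distinct positive shells
  per direction and at least six directions for the tensor; it does not
  pool information across directions under noise (no spatial or
  directional regularization).
- The split-plot ANOVA is the classical balanced decomposition, not a
  REML mixed model; subjects with missing cells must be dropped, not
  partially pooled.
- The S1-style spreadsheet importer is layout-configurable but assumes
  one record per subject × time × region × measure after mapping; truly
  bespoke layouts need a custom reader.
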