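# dkiblast

Diffusion kurtosis imaging (DKI) estimation and the downstream longitudinal
statistics used in preclinical neuroimaging studies of brain injury — in one
tested R package.

Serial multi-shell diffusion MRI can reveal microstructural injury that is
invisible on conventional T2-weighted images: mean kurtosis (MK) rises where
the tissue microenvironment becomes more heterogeneous (gliosis,
inflammation), even when mean diffusivity (MD) and fractional anisotropy
(FA) barely move. Turning raw 4D volumes into a defensible group-by-time
statistic involves a chain of steps — voxelwise model fitting, ROI
summaries, baseline normalization, a balanced split-plot ANOVA — each easy
to get subtly wrong. `dkiblast` implements that chain end to end, together
with a synthetic-data module that generates every input class with known
ground truth, so the whole pipeline is verifiable without a scanner.

## The model

For a gradient direction **n** and diffusion weighting b (s/mm²), the DKI
signal model extends the mono-exponential tensor model with a quadratic
term:

    ln S(b)/S0 = -b · D_app + (1/6) · b² · D_app² · K_app

where `D_app = nᵀ D n` is the apparent diffusivity along **n** and `K_app`
the apparent (excess) kurtosis along **n**, with
`K_app = (MD²/D_app²) · Σ nᵢnⱼnₖnₗ Wᵢⱼₖₗ` for the rank-4 kurtosis tensor W
and `MD = trace(D)/3`. Per voxel the package fits each direction's
`(D_app, K_app)` by linear least squares over the shells, assembles the
diffusion tensor from the per-direction diffusivities, and reports:

- **MD** — mean of the tensor eigenvalues (mm²/s),
- **FA** — `sqrt(3/2)·sqrt(Σ(λᵢ−MD)²)/sqrt(Σλᵢ²)` ∈ [0, 1],
- **MK** — the arithmetic mean of `K_app` over all measured directions.

Downstream, ROI means (bilateral regions averaged) are normalized to each
subject's pre-injury baseline, subjects missing any time point are dropped,
and a balanced two-way mixed-design (split-plot) repeated-measures ANOVA
tests group, time and group-by-time effects, with Fisher's LSD post-hoc
group comparisons at each time point. Spectroscopy tables are gated on the
Cramér–Rao lower bound (CRLB < 20%) and expressed as metabolite/tCr ratios;
fluorescence micrographs are quantified as the percent of ROI pixels above
2× the background intensity.

## Worked example

```r
library(dkiblast)

# acquisition: 30 directions x b = 1000/1500/2000 s/mm2 + 5 b0 volumes
scheme <- make_scheme(30, c(1000, 1500, 2000), n_b0 = 5, seed = 1)

# a two-compartment phantom: MK 0.6 on the left, 1.2 on the right
truth  <- phantom_geometry("two_block", dim = c(12, 12, 4), K1 = 0.6, K2 = 1.2)
series <- make_phantom(truth, scheme, sigma = 50, seed = 1)  # SNR 20

maps <- fit_volume(smooth_dwi(series, fwhm_mm = 0.3))
maps
#> <param_maps> 12 x 12 x 4 voxels; 217 ok, 359 clamped, 0 degenerate, 0 negative-signal
# ("clamped" counts voxels where at least one direction's noisy K_app was
#  pulled back into the physical [0, 3] range; their maps remain usable)

# longitudinal cohort with an injured-arm MK bump at d7/d14, then the stats
shift <- matrix(1, 2, 5); shift[2, 3:4] <- 1.15
tab <- make_cohort_table(cohort_spec(n_per_group = 6, means = list(MK = shift), seed = 1))
fit <- mixed_anova(complete_case_filter(normalize_to_baseline(tab)),
                   value_col = "normalized_value")
fit
#> Split-plot repeated-measures ANOVA: MK (2 groups x 6 subjects x 5 times)
#>   group         F(1,10) = 2.779, p = 0.126
#>   time          F(4,40) = 17.180, p = 0.000
#>   group_x_time  F(4,40) = 9.629, p = 0.000
fisher_lsd(fit)   # per-time group differences, unadjusted LSD convention
```

A transient two-time-point bump shows up exactly as it should: a strong
group-by-time interaction with little marginal group effect (the shift
averages out across the five levels).

The printed F ratios follow the classical split-plot convention: the group
effect is tested against the subject-within-group mean square (df 1, 10 for
2 × 6 rats), time and the interaction against the residual (df 4, 40 over
five time levels).

The same chain runs from the shell:

```sh
dkiblast all --config demo.yaml --seed 1 --out out/
```

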