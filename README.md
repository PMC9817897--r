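# dabscore

Digital immunoreactive scoring of DAB-immunostained tissue-microarray
(TMA) cores, with the downstream statistics used to compare scores between
histological groups — and a synthetic H-DAB image generator so the whole
pipeline is testable without any patient material.

## Who this is for

Pathology and cancer-biology groups that stain TMA cores with a
diaminobenzidine (DAB) chromogen over a hematoxylin counterstain and want a
reproducible, observer-free score per core, plus the statistical layer to
compare those scores across groups (e.g. Gleason patterns in prostate
cancer) and to analyse the accompanying Western-blot and plate-assay data.

## What it computes

Per core, from an 8-bit RGB brightfield image:

1. **Tissue mask** — "Minimum" histogram auto-threshold on Rec.601
   luminance (tissue is the dark side; background is near-white slide).
2. **Stain separation** — Beer–Lambert colour deconvolution. In optical
   density $OD = \log_{10}(I_0/I)$ co-localised stains add linearly, so the
   per-pixel stain amounts are the exact linear inverse of the
   Ruifrok–Johnston H-DAB stain matrix applied to the OD vector.
3. **DAB mask** — "Default" (legacy IsoData, intermeans fixed point)
   threshold on the deconvolved DAB image, intersected with the tissue mask.
4. **The score** —

   $$\mathrm{area\%} = 100\,\frac{|\mathrm{DAB}\cap\mathrm{tissue}|}{|\mathrm{tissue}|},\qquad
     \mathrm{DABwt\%} = 100\,\frac{\sum_v h_v\,(255-v)}{255\,\sum_v h_v},\qquad
     \mathrm{IRS} = \mathrm{area\%}\times\mathrm{DABwt\%}$$

   where $h_v$ is the histogram of the deconvolved DAB image over the
   scored region (DAB-positive tissue by default). IRS ranges 0–10000.

Downstream: a heteroscedastic group model (per-group means *and*
variances, pairwise Welch–Satterthwaite contrasts, Holm adjustment), a
date-blocked linear model with estimated marginal means, a
negative-binomial GLM (log link, ML dispersion) for fluorescence
intensities, loading-control normalisation, per-date fold changes tested
against 1, and Pearson/Spearman correlation utilities.

## Worked example

Simulate a core with known ground truth (30% of the tissue DAB-positive at
1.0 OD), score it, and compare:

```r
library(dabscore)

sim <- generate_core_image(fraction = 0.30, dab_amplitude = 1.0,
                           size = 128, seed = 7)
sim$truth$realized_dab_fraction
#> [1] 0.3001101

score_core(sim$image, core_id = "demo", marker = "INHBB", gleason_group = "4")
#>   core_id marker gleason_group area_pct dabwt_pct     irs tissue_threshold dab_threshold
#> 1    demo  INHBB             4 30.01101  89.92898 2698.86              180           140
```

The scored `area_pct` (30.01) matches the realised DAB fraction of the
simulated core (30.01%) exactly here; across many seeds and fraction
levels the mean absolute error stays below 0.3 percentage points.
`dabwt_pct` ≈ 89.9 says the positive pixels transmit about 10% of light —
exactly what 1.0 OD of DAB means — and `irs` is the product of the two.
The two threshold columns record what the auto-thresholds chose, for
cross-checking against an interactive Fiji session.

Group comparison on synthetic heteroscedastic scores (means and spreads
rising with group, as a positively associated marker would show):

```r
scores <- generate_group_scores(
  group_means = c(800, 900, 1000, 1600, 2000),
  group_sds   = c(300, 340, 400, 700, 900),
  n_per_group = c(15, 10, 40, 45, 30), seed = 1)

fit_hetero_groups(scores)
#> Heteroscedastic group fit (5 groups, holm-adjusted contrasts)
#>
#>   group  n      mean  variance
#>  normal 15  830.2529  93213.20
#>     1&2 10  991.9356  89816.02
#>       3 40 1045.7720 113808.35
#>       4 45 1686.6399 432509.79
#>       5 30 1833.6886 339216.19
#>
#> Pairwise Welch contrasts:
#>  group_i group_j estimate     se    df      t     p_raw           type     p_adj sig
#>   normal     1&2  -161.68 123.27 19.70 -1.312 2.047e-01   vs_reference 6.142e-01
#>   normal       4  -856.39 125.80 51.56 -6.808 1.043e-08   vs_reference 9.389e-08 ***
#>   normal       5 -1003.44 132.37 42.84 -7.581 1.921e-09   vs_reference 1.921e-08 ***
#>       3       4  -640.87 111.61 67.26 -5.742 2.453e-07 between_groups 1.717e-06 ***
#>   ...
```

Each contrast is a Welch comparison (its `df` is the Satterthwaite
approximation from the two group variances), so the strong group-4/5
differences are detected without assuming the groups share a variance.

An end-to-end run from the shell (simulate → score → group statistics,
with a manifest for reproducibility):

```sh
inst/cli/dabscore validate --out out/ --seed 11
```

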