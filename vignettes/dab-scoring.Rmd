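---
title: "Digital immunoreactive scoring of DAB-stained cores: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Digital immunoreactive scoring of DAB-stained cores: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dabscore)
```

## The problem

Immunohistochemistry with a diaminobenzidine (DAB) chromogen deposits a
brown reaction product wherever the antibody binds; a hematoxylin
counterstain marks nuclei in blue. On a tissue microarray (TMA), many small
cores from different cases are stained together, and each core needs a
number: how much of its tissue is DAB-positive, and how strongly. Manual
scoring is slow and carries inter-observer error; `dabscore` implements the
digital alternative: colour deconvolution of the brightfield image,
histogram auto-thresholding, and a per-core **immunoreactive score (IRS)**
defined as

$$\mathrm{IRS} \;=\; \mathrm{area\%} \times \mathrm{DABwt\%},$$

the percent of tissue area that is DAB-positive multiplied by a
histogram-weighted staining intensity. Both factors live in $[0, 100]$, so
IRS lives in $[0, 10000]$.

## Colour deconvolution

A brightfield pixel transmits light multiplicatively, so staining is linear
in optical density, $OD = \log_{10}(I_0 / I)$ per channel, with $I_0 = 255$
the reference white of an 8-bit image. Co-localised stains add their OD
vectors: if $c_H$ and $c_D$ are the per-pixel hematoxylin and DAB amounts
and $\mathbf{s}_H, \mathbf{s}_D$ their unit RGB absorbance vectors, the
pixel's OD 3-vector is $c_H \mathbf{s}_H + c_D \mathbf{s}_D$. `deconvolve()`
inverts this mixing exactly with the Ruifrok–Johnston H-DAB basis
(`hdab_stain_matrix()`): hematoxylin $\approx (0.650, 0.704, 0.286)$, DAB
$\approx (0.269, 0.568, 0.778)$, each normalised to unit length. The third
("residual") vector is the normalised cross product of the two, which makes
the matrix well-conditioned and means the residual channel captures whatever
the two stains cannot explain. A user-supplied nine-float matrix can replace
the default through the configuration file.

Numerical choices worth stating:

* **Base-10 logarithms** throughout, the absorbance convention. Other
  deconvolution implementations differ only by a constant factor that
  cancels in any round trip.
* **Zero-intensity pixels** are clamped to intensity 1 before the log, so
  the darkest representable OD is $\log_{10} 255 \approx 2.41$.
* **No non-negativity clamp inside `deconvolve()`**: quantisation noise can
  produce small negative amounts, and preserving them keeps the operation
  exactly linear (and exactly invertible, which the round-trip tests
  exploit). Clamping happens only when a single stain is rendered to an
  8-bit image with `concentration_to_gray8()`, which uses the convention
  255 = unstained, 0 = maximal stain.

**Dynamic-range limit.** An 8-bit image cannot represent a channel OD much
above $\log_{10} 255$. For a single stain at amounts up to 1.5 OD the full
render-and-recover round trip is accurate to better than 0.02 OD (the
worst case, at the top of the DAB range, is about 0.019). When both stains
are near 1.5 OD *on the same pixel* their summed channel OD approaches 3,
the transmitted intensity falls to a couple of gray levels, and the
recovery error grows several-fold. This is a property of 8-bit imaging,
not of the inversion: the package's accuracy claims are therefore stated
per stain, and the synthetic generator's default amplitudes (hematoxylin
0.6, DAB 1.0) keep co-stained pixels comfortably inside the representable
range, as real well-stained tissue is.

## Auto-thresholding

Two classic histogram algorithms drive the masks, chosen to mirror the
ImageJ/Fiji methods of the same names.

**Minimum (tissue selection).** The 256-bin luminance histogram is smoothed
with a 3-point moving mean (edge bins average over the neighbours that
exist) until exactly two local maxima remain; the threshold is the lowest
gray level strictly between them where the smoothed histogram is minimal.
Tissue is the dark side. Two details depart from a naive transcription:

* **Edge modes count.** A synthetic core sits on an exactly white
  background, so the background mode is a spike in the last bin, which a
  strictly interior peak test never sees. A run touching the histogram edge
  qualifies as a maximum when it exceeds its single neighbour.
* **Plateaus are single maxima.** Repeatedly averaging integer counts
  produces exact ties; a strict per-bin test can make a genuine mode
  invisible for one iteration, letting the loop stop with the wrong pair of
  peaks (observed: a trimodal blob/tissue/background histogram collapsing
  to blob-vs-background and a tissue mask of only the stained blobs). A
  maximal run of equal values higher than both neighbouring runs is
  therefore counted as one maximum.

The iteration cap is 10,000; histograms that never become bimodal (single
spike, strictly unimodal shapes, blank white images) raise a bimodality
failure, which `score_core()` reports annotated with the core id.

**Default / legacy IsoData (DAB positivity).** Starting from the midpoint
of the occupied gray range, the threshold moves to the rounded mean of
(mean gray at or below, mean gray above) until it reproduces itself.
Rounding is half-down, so tied candidates resolve to the lowest level.
Every returned level satisfies the intermeans fixed-point property, which
the tests verify by direct evaluation over random histograms. The DAB
threshold histogram is taken over the whole deconvolved DAB image by
default (mirroring a whole-image threshold in Fiji); a configuration switch
restricts it to tissue.

Both algorithms are invariant to scaling all counts by a positive integer,
and both return levels in $[0, 255]$.

## The per-core score

`score_core()` chains the stages: Rec.601 luminance → Minimum threshold →
tissue mask; OD transform → H-DAB deconvolution → DAB gray image → IsoData
threshold ∩ tissue → DAB mask. Then

* `area_pct` $= 100\,|{\rm DAB} \cap {\rm tissue}|\,/\,|{\rm tissue}|$;
* `dabwt_pct` $= 100 \sum_v h_v (255 - v) \,/\, (255 \sum_v h_v)$, the mean
  inverted intensity of the scored region — by default the DAB-positive
  tissue, so it measures *how dark the positive staining is*; a switch
  (`dabwt_region: tissue`) scores all tissue instead;
* `irs` = their product.

The luminance choice for the tissue threshold (rather than a single
channel) is the standard 8-bit conversion. A core whose DAB image is
uniform (nothing stained) is a *biological zero* — area 0, intensity 0,
IRS 0 — not an error, so an entirely negative marker does not abort a
batch. All stages are deterministic and pixel-permutation invariant, hence
rotation-invariant, and `score_batch()` output is bit-identical across
reruns.

## The synthetic generator as oracle

No patient material ships with the package; every claim is tested against
`generate_core_image()`, which *renders through the same physics the scorer
inverts*: a circular tissue disk (radius 0.42 × image side) carrying a
hematoxylin OD field (amplitude + Gaussian texture, clamped at zero), DAB
disks rejection-placed until they cover the requested fraction of tissue
to within one percentage point, mixed through the H-DAB matrix and
quantised to 8-bit RGB. The defaults — hematoxylin 0.6 OD, DAB 1.0 OD,
texture sd 0.05 OD — are chosen as a well-stained, moderately noisy core:
DAB at 1.0 OD transmits ~10% of light (clearly brown but not saturated)
over a counterstain at 0.6 OD. The generator records the *realised* blob
fraction, and recovery tests compare the scored area against it: across
fractions 0.05–0.5 the mean absolute error is below 0.3 percentage points.

What the simulation does **not** emulate: nuclear morphology and chromatin
texture, stromal/epithelial structure, scanner optics (blur, chromatic
noise, JPEG artefacts), uneven illumination, staining gradients and edge
artefacts of real cores. Passing recovery tests therefore demonstrate that
the inversion, thresholds and bookkeeping are correct — not that the
pipeline is robust to every failure mode of real slides. On real material
the recorded per-core thresholds (columns `tissue_threshold`,
`dab_threshold`) allow a spot-check against an interactive Fiji session.

Tabular generators mirror the distributional assumptions of the statistics
layer: Gaussian group scores with group-specific means *and* standard
deviations (clipped at zero, as scores are non-negative); negative-binomial
counts with $\mathrm{Var} = \mu + \mu^2/\theta$; balanced
treatment × date × replicate assay tables with additive effects; and
bivariate-Gaussian manual/digital score pairs mapped affinely onto a
typical score scale (mean 2000, sd 800) — affinely rather than clipped, so
the sample correlation is unbiased for the target.

## The statistics layer

**Heteroscedastic group comparison.** Scores across histological groups
show spread that grows with the mean, so a pooled-variance ANOVA is the
wrong null model. `fit_hetero_groups()` gives every group its own mean and
variance; each pairwise contrast is a Welch comparison with
Satterthwaite degrees of freedom. For a single factor this is exactly the
generalised-least-squares model with a per-group variance function — the
estimands coincide — in a form that is simple to verify. The package's own
Monte-Carlo check (null with variance ratio 25, $n = 10$ per group) puts
the Welch test's size at ~0.05 while the pooled $t$ comparison exceeds
0.06: the reason the variance model matters. Contrasts against the
reference group (normal tissue) are flagged separately from
between-pattern contrasts, matching the two annotation styles of
group-comparison figures. Report thresholds for significance stars are
0.05 / 0.01 / 0.001.

**Multiplicity.** Holm's step-down adjustment is the default everywhere.
Tukey-style adjustments assume homoscedasticity, which the variance model
above explicitly rejects; Holm controls the family-wise error rate under
arbitrary dependence and never under-corrects relative to Bonferroni.
`p_adjust: bonferroni|none` are available for comparison. Scores are
modelled untransformed by default; any transformation is left to the
caller.

**Date-blocked linear model.** Plate assays drift day to day, so the
testing date enters `fit_blocked_ols()` as an additive blocking factor
(`value ~ treatment + date`, no interaction). Treatment summaries are
estimated marginal means — predictions averaged over date levels, computed
with the emmeans package — with pairwise contrasts adjusted as above. On a
balanced design the marginal means equal the raw treatment means regardless
of the date effects (verified to 1e-8), and with zero residual noise the
fit recovers the generating coefficients exactly.

**Negative-binomial GLM.** Fluorescence intensities show variance growing
faster than the mean; `fit_nb_glm()` fits a log-link negative-binomial
regression by IRLS for the coefficients alternated with maximum-likelihood
estimation of $\theta$ (moment start, Newton on the profile score),
converging when both relative changes fall below $10^{-8}$; non-convergence
within 100 iterations is flagged in the result, never silently accepted.
Standard errors come from the inverse Fisher information at the optimum.
The implementation is checked against `MASS::glm.nb` on shared data
(agreement to ~1e-5) and against a Poisson fit in the large-$\theta$ limit;
parameter-recovery simulations at $n = 500$ give 95% Wald coverage within
[92%, 98%].

**Normalisation and fold changes.** Band intensities divide lane-by-lane by
the loading control (`normalize_to_loading_control()`); per-date ratios of
treated to control lines are tested against 1 with a one-sample $t$ test
(`fold_changes()`), with degenerate zero-variance cases mapped to $p = 0$
or $p = 1$ as appropriate. `pearson_corr()` and `spearman_corr()` (Pearson
on mid-ranks, $t$-approximation p values) cover the manual-vs-digital and
marker-vs-marker validations.

## Reproducibility

Every generator is a pure function of (parameters, seed). Pipeline runs
write a `manifest.json` recording the package version, configuration echo,
seed and input hashes; the `validate` subcommand (simulate 20 cores in four
groups → score → group statistics) produces bit-identical CSVs across
reruns with the same seed. Problem sizes used by the shipped checks — 96 ×
96-pixel cores, 25 cores per fraction level, 10,000 Monte-Carlo null
replicates, 200 negative-binomial recovery fits at $n = 500$ — were chosen
so the whole battery runs in a few minutes on a single CPU while keeping
Monte-Carlo error well inside the tolerance bands.

## Known limitations

* Fixed-basis deconvolution only: no per-slide stain-vector estimation
  (Macenko-style), no whole-slide handling or core de-arraying.
* The two thresholds shipped are the two the scoring procedure names;
  the other ImageJ auto-threshold variants and local/adaptive thresholding
  are out of scope.
* No separation of stromal and epithelial compartments and no nuclear
  counting: the score is a whole-core quantity by design.
* The threshold implementations follow this package's written definitions
  (smoothing kernel, edge and plateau rules, half-down rounding); other
  IsoData flavours and other Minimum transcriptions can differ by a few
  gray levels on the same histogram.
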