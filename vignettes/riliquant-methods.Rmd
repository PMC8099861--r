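---
title: "Quantifying radiation-induced lung injury: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying radiation-induced lung injury: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riliquant)
```

## The study design this package serves

Large-animal models of radiation-induced lung injury (RILI) irradiate one
lung (here the left caudal lobe of sheep, 5 x 6 Gy) and follow both lungs
longitudinally: a baseline CT before treatment, an acute scan about three
weeks after, and a chronic scan just before necropsy (the necropsy day
varies by animal, e.g. day 171 or 227). The un-irradiated right lung serves
as the within-animal control, so every imaging or histology variable is
analysed as the paired difference

$$\Delta = x_\mathrm{Rx} - x_\mathrm{CON},$$

which removes between-animal level differences before any time-course
modelling. `riliquant` implements the full quantitative chain for such a
study: masked CT radiomics, colour-deconvolution histomorphometry,
radiotherapy-plan summaries, the longitudinal statistics, and a synthetic
phantom generator that makes the whole chain testable without raw images.

## CT radiomics

### Regions

Two regions are used per lung and slice. First-order statistics are
computed on a *subpleural band*: the rim of lung pixels whose Euclidean
distance to the nearest non-lung pixel is at most `depth_px` (default 10).
We derive the band from the mask with a distance transform
(`subpleural_band()`), replacing manual brush selection with a
deterministic, mask-derived definition; if the lung is nowhere thicker
than the band depth the whole lung is returned with a warning. Texture
statistics are computed on thresholded *parenchyma*: mask pixels whose CT
number lies in the closed aerated-lung window [-1024, -242] HU
(`threshold_parenchyma()`). Pixels outside a region are background; they
are carried as `NA` sentinels and can never reach any statistic (a
property the test suite checks bit-for-bit).

### First-order statistics

`first_order_stats()` reports area (pixel count times pixel area), mean,
SD, CV, min, max, skewness and kurtosis of the region HU values. SD uses
the n-1 denominator. Skewness and kurtosis use population central moments
(`m3/m2^1.5`, `m4/m2^2 - 3`), with kurtosis reported as *excess*: the
reference per-animal tables contain negative kurtosis values, which is
only consistent with the excess convention. CV is reported verbatim as
SD/mean, so it is negative for the (negative) HU means of aerated lung;
we do not take absolute values. Degenerate inputs (n < 2, zero variance)
yield `NA` rather than silent zeros.

### Grey-level co-occurrence matrices

Region HU values are quantized to integer levels 1..64 by equal-width
binning (`quantize_levels()`), values outside the grey limits clamping to
the end bins. The grey limits default to the observed min/max of the
region - the default behaviour of the common GLCM tooling this
reproduces - with an explicit option to fix them (e.g. to the parenchymal
window) for cross-slice comparability; the limits actually used are
recorded in the output. One-pixel offsets at 0, 45, 90 and 135 degrees are
used, with the convention (image rows increasing downward):

| angle | (row, col) offset |
|------:|:------------------|
| 0     | (0, 1)            |
| 45    | (-1, 1)           |
| 90    | (-1, 0)           |
| 135   | (-1, -1)          |

A pair counts only when both pixels are inside the region. Each GLCM is
made symmetric by adding its transpose and normalized to sum to one.
Contrast, correlation, energy and homogeneity are computed per direction
and the *statistics* - not the matrices - are averaged over the four
directions, matching the reference procedure of computing per-GLCM
statistics and presenting their average. Correlation is undefined for a
direction whose marginal variance is zero (e.g. constant regions); such
directions are excluded from the average with a warning.

Entropy deliberately does not come from the GLCM: it is the Shannon
entropy in bits, $-\sum_i p_i \log_2 p_i$, of an equal-width histogram of
the region's raw HU values. The bin count defaults to 256 (the default of
the histogram tooling the procedure mirrors) and is configurable; the
sensitivity to this choice is the main reason it is exposed. A constant
region has entropy 0 and a histogram-uniform region attains the maximum
$\log_2 n_\mathrm{bins}$.

## Longitudinal and comparative statistics

### Phase pooling and the repeated-measures ANOVA

Because the chronic scan day differs between animals, raw study days give
an unbalanced layout. `study_phase()` pools days into the three design
occasions - baseline (< 0), acute (<= 90 d), chronic (> 90 d) - and
`rm_anova()` analyses the paired differences as a balanced two-way
layout: subjects as a random blocking factor, occasion as the fixed
effect. For the balanced complete case the mixed-model F-test reduces to
the closed-form partition

$$SS_\mathrm{total} = SS_\mathrm{time} + SS_\mathrm{sheep} + SS_\mathrm{error},
\qquad F = \frac{SS_\mathrm{time}/(t-1)}{SS_\mathrm{error}/((t-1)(s-1))},$$

which is what we implement (and cross-check against `stats::aov` in the
tests). Unbalanced designs are refused with an explicit error rather than
silently approximated; general mixed models are out of scope. With the
bundled per-animal tables (4 sheep x 3 occasions) the design has df (2, 6).

Data transforms follow a recorded policy rather than ad-hoc judgement:
with `transform = "auto"`, a Kolmogorov-Smirnov test against a normal
with the sample moments is run first and `log10(x - min(x) + 1)` applied
only if it rejects at 0.05; the decision is stored in the result. The KS
p-value is conservative because the parameters are estimated from the
sample; we flag this (`params_estimated`) instead of applying a
Lilliefors-type correction, keeping the test exactly as named in the
source procedure.

`one_way_anova()` (for comparisons against archived acute-cohort control
sections) delegates to the standard linear-model partition, and
`pearson_correlation()` to the product-moment formula with the two-sided
t conversion $t = r\sqrt{(n-2)/(1-r^2)}$.

### qPCR

Standard curves are ordinary least squares of Cq on log10 dilution;
amplification efficiency is $E = 10^{-1/\mathrm{slope}}$, so a perfectly
doubling reaction has slope $-1/\log_{10} 2 \approx -3.32$. Relative
quantification converts each Cq to a relative template amount through its
own gene's curve and reports the target/reference ratio. Curves with
non-negative slope are rejected as invalid.

## Histomorphometry

Brightfield fields are converted to optical density per channel,
$OD_c = -\log_{10}((I_c + 1)/I_{0,c})$ (the +1 keeps full absorption
finite; negative ODs from noise are clipped), and unmixed with a 3x3
stain-vector matrix whose rows are unit-norm per-stain OD directions.
The bundled vector sets are the classical haematoxylin + DAB pair for
immunostains and a red-dominant vector for Picrosirius Red; both complete
the third row with the normalized cross product. The source macros'
actual vectors are not published, so ours are explicit defaults,
overridable, and calibratable from a pure-stain control image
(`calibrate_stain_vector()`). The same applies to the positivity
threshold (OD > 0.15) and the cell size filter (20-500 um^2): they are
configuration with sensible defaults, not published constants, and no
result in this package depends on matching unpublished per-field numbers.

Tissue is defined photometrically (brightness below 230 or saturation
above 0.04), and all "per unit tissue area" quantities use that mask.
Positive cells are counted by thresholding the stain channel, a
morphological opening (radius 1 px) to remove speckle, 8-connected
component labelling, and the physical size filter. Per-subject values are
unweighted means over all valid fields - the aggregation the study
describes - with invalid (no-tissue) fields excluded and empty groups
reported as missing with a warning.

## Plan summaries

`ptv_lung_fraction()` interprets "total lung volume" as the sum of the
left and right lung volumes, the only volumes the summary table carries;
this interpretation reproduces all three published cohort numbers (mean
10.7%, range 9.1-11.8%). Percentages are computed from exact volumes and
rounded half-up to one decimal only at the end. Goal checks use the
thresholds as stated (mean PTV > 29 Gy, right-lung mean < 1 Gy, V1 < 10%,
PTV fraction < 15%), with a 0.05 Gy tolerance on the 1 Gy bronchus
maximum because the table prints one decimal; the 95%-of-PTV coverage
goal needs a dose-volume histogram and is reported as not evaluable.

## The synthetic phantoms

The CT generator builds each lung as an independent Gaussian random
field: white noise smoothed at a correlation scale (default 2 px),
standardized, then scaled to the target SD (110 HU) around the target
mean (-600 HU) and clipped to [-1024, 100] HU. Radiation effects are
additive on the Rx lung: acute +140 HU mean and +60 HU SD; chronic
-110 HU mean plus 2 px of extra smoothing. The magnitudes are calibrated
to the sign and approximate size of the paired differences in the bundled
per-animal tables - they are generator defaults, not claims about any
real cohort. Texture is induced through the smoothing scale because GLCM
features are emergent: homogeneity cannot be set directly, but smoothing
provably concentrates co-occurrences near the diagonal, and the
monotonicity (more smoothing, higher homogeneity, lower contrast) is a
tested property.

The histology generator composes fields through the same Beer-Lambert
model the quantification inverts: a diffuse stain region occupying an
*exact* pixel fraction (selected as the top quantile of a smoothed noise
field, so the truth is known to the pixel), disjoint discoid cells placed
by rejection sampling, and a uniform counterstain wash that makes every
pixel register as tissue. Gaussian 8-bit noise (SD 2) and quantization
are applied last. Because composition and analysis share only the model,
not code paths, recovery is a genuine round trip; after 8-bit
quantization we require the bulk of pixels (mean and 99th percentile of
the absolute concentration error) to recover closely rather than exact
equality.

What the phantoms do *not* emulate: lung anatomy, attenuation physics and
scanner noise spectra, registration error between timepoints, slide-level
stain variation, overlapping or non-circular nuclei. Passing the recovery
tests therefore demonstrates that the measurement chain is correct and
well calibrated, not that it is robust to every artefact of real data.

## Monte-Carlo calibration and problem sizes

Two simulation studies back the statistical claims, with sizes chosen to
keep the full suite fast while leaving Monte-Carlo error well inside the
tolerances: (i) effect recovery - 20 independent phantom studies at the
default 96 x 96 geometry must reproduce the acute-positive /
chronic-negative HU-mean difference pattern in at least 95% of runs;
(ii) null calibration - 1000 phantom studies at 64 x 64 with all effects
zero, where the RM-ANOVA rejection rate at alpha = 0.05 must lie within
0.05 +/- 0.02 (the F-test is exact under these conditions, so this is a
check on the whole simulate-measure-difference-test chain, not on the
F distribution). The histology round trip uses 100 fields of 256 x 256 px
at 0.5 um/px with 12% stained fraction and 12 cells of 50 um^2.

## Numerical choices and degenerate inputs

* Quantization clamps out-of-window values to the end bins; degenerate
  grey limits (lo = hi) map everything to level 1 with a warning.
* Empty regions (no lung pixels in the HU window, no valid GLCM pairs,
  empty tissue masks) raise errors; they are never silent zeros.
* `0 log 0` terms in the entropy sum are dropped by convention.
* GLCM symmetry is by construction (counts plus transpose), so the
  symmetry test is a guard against regressions, not a numerical check.
* Ties in the diffuse-region quantile selection are broken by `order()`'s
  stable ordering, keeping the generator deterministic.
* All generators are pure functions of (config, seed); the orchestrated
  pipeline writes byte-identical CSV/JSON outputs for identical inputs.

## Known limitations

* 2-D, single-slice radiomics only: no volumetric features, no automatic
  segmentation, no inter-timepoint registration.
* The closed-form RM-ANOVA covers balanced complete designs only.
* Colour deconvolution assumes the Beer-Lambert mixing model with
  spatially constant stain vectors; heavily co-localized stains degrade
  unmixing accuracy.
* DICOM input is not supported in this implementation; CT slices are
  read from 16-bit TIFF with a JSON sidecar carrying spacing and the
  linear HU calibration.
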