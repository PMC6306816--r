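---
title: "Quantifying fibril and cell alignment with fibrilign"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying fibril and cell alignment with fibrilign}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibrilign)
```

## The measurement problem

Cells growing on fibrillar substrates — corneal keratocytes on
microfluidically deposited collagen mats are the motivating system — tend to
orient along the fibrils (contact guidance), and the strength of that
co-alignment changes with soluble cues such as PDGF or TGF&beta;. Quantifying
it from micrographs requires two ingredients:

1. **The angular content distribution I(&phi;)** — the percent of image
   content attributable to structures oriented at each angle &phi; in
   [&minus;90&deg;, 90&deg;). fibrilign derives it from the 2D Fourier power
   spectrum: structures oriented at &phi; concentrate spectral energy along
   the perpendicular frequency direction, so integrating in-band power over
   frequency-space angle (and rotating by 90&deg; back into real space)
   yields the distribution. Orientations are *axial* data — a fibril at
   &phi; and &phi; + 180&deg; is the same fibril — so everything is reduced
   modulo 180&deg;.

2. **The orientation index** summarising I(&phi;) against a reference
   direction &theta; (the known fibril axis):

   $$\mathrm{OI}(\theta) = \left\{\,2\,\langle \cos^2(\phi - \theta)\rangle - 1\,\right\}\cdot 100\%,
   \qquad
   \langle \cos^2 \rangle = \frac{\sum_\phi I(\phi)\cos^2(\phi-\theta)}{\sum_\phi I(\phi)}.$$

   OI is +100% for content fully parallel to &theta;, &minus;100% fully
   perpendicular, and 0% for random orientations. By the double-angle
   identity it equals the I-weighted mean of cos 2(&phi;&minus;&theta;)
   &times; 100; `orientationIndex()` computes both forms and insists they
   agree to 10^&minus;9^, and the identity
   OI(&theta;+90&deg;) = &minus;OI(&theta;) is exact.

Per-condition OI samples are compared with classical one-way ANOVA followed
by Holm-Sidak step-down-adjusted pairwise comparisons
(`compareConditions()`), the standard workflow for this kind of experiment.

## The spectral estimator in detail

`orientationDistribution()` proceeds as follows; every choice here is a
deliberate numerical decision:

* **Padding.** Non-square or non-power-of-two images are centered in a
  square power-of-two canvas filled with the image mean. Padding (rather
  than resampling) preserves the angular metric exactly.
* **Mean subtraction before windowing.** Subtracting the mean first makes a
  constant image transform to exactly zero, which is then reported as a
  `"no structure"` error rather than a silently uniform distribution — an
  all-zero spectrum usually means an upstream masking mistake.
* **Hann window (default).** A finite image is implicitly periodized by the
  DFT; the resulting edge discontinuities produce a bright axis-aligned
  cross in the spectrum that would masquerade as 0&deg;/90&deg; alignment.
  The Hann window suppresses it. `window = "none"` is retained because
  integer-frequency test gratings are genuinely periodic and need no
  apodization.
* **Annular band.** Frequencies below `lowFreqCutoffPx` (default 4
  frequency-plane pixels — uneven illumination and other large-scale
  background) and above `highFreqCutoffFraction` of Nyquist (default 0.9 —
  pixel-level noise) are excluded.
* **Power weighting (default).** Squared spectral magnitude; `"amplitude"`
  is offered as an alternative weighting.
* **Binning.** Each spectral sample is assigned to the 1&deg; bin (default
  `nBins = 180`) containing its angle — nearest-bin accumulation, no
  interpolation, so the result is simple to reason about and to test.
  Percentages are normalized to sum to 100; discrete integrals such as the
  OI are Riemann sums over bins.
* **The 90&deg; rotation into real space happens inside the estimator.**
  All downstream angles are real-space structure orientations (0&deg; =
  image x-axis, counterclockwise positive, y up). Keeping frequency-space
  angles out of the interface prevents the classic off-by-90&deg; bug.
* **Ties in `peakOrientation()`** break toward the smallest angle, so a
  perfectly uniform distribution reports &minus;89.5&deg; — a documented
  convention, not a measurement.

`orientationIndex()` accepts any finite reference angle and reduces it into
[&minus;90&deg;, 90&deg;); the pipeline default is &theta; = 90&deg;,
matching substrates whose fibrils are patterned vertically, and analyses of
horizontally deposited fields simply pass `thetaRefDeg = 0`.

## The independent structure-tensor oracle

`structureTensorDistribution()` estimates the same distribution from image
gradients: Scharr-kernel derivatives, Gaussian-smoothed structure tensor
(default `smoothingPx = 2`), per-pixel orientation from the tensor
eigen-direction, weighted by the eigenvalue difference (the local
anisotropic energy). It shares the binning and normalization contract, so
the two estimators can be compared bin for bin. They are algorithmically
unrelated — one global and spectral, one local and differential — which is
what makes their agreement on synthetic fields informative.

Scharr kernels matter: plain central differences have an anisotropic
frequency response that biases thin-stroke orientations toward the
&plusmn;45&deg; diagonals by several degrees, which we found unacceptable
for an oracle with a &plusmn;5&deg; agreement contract.

## What the synthetic generator emulates

`generateFibrilField()` renders curvilinear fibril strokes over a flat
background with additive Gaussian noise:

* **Orientation law.** Fibril base orientations follow a von Mises
  distribution on the *doubled* angle 2&phi; with concentration &kappa;
  (`dispersionKappa`) — the standard axial-data construction.
  &kappa; = 0 is uniform (the "random" substrate); the circular standard
  deviation of orientation is approximately 1/(2&radic;&kappa;) radians,
  about 2.9&deg; at &kappa; = 100. The sampler (Best–Fisher rejection) is
  exposed as `sampleAxialOrientations()` so the law itself is testable.
* **Waviness.** Each fibril path is perturbed by a sinusoid perpendicular
  to its axis (defaults: amplitude 3 px, wavelength 60 px), echoing the
  wavy, interwoven look of flow-deposited collagen. This is *not* cosmetic
  for angular statistics: the tangent angle oscillates by
  &plusmn;atan(2&pi;A/&lambda;) &asymp; &plusmn;17&deg; at the defaults,
  which broadens I(&phi;) into a bimodal band around the base orientation
  and caps the achievable OI of a perfectly concentrated field near 85%
  rather than 100%. Tests that probe recovery of the orientation *law*
  (high-&kappa; OI bounds, cross-estimator peak agreement) therefore use
  waviness-free fields, while tests of the qualitative &kappa;&rarr;OI
  dose-response keep the default waviness.
* **Rendering.** Strokes are anti-aliased (linear edge profile) and
  composited by maximum, so crossings stay at stroke intensity instead of
  summing — matching how overlapping fibrils look in a micrograph rather
  than how they would add in a transmission model.
* **Scale.** Default raster 1024 &times; 1024 px at 0.3 &micro;m/px, so a
  1 mm freeze-wound disc (500 &micro;m radius, `woundSpec()`) fits with
  margin.
* **Determinism.** One integer seed drives a private RNG stream per
  operation (the caller's `.Random.seed` is saved and restored), and
  identical spec + seed is guaranteed bit-identical. Each generated raster
  records its spec and the sampled ground-truth orientations in its
  provenance, and `writeImageRaster()` writes a JSON sidecar from which the
  image can be regenerated exactly.

`generateCells()` composites dendritic (round body plus thin radiating
processes), elongated (capsule of a given axis ratio; ratio 1 degenerates
to a disc) or circular silhouettes — caricatures of serum-free, PDGF- and
TGF&beta;-treated keratocyte morphologies. The cell body radius (12 px) and
process length (60 px) are package defaults chosen to be proportionate on
the default raster; the underlying substrate raster and the binary cell
mask are stored in provenance. `applyWound()` then removes all cell content
strictly inside the wound disc and restores the recorded substrate there —
emulating a cryo-probe injury that detaches cells without disturbing the
collagen. On rasters without a recorded substrate the fill falls back to
the median of non-cell pixels.

What the generator does **not** emulate: optics (no PSF, no DIC shear
artifacts), fibril thickness variation or rope-like substructure,
cell-substrate intensity interactions, or any dynamics. Passing tests
demonstrate that the estimators recover known angular structure from
fibril-like textures; they do not certify performance on real micrographs
with different contrast mechanisms.

## Regional analysis and the pipeline

`tileRegions()` cuts an image into a non-overlapping grid (tiles of at
least 64 px) and labels each tile `wound` (entirely inside the disc),
`non-wound` (entirely outside) or `discarded` (straddling). Discarding
straddlers avoids analyzing tiles that contain the sharp wound boundary,
whose edge would contribute spurious spectral energy. Which regions a real
study would analyze is a convention; this tiling is ours and is stated in
the output's `region` column.

`runPipeline()` orchestrates simulate &rarr; analyze &rarr; compare from a
YAML configuration, writing a per-image `results.csv` (fixed, versioned
columns: `image_id, condition, region, peak_deg, oi_percent,
theta_ref_deg, n_bins, params_hash`), a `comparison.csv` with the ANOVA and
Holm-Sidak table, and a JSON `manifest.json` echoing the configuration.
Identical configuration and seed produce byte-identical CSVs. OI is
computed per image (or per tile), not per segmented cell: the analysis
operates on raw image content, and cell segmentation is out of scope by
design.

A small utility, `wallShearRate()`, converts a syringe-pump flow rate to
the parallel-plate wall shear rate 6Q/(wh&sup2;). For a 1500 &times; 60
&micro;m channel at 7.5 &micro;L/min it gives 138.9 s^&minus;1^; this
approximation ignores side-wall effects, and published values for such
setups may quote moderately higher numbers, so the function is documented
as approximate.

## Statistical choices

* Classical (pooled-variance) one-way ANOVA is the default, matching the
  named method; a Welch flag is available. Degenerate inputs have
  documented sentinels: zero within-group variance with unequal means
  reports F = &infin;, p = 0; all-identical values report F = 0, p = 1.
* Holm-Sidak: sort ascending, adjust step i of m by
  1 &minus; (1 &minus; p)^(m&minus;i+1)^, enforce a running maximum,
  restore input order. This is implemented directly (and verified against
  hand-computed cases) because the common `p.adjust` offerings provide
  Holm-Bonferroni, not the Sidak-based step-down.
* Pairwise comparisons cover all condition pairs, with pooled-MSE t
  statistics on the ANOVA residual degrees of freedom.
* Each analyzed image contributes one OI observation; if a study design
  nests images within experiments, the table interface lets the caller
  aggregate before comparison.

## Test problem sizes

The suite validates the estimators at two scales chosen to balance
statistical stability against runtime: quick unit checks use 256 px
rasters with 80 fibrils, while end-to-end checks (OI recovery bounds,
cross-estimator agreement, &kappa; dose-response) use 512 px rasters with
150 fibrils or the full default 1024 px rasters with 300 fibrils. At the
&kappa; = 0 extreme the 512 px/150-fibril scale keeps the sampling
fluctuation of OI within about &plusmn;7%, comfortably inside the
&plusmn;10% band the tests assert; smaller rasters fluctuate more. The
ANOVA type-I calibration uses 1000 null replicates of three groups of
eight.

## Known limitations

* The spectral estimator reports orientation of *content*, not of objects:
  images mixing fibrils and cells yield a blend weighted by contrast, and
  nothing separates the two without masks.
* Argmax of a broad distribution (&kappa; &le; 5) is intrinsically noisy
  at 1&deg; binning; peak-based comparisons at low concentration are only
  meaningful averaged over replicates.
* With the default waviness the maximum attainable OI is about 85%, so OI
  values from wavy synthetic fields should not be compared against
  perfectly straight-fibril expectations.
* The wall-shear-rate utility is a thin-channel approximation, documented
  as such.

## A worked example

```{r example}
spec <- fibrilFieldSpec(meanAngleDeg = 0, dispersionKappa = 50, seed = 1)
img  <- generateFibrilField(spec)
dist <- orientationDistribution(img)
peakOrientation(dist)
orientationIndex(dist, thetaRefDeg = 0)
```

```{r compare}
tab <- data.frame(
  condition  = rep(c("serum-free", "PDGF", "TGFb"), each = 4),
  oi_percent = c(21, 25, 19, 30, 62, 70, 58, 66, 60, 68, 55, 71))
compareConditions(tab)
```
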