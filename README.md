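# fibrilign

Fourier-based orientation analysis of fibrillar micrographs: how strongly
are fibrils — or the cells growing on them — aligned, and along which
direction?

The package is written for quantitative microscopy of contact guidance:
cells (the motivating system is corneal keratocytes) cultured on aligned
fibrillar collagen co-orient with the fibrils, and the degree of
co-alignment shifts with growth-factor treatment. fibrilign turns a
grayscale micrograph into two numbers a biologist can compare across
conditions, and ships a fully seeded synthetic micrograph generator so the
whole pipeline is testable against known ground truth without any imaging
data.

## The statistics at its core

**Angular content distribution.** For an image with structures at angles
φ ∈ [−90°, 90°) (axial data, identified mod 180°), the 2D FFT power
spectrum concentrates energy perpendicular to each structure. Integrating
in-band spectral power over frequency angle and rotating by 90° back into
real space gives I(φ), the percent of image content oriented at each angle
(`orientationDistribution()`, 1° bins by default, normalized to 100).

**Orientation index.** Against a reference angle θ (the known fibril
direction),

    OI(θ) = {2⟨cos²(φ − θ)⟩ − 1} · 100% ,
    ⟨cos²⟩ = Σ I(φ) cos²(φ − θ) / Σ I(φ)

so OI = +100% for content parallel to θ, −100% perpendicular, 0% random
(`orientationIndex()`). An independent structure-tensor estimator
(`structureTensorDistribution()`) provides a cross-check, and per-condition
OI samples are compared by one-way ANOVA with Holm-Sidak post-hoc
adjustment (`compareConditions()`).

The synthetic generator (`generateFibrilField()`, `generateCells()`,
`applyWound()`) draws fibril orientations from a doubled-angle von Mises
law with concentration κ, renders wavy anti-aliased strokes, composites
cell silhouettes, and can punch a circular freeze-wound that removes cells
while leaving the substrate intact — all bit-reproducible from one seed.

## Worked example

```r
library(fibrilign)

spec <- fibrilFieldSpec(meanAngleDeg = 0, dispersionKappa = 50, seed = 1)
img  <- generateFibrilField(spec)
img
#> ImageRaster: 1024 x 1024 px (0.3 um/px), channel 'synthetic fibrils'
#>   intensity range [0.025, 0.951]
#>   provenance: spec, orientationsDeg

dist <- orientationDistribution(img)
dist
#> OrientationDistribution: 180 bins over [-90, 90) [fft]
#>   peak at 0.5 deg (6.17% of content); total energy 1.69e+10

orientationIndex(dist, thetaRefDeg = 0)
#> OIResult: OI(0.0 deg) = 84.55%  (180 bins)
```

The field was generated with mean orientation 0° and high concentration
(κ = 50): the spectral peak lands half a bin from 0°, and the OI against
the deposition direction is 84.6% — strongly co-aligned, short of 100%
because the default fibril waviness (±17° tangent oscillation) broadens the
angular content, exactly as it does in real flow-deposited collagen.

Comparing conditions:

```r
tab <- data.frame(
  condition  = rep(c("serum-free", "PDGF", "TGFb"), each = 4),
  oi_percent = c(21, 25, 19, 30, 62, 70, 58, 66, 60, 68, 55, 71))
compareConditions(tab)
#> GroupComparison: 3 conditions (PDGF, serum-free, TGFb)
#>   group mean OI (%): PDGF=64.0, serum-free=23.8, TGFb=63.5
#>   ANOVA F = 61.6, p = 5.607e-06
#>   Holm-Sidak pairwise:
#>     PDGF vs serum-free: p_raw = 4.721e-06, p_adj = 1.416e-05
#>     PDGF vs TGFb: p_raw = 0.907, p_adj = 0.907
#>     serum-free vs TGFb: p_raw = 5.236e-06, p_adj = 1.416e-05
```

Both growth-factor groups differ from serum-free after adjustment; they do
not differ from each other.

Batch runs are driven by one YAML config through `runPipeline()` or the
thin CLI at `inst/scripts/fibrilign` (subcommands `simulate`, `analyze`,
`compare`, `run`), producing a per-image `results.csv`, a `comparison.csv`
and a JSON run manifest, byte-identical under a fixed seed.

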