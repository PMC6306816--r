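#' @import methods
NULL

#' ImageRaster: a grayscale micrograph-like raster
#'
#' The basic unit consumed by every analysis in the package: a 2D grayscale
#' intensity field scaled to \code{[0, 1]}, with a physical pixel size and a
#' free-form provenance record (generator spec, source file path, cell mask,
#' ...). Rows index the image y-axis (top row first), columns the x-axis;
#' real-space angles are measured from the x-axis, counterclockwise positive
#' (y pointing up), and identified modulo 180 degrees.
#'
#' @slot pixels numeric matrix, finite values in \code{[0, 1]}.
#' @slot pixelSizeUm positive scalar, microns per pixel.
#' @slot channelLabel free-text channel description.
#' @slot provenance list; generator specs store themselves here, file readers
#'   store the path, and \code{\link{generateCells}} stores the binary cell
#'   mask and the pre-composite base raster.
#'
#' @seealso \code{\link{ImageRaster}} (constructor), \code{\link{pixels}},
#'   \code{\link{orientationDistribution}}
#' @name ImageRaster-class
#' @rdname ImageRaster-class
#' @exportClass ImageRaster
setClass("ImageRaster",
  representation(
    pixels = "matrix",
    pixelSizeUm = "numeric",
    channelLabel = "character",
    provenance = "list"
  ),
  prototype(
    pixelSizeUm = 0.3,
    channelLabel = "gray",
    provenance = list()
  )
)

setValidity("ImageRaster", function(object) {
  p <- object@pixels
  if (!is.numeric(p)) return("pixels must be a numeric matrix")
  if (any(!is.finite(p))) return("pixels must be finite")
  if (min(p) < 0 || max(p) > 1) return("pixels must lie in [0, 1]")
  if (length(object@pixelSizeUm) != 1L || !is.finite(object@pixelSizeUm) ||
      object@pixelSizeUm <= 0)
    return("pixelSizeUm must be a positive scalar")
  TRUE
})

#' FibrilFieldSpec: generative parameters for a synthetic fibril mat
#'
#' Describes a field of wavy, interwoven fibrils whose orientations follow a
#' von Mises law on the doubled angle (axial data: a fibril at phi and
#' phi + 180 degrees is the same fibril). \code{dispersionKappa = 0} gives
#' orientations uniform on \code{[-90, 90)}; large kappa concentrates them at
#' \code{meanAngleDeg} with circular standard deviation about
#' \code{1/(2*sqrt(kappa))} radians.
#'
#' @slot imageSizePx integer pair (rows, cols), both positive.
#' @slot pixelSizeUm microns per pixel, positive.
#' @slot meanAngleDeg mean fibril orientation in \code{[-90, 90)}.
#' @slot dispersionKappa non-negative concentration of the doubled-angle
#'   von Mises distribution; 0 = uniform.
#' @slot nFibrils number of fibrils rendered.
#' @slot fibrilWidthPx stroke width in pixels.
#' @slot wavinessAmplitudePx,wavinessWavelengthPx sinusoidal perturbation of
#'   each fibril path, perpendicular to its axis.
#' @slot fibrilIntensity stroke intensity in \code{(0, 1]}.
#' @slot backgroundLevel background gray level in \code{[0, 1)}.
#' @slot noiseSd additive Gaussian noise standard deviation.
#' @slot seed integer RNG seed; identical spec + seed gives bit-identical
#'   images.
#'
#' @seealso \code{\link{fibrilFieldSpec}}, \code{\link{generateFibrilField}}
#' @name FibrilFieldSpec-class
#' @rdname FibrilFieldSpec-class
#' @exportClass FibrilFieldSpec
setClass("FibrilFieldSpec",
  representation(
    imageSizePx = "integer",
    pixelSizeUm = "numeric",
    meanAngleDeg = "numeric",
    dispersionKappa = "numeric",
    nFibrils = "integer",
    fibrilWidthPx = "numeric",
    wavinessAmplitudePx = "numeric",
    wavinessWavelengthPx = "numeric",
    fibrilIntensity = "numeric",
    backgroundLevel = "numeric",
    noiseSd = "numeric",
    seed = "integer"
  )
)

setValidity("FibrilFieldSpec", function(object) {
  if (length(object@imageSizePx) != 2L || any(object@imageSizePx <= 0L))
    return("imageSizePx must be two positive integers")
  if (object@pixelSizeUm <= 0) return("pixelSizeUm must be positive")
  if (object@meanAngleDeg < -90 || object@meanAngleDeg >= 90)
    return("meanAngleDeg must lie in [-90, 90)")
  if (object@dispersionKappa < 0) return("dispersionKappa must be >= 0")
  if (object@nFibrils < 0L) return("nFibrils must be >= 0")
  if (object@fibrilWidthPx <= 0) return("fibrilWidthPx must be positive")
  if (object@wavinessAmplitudePx < 0)
    return("wavinessAmplitudePx must be >= 0")
  if (object@wavinessWavelengthPx <= 0)
    return("wavinessWavelengthPx must be positive")
  if (object@fibrilIntensity <= 0 || object@fibrilIntensity > 1)
    return("fibrilIntensity must lie in (0, 1]")
  if (object@backgroundLevel < 0 || object@backgroundLevel >= 1)
    return("backgroundLevel must lie in [0, 1)")
  if (object@noiseSd < 0) return("noiseSd must be >= 0")
  TRUE
})

#' CellFieldSpec: generative parameters for synthetic cell silhouettes
#'
#' Cell bodies come in three morphologies mirroring the phenotypes seen on
#' patterned collagen: \code{"dendritic"} (round body with thin radiating
#' processes, the quiescent keratocyte look), \code{"elongated"} (ellipse
#' with a given axis ratio, the migratory fibroblast look), and
#' \code{"circular"}. \code{bodyAxisAngleDeg = NA} samples each cell's axis
#' uniformly.
#'
#' @slot nCells number of cells composited.
#' @slot morphology one of \code{"dendritic"}, \code{"elongated"},
#'   \code{"circular"}.
#' @slot bodyAxisAngleDeg body axis in degrees, or \code{NA} to sample per
#'   cell.
#' @slot elongationRatio major/minor axis ratio, >= 1; a ratio of 1
#'   degenerates to a circular body.
#' @slot nProcesses number of dendritic processes per cell (dendritic only).
#' @slot intensity silhouette intensity in \code{(0, 1]}.
#' @slot bodyRadiusPx,processLengthPx geometric defaults (minor-axis body
#'   radius and dendritic process length, pixels).
#' @slot seed integer RNG seed.
#'
#' @seealso \code{\link{cellFieldSpec}}, \code{\link{generateCells}}
#' @name CellFieldSpec-class
#' @rdname CellFieldSpec-class
#' @exportClass CellFieldSpec
setClass("CellFieldSpec",
  representation(
    nCells = "integer",
    morphology = "character",
    bodyAxisAngleDeg = "numeric",
    elongationRatio = "numeric",
    nProcesses = "integer",
    intensity = "numeric",
    bodyRadiusPx = "numeric",
    processLengthPx = "numeric",
    seed = "integer"
  )
)

setValidity("CellFieldSpec", function(object) {
  if (object@nCells < 0L) return("nCells must be >= 0")
  if (!object@morphology %in% c("dendritic", "elongated", "circular"))
    return("morphology must be 'dendritic', 'elongated' or 'circular'")
  if (object@elongationRatio < 1) return("elongationRatio must be >= 1")
  if (object@nProcesses < 0L) return("nProcesses must be >= 0")
  if (object@morphology == "circular" && object@nProcesses > 0L)
    return("circular morphology admits no processes (nProcesses must be 0)")
  if (object@intensity <= 0 || object@intensity > 1)
    return("intensity must lie in (0, 1]")
  if (object@bodyRadiusPx <= 0) return("bodyRadiusPx must be positive")
  if (object@processLengthPx < 0) return("processLengthPx must be >= 0")
  TRUE
})

#' WoundSpec: a circular freeze-injury region
#'
#' Emulates the cryogenic wound made by touching a 1 mm liquid-nitrogen-cooled
#' probe to the substrate: every cell strictly inside the disc is killed and
#' detaches, while the underlying fibrillar collagen is left intact. The
#' default radius of 500 microns is half the probe diameter.
#'
#' @slot centerPx integer pair (row, col) of the disc center.
#' @slot radiusUm disc radius in microns (>= 0; 0 is the identity wound).
#' @slot seed integer RNG seed (reserved; wounding itself is deterministic).
#'
#' @seealso \code{\link{woundSpec}}, \code{\link{applyWound}},
#'   \code{\link{tileRegions}}
#' @name WoundSpec-class
#' @rdname WoundSpec-class
#' @exportClass WoundSpec
setClass("WoundSpec",
  representation(
    centerPx = "integer",
    radiusUm = "numeric",
    seed = "integer"
  )
)

setValidity("WoundSpec", function(object) {
  if (length(object@centerPx) != 2L)
    return("centerPx must be an integer pair (row, col)")
  if (length(object@radiusUm) != 1L || !is.finite(object@radiusUm) ||
      object@radiusUm < 0)
    return("radiusUm must be a non-negative scalar")
  TRUE
})

#' SpectralParams: preprocessing and binning for the spectral analysis
#'
#' @slot nBins number of angular bins over \code{[-90, 90)}; default 180
#'   (1-degree bins).
#' @slot window \code{"hann"} (default) or \code{"none"}. The Hann window
#'   suppresses the FFT edge cross that would otherwise masquerade as 0/90
#'   degree alignment; \code{"none"} is appropriate for periodic test
#'   gratings.
#' @slot lowFreqCutoffPx radius (in frequency-plane pixels) of the excluded
#'   DC/low-frequency disc; default 4.
#' @slot highFreqCutoffFraction upper band edge as a fraction of the Nyquist
#'   radius, in \code{(0, 1]}; default 0.9.
#' @slot weighting \code{"power"} (squared magnitude, default) or
#'   \code{"amplitude"}.
#'
#' @seealso \code{\link{spectralParams}}, \code{\link{orientationDistribution}}
#' @name SpectralParams-class
#' @rdname SpectralParams-class
#' @exportClass SpectralParams
setClass("SpectralParams",
  representation(
    nBins = "integer",
    window = "character",
    lowFreqCutoffPx = "numeric",
    highFreqCutoffFraction = "numeric",
    weighting = "character"
  ),
  prototype(
    nBins = 180L,
    window = "hann",
    lowFreqCutoffPx = 4,
    highFreqCutoffFraction = 0.9,
    weighting = "power"
  )
)

setValidity("SpectralParams", function(object) {
  if (object@nBins <= 0L) return("nBins must be a positive integer")
  if (!object@window %in% c("hann", "none"))
    return("window must be 'hann' or 'none'")
  if (object@lowFreqCutoffPx < 0) return("lowFreqCutoffPx must be >= 0")
  if (object@highFreqCutoffFraction <= 0 || object@highFreqCutoffFraction > 1)
    return("highFreqCutoffFraction must lie in (0, 1]")
  if (!object@weighting %in% c("power", "amplitude"))
    return("weighting must be 'power' or 'amplitude'")
  TRUE
})

#' OrientationDistribution: binned angular content of an image
#'
#' The distribution I(phi): the percent of image content attributable to
#' real-space structures oriented at each angle phi in \code{[-90, 90)}.
#' Percentages are non-negative and sum to 100.
#'
#' @slot binCentersDeg uniformly spaced bin centers over \code{[-90, 90)}.
#' @slot percent percent of content per bin; sums to 100.
#' @slot totalEnergy total in-band spectral (or gradient) energy before
#'   normalization.
#' @slot params the \code{\linkS4class{SpectralParams}} used.
#' @slot source provenance list (method, image provenance, ...).
#'
#' @seealso \code{\link{orientationDistribution}},
#'   \code{\link{peakOrientation}}, \code{\link{orientationIndex}}
#' @name OrientationDistribution-class
#' @rdname OrientationDistribution-class
#' @exportClass OrientationDistribution
setClass("OrientationDistribution",
  representation(
    binCentersDeg = "numeric",
    percent = "numeric",
    totalEnergy = "numeric",
    params = "SpectralParams",
    source = "list"
  )
)

setValidity("OrientationDistribution", function(object) {
  n <- length(object@binCentersDeg)
  if (n < 1L) return("at least one bin required")
  if (length(object@percent) != n)
    return("percent and binCentersDeg must have the same length")
  if (any(!is.finite(object@percent)) || any(object@percent < 0))
    return("percent must be finite and non-negative")
  if (abs(sum(object@percent) - 100) > 1e-6)
    return("percent must sum to 100 (within 1e-6)")
  w <- 180 / n
  expected <- -90 + (seq_len(n) - 0.5) * w
  if (max(abs(object@binCentersDeg - expected)) > 1e-9)
    return("binCentersDeg must be uniform over [-90, 90)")
  if (!is.finite(object@totalEnergy) || object@totalEnergy <= 0)
    return("totalEnergy must be a positive scalar")
  TRUE
})

#' OIResult: orientation index at a reference angle
#'
#' OI(theta) = (2<cos^2(phi - theta)> - 1) * 100, the I(phi)-weighted
#' alignment of image content with the reference angle theta: +100 for
#' content fully parallel to theta, -100 fully perpendicular, 0 for random
#' orientations.
#'
#' @slot thetaRefDeg reference angle in \code{[-90, 90]}.
#' @slot oiPercent the index, in \code{[-100, 100]}.
#' @slot nBins number of angular bins the distribution had.
#' @slot source provenance list.
#'
#' @seealso \code{\link{orientationIndex}}, \code{\link{oiProfile}}
#' @name OIResult-class
#' @rdname OIResult-class
#' @exportClass OIResult
setClass("OIResult",
  representation(
    thetaRefDeg = "numeric",
    oiPercent = "numeric",
    nBins = "integer",
    source = "list"
  )
)

setValidity("OIResult", function(object) {
  if (object@thetaRefDeg < -90 || object@thetaRefDeg > 90)
    return("thetaRefDeg must lie in [-90, 90]")
  if (!is.finite(object@oiPercent) ||
      object@oiPercent < -100 - 1e-9 || object@oiPercent > 100 + 1e-9)
    return("oiPercent must lie in [-100, 100]")
  TRUE
})

#' GroupComparison: OI samples compared across conditions
#'
#' One-way ANOVA across condition groups of per-image OI values, with
#' Holm-Sidak-adjusted pairwise comparisons.
#'
#' @slot groupLabels condition names.
#' @slot oiSamples named list of per-group OI vectors (percent).
#' @slot fStatistic ANOVA F (possibly \code{Inf} when within-group variance
#'   is zero with unequal means).
#' @slot pValue ANOVA p-value.
#' @slot pairwise data.frame with columns \code{group1}, \code{group2},
#'   \code{p_raw}, \code{p_adj} (Holm-Sidak).
#'
#' @seealso \code{\link{compareConditions}}, \code{\link{oneWayAnova}},
#'   \code{\link{holmSidak}}
#' @name GroupComparison-class
#' @rdname GroupComparison-class
#' @exportClass GroupComparison
setClass("GroupComparison",
  representation(
    groupLabels = "character",
    oiSamples = "list",
    fStatistic = "numeric",
    pValue = "numeric",
    pairwise = "data.frame"
  )
)

setValidity("GroupComparison", function(object) {
  if (length(object@groupLabels) < 2L) return("need at least two groups")
  if (!identical(sort(names(object@oiSamples)), sort(object@groupLabels)))
    return("oiSamples must be named by groupLabels")
  if (object@fStatistic < 0) return("fStatistic must be >= 0")
  if (object@pValue < 0 || object@pValue > 1)
    return("pValue must lie in [0, 1]")
  if (nrow(object@pairwise) > 0) {
    if (any(object@pairwise$p_adj + 1e-12 < object@pairwise$p_raw))
      return("adjusted p must be >= raw p")
    if (any(object@pairwise$p_adj < 0 | object@pairwise$p_adj > 1))
      return("adjusted p must lie in [0, 1]")
  }
  TRUE
})
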