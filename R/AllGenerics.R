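#' Accessors for fibrilign objects
#'
#' @param object a fibrilign S4 object.
#' @name accessors
NULL

#' @describeIn accessors pixel matrix of an \code{ImageRaster}.
#' @export
setGeneric("pixels", function(object) standardGeneric("pixels"))

#' @describeIn accessors physical pixel size in microns per pixel.
#' @export
setGeneric("pixelSizeUm", function(object) standardGeneric("pixelSizeUm"))

#' @describeIn accessors provenance record.
#' @export
setGeneric("provenance", function(object) standardGeneric("provenance"))

#' @describeIn accessors binary cell mask stored by \code{generateCells}
#'   (or \code{NULL}).
#' @export
setGeneric("cellMask", function(object) standardGeneric("cellMask"))

#' @describeIn accessors angular bin centers in degrees.
#' @export
setGeneric("binCenters", function(object) standardGeneric("binCenters"))

#' @describeIn accessors percent of image content per angular bin.
#' @export
setGeneric("percentContent", function(object) standardGeneric("percentContent"))

#' @describeIn accessors total in-band energy before normalization.
#' @export
setGeneric("totalEnergy", function(object) standardGeneric("totalEnergy"))

#' @describeIn accessors orientation index in percent.
#' @export
setGeneric("oiPercent", function(object) standardGeneric("oiPercent"))

#' @describeIn accessors reference angle in degrees.
#' @export
setGeneric("thetaRef", function(object) standardGeneric("thetaRef"))

#' Peak of an orientation distribution
#'
#' @param dist an \code{\linkS4class{OrientationDistribution}}.
#' @return the bin center (degrees) of the maximal bin; ties are broken
#'   toward the smallest angle, so a perfectly uniform distribution returns
#'   the first bin center (-90 + half a bin width).
#' @export
setGeneric("peakOrientation", function(dist) standardGeneric("peakOrientation"))

#' Orientation index OI(theta)
#'
#' @param dist an \code{\linkS4class{OrientationDistribution}}.
#' @param thetaRefDeg reference angle in degrees (reduced mod 180 into
#'   \code{[-90, 90)}); defaults to 90, the along-flow fibril direction in
#'   vertically patterned substrates.
#' @return an \code{\linkS4class{OIResult}}.
#' @export
setGeneric("orientationIndex",
  function(dist, thetaRefDeg = 90) standardGeneric("orientationIndex"))

#' OI profile over all reference angles
#'
#' @param dist an \code{\linkS4class{OrientationDistribution}}.
#' @return data.frame with columns \code{theta_deg} and \code{oi_percent},
#'   OI evaluated at every bin center.
#' @export
setGeneric("oiProfile", function(dist) standardGeneric("oiProfile"))
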