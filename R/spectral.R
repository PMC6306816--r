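#' Construct spectral analysis parameters
#'
#' @param nBins number of angular bins over \code{[-90, 90)} (default 180,
#'   i.e. 1-degree bins).
#' @param window apodization window, \code{"hann"} or \code{"none"}.
#' @param lowFreqCutoffPx excluded low-frequency disc radius (frequency-plane
#'   pixels).
#' @param highFreqCutoffFraction upper band edge as a fraction of Nyquist.
#' @param weighting \code{"power"} or \code{"amplitude"}.
#' @return a \code{\linkS4class{SpectralParams}}.
#' @export
spectralParams <- function(nBins = 180L, window = c("hann", "none"),
                           lowFreqCutoffPx = 4,
                           highFreqCutoffFraction = 0.9,
                           weighting = c("power", "amplitude")) {
  new("SpectralParams", nBins = as.integer(nBins),
      window = match.arg(window), lowFreqCutoffPx = lowFreqCutoffPx,
      highFreqCutoffFraction = highFreqCutoffFraction,
      weighting = match.arg(weighting))
}

hannWindow <- function(n) 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / (n - 1)))

# Map angles (degrees in [-90, 90)) to 1-based bin indices.
axialBinIndex <- function(angleDeg, nBins) {
  w <- 180 / nBins
  ib <- floor((angleDeg + 90) / w) + 1
  pmin(pmax(ib, 1L), nBins)
}

axialBinCenters <- function(nBins) -90 + (seq_len(nBins) - 0.5) * 180 / nBins

# Shared assembly of an OrientationDistribution from per-sample angles and
# non-negative weights.
binAngularEnergy <- function(angleDeg, weight, params, source) {
  total <- sum(weight)
  if (!is.finite(total) || total <= 1e-12)
    stop("no structure: the image has no in-band energy ",
         "(constant or empty input)")
  ib <- axialBinIndex(angleDeg, params@nBins)
  energy <- numeric(params@nBins)
  agg <- rowsum(weight, ib)
  energy[as.integer(rownames(agg))] <- agg[, 1]
  new("OrientationDistribution",
      binCentersDeg = axialBinCenters(params@nBins),
      percent = 100 * energy / total,
      totalEnergy = total, params = params, source = source)
}

#' Angular content distribution from the 2D Fourier spectrum
#'
#' Computes I(phi), the percent of image content aligned at each real-space
#' angle phi, from the 2D FFT power spectrum. The image is padded with its
#' mean to the next square power of two, mean-subtracted, apodized (Hann by
#' default), and transformed; spectral energy in the annulus between
#' \code{lowFreqCutoffPx} and \code{highFreqCutoffFraction} of Nyquist is
#' accumulated into angular bins. Frequency-space angles are rotated by 90
#' degrees inside this function, so the returned bins report real-space
#' structure orientation (0 = image x-axis, counterclockwise positive, mod
#' 180); a fibril mat aligned along the x-axis peaks near 0 degrees.
#'
#' @param image an \code{\linkS4class{ImageRaster}} with at least 64 px per
#'   side.
#' @param params a \code{\linkS4class{SpectralParams}}.
#' @return an \code{\linkS4class{OrientationDistribution}} whose percentages
#'   sum to 100.
#' @examples
#' img <- generateFibrilField(fibrilFieldSpec(imageSizePx = c(128, 128),
#'   nFibrils = 40, meanAngleDeg = 30, dispersionKappa = 80, seed = 2))
#' d <- orientationDistribution(img)
#' peakOrientation(d)
#' @export
orientationDistribution <- function(image, params = spectralParams()) {
  stopifnot(is(image, "ImageRaster"), is(params, "SpectralParams"))
  validObject(params)
  m <- image@pixels
  if (min(dim(m)) < 64)
    stop("image must be at least 64 px per side")
  n <- 2^ceiling(log2(max(dim(m))))
  if (params@lowFreqCutoffPx >= params@highFreqCutoffFraction * (n / 2))
    stop("lowFreqCutoffPx must lie strictly inside the high-frequency cutoff")
  mu <- mean(m)
  padded <- matrix(mu, n, n)
  r0 <- floor((n - nrow(m)) / 2); c0 <- floor((n - ncol(m)) / 2)
  padded[r0 + seq_len(nrow(m)), c0 + seq_len(ncol(m))] <- m
  padded <- padded - mu
  if (params@window == "hann") {
    h <- hannWindow(n)
    padded <- padded * outer(h, h)
  }
  F <- stats::fft(padded)
  P <- if (params@weighting == "power") Mod(F)^2 else Mod(F)
  k <- c(0:(n / 2 - 1), -(n / 2):-1)
  ky <- matrix(k, n, n)          # along rows (image y, pointing down)
  kx <- matrix(k, n, n, byrow = TRUE)  # along columns (image x)
  radius <- sqrt(kx^2 + ky^2)
  band <- radius > params@lowFreqCutoffPx &
    radius <= params@highFreqCutoffFraction * (n / 2)
  # frequency angle in y-up convention, rotated 90 deg into real space
  psi <- atan2(-ky[band], kx[band]) * 180 / pi
  angle <- wrapAxialDeg(psi + 90)
  binAngularEnergy(angle, P[band], params,
                   source = list(method = "fft",
                                 image = image@provenance["path"],
                                 imageSizePx = dim(m)))
}

#' @rdname peakOrientation
#' @export
setMethod("peakOrientation", "OrientationDistribution", function(dist) {
  dist@binCentersDeg[which.max(dist@percent)]
})

#' Orientation distribution from the image structure tensor
#'
#' Independent, gradient-based estimate of the angular content
#' distribution, used as a cross-check of the spectral method. Image
#' gradients are formed with rotation-optimized Scharr kernels (plain
#' central differences bias thin strokes toward the diagonals), the
#' structure tensor components are smoothed with a Gaussian of standard
#' deviation \code{smoothingPx}, and
#' each interior pixel contributes its local structure orientation (the
#' eigen-direction perpendicular to the dominant gradient), weighted by the
#' local anisotropic energy (difference of tensor eigenvalues). Binning and
#' normalization follow the same contract as
#' \code{\link{orientationDistribution}}.
#'
#' @param image an \code{\linkS4class{ImageRaster}} with at least 64 px per
#'   side.
#' @param smoothingPx Gaussian sigma for tensor smoothing (px).
#' @param params a \code{\linkS4class{SpectralParams}} (only \code{nBins} is
#'   used).
#' @return an \code{\linkS4class{OrientationDistribution}}.
#' @export
structureTensorDistribution <- function(image, smoothingPx = 2,
                                        params = spectralParams()) {
  stopifnot(is(image, "ImageRaster"), smoothingPx > 0)
  m <- image@pixels
  if (min(dim(m)) < 64)
    stop("image must be at least 64 px per side")
  H <- nrow(m); W <- ncol(m)
  # Scharr derivatives: rotation-optimized 3x3 kernels; plain central
  # differences bias thin-stroke orientations toward the +-45 deg diagonals
  kScharr <- matrix(c(-3, 0, 3, -10, 0, 10, -3, 0, 3), 3, byrow = TRUE) / 32
  gx <- EBImage::filter2(m, kScharr)
  gy <- -EBImage::filter2(m, t(kScharr))  # y pointing up
  jxx <- EBImage::gblur(gx * gx, sigma = smoothingPx)
  jyy <- EBImage::gblur(gy * gy, sigma = smoothingPx)
  jxy <- EBImage::gblur(gx * gy, sigma = smoothingPx)
  margin <- ceiling(2 * smoothingPx + 2)
  keepR <- (margin + 1):(H - margin); keepC <- (margin + 1):(W - margin)
  jxx <- jxx[keepR, keepC]; jyy <- jyy[keepR, keepC]
  jxy <- jxy[keepR, keepC]
  gradAngle <- 0.5 * atan2(2 * jxy, jxx - jyy)   # dominant gradient direction
  angle <- wrapAxialDeg(gradAngle * 180 / pi + 90)
  weight <- sqrt((jxx - jyy)^2 + 4 * jxy^2)      # eigenvalue difference
  binAngularEnergy(as.vector(angle), as.vector(weight), params,
                   source = list(method = "structure_tensor",
                                 smoothingPx = smoothingPx,
                                 imageSizePx = dim(m)))
}

setMethod("show", "OrientationDistribution", function(object) {
  cat(sprintf("OrientationDistribution: %d bins over [-90, 90) [%s]\n",
              length(object@binCentersDeg),
              object@source$method %||% "unknown"))
  cat(sprintf("  peak at %.1f deg (%.2f%% of content); total energy %.3g\n",
              peakOrientation(object), max(object@percent),
              object@totalEnergy))
})

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname accessors
#' @export
setMethod("binCenters", "OrientationDistribution",
          function(object) object@binCentersDeg)

#' @rdname accessors
#' @export
setMethod("percentContent", "OrientationDistribution",
          function(object) object@percent)

#' @rdname accessors
#' @export
setMethod("totalEnergy", "OrientationDistribution",
          function(object) object@totalEnergy)
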