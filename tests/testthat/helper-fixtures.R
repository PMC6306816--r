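# Shared fixtures: analytic gratings, hand-built angular distributions, and
# small fibril fields sized for fast tests.

# Sinusoidal grating whose stripes run along `angleDeg` (real-space, x-axis
# reference, CCW positive): intensity varies along angleDeg + 90.
makeGrating <- function(n = 256, angleDeg = 30, cycles = 16, contrast = 0.4) {
  xc <- matrix(seq_len(n), n, n, byrow = TRUE)
  yup <- -matrix(seq_len(n), n, n)
  a <- (angleDeg + 90) * pi / 180
  g <- 0.5 + contrast * sin(2 * pi * cycles / n * (xc * cos(a) + yup * sin(a)))
  ImageRaster(g)
}

distBinCenters <- function(nBins = 180L) -90 + (seq_len(nBins) - 0.5) * 180 / nBins

# Distribution with all mass in the bin containing `atDeg`.
makeDeltaDist <- function(atDeg, nBins = 180L) {
  pct <- numeric(nBins)
  pct[findInterval(atDeg, seq(-90, 90, length.out = nBins + 1),
                   rightmost.closed = TRUE)] <- 100
  new("OrientationDistribution", binCentersDeg = distBinCenters(nBins),
      percent = pct, totalEnergy = 1,
      params = spectralParams(nBins = nBins), source = list(method = "test"))
}

makeUniformDist <- function(nBins = 180L) {
  new("OrientationDistribution", binCentersDeg = distBinCenters(nBins),
      percent = rep(100 / nBins, nBins), totalEnergy = 1,
      params = spectralParams(nBins = nBins), source = list(method = "test"))
}

makeRandomDist <- function(nBins = 180L) {
  w <- stats::runif(nBins)
  new("OrientationDistribution", binCentersDeg = distBinCenters(nBins),
      percent = 100 * w / sum(w), totalEnergy = sum(w),
      params = spectralParams(nBins = nBins), source = list(method = "test"))
}

# Distribution with equal mass in the bins containing a1 and a2.
makeTwoPointDist <- function(a1, a2, nBins = 180L) {
  edges <- seq(-90, 90, length.out = nBins + 1)
  pct <- numeric(nBins)
  pct[findInterval(a1, edges, rightmost.closed = TRUE)] <- 50
  pct[findInterval(a2, edges, rightmost.closed = TRUE)] <-
    pct[findInterval(a2, edges, rightmost.closed = TRUE)] + 50
  new("OrientationDistribution", binCentersDeg = distBinCenters(nBins),
      percent = pct, totalEnergy = 1,
      params = spectralParams(nBins = nBins), source = list(method = "test"))
}

# Small fibril field for fast unit tests.
smallFibrilField <- function(meanAngleDeg = 0, kappa = 50, seed = 1,
                             sizePx = 256, nFibrils = 80,
                             wavinessAmplitudePx = 3, noiseSd = 0.02) {
  generateFibrilField(fibrilFieldSpec(
    imageSizePx = c(sizePx, sizePx), nFibrils = nFibrils,
    meanAngleDeg = meanAngleDeg, dispersionKappa = kappa,
    wavinessAmplitudePx = wavinessAmplitudePx, noiseSd = noiseSd,
    seed = seed))
}

# Absolute axial distance between two angles, degrees in [0, 90].
axialDistDeg <- function(a, b) {
  d <- abs((a - b) %% 180)
  pmin(d, 180 - d)
}
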