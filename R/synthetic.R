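#' Specify a synthetic fibril field
#'
#' Constructor with the package defaults: a 1024 x 1024 px raster at
#' 0.3 um/px (so a 1 mm freeze wound fits with margin), gently wavy fibrils
#' (3 px amplitude, 60 px wavelength) echoing the look of microfluidically
#' deposited collagen mats.
#'
#' @param imageSizePx integer pair (rows, cols).
#' @param pixelSizeUm microns per pixel.
#' @param meanAngleDeg mean fibril orientation, degrees in \code{[-90, 90)}.
#' @param dispersionKappa concentration of the doubled-angle von Mises law;
#'   0 = uniformly random orientations.
#' @param nFibrils number of fibrils.
#' @param fibrilWidthPx stroke width (px).
#' @param wavinessAmplitudePx,wavinessWavelengthPx sinusoidal path
#'   perturbation (px).
#' @param fibrilIntensity stroke intensity in \code{(0, 1]}.
#' @param backgroundLevel background gray level in \code{[0, 1)}.
#' @param noiseSd additive Gaussian noise sd.
#' @param seed integer seed.
#' @return a \code{\linkS4class{FibrilFieldSpec}}.
#' @examples
#' spec <- fibrilFieldSpec(imageSizePx = c(256, 256), nFibrils = 50,
#'                         meanAngleDeg = 0, dispersionKappa = 50, seed = 1)
#' @export
fibrilFieldSpec <- function(imageSizePx = c(1024L, 1024L),
                            pixelSizeUm = 0.3,
                            meanAngleDeg = 0,
                            dispersionKappa = 0,
                            nFibrils = 300L,
                            fibrilWidthPx = 3,
                            wavinessAmplitudePx = 3,
                            wavinessWavelengthPx = 60,
                            fibrilIntensity = 0.85,
                            backgroundLevel = 0.12,
                            noiseSd = 0.02,
                            seed = 1L) {
  if (any(!is.finite(imageSizePx)) || any(imageSizePx <= 0))
    stop("imageSizePx must be positive")
  if (!is.finite(wavinessWavelengthPx) || wavinessWavelengthPx <= 0)
    stop("wavinessWavelengthPx must be positive")
  new("FibrilFieldSpec",
      imageSizePx = as.integer(imageSizePx),
      pixelSizeUm = pixelSizeUm,
      meanAngleDeg = meanAngleDeg,
      dispersionKappa = dispersionKappa,
      nFibrils = as.integer(nFibrils),
      fibrilWidthPx = fibrilWidthPx,
      wavinessAmplitudePx = wavinessAmplitudePx,
      wavinessWavelengthPx = wavinessWavelengthPx,
      fibrilIntensity = fibrilIntensity,
      backgroundLevel = backgroundLevel,
      noiseSd = noiseSd,
      seed = as.integer(seed))
}

#' Specify synthetic cell silhouettes
#'
#' @param nCells number of cells.
#' @param morphology \code{"dendritic"}, \code{"elongated"} or
#'   \code{"circular"}.
#' @param bodyAxisAngleDeg body axis in degrees, or \code{NA} /
#'   \code{"sampled"} to draw each cell's axis uniformly.
#' @param elongationRatio major/minor axis ratio (>= 1).
#' @param nProcesses dendritic processes per cell.
#' @param intensity silhouette intensity.
#' @param bodyRadiusPx minor-axis body radius (px).
#' @param processLengthPx dendritic process length (px).
#' @param seed integer seed.
#' @return a \code{\linkS4class{CellFieldSpec}}.
#' @export
cellFieldSpec <- function(nCells = 20L,
                          morphology = c("dendritic", "elongated", "circular"),
                          bodyAxisAngleDeg = NA_real_,
                          elongationRatio = 3,
                          nProcesses = if (match.arg(morphology) == "dendritic") 5L else 0L,
                          intensity = 0.95,
                          bodyRadiusPx = 12,
                          processLengthPx = 60,
                          seed = 1L) {
  morphology <- match.arg(morphology)
  if (identical(bodyAxisAngleDeg, "sampled")) bodyAxisAngleDeg <- NA_real_
  new("CellFieldSpec",
      nCells = as.integer(nCells),
      morphology = morphology,
      bodyAxisAngleDeg = as.numeric(bodyAxisAngleDeg),
      elongationRatio = elongationRatio,
      nProcesses = as.integer(nProcesses),
      intensity = intensity,
      bodyRadiusPx = bodyRadiusPx,
      processLengthPx = processLengthPx,
      seed = as.integer(seed))
}

#' Specify a circular freeze wound
#'
#' @param centerPx integer pair (row, col); defaults to the image center when
#'   applied.
#' @param radiusUm wound radius in microns; the default 500 um is half the
#'   1 mm probe diameter.
#' @param seed integer seed (reserved).
#' @return a \code{\linkS4class{WoundSpec}}.
#' @export
woundSpec <- function(centerPx = c(512L, 512L), radiusUm = 500, seed = 1L) {
  new("WoundSpec", centerPx = as.integer(centerPx), radiusUm = radiusUm,
      seed = as.integer(seed))
}

# Anti-aliased splat of a sampled path: each pixel takes the maximum over
# nearby path points of a linear edge profile of half-width width/2.
# Returns (pixel index, value) pairs, deduplicated by max, for a canvas of
# size H x W; max-compositing keeps crossings at stroke intensity instead of
# summing.
splatPairs <- function(xs, ys, width, H, W) {
  keep <- xs > -width & xs < W + width & ys > -width & ys < H + width
  xs <- xs[keep]; ys <- ys[keep]
  if (length(xs) == 0L) return(list(idx = integer(0), val = numeric(0)))
  r <- ceiling(width / 2 + 1)
  offs <- expand.grid(dx = -r:r, dy = -r:r)
  # a point lies within 0.71 px of its rounded pixel, so only offsets within
  # width/2 + 0.5 + 0.71 of the origin can receive a positive profile value
  offs <- offs[sqrt(offs$dx^2 + offs$dy^2) <= width / 2 + 1.21, ]
  ix <- round(xs); iy <- round(ys)
  PX <- outer(ix, offs$dx, "+")
  PY <- outer(iy, offs$dy, "+")
  DX <- outer(ix - xs, offs$dx, "+")
  DY <- outer(iy - ys, offs$dy, "+")
  v <- (width / 2 + 0.5) - sqrt(DX * DX + DY * DY)
  v <- pmin(pmax(v, 0), 1)
  ok <- v > 0 & PX >= 1 & PX <= W & PY >= 1 & PY <= H
  dedupeMax(as.integer((PX[ok] - 1) * H + PY[ok]), v[ok])
}

dedupeMax <- function(idx, val) {
  o <- order(idx, -val)
  idx <- idx[o]; val <- val[o]
  first <- !duplicated(idx)
  list(idx = idx[first], val = val[first])
}

# Apply one or more splat pair sets to a canvas by max-compositing.
splatPath <- function(canvas, xs, ys, width, value = 1) {
  p <- splatPairs(xs, ys, width, nrow(canvas), ncol(canvas))
  if (length(p$idx))
    canvas[p$idx] <- pmax(canvas[p$idx], p$val * value)
  canvas
}

#' Generate a synthetic fibril field
#'
#' Renders \code{nFibrils} curvilinear strokes whose base orientations are
#' drawn from the doubled-angle von Mises law
#' (\code{meanAngleDeg}, \code{dispersionKappa}), each perturbed by a
#' sinusoidal waviness perpendicular to its axis, composited by maximum
#' (fibrils overlay, they do not sum), over a flat background with additive
#' Gaussian noise clipped to \code{[0, 1]}. Identical spec and seed give
#' bit-identical images. The sampled base orientations are stored in
#' \code{provenance(x)$orientationsDeg} as ground truth.
#'
#' @param spec a \code{\linkS4class{FibrilFieldSpec}}.
#' @return an \code{\linkS4class{ImageRaster}}.
#' @examples
#' img <- generateFibrilField(fibrilFieldSpec(imageSizePx = c(128, 128),
#'   nFibrils = 30, meanAngleDeg = 0, dispersionKappa = 50, seed = 7))
#' @export
generateFibrilField <- function(spec) {
  stopifnot(is(spec, "FibrilFieldSpec"))
  validObject(spec)
  H <- spec@imageSizePx[1]; W <- spec@imageSizePx[2]
  withSeed(spec@seed, {
    phis <- sampleAxialOrientations(spec@nFibrils, spec@meanAngleDeg,
                                    spec@dispersionKappa)
    strokes <- matrix(0, H, W)
    if (spec@nFibrils > 0L) {
      L <- 1.4 * sqrt(H^2 + W^2)
      ts <- seq(-L / 2, L / 2, by = 0.75)
      pairs <- vector("list", spec@nFibrils)
      for (k in seq_len(spec@nFibrils)) {
        cx <- stats::runif(1, 1, W)
        cy <- stats::runif(1, 1, H)
        phase <- stats::runif(1, 0, 2 * pi)
        phi <- degToRad(phis[k])
        off <- spec@wavinessAmplitudePx *
          sin(2 * pi * ts / spec@wavinessWavelengthPx + phase)
        xs <- cx + ts * cos(phi) + off * sin(phi)
        ys <- cy - ts * sin(phi) + off * cos(phi)
        pairs[[k]] <- splatPairs(xs, ys, spec@fibrilWidthPx, H, W)
      }
      all <- dedupeMax(unlist(lapply(pairs, `[[`, "idx")),
                       unlist(lapply(pairs, `[[`, "val")))
      strokes[all$idx] <- all$val
    }
    px <- pmax(spec@fibrilIntensity * strokes, spec@backgroundLevel)
    if (spec@noiseSd > 0)
      px <- px + matrix(stats::rnorm(H * W, 0, spec@noiseSd), H, W)
    ImageRaster(clamp01(px), pixelSizeUm = spec@pixelSizeUm,
                channelLabel = "synthetic fibrils",
                provenance = list(spec = spec, orientationsDeg = phis))
  })
}

#' Composite synthetic cell silhouettes over a base raster
#'
#' Cells are placed with a minimum-distance rejection rule so that, barring a
#' crowded field, silhouettes do not overlap. The returned raster carries the
#' binary cell mask and the untouched base raster in its provenance (used by
#' \code{\link{applyWound}} to restore the substrate under killed cells).
#' With \code{nCells = 0} the base raster is returned unchanged.
#'
#' @param spec a \code{\linkS4class{CellFieldSpec}}.
#' @param base an \code{\linkS4class{ImageRaster}} (e.g. a fibril field).
#' @return an \code{\linkS4class{ImageRaster}} with provenance entries
#'   \code{cellMask} (logical matrix) and \code{base}.
#' @export
generateCells <- function(spec, base) {
  stopifnot(is(spec, "CellFieldSpec"), is(base, "ImageRaster"))
  validObject(spec)
  if (spec@nCells == 0L) return(base)
  H <- nrow(base@pixels); W <- ncol(base@pixels)
  withSeed(spec@seed, {
    effRatio <- if (spec@morphology == "elongated") spec@elongationRatio
                else 1
    extent <- spec@bodyRadiusPx * effRatio +
      if (spec@morphology == "dendritic") spec@processLengthPx else 0
    minDist <- 2 * extent + 4
    centers <- placeCenters(spec@nCells, H, W, margin = extent + 2,
                            minDist = minDist)
    layer <- matrix(0, H, W)
    for (k in seq_len(nrow(centers))) {
      ang <- if (is.na(spec@bodyAxisAngleDeg)) stats::runif(1, -90, 90)
             else spec@bodyAxisAngleDeg
      layer <- drawCell(layer, centers[k, 1], centers[k, 2], ang, spec)
    }
    # any painted pixel (including the anti-aliased fringe) belongs to the
    # silhouette, so wounding can restore the substrate exactly
    mask <- layer > 0
    px <- pmax(base@pixels, spec@intensity * layer)
    ImageRaster(clamp01(px), pixelSizeUm = base@pixelSizeUm,
                channelLabel = base@channelLabel,
                provenance = c(list(cellSpec = spec, cellMask = mask,
                                    base = base),
                               base@provenance["spec"]))
  })
}

# Minimum-distance rejection placement; falls back to unconstrained draws if
# the field is too crowded to satisfy the spacing.
placeCenters <- function(n, H, W, margin, minDist) {
  cx <- numeric(0); cy <- numeric(0)
  tries <- 0L
  while (length(cx) < n && tries < 200L * n) {
    x <- stats::runif(1, 1 + margin, W - margin)
    y <- stats::runif(1, 1 + margin, H - margin)
    if (length(cx) == 0L || min((cx - x)^2 + (cy - y)^2) >= minDist^2) {
      cx <- c(cx, x); cy <- c(cy, y)
    }
    tries <- tries + 1L
  }
  while (length(cx) < n) {
    cx <- c(cx, stats::runif(1, 1, W)); cy <- c(cy, stats::runif(1, 1, H))
  }
  cbind(y = cy, x = cx)
}

drawCell <- function(layer, cy, cx, angleDeg, spec) {
  phi <- degToRad(angleDeg)
  r <- spec@bodyRadiusPx
  halfLen <- switch(spec@morphology,
                    circular = 0,
                    dendritic = 0,
                    elongated = r * (spec@elongationRatio - 1))
  # capsule body: a segment splatted at width 2r (degenerates to a disc)
  ts <- if (halfLen > 0) seq(-halfLen, halfLen, by = 0.75) else 0
  xs <- cx + ts * cos(phi)
  ys <- cy - ts * sin(phi)
  layer <- splatPath(layer, xs, ys, 2 * r)
  if (spec@morphology == "dendritic" && spec@nProcesses > 0L) {
    angs <- stats::runif(spec@nProcesses, 0, 2 * pi)
    for (a in angs) {
      ts <- seq(0, spec@processLengthPx, by = 0.75)
      layer <- splatPath(layer, cx + ts * cos(a), cy - ts * sin(a),
                         width = 2.5)
    }
  }
  layer
}

#' Apply a circular freeze wound to an image
#'
#' Removes cell content strictly inside the wound disc, restoring the
#' underlying substrate there; fibril/background content is untouched
#' everywhere (the cryo-probe kills cells without disturbing the collagen).
#' On a raster produced by \code{\link{generateCells}} the stored base
#' raster is restored exactly; otherwise wounded cell pixels are filled with
#' the median of the non-cell pixels.
#'
#' @param image an \code{\linkS4class{ImageRaster}}.
#' @param spec a \code{\linkS4class{WoundSpec}}.
#' @param mask optional logical cell mask; defaults to
#'   \code{cellMask(image)}.
#' @return an \code{\linkS4class{ImageRaster}} with the wound applied and an
#'   updated cell mask in its provenance.
#' @export
applyWound <- function(image, spec, mask = cellMask(image)) {
  stopifnot(is(image, "ImageRaster"), is(spec, "WoundSpec"))
  validObject(spec)
  H <- nrow(image@pixels); W <- ncol(image@pixels)
  radiusPx <- spec@radiusUm / image@pixelSizeUm
  if (radiusPx == 0) return(image)
  cy <- spec@centerPx[1]; cx <- spec@centerPx[2]
  nearY <- min(max(cy, 1), H); nearX <- min(max(cx, 1), W)
  if ((nearY - cy)^2 + (nearX - cx)^2 >= radiusPx^2)
    stop("wound disc lies entirely outside the image")
  if (is.null(mask)) mask <- matrix(FALSE, H, W)
  if (!all(dim(mask) == c(H, W)))
    stop("cell mask dimensions must match the image")
  inside <- outer((seq_len(H) - cy)^2, (seq_len(W) - cx)^2, "+") < radiusPx^2
  wounded <- inside & mask
  px <- image@pixels
  base <- image@provenance[["base"]]
  fill <- if (is(base, "ImageRaster")) base@pixels[wounded]
          else stats::median(px[!mask])
  px[wounded] <- fill
  prov <- image@provenance
  newMask <- mask
  newMask[inside] <- FALSE
  prov$cellMask <- newMask
  prov$wound <- spec
  ImageRaster(clamp01(px), pixelSizeUm = image@pixelSizeUm,
              channelLabel = image@channelLabel, provenance = prov)
}

#' Wall shear rate in a thin rectangular channel
#'
#' Parallel-plate approximation \code{6 * Q / (w * h^2)} for the shear rate
#' at the wall of a channel of width \code{w} and height \code{h} (valid for
#' \code{h << w}; treat the result as approximate near unity aspect ratios).
#' For the deposition conditions of a 1500 x 60 um channel at 7.5 uL/min the
#' formula gives about 139 s^-1.
#'
#' @param flowUlPerMin volumetric flow rate in microliters per minute.
#' @param widthUm channel width in microns.
#' @param heightUm channel height in microns (must not exceed the width).
#' @return wall shear rate in s^-1.
#' @examples
#' wallShearRate(7.5, widthUm = 1500, heightUm = 60)
#' @export
wallShearRate <- function(flowUlPerMin, widthUm, heightUm) {
  if (!is.finite(flowUlPerMin) || flowUlPerMin <= 0)
    stop("flow rate must be positive")
  if (!is.finite(widthUm) || widthUm <= 0 ||
      !is.finite(heightUm) || heightUm <= 0)
    stop("channel dimensions must be positive")
  if (heightUm > widthUm)
    stop("heightUm must not exceed widthUm (parallel-plate approximation)")
  q <- flowUlPerMin * 1e-9 / 60           # m^3/s
  w <- widthUm * 1e-6; h <- heightUm * 1e-6
  6 * q / (w * h^2)
}
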