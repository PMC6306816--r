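# Synthetic image generator: determinism, angular law, cells, wound, shear.

test_that("empty scene is a constant background and generation is deterministic", {
  spec <- fibrilFieldSpec(imageSizePx = c(128, 128), nFibrils = 0,
                          noiseSd = 0, backgroundLevel = 0.2, seed = 5)
  img <- generateFibrilField(spec)
  expect_true(all(pixels(img) == 0.2))
  expect_equal(dim(img), c(128L, 128L))

  spec2 <- fibrilFieldSpec(imageSizePx = c(128, 128), nFibrils = 40,
                           dispersionKappa = 10, seed = 42)
  a <- generateFibrilField(spec2)
  b <- generateFibrilField(spec2)
  expect_identical(pixels(a), pixels(b))
  expect_identical(provenance(a)$orientationsDeg,
                   provenance(b)$orientationsDeg)
  # different seed, different field
  c <- generateFibrilField(fibrilFieldSpec(imageSizePx = c(128, 128),
                                           nFibrils = 40,
                                           dispersionKappa = 10, seed = 43))
  expect_false(identical(pixels(a), pixels(c)))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(99)
  before <- .Random.seed
  invisible(generateFibrilField(fibrilFieldSpec(imageSizePx = c(64, 64),
                                                nFibrils = 5, seed = 1)))
  expect_identical(.Random.seed, before)
})

test_that("kappa = 0 orientations are uniform on [-90, 90)", {
  phi <- sampleAxialOrientations(2e4, meanAngleDeg = 0, kappa = 0, seed = 11)
  expect_true(all(phi >= -90 & phi < 90))
  counts <- table(cut(phi, breaks = seq(-90, 90, by = 10)))
  gof <- suppressWarnings(chisq.test(as.vector(counts)))
  expect_gt(gof$p.value, 0.01)
})

test_that("large kappa concentrates orientations at the mean", {
  # in the kappa -> large limit every draw sits at the mean
  phi <- sampleAxialOrientations(1e4, meanAngleDeg = 20, kappa = 1e6,
                                 seed = 12)
  expect_true(all(axialDistDeg(phi, 20) <= 3))
  # at kappa = 100 the circular sd of the orientation is ~ 1/(2*sqrt(kappa))
  phi100 <- sampleAxialOrientations(2e4, meanAngleDeg = 20, kappa = 100,
                                    seed = 13)
  psi <- 2 * phi100 * pi / 180
  R <- sqrt(mean(cos(psi))^2 + mean(sin(psi))^2)
  sdDeg <- sqrt(-2 * log(R)) / 2 * 180 / pi
  expect_equal(sdDeg, 1 / (2 * sqrt(100)) * 180 / pi, tolerance = 0.1)
})

test_that("circular mean of sampled orientations recovers the target mean", {
  for (mu in c(-60, 0, 37)) {
    phi <- sampleAxialOrientations(500, meanAngleDeg = mu, kappa = 10,
                                   seed = 7 + mu)
    expect_lte(axialDistDeg(circularMeanAxialDeg(phi), mu), 2)
  }
})

test_that("parameter errors are raised for invalid fibril specs", {
  expect_error(fibrilFieldSpec(imageSizePx = c(0, 128)), "positive")
  expect_error(fibrilFieldSpec(wavinessWavelengthPx = 0), "positive")
  expect_error(fibrilFieldSpec(dispersionKappa = -1), "dispersionKappa")
  expect_error(fibrilFieldSpec(meanAngleDeg = 90), "meanAngleDeg")
})

test_that("nCells = 0 leaves the base raster unchanged", {
  base <- smallFibrilField(seed = 3, sizePx = 128, nFibrils = 20)
  out <- generateCells(cellFieldSpec(nCells = 0, morphology = "circular",
                                     nProcesses = 0), base)
  expect_identical(pixels(out), pixels(base))
})

test_that("elongated cells with ratio 1 degenerate to circular bodies", {
  base <- ImageRaster(matrix(0.1, 160, 160))
  el <- generateCells(cellFieldSpec(nCells = 3, morphology = "elongated",
                                    elongationRatio = 1, seed = 8), base)
  ci <- generateCells(cellFieldSpec(nCells = 3, morphology = "circular",
                                    nProcesses = 0, seed = 8), base)
  expect_identical(pixels(el), pixels(ci))
})

test_that("dendritic cells form one connected component each", {
  base <- ImageRaster(matrix(0.05, 400, 400))
  out <- generateCells(cellFieldSpec(nCells = 3, morphology = "dendritic",
                                     nProcesses = 6, seed = 21), base)
  mask <- cellMask(out)
  comps <- EBImage::bwlabel(mask * 1)
  expect_equal(max(comps), 3)
})

test_that("circular morphology with processes is a parameter error", {
  expect_error(cellFieldSpec(morphology = "circular", nProcesses = 2),
               "circular")
})

test_that("elongated cells at 90 degrees give positive OI(90) on the mask", {
  base <- ImageRaster(matrix(0, 512, 512))
  out <- generateCells(cellFieldSpec(nCells = 10, morphology = "elongated",
                                     bodyAxisAngleDeg = -90,
                                     elongationRatio = 6,
                                     bodyRadiusPx = 6, seed = 31), base)
  d <- orientationDistribution(out)
  expect_gt(oiPercent(orientationIndex(d, 90)), 0)
})

test_that("a zero-radius wound is the identity", {
  base <- smallFibrilField(seed = 3, sizePx = 128, nFibrils = 20)
  withCells <- generateCells(cellFieldSpec(nCells = 2,
                                           morphology = "circular",
                                           nProcesses = 0, seed = 4), base)
  out <- applyWound(withCells, woundSpec(centerPx = c(64, 64), radiusUm = 0))
  expect_identical(pixels(out), pixels(withCells))
})

test_that("wounding a fibril-only image changes nothing", {
  base <- smallFibrilField(seed = 6, sizePx = 128, nFibrils = 30)
  out <- applyWound(base, woundSpec(centerPx = c(64, 64), radiusUm = 15))
  expect_identical(pixels(out), pixels(base))
})

test_that("wound removes cells inside the disc and restores the substrate", {
  base <- smallFibrilField(seed = 5, sizePx = 256, nFibrils = 60)
  withCells <- generateCells(cellFieldSpec(nCells = 5,
                                           morphology = "dendritic",
                                           nProcesses = 5, seed = 6), base)
  ws <- woundSpec(centerPx = c(128, 128), radiusUm = 25)
  out <- applyWound(withCells, ws)
  rPx <- 25 / pixelSizeUm(base)
  inside <- outer((1:256 - 128)^2, (1:256 - 128)^2, "+") < rPx^2
  # substrate restored exactly inside the disc
  expect_identical(pixels(out)[inside], pixels(base)[inside])
  # untouched outside the disc
  expect_identical(pixels(out)[!inside], pixels(withCells)[!inside])
  # mask cleared inside the disc
  expect_false(any(cellMask(out)[inside]))
})

test_that("a wound covering the whole image leaves it cell-free", {
  base <- smallFibrilField(seed = 5, sizePx = 128, nFibrils = 20)
  withCells <- generateCells(cellFieldSpec(nCells = 3,
                                           morphology = "circular",
                                           nProcesses = 0, seed = 6), base)
  out <- applyWound(withCells, woundSpec(centerPx = c(64, 64),
                                         radiusUm = 1000))
  expect_identical(pixels(out), pixels(base))
  expect_false(any(cellMask(out)))
})

test_that("a wound disc entirely outside the image is an error", {
  base <- smallFibrilField(seed = 5, sizePx = 128, nFibrils = 20)
  expect_error(applyWound(base, woundSpec(centerPx = c(500, 500),
                                          radiusUm = 10)),
               "outside")
})

test_that("wall shear rate follows the parallel-plate formula", {
  # 6 Q / (w h^2) on the deposition channel geometry
  expect_equal(wallShearRate(7.5, widthUm = 1500, heightUm = 60), 138.8889,
               tolerance = 1e-6)
  expect_equal(wallShearRate(1, widthUm = 1000, heightUm = 1000), 0.1)
  # linear in flow rate
  expect_equal(wallShearRate(15, 1500, 60), 2 * wallShearRate(7.5, 1500, 60))
  expect_error(wallShearRate(0, 1500, 60), "positive")
  expect_error(wallShearRate(7.5, 60, 1500), "exceed")
})

test_that("TIFF round trip preserves pixels to 16-bit precision and the sidecar replays the spec", {
  img <- smallFibrilField(seed = 9, sizePx = 128, nFibrils = 30)
  path <- file.path(withr::local_tempdir(), "img.tif")
  writeImageRaster(img, path)
  back <- readImageRaster(path)
  expect_lte(max(abs(pixels(back) - pixels(img))), 1 / 65535)
  expect_equal(pixelSizeUm(back), pixelSizeUm(img))
  meta <- provenance(back)$sidecar
  expect_equal(meta$provenance$spec$dispersionKappa, 50)
  # regenerate from the sidecar spec: bit-identical to the original
  sl <- meta$provenance$spec
  spec2 <- fibrilFieldSpec(imageSizePx = sl$imageSizePx,
                           pixelSizeUm = sl$pixelSizeUm,
                           meanAngleDeg = sl$meanAngleDeg,
                           dispersionKappa = sl$dispersionKappa,
                           nFibrils = sl$nFibrils,
                           fibrilWidthPx = sl$fibrilWidthPx,
                           wavinessAmplitudePx = sl$wavinessAmplitudePx,
                           wavinessWavelengthPx = sl$wavinessWavelengthPx,
                           fibrilIntensity = sl$fibrilIntensity,
                           backgroundLevel = sl$backgroundLevel,
                           noiseSd = sl$noiseSd, seed = sl$seed)
  expect_identical(pixels(generateFibrilField(spec2)), pixels(img))
})
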