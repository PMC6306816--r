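#' Partition an image into wound / non-wound analysis tiles
#'
#' Cuts the image into a non-overlapping grid of square tiles and labels
#' each tile \code{"wound"} (entirely inside the wound disc),
#' \code{"non-wound"} (entirely outside), or \code{"discarded"} (straddling
#' the wound edge). Straddling tiles are excluded from analysis so the
#' sharp wound boundary cannot leak artifactual orientations into the FFT.
#' Without a wound every tile is \code{"non-wound"}.
#'
#' @param image an \code{\linkS4class{ImageRaster}}.
#' @param wound a \code{\linkS4class{WoundSpec}} or \code{NULL}.
#' @param tileSizePx tile side in pixels (>= 64, must fit in the image).
#' @return list with elements \code{tiles} (list of
#'   \code{\linkS4class{ImageRaster}} with per-tile provenance), and
#'   \code{table}: data.frame of \code{row0}, \code{col0}, \code{label} for
#'   every grid tile (including discarded ones, which carry no raster).
#' @export
tileRegions <- function(image, wound = NULL, tileSizePx = 256L) {
  stopifnot(is(image, "ImageRaster"))
  H <- nrow(image@pixels); W <- ncol(image@pixels)
  if (tileSizePx < 64) stop("tileSizePx must be at least 64")
  nr <- floor(H / tileSizePx); nc <- floor(W / tileSizePx)
  if (nr < 1 || nc < 1) stop("tile does not fit in the image")
  radiusPx <- if (is.null(wound)) 0 else wound@radiusUm / image@pixelSizeUm
  cy <- if (is.null(wound)) NA else wound@centerPx[1]
  cx <- if (is.null(wound)) NA else wound@centerPx[2]
  grid <- expand.grid(ti = seq_len(nr), tj = seq_len(nc))
  labels <- character(nrow(grid))
  tiles <- list()
  for (g in seq_len(nrow(grid))) {
    r0 <- (grid$ti[g] - 1) * tileSizePx + 1
    c0 <- (grid$tj[g] - 1) * tileSizePx + 1
    r1 <- r0 + tileSizePx - 1; c1 <- c0 + tileSizePx - 1
    if (radiusPx <= 0) {
      lab <- "non-wound"
    } else {
      corners <- rbind(c(r0, c0), c(r0, c1), c(r1, c0), c(r1, c1))
      dFar <- sqrt(max((corners[, 1] - cy)^2 + (corners[, 2] - cx)^2))
      nearY <- min(max(cy, r0), r1); nearX <- min(max(cx, c0), c1)
      dNear <- sqrt((nearY - cy)^2 + (nearX - cx)^2)
      lab <- if (dFar < radiusPx) "wound"
             else if (dNear >= radiusPx) "non-wound"
             else "discarded"
    }
    labels[g] <- lab
    if (lab != "discarded") {
      sub <- ImageRaster(image@pixels[r0:r1, c0:c1],
                         pixelSizeUm = image@pixelSizeUm,
                         channelLabel = image@channelLabel,
                         provenance = list(parent = image@provenance,
                                           region = lab,
                                           row0 = r0, col0 = c0))
      tiles[[length(tiles) + 1L]] <- sub
    }
  }
  if (!any(labels != "discarded"))
    stop("no complete tile on either side of the wound")
  list(tiles = tiles,
       table = data.frame(row0 = (grid$ti - 1) * tileSizePx + 1,
                          col0 = (grid$tj - 1) * tileSizePx + 1,
                          label = labels))
}

# Short stable fingerprint of the spectral parameters for result rows.
paramsHash <- function(params) {
  s <- sprintf("%d|%s|%g|%g|%s", params@nBins, params@window,
               params@lowFreqCutoffPx, params@highFreqCutoffFraction,
               params@weighting)
  sprintf("%08x", sum(utf8ToInt(s) * seq_along(utf8ToInt(s))) %% 0xffffffff)
}

#' Simulate a batch of condition-labelled fibril images
#'
#' One fibril field per image, with per-condition generator settings and
#' per-image seeds derived deterministically from \code{baseSeed}. When
#' \code{outputDir} is given, each image is written as 16-bit TIFF with its
#' JSON sidecar.
#'
#' @param conditions named list; each element is a list of
#'   \code{\link{fibrilFieldSpec}} argument overrides plus \code{nImages}.
#' @param baseSeed integer; image k of condition j uses seed
#'   \code{baseSeed + 1000 * j + k}.
#' @param outputDir optional directory for TIFF output.
#' @return list with \code{images} (list of
#'   \code{\linkS4class{ImageRaster}}) and \code{table} (data.frame of
#'   \code{image_id}, \code{condition}, \code{seed}, \code{path}).
#' @export
simulateImages <- function(conditions, baseSeed = 1L, outputDir = NULL) {
  stopifnot(is.list(conditions), length(conditions) >= 1,
            !is.null(names(conditions)))
  if (!is.null(outputDir))
    dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)
  images <- list(); rows <- list()
  for (j in seq_along(conditions)) {
    cond <- names(conditions)[j]
    cfg <- conditions[[j]]
    nImages <- cfg$nImages %||% 1L
    cfg$nImages <- NULL
    for (k in seq_len(nImages)) {
      seed <- as.integer((baseSeed + 1000L * j + k) %% .Machine$integer.max)
      spec <- do.call(fibrilFieldSpec, c(cfg, list(seed = seed)))
      img <- generateFibrilField(spec)
      id <- sprintf("%s_%03d", cond, k)
      path <- NA_character_
      if (!is.null(outputDir)) {
        path <- file.path(outputDir, paste0(id, ".tif"))
        writeImageRaster(img, path)
      }
      images[[id]] <- img
      rows[[length(rows) + 1L]] <-
        data.frame(image_id = id, condition = cond, seed = seed,
                   path = path)
    }
  }
  list(images = images, table = do.call(rbind, rows))
}

#' Analyze a batch of images: I(phi) and OI per image (or per tile)
#'
#' @param images named list of \code{\linkS4class{ImageRaster}} (names are
#'   image ids) or a character vector of TIFF/PNG paths.
#' @param conditionMap named character vector mapping image id to condition
#'   label; unnamed images get condition \code{"unlabelled"}.
#' @param params a \code{\linkS4class{SpectralParams}}.
#' @param thetaRefDeg OI reference angle (degrees).
#' @param regionPolicy \code{"whole_image"} or \code{"tiles"}.
#' @param tileSizePx tile side when \code{regionPolicy = "tiles"}.
#' @param wound optional \code{\linkS4class{WoundSpec}} for wound/non-wound
#'   tile labelling.
#' @return data.frame with columns \code{image_id}, \code{condition},
#'   \code{region}, \code{peak_deg}, \code{oi_percent},
#'   \code{theta_ref_deg}, \code{n_bins}, \code{params_hash}. Unreadable
#'   images are collected as warnings; the call fails only if every image
#'   fails.
#' @export
analyzeImages <- function(images, conditionMap = NULL,
                          params = spectralParams(), thetaRefDeg = 90,
                          regionPolicy = c("whole_image", "tiles"),
                          tileSizePx = 256L, wound = NULL) {
  regionPolicy <- match.arg(regionPolicy)
  if (is.character(images)) {
    paths <- images
    images <- lapply(paths, function(p) tryCatch(readImageRaster(p),
                                                 error = function(e) e))
    names(images) <- tools::file_path_sans_ext(basename(paths))
  }
  if (length(images) == 0L) stop("no input images")
  rows <- list(); failures <- character(0)
  hash <- paramsHash(params)
  for (id in names(images)) {
    img <- images[[id]]
    if (inherits(img, "error")) {
      failures <- c(failures, sprintf("%s: %s", id, conditionMessage(img)))
      next
    }
    cond <- if (!is.null(conditionMap) && id %in% names(conditionMap))
      conditionMap[[id]] else "unlabelled"
    units <- if (regionPolicy == "whole_image") {
      list(list(raster = img, region = "whole"))
    } else {
      tl <- tileRegions(img, wound = wound, tileSizePx = tileSizePx)
      lapply(tl$tiles, function(t)
        list(raster = t, region = t@provenance$region))
    }
    for (u in units) {
      res <- tryCatch({
        d <- orientationDistribution(u$raster, params)
        oi <- orientationIndex(d, thetaRefDeg)
        data.frame(image_id = id, condition = cond, region = u$region,
                   peak_deg = peakOrientation(d),
                   oi_percent = oi@oiPercent,
                   theta_ref_deg = oi@thetaRefDeg,
                   n_bins = params@nBins, params_hash = hash)
      }, error = function(e) e)
      if (inherits(res, "error"))
        failures <- c(failures, sprintf("%s: %s", id, conditionMessage(res)))
      else rows[[length(rows) + 1L]] <- res
    }
  }
  if (length(rows) == 0L)
    stop("all images failed to analyze:\n  ",
         paste(failures, collapse = "\n  "))
  if (length(failures))
    warning("some images failed:\n  ", paste(failures, collapse = "\n  "))
  do.call(rbind, rows)
}

#' Run the full pipeline from a configuration
#'
#' Orchestrates simulate -> analyze -> compare. The configuration may be a
#' YAML file path or an equivalent nested list with fields \code{mode}
#' (\code{"run"}, \code{"simulate"}, \code{"analyze"} or \code{"compare"}),
#' \code{seed}, \code{theta_ref_deg}, \code{spectral} (params overrides),
#' \code{region_policy}, \code{tile_size_px}, \code{wound}
#' (\code{center_px}, \code{radius_um}), \code{conditions} (for simulate),
#' \code{input} (directory or file list, for analyze),
#' \code{input_csv} (for compare) and \code{output_dir}. Outputs are a
#' per-image \code{results.csv}, a \code{comparison.csv} and a JSON
#' \code{manifest.json} echoing the configuration and package version.
#' Identical configuration and seed give byte-identical CSVs.
#'
#' @param config YAML path or list.
#' @param outputDir overrides \code{config$output_dir}.
#' @return list with \code{results} (per-image data.frame),
#'   \code{comparison} (a \code{\linkS4class{GroupComparison}} or
#'   \code{NULL}), and \code{paths} of the files written.
#' @export
runPipeline <- function(config, outputDir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  mode <- config$mode %||% "run"
  outDir <- outputDir %||% config$output_dir %||% stop("output_dir required")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed %||% 1L)
  thetaRef <- config$theta_ref_deg %||% 90
  if (thetaRef < -90 || thetaRef > 90)
    stop("theta_ref_deg must lie in [-90, 90]")
  sp <- do.call(spectralParams, config$spectral %||% list())
  regionPolicy <- config$region_policy %||% "whole_image"
  tileSize <- config$tile_size_px %||% 256L
  if (regionPolicy == "tiles" && tileSize < 64)
    stop("tile_size_px must be >= 64 when region_policy is 'tiles'")
  wound <- NULL
  if (!is.null(config$wound))
    wound <- woundSpec(centerPx = unlist(config$wound$center_px),
                       radiusUm = config$wound$radius_um %||% 500)

  results <- NULL; comparison <- NULL; paths <- list()
  message("fibrilign: mode '", mode, "', seed ", seed)

  if (mode %in% c("run", "simulate")) {
    if (is.null(config$conditions)) stop("conditions required for simulate")
    sim <- simulateImages(config$conditions, baseSeed = seed,
                          outputDir = if (mode == "simulate" ||
                                          isTRUE(config$write_images))
                            file.path(outDir, "images") else NULL)
    message("fibrilign: simulated ", length(sim$images), " image(s)")
    condMap <- stats::setNames(sim$table$condition, sim$table$image_id)
    if (mode == "run")
      results <- analyzeImages(sim$images, conditionMap = condMap,
                               params = sp, thetaRefDeg = thetaRef,
                               regionPolicy = regionPolicy,
                               tileSizePx = tileSize, wound = wound)
  }
  if (mode == "analyze") {
    if (is.null(config$input)) stop("input required for analyze")
    files <- config$input
    if (length(files) == 1L && !file.exists(files))
      stop("empty input: no such file or directory: ", files)
    if (length(files) == 1L && dir.exists(files))
      files <- list.files(files, pattern = "\\.(tif|tiff|png)$",
                          full.names = TRUE, ignore.case = TRUE)
    if (length(files) == 0L) stop("empty input directory")
    condMap <- unlist(config$condition_map %||% NULL)
    results <- analyzeImages(files, conditionMap = condMap, params = sp,
                             thetaRefDeg = thetaRef,
                             regionPolicy = regionPolicy,
                             tileSizePx = tileSize, wound = wound)
  }
  if (mode == "compare") {
    if (is.null(config$input_csv)) stop("input_csv required for compare")
    results <- utils::read.csv(config$input_csv)
  }

  if (!is.null(results)) {
    paths$results <- file.path(outDir, "results.csv")
    utils::write.csv(results, paths$results, row.names = FALSE)
    message("fibrilign: wrote ", nrow(results), " result row(s)")
    if (length(unique(results$condition)) >= 2L) {
      comparison <- compareConditions(results,
                                      welch = isTRUE(config$welch))
      paths$comparison <- file.path(outDir, "comparison.csv")
      utils::write.csv(as.data.frame(comparison), paths$comparison,
                       row.names = FALSE)
      message("fibrilign: ANOVA F = ",
              format(comparison@fStatistic, digits = 4),
              ", p = ", format(comparison@pValue, digits = 4))
    }
  }

  manifest <- list(
    package = "fibrilign",
    version = as.character(utils::packageVersion("fibrilign")),
    mode = mode, seed = seed, theta_ref_deg = thetaRef,
    region_policy = regionPolicy,
    config = config
  )
  paths$manifest <- file.path(outDir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  invisible(list(results = results, comparison = comparison, paths = paths))
}
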