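#' Construct an ImageRaster
#'
#' @param pixels numeric matrix with finite values in \code{[0, 1]} (rows =
#'   image y, columns = image x).
#' @param pixelSizeUm microns per pixel.
#' @param channelLabel free-text channel description.
#' @param provenance list recording where the raster came from.
#' @return an \code{\linkS4class{ImageRaster}}.
#' @examples
#' img <- ImageRaster(matrix(0.5, 64, 64))
#' dim(pixels(img))
#' @export
ImageRaster <- function(pixels, pixelSizeUm = 0.3, channelLabel = "gray",
                        provenance = list()) {
  new("ImageRaster", pixels = pixels, pixelSizeUm = pixelSizeUm,
      channelLabel = channelLabel, provenance = provenance)
}

#' @rdname accessors
#' @export
setMethod("pixels", "ImageRaster", function(object) object@pixels)

#' @rdname accessors
#' @export
setMethod("pixelSizeUm", "ImageRaster", function(object) object@pixelSizeUm)

#' @rdname accessors
#' @export
setMethod("provenance", "ImageRaster", function(object) object@provenance)

#' @rdname accessors
#' @export
setMethod("cellMask", "ImageRaster", function(object) {
  object@provenance[["cellMask"]]
})

#' @export
setMethod("dim", "ImageRaster", function(x) dim(x@pixels))

setMethod("show", "ImageRaster", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("ImageRaster: %d x %d px (%.3g um/px), channel '%s'\n",
              d[1], d[2], object@pixelSizeUm, object@channelLabel))
  cat(sprintf("  intensity range [%.3f, %.3f]\n",
              min(object@pixels), max(object@pixels)))
  if (length(object@provenance))
    cat("  provenance:", paste(names(object@provenance), collapse = ", "),
        "\n")
})

#' Write an ImageRaster to 16-bit grayscale TIFF with a JSON sidecar
#'
#' The sidecar (same path with extension \code{.json}) records the pixel
#' size, channel label and any serialisable provenance (generator specs in
#' particular), so a synthetic image can be regenerated or its analysis
#' replayed from disk.
#'
#' @param image an \code{\linkS4class{ImageRaster}}.
#' @param path output TIFF path.
#' @return \code{path}, invisibly.
#' @seealso \code{\link{readImageRaster}}
#' @export
writeImageRaster <- function(image, path) {
  stopifnot(is(image, "ImageRaster"))
  tiff::writeTIFF(image@pixels, path, bits.per.sample = 16L,
                  compression = "none")
  sidecar <- paste0(tools::file_path_sans_ext(path), ".json")
  meta <- list(
    pixel_size_um = image@pixelSizeUm,
    channel_label = image@channelLabel,
    provenance = provenanceToList(image@provenance)
  )
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# Drop non-serialisable provenance entries (masks, base rasters) and expand
# S4 specs into plain lists for the JSON sidecar.
provenanceToList <- function(prov) {
  out <- list()
  for (nm in names(prov)) {
    x <- prov[[nm]]
    if (isVirtualClass(class(x)) || is.function(x)) next
    if (is(x, "FibrilFieldSpec") || is(x, "CellFieldSpec") ||
        is(x, "WoundSpec")) {
      sl <- lapply(slotNames(x), function(s) slot(x, s))
      names(sl) <- slotNames(x)
      out[[nm]] <- c(list(class = class(x)[1]), sl)
    } else if (is.matrix(x) || is(x, "ImageRaster")) {
      next  # rasters/masks are not serialised into the sidecar
    } else if (is.atomic(x) || is.list(x)) {
      out[[nm]] <- x
    }
  }
  out
}

#' Read a grayscale raster from TIFF or PNG
#'
#' Multi-page TIFFs are treated as independent frames: \code{frame} selects
#' one. RGB(A) input is converted to grayscale by channel averaging. If a
#' JSON sidecar written by \code{\link{writeImageRaster}} is present its
#' pixel size overrides \code{pixelSizeUm}.
#'
#' @param path TIFF or PNG file.
#' @param pixelSizeUm microns per pixel, used when no sidecar is found.
#' @param frame 1-based frame index for multi-page TIFF.
#' @return an \code{\linkS4class{ImageRaster}}.
#' @export
readImageRaster <- function(path, pixelSizeUm = 0.3, frame = 1L) {
  if (!file.exists(path)) stop("no such image file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    frames <- tiff::readTIFF(path, all = TRUE)
    if (frame < 1L || frame > length(frames))
      stop("frame ", frame, " out of range (", length(frames), " frames)")
    m <- frames[[frame]]
  } else if (ext == "png") {
    m <- png::readPNG(path)
  } else {
    stop("unsupported image format: .", ext, " (TIFF or PNG expected)")
  }
  if (length(dim(m)) == 3L) m <- apply(m[, , 1:min(3L, dim(m)[3]), drop = FALSE],
                                       c(1, 2), mean)
  prov <- list(path = path, frame = frame)
  sidecar <- paste0(tools::file_path_sans_ext(path), ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(meta$pixel_size_um)) pixelSizeUm <- meta$pixel_size_um
    prov$sidecar <- meta
  }
  ImageRaster(clamp01(m), pixelSizeUm = pixelSizeUm,
              channelLabel = "file", provenance = prov)
}
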