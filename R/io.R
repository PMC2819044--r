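# Readers and writers: 8-bit grayscale PNG/TIFF/BMP images, ROI masks,
# ground-truth sidecars and CSV reports.

.readGreyArray <- function(path) {
  ext <- tolower(tools::file_ext(path))
  a <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("reading TIFF requires the 'tiff' package")
      tiff::readTIFF(path)
    },
    bmp = return(.readBMP(path)),
    stop("unsupported image format '", ext, "' for ", path,
         " (PNG, TIFF and BMP are supported)"))
  if (length(dim(a)) == 3) a <- a[, , 1]
  round(a * 255)
}

# Minimal uncompressed BMP reader (8-bit palette or 24-bit), the native
# capture format of older acquisition setups; no installed package reads it.
.readBMP <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  u16 <- function(i) sum(as.integer(raw[i + 0:1]) * c(1, 256))
  u32 <- function(i) sum(as.integer(raw[i + 0:3]) * 256^(0:3))
  if (rawToChar(raw[1:2]) != "BM") stop("not a BMP file: ", path)
  offset <- u32(11)
  width <- u32(19); height <- u32(23)
  bpp <- u16(29); compression <- u32(31)
  if (compression != 0) stop("compressed BMP is not supported")
  if (!bpp %in% c(8, 24)) stop("only 8-bit and 24-bit BMP are supported")
  g <- matrix(0, height, width)
  if (bpp == 8) {
    hdrSize <- u32(15)
    nCol <- u32(47); if (nCol == 0) nCol <- 256
    pal <- matrix(as.integer(raw[14 + hdrSize + seq_len(4 * nCol)]),
                  ncol = 4, byrow = TRUE)
    palGrey <- rowMeans(pal[, 1:3])
    stride <- 4 * ceiling(width / 4)
    for (r in seq_len(height)) {
      rowBytes <- as.integer(raw[offset + (r - 1) * stride + seq_len(width)])
      g[height - r + 1, ] <- palGrey[rowBytes + 1]  # bottom-up storage
    }
  } else {
    stride <- 4 * ceiling(3 * width / 4)
    for (r in seq_len(height)) {
      rowBytes <- as.integer(raw[offset + (r - 1) * stride + seq_len(3 * width)])
      px <- matrix(rowBytes, nrow = 3)
      g[height - r + 1, ] <- colMeans(px)
    }
  }
  round(g)
}

#' Read an epithelium image and its ROI mask
#'
#' Reads an 8-bit grayscale image (PNG, TIFF or uncompressed BMP) and an
#' optional binary ROI mask image of the same size (foreground = pixels
#' above half intensity). Without a mask the ROI defaults to the full frame
#' with a warning. Inputs whose basal lamina is at the top can be flipped
#' with `flipVertical` (the analysis convention is basal at the bottom).
#'
#' @param path image file path.
#' @param roiPath optional mask file path.
#' @param pixelArea um^2 per pixel calibration.
#' @param flipVertical flip both rasters upside down after reading.
#' @return an [EpitheliumImage-class].
#' @export
readEpitheliumImage <- function(path, roiPath = NULL,
                                pixelArea = defaultPixelArea(),
                                flipVertical = FALSE) {
  if (!file.exists(path)) stop("image file not found: ", path)
  grey <- .readGreyArray(path)
  if (is.null(roiPath)) {
    warning("no ROI mask supplied for ", path, "; using the full frame")
    roi <- matrix(TRUE, nrow(grey), ncol(grey))
  } else {
    if (!file.exists(roiPath)) stop("ROI file not found: ", roiPath)
    roi <- .readGreyArray(roiPath) > 127
    if (!all(dim(roi) == dim(grey)))
      stop("ROI dimensions ", paste(dim(roi), collapse = "x"),
           " do not match image dimensions ",
           paste(dim(grey), collapse = "x"), " for ", path)
  }
  if (flipVertical) {
    grey <- grey[rev(seq_len(nrow(grey))), , drop = FALSE]
    roi <- roi[rev(seq_len(nrow(roi))), , drop = FALSE]
  }
  new("EpitheliumImage", grey = grey, roi = roi, pixelArea = pixelArea)
}

#' Write an epithelium image (and optionally its ROI) as 8-bit grey PNG
#'
#' @param img an [EpitheliumImage-class].
#' @param path output PNG path for the grey raster.
#' @param roiPath optional output PNG path for the ROI mask.
#' @return `path`, invisibly.
#' @export
writeEpitheliumImage <- function(img, path, roiPath = NULL) {
  stopifnot(is(img, "EpitheliumImage"))
  png::writePNG(img@grey / 255, path)
  if (!is.null(roiPath)) png::writePNG(img@roi * 1, roiPath)
  invisible(path)
}

#' Write and read a ground-truth sidecar (JSON)
#'
#' @param truth a [GroundTruth-class].
#' @param path JSON file path.
#' @return `path` invisibly for the writer; a list for the reader.
#' @export
writeGroundTruth <- function(truth, path) {
  stopifnot(is(truth, "GroundTruth"))
  jsonlite::write_json(list(
    centers = unname(truth@centers), areas = truth@areas,
    roiArea = truth@roiArea, compartment = truth@compartment,
    differentiatedRows = range(which(rowSums(truth@differentiatedMask) > 0))
  ), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeGroundTruth
#' @export
readGroundTruth <- function(path) jsonlite::read_json(path, simplifyVector = TRUE)

#' Write and read a per-image report (CSV)
#'
#' The report holds the six parameters (pixel and um^2 scale), the three
#' ratios, the coefficient k, the score and the grade; reading a written
#' report recovers the values.
#'
#' @param result a [CervicalResult-class] (writer).
#' @param path CSV file path.
#' @return `path` invisibly for the writer; a `data.frame` for the reader.
#' @export
writeReport <- function(result, path) {
  stopifnot(is(result, "CervicalResult"))
  write.csv(format(featureTable(result), digits = 17, trim = TRUE,
                   scientific = FALSE),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeReport
#' @export
readReport <- function(path) read.csv(path, stringsAsFactors = FALSE)
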