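# Nuclear segmentation: contrast normalisation, thresholding, mask cleaning
# and suppression of edge-cutting nuclei, then measurement of the ROI and
# mean nuclear areas (parameters A and N).

#' Contrast-normalise an epithelium image
#'
#' Linearly rescales the grey levels inside the ROI so that the 1st and 99th
#' percentiles map to 0 and 255 (the "increase light and contrast" step);
#' values are clipped and rounded, pixels outside the ROI are untouched. The
#' operation is idempotent up to rounding. A constant ROI is returned
#' unchanged with a warning.
#'
#' @param img an [EpitheliumImage-class].
#' @return the normalised [EpitheliumImage-class].
#' @export
preprocessImage <- function(img) {
  stopifnot(is(img, "EpitheliumImage"))
  v <- img@grey[img@roi]
  q <- quantile(v, c(0.01, 0.99), names = FALSE)
  if (q[2] <= q[1]) {
    warning("constant grey level inside the ROI; image returned unchanged")
    return(img)
  }
  g <- img@grey
  g[img@roi] <- round(pmin(255, pmax(0, (v - q[1]) / (q[2] - q[1]) * 255)))
  new("EpitheliumImage", grey = g, roi = img@roi, pixelArea = img@pixelArea)
}

#' Threshold nuclei
#'
#' Marks as foreground the ROI pixels darker than the threshold. By default
#' the threshold is Otsu's criterion computed on the ROI pixels only; a
#' manual grey-level threshold can be supplied instead.
#'
#' @param img an [EpitheliumImage-class] (normally preprocessed).
#' @param threshold optional manual grey level; pixels with `grey <
#'   threshold` are selected.
#' @return logical nucleus mask.
#' @export
thresholdNuclei <- function(img, threshold = NULL) {
  stopifnot(is(img, "EpitheliumImage"))
  v <- img@grey[img@roi]
  if (length(v) == 0) stop("empty ROI")
  if (is.null(threshold) || is.na(threshold)) {
    threshold <- 255 * EBImage::otsu(
      EBImage::Image(matrix(v / 255, ncol = 1)), range = c(0, 1),
      levels = 256)
  }
  img@grey < threshold & img@roi
}

#' Clean a binary nucleus mask
#'
#' Fills interior holes of the foreground components and removes components
#' smaller than `minArea` (noise specks). Idempotent.
#'
#' @param mask logical matrix.
#' @param minArea minimum component area kept, px^2.
#' @return logical matrix.
#' @export
cleanMask <- function(mask, minArea = 30) {
  filled <- fillHoles(mask)
  lab <- cpp_label8(filled)
  if (max(lab) == 0) return(filled)
  sizes <- tabulate(lab, nbins = max(lab))
  keep <- which(sizes >= minArea)
  filled & (lab %in% keep)
}

#' Suppress edge-cutting nuclei and label the survivors
#'
#' Connected components touching the outer image frame are removed (the
#' 1-px-border rule: a nucleus cut by the frame cannot be measured), the
#' survivors are labelled 1..count in raster order and their mean area is
#' computed.
#'
#' @param mask cleaned logical nucleus mask.
#' @param roi logical ROI mask (same dimensions).
#' @return a [NucleiLabelMap-class]; `count = 0` with a warning when every
#'   nucleus touched the frame.
#' @export
suppressBorderNuclei <- function(mask, roi) {
  stopifnot(all(dim(mask) == dim(roi)))
  mask <- mask & roi
  lab <- cpp_label8(mask)
  nlab <- max(lab)
  if (nlab > 0) {
    border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
    border <- border[border > 0]
    if (length(border)) {
      lab[lab %in% border] <- 0L
      # relabel survivors compactly, preserving raster order
      surv <- sort(unique(lab[lab > 0]))
      lab[] <- match(lab, surv, nomatch = 0L)
      nlab <- length(surv)
    }
  }
  if (nlab == 0) {
    warning("no nuclei survived border suppression")
    return(new("NucleiLabelMap", labels = lab, count = 0L,
               meanArea = NA_real_))
  }
  new("NucleiLabelMap", labels = lab, count = as.integer(nlab),
      meanArea = sum(lab > 0) / nlab)
}

#' Measure epithelium and mean nuclear area
#'
#' The first two parameters of the feature vector: A = ROI foreground area
#' and N = mean nucleus area, in px^2 and um^2.
#'
#' @param nuclei a [NucleiLabelMap-class].
#' @param img the [EpitheliumImage-class] the nuclei came from.
#' @return data.frame with columns `A`, `N`, `A_um2`, `N_um2` (`N` is `NA`,
#'   not zero, when no nuclei were measured).
#' @export
measureBasic <- function(nuclei, img) {
  stopifnot(is(nuclei, "NucleiLabelMap"), is(img, "EpitheliumImage"))
  A <- sum(img@roi)
  N <- if (nuclei@count > 0) nuclei@meanArea else NA_real_
  data.frame(A = A, N = N,
    A_um2 = A * img@pixelArea, N_um2 = N * img@pixelArea)
}

#' Segment the nuclei of an image
#'
#' Convenience chain: [preprocessImage()], [thresholdNuclei()],
#' [cleanMask()], [suppressBorderNuclei()].
#'
#' @param img an [EpitheliumImage-class].
#' @param threshold optional manual threshold (default: Otsu).
#' @param minArea minimum nucleus area kept.
#' @return list with `nuclei` (a [NucleiLabelMap-class]) and `preprocessed`
#'   (the normalised image, used downstream for chromaticism).
#' @export
segmentNuclei <- function(img, threshold = NULL, minArea = 30) {
  pre <- preprocessImage(img)
  mask <- thresholdNuclei(pre, threshold)
  mask <- cleanMask(mask, minArea)
  list(nuclei = suppressBorderNuclei(mask, pre@roi), preprocessed = pre)
}
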