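# The dilation/erosion differentiation measurement: nuclear radius from the
# mean nucleus area, the coefficient k from the mean inter-nuclear edge,
# and a morphological closing of the nuclei mask whose basal-anchored part
# is the differentiated epithelium compartment (parameter D).

#' Mean nuclear radius from the mean nucleus area
#'
#' r = `round(sqrt(area / pi))`, floored at 1 px: the radius of the disc of
#' equivalent area (a 199 px nucleus has an 8 px radius).
#'
#' @param meanArea mean nucleus area, px^2 (> 0).
#' @return radius in pixels (integer-valued).
#' @examples
#' nuclearRadius(199)  # 8
#' @export
nuclearRadius <- function(meanArea) {
  if (!is.finite(meanArea) || meanArea <= 0)
    stop("mean nucleus area must be positive")
  max(1, round(sqrt(meanArea / pi)))
}

#' Dilation/erosion coefficient
#'
#' The closing size: the mean inter-nuclear distance divided by one quarter
#' of the mean nuclear radius, `k = round(4 * meanEdge / radius)`. With
#' this k, nuclei whose spacing is at most the mean edge end up merged by
#' the closing, so the compact (differentiated) compartment coalesces while
#' sparse upper nuclei stay isolated.
#'
#' @param meanEdge mean Delaunay edge length (or particle separation), px.
#' @param radius mean nuclear radius, px (>= 1).
#' @return k in pixels (integer-valued).
#' @examples
#' dilationCoefficient(32, 8)  # 16
#' dilationCoefficient(60, 8)  # 30
#' @export
dilationCoefficient <- function(meanEdge, radius) {
  if (!is.finite(radius) || radius < 1)
    stop("nuclear radius must be at least 1 pixel")
  if (!is.finite(meanEdge) || meanEdge < 0)
    stop("mean edge must be non-negative")
  round(4 * meanEdge / radius)
}

#' Morphological closing of the nuclei mask
#'
#' Dilation by the chessboard ball of radius `k` followed by erosion with
#' the same element, both constrained to the ROI (outside-ROI area acts as
#' filled space for the erosion, so the result is clipped to but never
#' eaten at the ROI boundary). The closing is extensive (a superset of the
#' input within the ROI) and idempotent, and merges objects separated by
#' gaps of at most `2k` pixels.
#'
#' @param mask logical nucleus mask.
#' @param k closing radius in pixels (`k = 0` is the identity).
#' @param roi optional logical ROI mask (default: whole frame).
#' @return logical matrix.
#' @export
morphologicalClosing <- function(mask, k, roi = NULL) {
  stopifnot(k >= 0)
  k <- as.integer(round(k))
  mask <- mask > 0
  if (is.null(roi)) roi <- matrix(TRUE, nrow(mask), ncol(mask))
  roi <- roi > 0
  if (k == 0) return(mask & roi)
  d <- boxDilate(mask, k) | !roi
  boxErode(d, k, padValue = TRUE) & roi
}

#' Measure the differentiated epithelium
#'
#' Closes the nuclei mask with the coefficient `k`, fills interior holes,
#' and keeps the connected components anchored to the basal side of the ROI
#' (touching its bottom `basalBand` rows): that basal-anchored block is the
#' differentiated compartment, its area is D, and the rest of the ROI is
#' the upper (non-differentiated) region. The area of the unfiltered
#' closing is reported alongside for comparison.
#'
#' @param nuclei a [NucleiLabelMap-class].
#' @param k dilation/erosion coefficient, px.
#' @param roi logical ROI mask.
#' @param basalBand height of the basal attachment band, px.
#' @return a [DifferentiationResult-class].
#' @export
measureDifferentiation <- function(nuclei, k, roi, basalBand = 5) {
  stopifnot(is(nuclei, "NucleiLabelMap"))
  roi <- roi > 0
  mask <- nuclei@labels > 0
  closed <- fillHoles(morphologicalClosing(mask, k, roi))
  closingArea <- sum(closed)
  diffMask <- matrix(FALSE, nrow(roi), ncol(roi))
  if (closingArea > 0) {
    lab <- cpp_label8(closed)
    roiRows <- which(rowSums(roi) > 0)
    basalRows <- seq(max(roiRows) - basalBand + 1, max(roiRows))
    anchored <- unique(as.vector(lab[basalRows, ]))
    anchored <- anchored[anchored > 0]
    if (length(anchored)) diffMask <- closed & (lab %in% anchored)
  }
  new("DifferentiationResult",
    coefficientK = as.numeric(k), meanRadius = nuclearRadius(
      if (nuclei@count > 0) nuclei@meanArea else 1),
    differentiatedMask = diffMask, upperMask = roi & !diffMask,
    D = sum(diffMask), closingArea = closingArea)
}
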