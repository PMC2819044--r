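# Nuclear chromaticism: the segmented nuclei are superimposed on the
# contrast-normalised grey image, the result inverted, and its level
# measured over the whole ROI (Hst) and over the upper non-differentiated
# region (HstU). Staining density of the nuclei drives both.

#' Chromaticism of nuclei within a region
#'
#' Mean inverted grey level `255 - grey` over the pixels that are
#' simultaneously nucleus and region. With `denominator = "nuclei"`
#' (default) the mean is taken over the nucleus pixels themselves (the
#' darkness of the average nucleus pixel); with `denominator = "region"`
#' the inverted nuclei-masked image is averaged over the whole region
#' (non-nucleus pixels count as 0), which is the integrated measure used by
#' the pipeline. An empty intersection gives 0.
#'
#' @param img an [EpitheliumImage-class].
#' @param nuclei a [NucleiLabelMap-class] (or logical mask).
#' @param region optional logical region mask (default: the ROI).
#' @param denominator `"nuclei"` or `"region"`.
#' @return inverted-grey mean in \[0, 255\].
#' @export
nucleiChromaticism <- function(img, nuclei, region = NULL,
                               denominator = c("nuclei", "region")) {
  denominator <- match.arg(denominator)
  stopifnot(is(img, "EpitheliumImage"))
  mask <- if (is(nuclei, "NucleiLabelMap")) nuclei@labels > 0 else nuclei > 0
  if (!all(dim(mask) == dim(img@grey)))
    stop("nuclei mask dimensions do not match the image")
  if (is.null(region)) region <- img@roi
  if (!all(dim(region) == dim(img@grey)))
    stop("region dimensions do not match the image")
  region <- region > 0
  sel <- mask & region
  if (!any(sel)) return(0)
  denom <- if (denominator == "nuclei") sum(sel) else sum(region)
  sum(255 - img@grey[sel]) / denom
}

#' Total and upper nuclei chromaticism
#'
#' Hst is the region-normalised chromaticism of all nuclei over the ROI;
#' HstU is the same measure over the upper (non-differentiated) region.
#' Full 256-bin histograms of the inverted nucleus grey levels are attached
#' for inspection.
#'
#' @param img the (preprocessed) [EpitheliumImage-class].
#' @param nuclei a [NucleiLabelMap-class].
#' @param diff a [DifferentiationResult-class] providing the upper region.
#' @return a [ChromaticsResult-class].
#' @export
measureChromatics <- function(img, nuclei, diff) {
  stopifnot(is(diff, "DifferentiationResult"))
  Hst <- nucleiChromaticism(img, nuclei, img@roi, denominator = "region")
  HstU <- nucleiChromaticism(img, nuclei, diff@upperMask,
                             denominator = "region")
  mask <- nuclei@labels > 0
  histOf <- function(region) {
    sel <- mask & region
    tabulate(pmin(255, pmax(0, round(255 - img@grey[sel]))) + 1, nbins = 256)
  }
  new("ChromaticsResult", Hst = Hst, HstU = HstU,
      histTotal = histOf(img@roi), histUpper = histOf(diff@upperMask))
}
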