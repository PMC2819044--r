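#' Pipeline configuration
#'
#' Collects the tunable parameters of the analysis pipeline with their
#' documented defaults: Otsu thresholding on ROI pixels, 30 px^2 minimum
#' component area, the computed pixel-area calibration, unique-edge mean
#' edge length, a self-calibrated dilation/erosion coefficient and a 5 px
#' basal attachment band.
#'
#' @param threshold manual grey threshold, `NA` = Otsu.
#' @param minArea minimum nucleus area kept by cleaning, px^2.
#' @param pixelArea um^2 per pixel.
#' @param edgeMode `"unique"` or `"triangle"` mean-edge counting.
#' @param coefficientK manual closing coefficient, `NA` = derive per image.
#' @param basalBand basal attachment band height, px.
#' @param flipVertical flip inputs whose basal lamina is at the top.
#' @return a [PipelineConfig-class].
#' @export
cinConfig <- function(threshold = NA_real_, minArea = 30,
                      pixelArea = defaultPixelArea(),
                      edgeMode = c("unique", "triangle"),
                      coefficientK = NA_real_, basalBand = 5,
                      flipVertical = FALSE) {
  edgeMode <- match.arg(edgeMode)
  new("PipelineConfig", threshold = as.numeric(threshold),
    minArea = as.numeric(minArea), pixelArea = as.numeric(pixelArea),
    edgeMode = edgeMode, coefficientK = as.numeric(coefficientK),
    basalBand = as.numeric(basalBand),
    flipVertical = isTRUE(flipVertical))
}
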