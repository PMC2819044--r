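# Reference group statistics (means and SDs of the six parameters in the
# four diagnostic groups, pixel units) used to seed the generator presets
# and the default score calibration.
.cinReference <- local({
  tab <- data.frame(
    group  = c("NORMAL", "CIN1", "CIN2", "CIN3"),
    A      = c(212018.0, 211203.0, 193261.0, 183499.0),
    A_sd   = c(25165.0, 19507.0, 34755.0, 36993.0),
    N      = c(173.9, 239.1, 200.6, 206.7),
    N_sd   = c(33.8, 50.7, 41.5, 37.0),
    V      = c(1740.3, 995.5, 595.1, 442.3),
    V_sd   = c(277.5, 170.0, 114.8, 37.4),
    D      = c(30136.3, 75070.4, 111642.0, 157383.9),
    D_sd   = c(4066.0, 10032.7, 27981.4, 32505.0),
    Hst    = c(19.1, 46.7, 59.5, 75.6),
    Hst_sd = c(5.3, 8.2, 9.7, 15.2),
    HstU   = c(7.3, 13.4, 15.6, 3.5),
    HstU_sd = c(2.2, 3.0, 3.8, 2.5),
    stringsAsFactors = FALSE)
  tab$ncRatio <- tab$N / tab$V
  tab$diffRatio <- tab$D / tab$A
  tab$histRatio <- tab$HstU / tab$Hst
  tab
})

# fixed rendering constants of the generator (grey levels, 0-255)
.genBackgroundGrey <- 210
.genUpperDarkness <- 200   # inverted grey of upper-band nuclei
.genNoiseSd <- 4

#' Reference group statistics of the four diagnostic groups
#'
#' Mean and SD of the six morphometric parameters (A, N, V, D, Hst, HstU)
#' per diagnostic group, in pixel units, plus the three derived ratio means.
#' These reference statistics seed the generator presets
#' ([makePreset()]) and the default score calibration
#' ([defaultCalibration()]).
#'
#' @return a `data.frame` with one row per group.
#' @examples
#' cinReferenceTable()[, c("group", "N", "V", "diffRatio")]
#' @export
cinReferenceTable <- function() .cinReference

#' Generator preset for a diagnostic group
#'
#' Builds the generative parameters of the synthetic epithelium generator
#' for one diagnostic group. Mean nucleus area, mean zone area and the
#' differentiated-area fraction come straight from the reference group
#' means; the darkness of the two nuclear compartments and the sparse upper
#' density are derived in closed form so that the measured chromaticism
#' values land near the reference Hst and HstU:
#' with `f` the differentiated fraction, `s_u` the upper zone area and
#' `d_u` the fixed upper darkness,
#' `s_u = d_u * N / HstU` and
#' `d_basal = (Hst - HstU * (1 - f)) / (N * (1/V - (1 - f)/s_u))`.
#'
#' @param label one of `"NORMAL"`, `"CIN1"`, `"CIN2"`, `"CIN3"`
#'   (case-insensitive).
#' @return a [GroupPreset-class].
#' @examples
#' makePreset("NORMAL")
#' makePreset("CIN3")@differentiationFraction  # ~0.858
#' @export
makePreset <- function(label) {
  lab <- toupper(as.character(label)[1])
  ref <- .cinReference
  i <- match(lab, ref$group)
  if (is.na(i))
    stop("unknown group label '", label, "'; expected one of ",
         paste(ref$group, collapse = ", "))
  f <- ref$diffRatio[i]
  upperZone <- .genUpperDarkness * ref$N[i] / ref$HstU[i]
  basalDark <- (ref$Hst[i] - ref$HstU[i] * (1 - f)) /
    (ref$N[i] * (1 / ref$V[i] - (1 - f) / upperZone))
  basalDark <- min(255, max(0, basalDark))
  new("GroupPreset", label = lab,
    meanNucleusArea = ref$N[i], sdNucleusArea = ref$N_sd[i],
    meanZoneArea = ref$V[i], differentiationFraction = f,
    nucleusDarkness = basalDark, upperNucleusDarkness = .genUpperDarkness,
    backgroundGrey = .genBackgroundGrey, upperZoneArea = upperZone)
}

#' Default pixel-area calibration
#'
#' The optical calibration of the reference acquisition setup: a 472 x 608
#' frame (286,976 px) images 0.066 mm^2 of slide, i.e. about 0.230 um^2 per
#' pixel. The value 0.22 is also quoted for this setup; the computed
#' quotient is used as the default and can be overridden everywhere a
#' `pixelArea` argument appears.
#'
#' @return um^2 per pixel (scalar).
#' @export
defaultPixelArea <- function() 0.066e6 / 286976
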