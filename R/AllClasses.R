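#' @import methods
NULL

#' EpitheliumImage: a grayscale epithelium micrograph with its ROI
#'
#' The unit of analysis: an 8-bit grayscale raster together with a binary
#' region-of-interest mask delineating the epithelium between basal lamina
#' (image bottom, by convention) and surface, and the pixel-area calibration
#' of the optical system.
#'
#' @slot grey numeric matrix of grey levels in \[0, 255\].
#' @slot roi logical matrix of the same dimensions; `TRUE` = epithelium.
#' @slot pixelArea micrometers squared per pixel (calibration scalar).
#'
#' @seealso [readEpitheliumImage()], [generateEpithelium()], [fig2Scene()]
#' @export
setClass("EpitheliumImage",
  representation(grey = "matrix", roi = "matrix", pixelArea = "numeric"),
  validity = function(object) {
    if (!all(dim(object@grey) == dim(object@roi)))
      return("grey and roi must have identical dimensions")
    if (!is.logical(object@roi))
      return("roi must be a logical matrix")
    if (!any(object@roi))
      return("roi must contain at least one foreground pixel")
    rng <- range(object@grey)
    if (rng[1] < 0 || rng[2] > 255)
      return("grey levels must lie in [0, 255]")
    if (length(object@pixelArea) != 1 || object@pixelArea <= 0)
      return("pixelArea must be a single positive number")
    TRUE
  })

#' GroupPreset: generative parameters for one diagnostic group
#'
#' Parameters of the synthetic epithelium generator for one of the four
#' diagnostic groups (NORMAL, CIN1, CIN2, CIN3), derived from the reference
#' group means (see [cinReferenceTable()]).
#'
#' @slot label group label, one of `"NORMAL"`, `"CIN1"`, `"CIN2"`, `"CIN3"`.
#' @slot meanNucleusArea,sdNucleusArea per-nucleus area distribution (px^2).
#' @slot meanZoneArea target mean zone-of-influence (cytoplasm) area (px^2).
#' @slot differentiationFraction target differentiated-area fraction D/A.
#' @slot nucleusDarkness inverted grey level of basal-zone nuclei in \[0,255\].
#' @slot upperNucleusDarkness inverted grey level of upper-zone nuclei.
#' @slot backgroundGrey background grey level in \[0,255\].
#' @slot upperZoneArea target per-nucleus zone area in the upper
#'   (non-differentiated) band (px^2); fixes the sparse upper density so the
#'   measured chromaticism ratios land near the reference values.
#' @export
setClass("GroupPreset",
  representation(label = "character",
    meanNucleusArea = "numeric", sdNucleusArea = "numeric",
    meanZoneArea = "numeric", differentiationFraction = "numeric",
    nucleusDarkness = "numeric", upperNucleusDarkness = "numeric",
    backgroundGrey = "numeric", upperZoneArea = "numeric"),
  validity = function(object) {
    if (object@meanNucleusArea >= object@meanZoneArea)
      return("mean nucleus area must be smaller than mean zone area")
    if (object@differentiationFraction < 0 || object@differentiationFraction > 1)
      return("differentiationFraction must lie in [0, 1]")
    for (s in c("nucleusDarkness", "upperNucleusDarkness", "backgroundGrey")) {
      v <- slot(object, s)
      if (v < 0 || v > 255) return(sprintf("%s must lie in [0, 255]", s))
    }
    TRUE
  })

#' GroundTruth: known truth behind a synthetic epithelium image
#'
#' @slot centers n x 2 matrix of nucleus centers (row, col), pixel units.
#' @slot areas realized per-nucleus pixel areas.
#' @slot roiArea ROI foreground pixel count.
#' @slot differentiatedMask logical raster of the true differentiated band.
#' @slot compartment per-nucleus band assignment, `"basal"` or `"upper"`.
#' @export
setClass("GroundTruth",
  representation(centers = "matrix", areas = "numeric", roiArea = "numeric",
    differentiatedMask = "matrix", compartment = "character"),
  validity = function(object) {
    if (nrow(object@centers) != length(object@areas))
      return("number of centers must equal number of areas")
    if (nrow(object@centers) != length(object@compartment))
      return("number of centers must equal length of compartment")
    TRUE
  })

#' NucleiLabelMap: labelled nuclear segmentation
#'
#' Result of segmentation after cleaning and suppression of edge-cutting
#' nuclei: an integer label raster (0 = background, k >= 1 = nucleus k).
#'
#' @slot labels integer matrix of nucleus labels.
#' @slot count number of nuclei.
#' @slot meanArea mean nucleus area in px^2 (the parameter N); `NA` when
#'   `count` is zero.
#' @seealso [suppressBorderNuclei()]
#' @export
setClass("NucleiLabelMap",
  representation(labels = "matrix", count = "integer", meanArea = "numeric"),
  validity = function(object) {
    if (object@count > 0) {
      tot <- sum(object@labels > 0)
      if (abs(object@meanArea * object@count - tot) > 1e-6)
        return("meanArea * count must equal total labelled pixel count")
    }
    TRUE
  })

#' InfluenceMap: Voronoi zones of influence of the nuclei
#'
#' Partition of the ROI into per-nucleus zones of influence (every ROI pixel
#' carries the label of its geodesically nearest nucleus), the morphological
#' proxy for cytoplasmic territory.
#'
#' @slot zones integer matrix of zone labels over the ROI.
#' @slot meanZoneArea mean zone area in px^2 (the parameter V).
#' @seealso [influenceZones()]
#' @export
setClass("InfluenceMap",
  representation(zones = "matrix", meanZoneArea = "numeric"))

#' Triangulation: Delaunay graph of zone centers
#'
#' @slot points n x 2 matrix of vertex coordinates (row, col).
#' @slot edges m x 2 integer matrix of unique vertex-index pairs.
#' @slot meanEdgeLength mean Euclidean edge length in pixels.
#' @slot degenerate `TRUE` when the points were collinear and a chain of
#'   consecutive edges was returned instead of a triangulation.
#' @seealso [delaunayTriangulation()]
#' @export
setClass("Triangulation",
  representation(points = "matrix", edges = "matrix",
    meanEdgeLength = "numeric", degenerate = "logical"),
  validity = function(object) {
    if (nrow(object@edges) > 0) {
      if (any(object@edges[, 1] == object@edges[, 2]))
        return("edges must join two distinct points")
      if (max(object@edges) > nrow(object@points))
        return("edge indices must reference existing points")
    }
    TRUE
  })

#' DifferentiationResult: the differentiated-epithelium measurement
#'
#' @slot coefficientK dilation/erosion coefficient in pixels.
#' @slot meanRadius mean nuclear radius r in pixels.
#' @slot differentiatedMask logical raster of the basal-anchored
#'   differentiated compartment.
#' @slot upperMask logical raster of the upper (non-differentiated) region;
#'   together the two masks partition the ROI.
#' @slot D differentiated area in px^2.
#' @slot closingArea area of the pure (unfiltered) closing, for comparison.
#' @seealso [measureDifferentiation()]
#' @export
setClass("DifferentiationResult",
  representation(coefficientK = "numeric", meanRadius = "numeric",
    differentiatedMask = "matrix", upperMask = "matrix",
    D = "numeric", closingArea = "numeric"),
  validity = function(object) {
    if (abs(sum(object@differentiatedMask) - object@D) > 1e-6)
      return("D must equal the differentiated mask area")
    if (any(object@differentiatedMask & object@upperMask))
      return("differentiated and upper masks must be disjoint")
    TRUE
  })

#' ChromaticsResult: nuclear chromaticism measurements
#'
#' @slot Hst total nuclei chromaticism: mean inverted grey of the
#'   nuclei-masked image over the ROI, in \[0, 255\].
#' @slot HstU upper nuclei chromaticism: same measure over the upper
#'   (non-differentiated) region; 0 when no nucleus pixel lies there.
#' @slot histTotal,histUpper 256-bin histograms of inverted nucleus grey
#'   levels (bin i = inverted level i-1), for inspection.
#' @seealso [measureChromatics()]
#' @export
setClass("ChromaticsResult",
  representation(Hst = "numeric", HstU = "numeric",
    histTotal = "numeric", histUpper = "numeric"),
  validity = function(object) {
    if (object@Hst < 0 || object@Hst > 255 ||
        object@HstU < 0 || object@HstU > 255)
      return("Hst and HstU must lie in [0, 255]")
    TRUE
  })

#' FeatureVector: the six measured parameters of one image
#'
#' @slot A epithelium (ROI) area, px^2.
#' @slot N mean nucleus area, px^2 (`NA` when no nuclei survive).
#' @slot V mean zone-of-influence area, px^2.
#' @slot D differentiated epithelium area, px^2.
#' @slot Hst,HstU total and upper nuclei chromaticism.
#' @slot k dilation/erosion coefficient used, px.
#' @slot pixelArea calibration, um^2 per pixel.
#' @export
setClass("FeatureVector",
  representation(A = "numeric", N = "numeric", V = "numeric", D = "numeric",
    Hst = "numeric", HstU = "numeric", k = "numeric", pixelArea = "numeric"))

#' RatioSet: the three discriminant ratios
#'
#' @slot ncRatio nucleo-cytoplasmic ratio N/V.
#' @slot diffRatio epithelial differentiation ratio DR = D/A.
#' @slot histRatio upper nuclei histogram ratio HstR = HstU/Hst.
#' @seealso [computeRatios()]
#' @export
setClass("RatioSet",
  representation(ncRatio = "numeric", diffRatio = "numeric",
    histRatio = "numeric"),
  validity = function(object) {
    if (!is.na(object@diffRatio) &&
        (object@diffRatio < 0 || object@diffRatio > 1))
      return("diffRatio must lie in [0, 1]")
    if (!is.na(object@histRatio) && object@histRatio < 0)
      return("histRatio must be non-negative")
    TRUE
  })

#' ScoreCalibration: affine map from ratios to the cervical score scale
#'
#' Weights and offset of `score = w1*ncRatio + w2*diffRatio +
#' w3*(1 - histRatio) + b`, together with the reference group-mean ratios
#' and target scores it was fitted on.
#'
#' @slot weights named numeric of length 3 (`nc`, `dr`, `hst`).
#' @slot offset intercept b.
#' @slot reference 4 x 3 matrix of group-mean ratios (nc, dr, hstR).
#' @slot targets reference scores per group (ascending with grade).
#' @slot grades group labels matching `targets`.
#' @seealso [fitCalibration()], [defaultCalibration()]
#' @export
setClass("ScoreCalibration",
  representation(weights = "numeric", offset = "numeric",
    reference = "matrix", targets = "numeric", grades = "character"))

#' CervicalResult: ratios, score and grade for one image
#'
#' @slot features the six measured parameters.
#' @slot ratios the three discriminant ratios.
#' @slot score calibrated cervical score (clipped to \[0, 120\]).
#' @slot grade assigned grade, or `NA` when no nuclei were found.
#' @seealso [runPipeline()]
#' @export
setClass("CervicalResult",
  representation(features = "FeatureVector", ratios = "RatioSet",
    score = "numeric", grade = "character"))

#' PipelineConfig: tunable parameters of the analysis pipeline
#'
#' @slot threshold manual grey-level threshold; `NA` = Otsu on ROI pixels.
#' @slot minArea minimum component area kept by mask cleaning (px^2).
#' @slot pixelArea um^2 per pixel calibration.
#' @slot edgeMode `"unique"` (each shared edge counted once, default) or
#'   `"triangle"` (per-triangle multiplicity) for the mean edge length.
#' @slot coefficientK manual dilation/erosion coefficient; `NA` = derive from
#'   this image's mean edge and nuclear radius (self-calibrating).
#' @slot basalBand height in pixels of the basal attachment band.
#' @slot flipVertical flip input images whose basal lamina is at the top.
#' @seealso [cinConfig()]
#' @export
setClass("PipelineConfig",
  representation(threshold = "numeric", minArea = "numeric",
    pixelArea = "numeric", edgeMode = "character", coefficientK = "numeric",
    basalBand = "numeric", flipVertical = "logical"))
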