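#' Accessor generics
#'
#' Small accessor family for the core classes: `greyValues()` and `roiMask()`
#' on an [EpitheliumImage-class], `nucleiCount()` and `meanNucleusArea()` on a
#' [NucleiLabelMap-class], `meanZoneArea()` on an [InfluenceMap-class],
#' `meanEdgeLength()` on a [Triangulation-class], and `scoreValue()` /
#' `gradeLabel()` / `featureTable()` on a [CervicalResult-class].
#'
#' @param object one of the cervimorph S4 objects.
#' @return the corresponding slot value; `featureTable()` returns a one-row
#'   `data.frame` with the six parameters, the ratios, score and grade.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("greyValues", function(object) standardGeneric("greyValues"))
#' @rdname accessors
#' @export
setGeneric("roiMask", function(object) standardGeneric("roiMask"))
#' @rdname accessors
#' @export
setGeneric("nucleiCount", function(object) standardGeneric("nucleiCount"))
#' @rdname accessors
#' @export
setGeneric("meanNucleusArea",
  function(object) standardGeneric("meanNucleusArea"))
#' @rdname accessors
#' @export
setGeneric("meanZoneArea", function(object) standardGeneric("meanZoneArea"))
#' @rdname accessors
#' @export
setGeneric("meanEdgeLength",
  function(object) standardGeneric("meanEdgeLength"))
#' @rdname accessors
#' @export
setGeneric("scoreValue", function(object) standardGeneric("scoreValue"))
#' @rdname accessors
#' @export
setGeneric("gradeLabel", function(object) standardGeneric("gradeLabel"))
#' @rdname accessors
#' @export
setGeneric("featureTable", function(object) standardGeneric("featureTable"))

#' @rdname accessors
setMethod("greyValues", "EpitheliumImage", function(object) object@grey)
#' @rdname accessors
setMethod("roiMask", "EpitheliumImage", function(object) object@roi)
#' @rdname accessors
setMethod("nucleiCount", "NucleiLabelMap", function(object) object@count)
#' @rdname accessors
setMethod("meanNucleusArea", "NucleiLabelMap",
  function(object) object@meanArea)
#' @rdname accessors
setMethod("meanZoneArea", "InfluenceMap", function(object) object@meanZoneArea)
#' @rdname accessors
setMethod("meanEdgeLength", "Triangulation",
  function(object) object@meanEdgeLength)
#' @rdname accessors
setMethod("scoreValue", "CervicalResult", function(object) object@score)
#' @rdname accessors
setMethod("gradeLabel", "CervicalResult", function(object) object@grade)

#' @rdname accessors
setMethod("featureTable", "CervicalResult", function(object) {
  f <- object@features
  r <- object@ratios
  data.frame(
    A = f@A, N = f@N, V = f@V, D = f@D, Hst = f@Hst, HstU = f@HstU,
    k = f@k, A_um2 = f@A * f@pixelArea, N_um2 = f@N * f@pixelArea,
    ncRatio = r@ncRatio, diffRatio = r@diffRatio, histRatio = r@histRatio,
    score = object@score, grade = object@grade,
    stringsAsFactors = FALSE)
})

setMethod("show", "EpitheliumImage", function(object) {
  cat(sprintf("EpitheliumImage: %d x %d px, ROI %d px (%.1f%%), %.3f um^2/px\n",
    nrow(object@grey), ncol(object@grey), sum(object@roi),
    100 * mean(object@roi), object@pixelArea))
})

setMethod("show", "GroupPreset", function(object) {
  cat(sprintf(paste0("GroupPreset %s: N = %.1f px^2 (sd %.1f), V = %.1f px^2,",
      " D/A = %.3f\n  darkness basal/upper = %.0f/%.0f, background = %.0f\n"),
    object@label, object@meanNucleusArea, object@sdNucleusArea,
    object@meanZoneArea, object@differentiationFraction,
    object@nucleusDarkness, object@upperNucleusDarkness,
    object@backgroundGrey))
})

setMethod("show", "NucleiLabelMap", function(object) {
  cat(sprintf("NucleiLabelMap: %d nuclei, mean area %.1f px^2\n",
    object@count, object@meanArea))
})

setMethod("show", "InfluenceMap", function(object) {
  cat(sprintf("InfluenceMap: %d zones, mean zone area %.1f px^2\n",
    max(object@zones), object@meanZoneArea))
})

setMethod("show", "Triangulation", function(object) {
  cat(sprintf("Triangulation: %d points, %d edges, mean edge %.2f px%s\n",
    nrow(object@points), nrow(object@edges), object@meanEdgeLength,
    if (object@degenerate) " (degenerate: collinear chain)" else ""))
})

setMethod("show", "DifferentiationResult", function(object) {
  cat(sprintf(
    "DifferentiationResult: k = %d, r = %d, D = %d px^2 (closing %d px^2)\n",
    as.integer(object@coefficientK), as.integer(object@meanRadius),
    as.integer(object@D), as.integer(object@closingArea)))
})

setMethod("show", "CervicalResult", function(object) {
  cat("CervicalResult\n")
  cat(sprintf("  score = %.1f, grade = %s\n", object@score, object@grade))
  cat(sprintf("  N/V = %.4f, DR = %.4f, HstR = %.4f\n",
    object@ratios@ncRatio, object@ratios@diffRatio, object@ratios@histRatio))
})

setMethod("show", "ScoreCalibration", function(object) {
  cat("ScoreCalibration: score = ",
    sprintf("%.2f*ncRatio + %.2f*diffRatio + %.2f*(1 - histRatio) + %.2f\n",
      object@weights[1], object@weights[2], object@weights[3],
      object@offset))
  ref <- cbind(object@reference, target = object@targets)
  rownames(ref) <- object@grades
  print(round(ref, 4))
})
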