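# Discriminant ratios, score calibration, the cervical score, grade
# assignment and the between-group Welch tests.

#' Compute the three discriminant ratios
#'
#' From the six measured parameters: the nucleo-cytoplasmic ratio N/V, the
#' epithelial differentiation ratio DR = D/A, and the upper nuclei
#' histogram ratio HstR = HstU/Hst (defined as 0 when Hst = 0).
#'
#' @param features a [FeatureVector-class].
#' @return a [RatioSet-class].
#' @export
computeRatios <- function(features) {
  stopifnot(is(features, "FeatureVector"))
  if (!is.finite(features@A) || features@A <= 0)
    stop("epithelium area A must be positive")
  if (!is.finite(features@V) || features@V <= 0)
    stop("cytoplasm area V must be positive")
  if (is.finite(features@N) && is.finite(features@V) &&
      features@N > features@V)
    warning("N exceeds V: nucleus larger than its zone of influence")
  hr <- if (is.finite(features@Hst) && features@Hst > 0)
    features@HstU / features@Hst else 0
  new("RatioSet",
    ncRatio = features@N / features@V,
    diffRatio = features@D / features@A,
    histRatio = hr)
}

#' Fit the score calibration
#'
#' Least-squares affine fit of `score = w1*nc + w2*dr + w3*(1 - hstR) + b`
#' on reference group-mean ratio triples against target scores. With four
#' reference groups and four parameters the fit is exact, so the reference
#' triples map exactly onto their targets (in particular the high-grade
#' reference maps to 100).
#'
#' @param reference 4 x 3 matrix of group-mean ratios, columns
#'   (ncRatio, diffRatio, histRatio).
#' @param targets numeric target scores, one per reference group.
#' @param grades optional group labels (default NORMAL..CIN3).
#' @return a [ScoreCalibration-class].
#' @export
fitCalibration <- function(reference, targets,
                           grades = c("NORMAL", "CIN1", "CIN2", "CIN3")) {
  reference <- as.matrix(reference)
  if (nrow(reference) != length(targets))
    stop("one target score per reference row is required")
  X <- cbind(reference[, 1], reference[, 2], 1 - reference[, 3], 1)
  qx <- qr(X)
  if (qx$rank < 4)
    stop("rank-deficient reference set: calibration is not identifiable")
  w <- qr.coef(qx, targets)
  colnames(reference) <- c("ncRatio", "diffRatio", "histRatio")
  new("ScoreCalibration",
    weights = c(nc = w[[1]], dr = w[[2]], hst = w[[3]]), offset = w[[4]],
    reference = reference, targets = as.numeric(targets),
    grades = as.character(grades))
}

#' The shipped default calibration
#'
#' The affine calibration fitted on the reference group-mean ratios
#' (see [cinReferenceTable()]) against the reference scores 27 (NORMAL),
#' 51 (CIN1), 78 (CIN2) and 100 (CIN3).
#'
#' @return a [ScoreCalibration-class].
#' @export
defaultCalibration <- function() {
  ref <- .cinReference
  fitCalibration(
    cbind(ref$ncRatio, ref$diffRatio, ref$histRatio),
    targets = c(27, 51, 78, 100), grades = ref$group)
}

#' Evaluate the cervical score
#'
#' Affine evaluation of the calibration on a ratio triple, clipped to
#' \[0, 120\]. Higher scores mean higher grade.
#'
#' @param ratios a [RatioSet-class].
#' @param calibration a [ScoreCalibration-class].
#' @return the score (scalar).
#' @export
cervicalScore <- function(ratios, calibration = defaultCalibration()) {
  stopifnot(is(ratios, "RatioSet"), is(calibration, "ScoreCalibration"))
  w <- calibration@weights
  s <- w[[1]] * ratios@ncRatio + w[[2]] * ratios@diffRatio +
    w[[3]] * (1 - ratios@histRatio) + calibration@offset
  min(120, max(0, s))
}

#' Assign a grade from a score
#'
#' Nearest calibrated reference score wins; ties go to the higher grade
#' (the clinically conservative choice).
#'
#' @param score finite score value.
#' @param calibration a [ScoreCalibration-class].
#' @return grade label (character).
#' @examples
#' classifyScore(10)   # "NORMAL"
#' classifyScore(39)   # midpoint of 27 and 51, tie goes up: "CIN1"
#' @export
classifyScore <- function(score, calibration = defaultCalibration()) {
  stopifnot(is.finite(score))
  d <- abs(score - calibration@targets)
  calibration@grades[max(which(d == min(d)))]
}

#' Welch two-sample t-test p-value
#'
#' Two-sided Welch t-test (Welch-Satterthwaite degrees of freedom), applied
#' unconditionally. Degenerate inputs with zero variance in both groups
#' give p = 1 for equal means and p = 0 otherwise.
#'
#' @param a,b numeric vectors of length >= 2.
#' @return the p-value.
#' @export
welchTest <- function(a, b) {
  if (length(a) < 2 || length(b) < 2)
    stop("both groups need at least two observations")
  if (var(a) == 0 && var(b) == 0)
    return(if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0)
  t.test(a, b, var.equal = FALSE)$p.value
}
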