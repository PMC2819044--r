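# End-to-end pipeline: segmentation -> influence zones -> triangulation ->
# differentiation -> chromaticism -> ratios, score, grade; and group-wise
# batch analysis with successive Welch tests.

#' Run the full analysis pipeline on one image
#'
#' Executes the whole chain on an epithelium image: contrast normalisation,
#' Otsu thresholding, mask cleaning, suppression of edge-cutting nuclei,
#' Voronoi zones of influence, geodesic centers, Delaunay triangulation,
#' dilation/erosion differentiation measurement, chromaticism, and finally
#' the three ratios, the calibrated score and a grade. Deterministic for
#' fixed inputs and configuration.
#'
#' @param image an [EpitheliumImage-class] or a path to an image file
#'   (see [readEpitheliumImage()]).
#' @param roi optional ROI: a logical matrix or a path to a mask image;
#'   ignored when `image` is already an [EpitheliumImage-class].
#' @param config a [PipelineConfig-class], see [cinConfig()].
#' @param calibration a [ScoreCalibration-class].
#' @return a [CervicalResult-class]; when no nuclei survive segmentation
#'   the features are `NA`-valued (except A) and no grade is assigned.
#' @examples
#' g <- generateEpithelium(makePreset("CIN3"), seed = 1, width = 304,
#'                         height = 236)
#' runPipeline(g$image)
#' @export
runPipeline <- function(image, roi = NULL, config = cinConfig(),
                        calibration = defaultCalibration()) {
  if (is.character(image))
    image <- readEpitheliumImage(image, roiPath = roi,
      pixelArea = config@pixelArea, flipVertical = config@flipVertical)
  stopifnot(is(image, "EpitheliumImage"))

  seg <- segmentNuclei(image, threshold = config@threshold,
                       minArea = config@minArea)
  nuclei <- seg$nuclei
  pre <- seg$preprocessed
  A <- sum(image@roi)

  if (nuclei@count == 0) {
    f <- new("FeatureVector", A = A, N = NA_real_, V = NA_real_,
      D = NA_real_, Hst = NA_real_, HstU = NA_real_, k = NA_real_,
      pixelArea = image@pixelArea)
    return(new("CervicalResult", features = f,
      ratios = new("RatioSet", ncRatio = NA_real_, diffRatio = NA_real_,
                   histRatio = NA_real_),
      score = NA_real_, grade = NA_character_))
  }

  zones <- influenceZones(nuclei, image@roi)
  centers <- geodesicCenters(zones)
  tri <- delaunayTriangulation(centers, roi = image@roi,
                               edgeMode = config@edgeMode)
  r <- nuclearRadius(nuclei@meanArea)
  k <- if (is.finite(config@coefficientK)) config@coefficientK
       else if (is.finite(tri@meanEdgeLength))
         dilationCoefficient(tri@meanEdgeLength, r)
       else 0
  diffRes <- measureDifferentiation(nuclei, k, image@roi,
                                    basalBand = config@basalBand)
  chrom <- measureChromatics(pre, nuclei, diffRes)

  features <- new("FeatureVector", A = A, N = nuclei@meanArea,
    V = zones@meanZoneArea, D = diffRes@D, Hst = chrom@Hst,
    HstU = chrom@HstU, k = k, pixelArea = image@pixelArea)
  ratios <- computeRatios(features)
  score <- cervicalScore(ratios, calibration)
  new("CervicalResult", features = features, ratios = ratios,
      score = score, grade = classifyScore(score, calibration))
}

#' Generate a seeded synthetic batch
#'
#' One sub-list per image with elements `image`, `truth`, `group`, `seed`.
#' Every group uses the same seed sequence `(seed - 1) * n + 1..n`, so
#' `seed = 1` gives images seeded 1..n per group.
#'
#' @param groups diagnostic group labels.
#' @param n images per group.
#' @param seed batch seed.
#' @param width,height image size in pixels.
#' @return list of per-image sub-lists.
#' @export
generateBatch <- function(groups = c("NORMAL", "CIN1", "CIN2", "CIN3"),
                          n = 10, seed = 1, width = 608, height = 472) {
  seeds <- (seed - 1) * n + seq_len(n)
  out <- list()
  for (g in groups) {
    preset <- makePreset(g)
    for (s in seeds) {
      gen <- generateEpithelium(preset, seed = s, width = width,
                                height = height)
      out[[length(out) + 1]] <- list(image = gen$image, truth = gen$truth,
                                     group = g, seed = s)
    }
  }
  out
}

#' Run the pipeline over a batch of images
#'
#' Accepts either the output of [generateBatch()] or a manifest
#' `data.frame` with columns `image`, `roi` (optional paths) and `group`.
#' Produces the per-image feature table, a group-wise mean/SD summary and
#' Welch t-tests between successive groups (in the order the groups first
#' appear). Missing manifest files are skipped with a warning; groups are
#' excluded from the tests when they hold fewer than two images.
#'
#' @param batch list of `list(image=, group=)` entries or a manifest
#'   `data.frame`.
#' @param config a [PipelineConfig-class].
#' @param calibration a [ScoreCalibration-class].
#' @return list with `perImage`, `groupSummary` and `welch` data frames.
#' @export
runBatch <- function(batch, config = cinConfig(),
                     calibration = defaultCalibration()) {
  if (is.data.frame(batch)) {
    entries <- list()
    for (i in seq_len(nrow(batch))) {
      if (!file.exists(batch$image[i])) {
        warning("skipping missing image file: ", batch$image[i])
        next
      }
      roi <- if ("roi" %in% names(batch) && nzchar(batch$roi[i]) &&
                 !is.na(batch$roi[i])) batch$roi[i] else NULL
      img <- readEpitheliumImage(batch$image[i], roiPath = roi,
        pixelArea = config@pixelArea, flipVertical = config@flipVertical)
      entries[[length(entries) + 1]] <-
        list(image = img, group = as.character(batch$group[i]),
             seed = NA_integer_)
    }
  } else entries <- batch

  rows <- lapply(seq_along(entries), function(i) {
    e <- entries[[i]]
    res <- runPipeline(e$image, config = config, calibration = calibration)
    cbind(data.frame(id = i, group = e$group,
                     seed = if (!is.null(e$seed)) e$seed else NA_integer_),
          featureTable(res))
  })
  perImage <- do.call(rbind, rows)
  perImage <- perImage[order(match(perImage$group, unique(perImage$group)),
                             perImage$id), ]

  params <- c("A", "N", "V", "D", "Hst", "HstU", "ncRatio", "diffRatio",
              "histRatio", "score")
  groups <- unique(perImage$group)
  groupSummary <- do.call(rbind, lapply(groups, function(g) {
    sub <- perImage[perImage$group == g, params, drop = FALSE]
    data.frame(group = g, n = nrow(sub),
      as.list(setNames(colMeans(sub, na.rm = TRUE), paste0(params, "_mean"))),
      as.list(setNames(apply(sub, 2, sd, na.rm = TRUE),
                       paste0(params, "_sd"))))
  }))

  welch <- NULL
  if (length(groups) >= 2) {
    pairs <- cbind(groups[-length(groups)], groups[-1])
    welch <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
      a <- perImage[perImage$group == pairs[i, 1], , drop = FALSE]
      b <- perImage[perImage$group == pairs[i, 2], , drop = FALSE]
      if (nrow(a) < 2 || nrow(b) < 2) return(NULL)
      p <- vapply(params, function(pp) welchTest(a[[pp]], b[[pp]]),
                  numeric(1))
      data.frame(group1 = pairs[i, 1], group2 = pairs[i, 2],
                 as.list(setNames(p, paste0("p_", params))))
    }))
  }
  list(perImage = perImage, groupSummary = groupSummary, welch = welch)
}
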