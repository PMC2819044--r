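# Synthetic epithelium generator: renders seeded images with known ground
# truth that match the group statistics of the four diagnostic groups --
# a dense basal (differentiated) band of dark elliptical nuclei occupying
# the lower differentiation fraction of the ROI, sparse lighter nuclei
# above, mild Gaussian grey noise. Basal lamina is at the image bottom.

# run expr with a private RNG stream seeded by `seed`
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Mitchell best-candidate (farthest-point) sampling: n points in the
# rectangle rlim x clim, each new point the candidate farthest from the
# existing set. Approximates a blue-noise layout at the target density.
.bestCandidate <- function(n, rlim, clim, ncand = 30) {
  pts <- matrix(0, n, 2)
  if (n < 1) return(pts[0, , drop = FALSE])
  pts[1, ] <- c(runif(1, rlim[1], rlim[2]), runif(1, clim[1], clim[2]))
  if (n >= 2) for (i in 2:n) {
    cr <- runif(ncand, rlim[1], rlim[2])
    cc <- runif(ncand, clim[1], clim[2])
    prev <- pts[seq_len(i - 1), , drop = FALSE]
    d2 <- outer(cr, prev[, 1], "-")^2 + outer(cc, prev[, 2], "-")^2
    j <- which.max(apply(d2, 1, min))
    pts[i, ] <- c(cr[j], cc[j])
  }
  pts
}

# pixel set (row, col matrix) of an ellipse of given area, axis ratio q and
# orientation, centred at (cy, cx)
.ellipsePixels <- function(cy, cx, area, q, theta, scale = 1) {
  a <- sqrt(area * scale / (pi * q))
  b <- q * a
  ext <- ceiling(a)
  rs <- (round(cy) - ext):(round(cy) + ext)
  cs <- (round(cx) - ext):(round(cx) + ext)
  dr <- rs - cy
  dc <- cs - cx
  # rotated normalized coordinates
  u <- outer(dr, dc * 0, "+") * cos(theta) + outer(dr * 0, dc, "+") * sin(theta)
  v <- -outer(dr, dc * 0, "+") * sin(theta) + outer(dr * 0, dc, "+") * cos(theta)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  w <- which(inside, arr.ind = TRUE)
  cbind(rs[w[, 1]], cs[w[, 2]])
}

# truncated normal area draws (+/- 2 sd, floored)
.drawAreas <- function(n, mean, sd) {
  if (n < 1) return(numeric(0))
  u <- runif(n, stats::pnorm(-2), stats::pnorm(2))
  pmax(20, mean + sd * stats::qnorm(u))
}

#' Generate a synthetic epithelium image with ground truth
#'
#' Renders a seeded synthetic epithelium micrograph for a diagnostic-group
#' preset: a rectangular ROI with the basal lamina at the image bottom, a
#' dense band of dark elliptical nuclei filling the lower
#' `differentiationFraction` of the ROI height, sparse lighter nuclei in the
#' upper band, and mild additive Gaussian noise. Nuclei never overlap (a
#' colliding nucleus is shrunk slightly or dropped) and never touch each
#' other even diagonally, so segmentation at the preset densities is exact
#' up to thresholding. Identical `(preset, seed, width, height)` reproduce
#' the identical raster bit for bit.
#'
#' @param preset a [GroupPreset-class], see [makePreset()].
#' @param seed integer seed for the private RNG stream.
#' @param width,height image size in pixels (default: the 608 x 472 frame
#'   of the reference acquisition geometry).
#' @return a list with `image` (an [EpitheliumImage-class]) and `truth`
#'   (a [GroundTruth-class]).
#' @examples
#' g <- generateEpithelium(makePreset("CIN3"), seed = 7, width = 304,
#'                         height = 236)
#' g$image
#' @export
generateEpithelium <- function(preset, seed, width = 608, height = 472) {
  stopifnot(is(preset, "GroupPreset"))
  if (preset@meanZoneArea <= 0) stop("degenerate preset: zero zone area")
  margin <- 10
  if (width <= 4 * margin || height <= 4 * margin)
    stop("geometry too small: image must exceed ", 4 * margin, " px per side")
  rTop <- margin + 1; rBot <- height - margin
  cLeft <- margin + 1; cRight <- width - margin
  roiH <- rBot - rTop + 1; roiW <- cRight - cLeft + 1
  A <- roiH * roiW
  f <- preset@differentiationFraction
  bandH <- max(1, round(f * roiH))
  bandTop <- rBot - bandH + 1
  bandArea <- bandH * roiW
  upperArea <- A - bandArea

  nTotal <- round(A / preset@meanZoneArea)
  if (nTotal < 30)
    stop("geometry too small to hold 30 nuclei at zone area ",
         round(preset@meanZoneArea), "; enlarge the image")
  nU <- min(nTotal - 1L, round(upperArea / preset@upperZoneArea))
  nU <- max(0L, as.integer(nU))
  nD <- as.integer(nTotal - nU)
  if (nD * preset@meanNucleusArea > 0.85 * bandArea)
    stop("geometry too small: basal band cannot hold ", nD,
         " non-overlapping nuclei")

  rmax <- sqrt((preset@meanNucleusArea + 2 * preset@sdNucleusArea) / pi)
  inset <- ceiling(rmax) + 1

  .withSeed(seed, {
    # basal band placement (dense)
    pD <- .bestCandidate(nD,
      rlim = c(bandTop + 1, rBot - inset),
      clim = c(cLeft + inset, cRight - inset), ncand = 60)
    # upper band placement (sparse), stood off from the band boundary so the
    # closing does not bridge upper nuclei to the basal slab
    standoff <- min(sqrt(preset@upperZoneArea),
                    0.4 * max(1, roiH - bandH))
    upTop <- rTop + inset
    upBot <- bandTop - standoff
    if (upBot - upTop < 2) upBot <- min(bandTop - 4, upTop + 2)
    pU <- if (nU > 0 && upBot > upTop)
      .bestCandidate(nU, rlim = c(upTop, upBot),
        clim = c(cLeft + inset, cRight - inset), ncand = 15)
    else matrix(0, 0, 2)
    nU <- nrow(pU)

    centers <- rbind(pD, pU)
    compartment <- rep(c("basal", "upper"), c(nD, nU))
    n <- nrow(centers)
    areas <- .drawAreas(n, preset@meanNucleusArea, preset@sdNucleusArea)
    # assign the larger basal areas to the roomier basal spots so that tight
    # pairs rarely force a shrink
    if (nD >= 3) {
      d <- as.matrix(stats::dist(pD)); diag(d) <- Inf
      clearance <- apply(d, 1, min)
      iD <- seq_len(nD)
      areas[iD][order(clearance)] <- sort(areas[iD])
    }
    qs <- runif(n, 0.7, 1)
    thetas <- runif(n, 0, pi)

    roi <- matrix(FALSE, height, width)
    roi[rTop:rBot, cLeft:cRight] <- TRUE
    nucGrey <- matrix(NA_real_, height, width)
    forbidden <- matrix(FALSE, height, width)
    keep <- logical(n)
    realArea <- numeric(n)
    darkness <- ifelse(compartment == "basal",
      preset@nucleusDarkness, preset@upperNucleusDarkness)
    for (i in seq_len(n)) {
      scale <- 1
      px <- NULL
      for (try in 1:10) {
        cand <- .ellipsePixels(centers[i, 1], centers[i, 2], areas[i],
                               qs[i], thetas[i], scale)
        cand <- cand[roi[cand], , drop = FALSE]
        if (nrow(cand) > 0 && !any(forbidden[cand])) { px <- cand; break }
        scale <- scale * 0.93
      }
      if (is.null(px)) next
      keep[i] <- TRUE
      realArea[i] <- nrow(px)
      nucGrey[px] <- 255 - darkness[i]
      # block the pixels and their 8-neighbourhood for later nuclei
      for (dr in -1:1) for (dc in -1:1)
        forbidden[cbind(px[, 1] + dr, px[, 2] + dc)] <- TRUE
    }

    grey <- matrix(preset@backgroundGrey, height, width)
    sel <- !is.na(nucGrey)
    grey[sel] <- nucGrey[sel]
    grey <- grey + rnorm(length(grey), 0, .genNoiseSd)
    grey <- matrix(pmin(255, pmax(0, round(grey))), height, width)

    diffMask <- roi
    diffMask[seq_len(bandTop - 1), ] <- FALSE

    img <- new("EpitheliumImage", grey = grey, roi = roi,
               pixelArea = defaultPixelArea())
    truth <- new("GroundTruth",
      centers = centers[keep, , drop = FALSE], areas = realArea[keep],
      roiArea = A, differentiatedMask = diffMask,
      compartment = compartment[keep])
    list(image = img, truth = truth)
  })
}

#' The three-disc worked-example scene
#'
#' A binary-valued image holding exactly three collinear discs of 197 px
#' area each (the discrete disc of radius 8), the middle disc separated
#' from its neighbours by border-to-border gaps of 32 and 60 px. The ROI
#' covers the whole frame. This is the textbook scene for the
#' dilation/erosion coefficient: closing with k = 16 merges the near pair,
#' closing with k = 30 merges all three.
#'
#' @return an [EpitheliumImage-class] (nuclei at grey 0, background 255).
#' @seealso [dilationCoefficient()], [morphologicalClosing()]
#' @export
fig2Scene <- function() {
  height <- 150; width <- 300
  grey <- matrix(255, height, width)
  disc <- which(outer((-8:8)^2, (-8:8)^2, "+") <= 64, arr.ind = TRUE)
  for (cx in c(60, 108, 184)) {
    grey[cbind(disc[, 1] + 75 - 9, disc[, 2] + cx - 9)] <- 0
  }
  new("EpitheliumImage", grey = grey,
      roi = matrix(TRUE, height, width), pixelArea = defaultPixelArea())
}
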