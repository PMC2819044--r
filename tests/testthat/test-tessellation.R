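# Influence zones, geodesic centers and the Delaunay triangulation.

test_that("a single nucleus owns the whole ROI", {
  lab <- matrix(0L, 20, 30); lab[10, 15] <- 1L
  roi <- matrix(TRUE, 20, 30)
  z <- influenceZones(asNuclei(lab > 0), roi)
  expect_true(all(z@zones == 1))
  expect_equal(meanZoneArea(z), 600)
})

test_that("mirror-symmetric nuclei split the ROI into equal zones", {
  lab <- matrix(0L, 21, 40)
  lab[11, 10] <- 1L; lab[11, 31] <- 2L
  z <- influenceZones(asNuclei(lab > 0), matrix(TRUE, 21, 40))
  expect_equal(sum(z@zones == 1), sum(z@zones == 2))
})

test_that("zones partition the ROI and match the exhaustive oracle", {
  set.seed(42)
  for (rep in 1:3) {
    h <- sample(40:90, 1); w <- sample(40:90, 1)
    n <- sample(5:25, 1)
    pts <- unique(cbind(sample(2:(h - 1), n, TRUE),
                        sample(2:(w - 1), n, TRUE)), MARGIN = 1)
    lab <- matrix(0L, h, w)
    lab[pts] <- seq_len(nrow(pts))
    roi <- matrix(TRUE, h, w)
    nuc <- new("NucleiLabelMap", labels = lab,
               count = nrow(pts), meanArea = 1)
    z <- influenceZones(nuc, roi)
    # partition conservation: every ROI pixel carries exactly one label
    expect_true(all(z@zones[roi] >= 1))
    expect_equal(sum(tabulate(z@zones[roi])), sum(roi))
    # equality with the brute-force nearest-nucleus search
    expect_identical(z@zones, bruteVoronoi(lab, roi))
  }
})

test_that("zones contain their own nucleus and zero nuclei are rejected", {
  g <- generateEpithelium(makePreset("CIN2"), seed = 1, width = 304,
                          height = 236)
  seg <- segmentNuclei(g$image)
  z <- influenceZones(seg$nuclei, roiMask(g$image))
  lab <- seg$nuclei@labels
  sel <- lab > 0
  expect_true(all(z@zones[sel] == lab[sel]))
  empty <- new("NucleiLabelMap", labels = matrix(0L, 5, 5), count = 0L,
               meanArea = NA_real_)
  expect_error(influenceZones(empty, matrix(TRUE, 5, 5)), "at least one")
})

test_that("geodesic centers minimise the within-zone eccentricity", {
  # symmetric rectangle: the exact middle
  z <- matrix(1L, 11, 21)
  expect_equal(as.vector(geodesicCenters(z)), c(6, 11))
  # single-pixel zone: itself
  z1 <- matrix(0L, 5, 5); z1[3, 4] <- 1L
  expect_equal(as.vector(geodesicCenters(z1)), c(3, 4))
  # L-shaped zone: center lies inside the L and matches the exhaustive
  # oracle (the Euclidean centroid would fall outside the region)
  L <- matrix(FALSE, 30, 30)
  L[5:25, 5:10] <- TRUE; L[20:25, 5:25] <- TRUE
  zl <- matrix(0L, 30, 30); zl[L] <- 1L
  ctr <- geodesicCenters(zl)
  expect_true(L[ctr[1, 1], ctr[1, 2]])
  expect_equal(as.vector(ctr), as.vector(bruteGeodesicCenter(L)))
  centroid <- round(colMeans(which(L, arr.ind = TRUE)))
  expect_false(L[centroid[1], centroid[2]])
})

test_that("geodesic centers match the oracle on random blobby zones", {
  set.seed(7)
  for (rep in 1:4) {
    m <- matrix(runif(35 * 35) < 0.55, 35, 35)
    lab <- labelComponents(m)
    big <- which.max(tabulate(lab))
    z <- matrix(0L, 35, 35); z[lab == big] <- 1L
    expect_equal(as.vector(geodesicCenters(z)),
                 as.vector(bruteGeodesicCenter(z == 1L)))
  }
})

test_that("the Delaunay triangulation reproduces hand geometry", {
  # right triangle with legs 30 and 40: edges 30, 40, 50, mean 40
  tri <- delaunayTriangulation(rbind(c(1, 1), c(1, 31), c(41, 1)))
  expect_equal(nrow(tri@edges), 3)
  expect_equal(meanEdgeLength(tri), 40)
  # two points 32 px apart: a single edge
  t2 <- delaunayTriangulation(rbind(c(1, 1), c(1, 33)))
  expect_equal(nrow(t2@edges), 1)
  expect_equal(meanEdgeLength(t2), 32)
  # collinear points: flagged chain
  expect_warning(
    t3 <- delaunayTriangulation(rbind(c(1, 1), c(1, 11), c(1, 21))),
    "collinear")
  expect_true(t3@degenerate)
  expect_equal(nrow(t3@edges), 2)
  expect_equal(meanEdgeLength(t3), 10)
})

test_that("triangulations satisfy the empty-circumcircle property", {
  set.seed(3)
  for (rep in 1:4) {
    n <- sample(10:30, 1)
    pts <- cbind(runif(n, 1, 100), runif(n, 1, 100))
    tris <- cervimorph:::.bowyerWatson(pts)
    expect_gt(nrow(tris), 0)
    expect_false(circumcircleViolated(pts, tris))
  }
  # integer grid coordinates (heavily cocircular) still triangulate
  gpts <- as.matrix(expand.grid(seq(1, 41, by = 10), seq(1, 41, by = 10)))
  trg <- delaunayTriangulation(gpts)
  expect_true(all(tabulate(trg@edges, nrow(gpts)) > 0))
})

test_that("mean edge length is translation and rotation invariant", {
  set.seed(13)
  pts <- cbind(runif(15, 1, 60), runif(15, 1, 60))
  base <- meanEdgeLength(delaunayTriangulation(pts))
  shifted <- meanEdgeLength(delaunayTriangulation(pts + 37))
  rotated <- meanEdgeLength(delaunayTriangulation(
    cbind(pts[, 2], 100 - pts[, 1])))  # 90 degree rotation
  expect_equal(shifted, base, tolerance = 1e-9)
  expect_equal(rotated, base, tolerance = 1e-9)
})

test_that("edges crossing outside a U-shaped ROI are pruned", {
  roi <- matrix(FALSE, 40, 60)
  roi[5:35, 5:15] <- TRUE    # left arm
  roi[5:35, 45:55] <- TRUE   # right arm
  roi[30:35, 5:55] <- TRUE   # bottom bridge
  pts <- rbind(c(8, 10), c(20, 10), c(8, 50), c(20, 50), c(33, 30))
  tri <- delaunayTriangulation(pts, roi = roi)
  crossing <- apply(tri@edges, 1, function(e) {
    arms <- c(pts[e[1], 2] < 30, pts[e[2], 2] < 30)
    rows <- c(pts[e[1], 1], pts[e[2], 1])
    xor(arms[1], arms[2]) && all(rows < 30)
  })
  expect_false(any(crossing))
  # the same points with a full-frame ROI do keep cross-gap edges
  triFull <- delaunayTriangulation(pts)
  expect_gt(nrow(triFull@edges), nrow(tri@edges))
})

test_that("mean zone area recovers ROI area / nucleus count on presets", {
  g <- generateEpithelium(makePreset("CIN1"), seed = 6, width = 304,
                          height = 236)
  seg <- segmentNuclei(g$image)
  z <- influenceZones(seg$nuclei, roiMask(g$image))
  expect_equal(meanZoneArea(z),
               sum(roiMask(g$image)) / nrow(g$truth@centers),
               tolerance = 0.10)
})
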