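# Nuclear radius, dilation/erosion coefficient, constrained closing and
# the differentiated-epithelium measurement.

test_that("nuclear radius follows the equivalent-disc formula", {
  expect_equal(nuclearRadius(199), 8)
  expect_equal(nuclearRadius(pi), 1)
  expect_equal(nuclearRadius(314), 10)
  expect_equal(nuclearRadius(0.5), 1)  # floored at 1 px
  expect_error(nuclearRadius(0), "positive")
  expect_error(nuclearRadius(-3), "positive")
})

test_that("the coefficient divides the edge by a quarter of the radius", {
  expect_equal(dilationCoefficient(32, 8), 16)
  expect_equal(dilationCoefficient(60, 8), 30)
  expect_equal(dilationCoefficient(0, 5), 0)
  expect_equal(dilationCoefficient(10, 4), 10)
  expect_error(dilationCoefficient(10, 0), "at least 1")
})

test_that("closing the worked-example scene merges as the coefficients say", {
  sc <- fig2Scene()
  mask <- greyValues(sc) == 0
  expect_identical(morphologicalClosing(mask, 0, roiMask(sc)), mask)
  comps <- function(k) max(labelComponents(
    morphologicalClosing(mask, k, roiMask(sc))))
  expect_equal(comps(16), 2)   # the 32-px pair merges
  expect_equal(comps(15), 3)   # one less and nothing merges
  expect_equal(comps(31), 1)   # both gaps close
})

test_that("closing is extensive, idempotent and ROI-bounded", {
  set.seed(17)
  for (rep in 1:4) {
    roi <- matrix(FALSE, 35, 35)
    roi[sample(3:10, 1):sample(25:33, 1), sample(3:10, 1):sample(25:33, 1)] <- TRUE
    m <- randomMask(35, 35, 0.15) & roi
    for (k in c(1, 3, 6)) {
      cl <- morphologicalClosing(m, k, roi)
      expect_true(all(cl[m]))                       # extensivity
      expect_identical(morphologicalClosing(cl, k, roi), cl)  # idempotence
      expect_false(any(cl & !roi))                  # clipped to the ROI
    }
  }
})

test_that("the differentiated area is non-decreasing in k", {
  g <- generateEpithelium(makePreset("CIN1"), seed = 4, width = 304,
                          height = 236)
  seg <- segmentNuclei(g$image)
  roi <- roiMask(g$image)
  D <- vapply(c(0, 2, 5, 9, 14, 20), function(k)
    measureDifferentiation(seg$nuclei, k, roi)@D, numeric(1))
  expect_true(all(diff(D) >= 0))
})

test_that("the basal-anchored closing recovers a two-band layout", {
  # dense half-height grid of discs at the bottom, a few sparse discs above
  h <- 200; w <- 240
  dense <- as.matrix(expand.grid(seq(104, 192, by = 18),
                                 seq(12, 228, by = 18)))
  sparse <- rbind(c(30, 60), c(40, 170), c(20, 120))
  grey <- discImage(h, w, rbind(dense, sparse), radius = 6)
  img <- asImage(grey)
  nuc <- asNuclei(grey == 0)
  tri <- delaunayTriangulation(geodesicCenters(
    influenceZones(nuc, roiMask(img))), roi = roiMask(img))
  k <- dilationCoefficient(meanEdgeLength(tri),
                           nuclearRadius(meanNucleusArea(nuc)))
  res <- measureDifferentiation(nuc, k, roiMask(img))
  truthBand <- matrix(FALSE, h, w); truthBand[99:200, ] <- TRUE
  iou <- sum(res@differentiatedMask & truthBand) /
    sum(res@differentiatedMask | truthBand)
  expect_gt(iou, 0.8)
  # the sparse upper discs stay outside the differentiated compartment
  expect_false(any(res@differentiatedMask[sparse]))
  # masks partition the ROI
  expect_true(all(xor(res@differentiatedMask, res@upperMask)[roiMask(img)]))
  expect_equal(res@D, sum(res@differentiatedMask))
})

test_that("no nuclei gives D = 0 and upper = ROI; saturation gives D ~ A", {
  roi <- matrix(TRUE, 60, 60)
  empty <- asNuclei(matrix(FALSE, 60, 60))
  r0 <- measureDifferentiation(empty, 10, roi)
  expect_equal(r0@D, 0)
  expect_identical(r0@upperMask, roi)
  # nuclei everywhere with gaps < 2k: the closing floods the whole ROI
  pts <- as.matrix(expand.grid(seq(6, 54, by = 12), seq(6, 54, by = 12)))
  grey <- discImage(60, 60, pts, radius = 4)
  nuc <- asNuclei(grey == 0)
  rs <- measureDifferentiation(nuc, 10, roi)
  expect_equal(rs@D / sum(roi), 1, tolerance = 0.02)
})

test_that("measured D/A increases strictly from NORMAL to CIN3", {
  dr <- vapply(c("NORMAL", "CIN1", "CIN2", "CIN3"), function(grp) {
    g <- generateEpithelium(makePreset(grp), seed = 2)
    res <- runPipeline(g$image)
    featureTable(res)$diffRatio
  }, numeric(1))
  expect_true(all(diff(dr) > 0))
})
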