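# Contrast normalisation, thresholding, mask cleaning, border suppression
# and the basic area measurements.

test_that("preprocess maps the 1st/99th ROI percentiles to 0/255", {
  # percentiles already at (0, 255): unchanged
  g <- matrix(c(rep(0, 300), rep(255, 300)), 20, 30)
  img <- asImage(g)
  expect_identical(greyValues(preprocessImage(img)), g)
  # hand linear map: percentiles (50, 150), pixel 100 -> (100-50)/100*255
  v <- c(rep(50, 100), 100, rep(150, 100))
  img2 <- asImage(matrix(v, 1))
  out <- greyValues(preprocessImage(img2))[1, 101]
  expect_true(out %in% c(127, 128))
  expect_equal(greyValues(preprocessImage(img2))[1, 1], 0)
  expect_equal(greyValues(preprocessImage(img2))[1, 201], 255)
})

test_that("preprocess warns and returns a constant ROI unchanged", {
  img <- asImage(matrix(128, 10, 10))
  expect_warning(out <- preprocessImage(img), "constant")
  expect_identical(greyValues(out), greyValues(img))
})

test_that("preprocess is idempotent up to rounding", {
  set.seed(5)
  img <- asImage(matrix(round(runif(2000, 40, 220)), 40, 50))
  once <- preprocessImage(img)
  twice <- preprocessImage(once)
  expect_lt(max(abs(greyValues(twice) - greyValues(once))), 3)
})

test_that("preprocess leaves pixels outside the ROI untouched", {
  roi <- matrix(FALSE, 20, 20); roi[5:15, 5:15] <- TRUE
  g <- matrix(round(seq(30, 220, length.out = 400)), 20, 20)
  out <- preprocessImage(asImage(g, roi))
  expect_identical(greyValues(out)[!roi], g[!roi])
})

test_that("thresholding separates a two-level image and honours manual values", {
  g <- matrix(200, 30, 30); g[10:15, 10:15] <- 40
  img <- asImage(g)
  expect_identical(thresholdNuclei(img), g == 40)
  expect_false(any(thresholdNuclei(img, threshold = 0)))
  sc <- fig2Scene()
  expect_identical(thresholdNuclei(sc), greyValues(sc) == 0)
})

test_that("cleaning fills holes, removes specks, and is idempotent", {
  annulus <- matrix(FALSE, 15, 15)
  annulus[4:11, 4:11] <- TRUE; annulus[7:8, 7:8] <- FALSE
  filled <- cleanMask(annulus, minArea = 10)
  expect_true(all(filled[4:11, 4:11]))
  speck <- matrix(FALSE, 15, 15); speck[2, 2:3] <- TRUE
  expect_false(any(cleanMask(speck, minArea = 10)))
  expect_false(any(cleanMask(matrix(FALSE, 5, 5), 10)))
  # worked-example scene: three solid discs pass through unchanged
  scMask <- greyValues(fig2Scene()) == 0
  expect_identical(cleanMask(scMask, 30), scMask)
  set.seed(8)
  for (rep in 1:3) {
    m <- randomMask(40, 40, 0.4)
    once <- cleanMask(m, 12)
    expect_identical(cleanMask(once, 12), once)
  }
})

test_that("border suppression removes frame-cutting nuclei only", {
  interior <- matrix(FALSE, 40, 40); interior[15:20, 15:20] <- TRUE
  roi <- matrix(TRUE, 40, 40)
  nl <- suppressBorderNuclei(interior, roi)
  expect_equal(nucleiCount(nl), 1)
  clipped <- matrix(FALSE, 40, 40); clipped[1:5, 10:14] <- TRUE
  expect_warning(nl2 <- suppressBorderNuclei(clipped, roi), "no nuclei")
  expect_equal(nucleiCount(nl2), 0)
  expect_true(is.na(meanNucleusArea(nl2)))
  # worked-example discs sit interior: all three survive at ~199 px
  sc <- fig2Scene()
  nl3 <- suppressBorderNuclei(greyValues(sc) == 0, roiMask(sc))
  expect_equal(nucleiCount(nl3), 3)
  expect_lte(abs(meanNucleusArea(nl3) - 199), 2)
})

test_that("no labelled pixel ever touches the frame (random masks)", {
  set.seed(21)
  for (rep in 1:5) {
    m <- randomMask(30, 35, 0.35)
    nl <- suppressWarnings(suppressBorderNuclei(m, matrix(TRUE, 30, 35)))
    lab <- nl@labels
    expect_true(all(lab[1, ] == 0) && all(lab[30, ] == 0) &&
                all(lab[, 1] == 0) && all(lab[, 35] == 0))
    expect_true(all((lab > 0) <= m))
  }
})

test_that("a full 472 x 608 frame measures A = 286,976 px", {
  img <- asImage(matrix(200, 472, 608))
  nl <- asNuclei(matrix(FALSE, 472, 608))
  mb <- suppressWarnings(measureBasic(nl, img))
  expect_identical(mb$A, 286976L)
  expect_true(is.na(mb$N))
  expect_equal(mb$A_um2, 286976 * defaultPixelArea())
})

test_that("A is invariant under preprocessing and thresholding", {
  g <- generateEpithelium(makePreset("CIN1"), seed = 2, width = 304,
                          height = 236)
  A0 <- sum(roiMask(g$image))
  pre <- preprocessImage(g$image)
  expect_identical(sum(roiMask(pre)), A0)
  seg <- segmentNuclei(g$image)
  expect_identical(sum(roiMask(seg$preprocessed)), A0)
})
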