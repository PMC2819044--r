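# Ratios, calibration, score, grade assignment and the Welch test.

fv <- function(A, N, V, D, Hst, HstU)
  new("FeatureVector", A = A, N = N, V = V, D = D, Hst = Hst, HstU = HstU,
      k = 0, pixelArea = defaultPixelArea())

test_that("ratios are the three published quotients", {
  r <- computeRatios(fv(212018, 173.9, 1740.3, 30136.3, 19.1, 7.3))
  expect_equal(r@ncRatio, 173.9 / 1740.3, tolerance = 1e-12)
  expect_equal(round(r@ncRatio, 4), 0.0999)
  r3 <- computeRatios(fv(183499, 206.7, 442.3, 157383.9, 75.6, 3.5))
  expect_equal(round(r3@diffRatio, 3), 0.858)
  same <- computeRatios(fv(1000, 10, 100, 500, 40, 40))
  expect_equal(same@histRatio, 1)
  zero <- computeRatios(fv(1000, 10, 100, 500, 0, 0))
  expect_equal(zero@histRatio, 0)
  expect_error(computeRatios(fv(0, 10, 100, 0, 1, 1)), "A must be positive")
  expect_error(computeRatios(fv(10, 10, 0, 0, 1, 1)), "V must be positive")
  expect_warning(computeRatios(fv(1000, 200, 100, 10, 1, 1)), "N exceeds V")
})

test_that("the default calibration reproduces the reference scores exactly", {
  cal <- defaultCalibration()
  ref <- cinReferenceTable()
  for (i in 1:4) {
    r <- new("RatioSet", ncRatio = ref$ncRatio[i],
             diffRatio = ref$diffRatio[i], histRatio = ref$histRatio[i])
    s <- cervicalScore(r, cal)
    expect_equal(s, c(27, 51, 78, 100)[i], tolerance = 1e-6)
  }
  # four reference groups, four parameters: the high-grade residual is zero
  expect_lt(abs(cervicalScore(new("RatioSet",
    ncRatio = ref$ncRatio[4], diffRatio = ref$diffRatio[4],
    histRatio = ref$histRatio[4]), cal) - 100), 1)
})

test_that("degenerate calibrations behave as documented", {
  ref <- as.matrix(cinReferenceTable()[, c("ncRatio", "diffRatio",
                                           "histRatio")])
  flat <- fitCalibration(ref, targets = c(50, 50, 50, 50))
  expect_equal(unname(flat@weights), c(0, 0, 0), tolerance = 1e-8)
  expect_equal(flat@offset, 50, tolerance = 1e-8)
  bad <- ref; bad[, 2] <- 2 * bad[, 1]; bad[, 3] <- 1 - 3 * bad[, 1]
  expect_error(fitCalibration(bad, targets = c(1, 2, 3, 4)),
               "rank-deficient")
  expect_error(fitCalibration(ref, targets = c(1, 2)), "one target score")
})

test_that("scores clip to [0, 120] and zero calibration gives zero", {
  nil <- new("ScoreCalibration", weights = c(nc = 0, dr = 0, hst = 0),
    offset = 0, reference = matrix(0, 4, 3),
    targets = c(27, 51, 78, 100),
    grades = c("NORMAL", "CIN1", "CIN2", "CIN3"))
  z <- new("RatioSet", ncRatio = 0, diffRatio = 0, histRatio = 0)
  expect_equal(cervicalScore(z, nil), 0)
  big <- new("ScoreCalibration", weights = c(nc = 1000, dr = 0, hst = 0),
    offset = 0, reference = matrix(0, 4, 3),
    targets = c(27, 51, 78, 100),
    grades = c("NORMAL", "CIN1", "CIN2", "CIN3"))
  expect_equal(cervicalScore(new("RatioSet", ncRatio = 1, diffRatio = 0,
                                 histRatio = 0), big), 120)
})

test_that("grades go to the nearest reference score, ties upward", {
  expect_equal(classifyScore(100), "CIN3")
  expect_equal(classifyScore(10), "NORMAL")
  expect_equal(classifyScore(39), "CIN1")   # midpoint of 27 and 51
  expect_equal(classifyScore(64.5), "CIN2") # midpoint of 51 and 78
  cal <- defaultCalibration()
  ref <- cinReferenceTable()
  for (i in 1:4) {
    r <- new("RatioSet", ncRatio = ref$ncRatio[i],
             diffRatio = ref$diffRatio[i], histRatio = ref$histRatio[i])
    expect_equal(classifyScore(cervicalScore(r, cal), cal), ref$group[i])
  }
})

test_that("the Welch test matches the textbook formula and its edge cases", {
  expect_equal(welchTest(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_lt(welchTest(c(0, 0, 0, 0), c(10, 10, 10, 10.0001)), 0.001)
  expect_equal(welchTest(c(5, 5, 5), c(5, 5)), 1)
  expect_equal(welchTest(c(5, 5, 5), c(7, 7)), 0)
  # textbook Welch-Satterthwaite oracle on a random pair
  set.seed(31)
  a <- rnorm(12, 3, 2); b <- rnorm(9, 5, 4)
  tstat <- (mean(a) - mean(b)) / sqrt(var(a) / 12 + var(b) / 9)
  df <- (var(a) / 12 + var(b) / 9)^2 /
    ((var(a) / 12)^2 / 11 + (var(b) / 9)^2 / 8)
  expect_equal(welchTest(a, b), 2 * pt(-abs(tstat), df), tolerance = 1e-12)
  expect_error(welchTest(1, c(1, 2)), "at least two")
})

test_that("group D values drawn from the reference moments separate", {
  set.seed(123)
  dNormal <- rnorm(10, 30136.3, 4066.0)
  dCin1 <- rnorm(10, 75070.4, 10032.7)
  expect_lt(welchTest(dNormal, dCin1), 0.05)
})
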