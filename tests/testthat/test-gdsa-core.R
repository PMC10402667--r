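test_that("normalizeToPercent rescales to percent of the image maximum", {
  expect_equal(normalizeToPercent(matrix(c(1, 4, 2, 4), 2, 2)),
               matrix(c(25, 100, 50, 100), 2, 2))
  expect_equal(normalizeToPercent(matrix(3.7, 4, 4)), matrix(100, 4, 4))
  # the output maximum is exactly 100, not merely close
  set.seed(5)
  out <- normalizeToPercent(matrix(runif(64), 8, 8))
  expect_identical(max(out), 100)
  expect_error(normalizeToPercent(matrix(0, 3, 3)), "empty delivery")
})

test_that("gradientMap matches hand-derived closed forms", {
  pitch <- 0.336
  # constant field: all zero
  expect_equal(pixels(gradientMap(matrix(42, 5, 5), pitch)),
               matrix(0, 5, 5))
  # 1-D ramp of g percent per pixel: interior gradient g*sqrt(2)/pitch
  g <- 1.5
  ramp <- matrix(g * (1:7), 7, 7, byrow = TRUE)
  gm <- pixels(gradientMap(ramp, pitch))
  expect_equal(gm[2:6, 2:6], matrix(g * sqrt(2) / pitch, 5, 5))
  # edge pixels of the ramp have a single ramp-direction neighbour pair
  expect_equal(gm[1, 2:6], rep(g * sqrt(2) / pitch, 5))
  expect_equal(gm[2:6, 1], rep(g / pitch, 5))
  expect_error(gradientMap(matrix(1, 1, 5), pitch), "degenerate")
})

test_that("gradientMap equals the brute-force neighbour-loop oracle", {
  set.seed(101)
  for (trial in 1:10) {
    d <- matrix(runif(32 * 32, 0, 100), 32, 32)
    fast <- pixels(gradientMap(d, 0.336))
    slow <- bruteGradient(d, 0.336)
    expect_lt(max(abs(fast - slow)) / max(slow), 1e-12)
    fastMean <- pixels(gradientMap(d, 0.336, agg = "mean"))
    slowMean <- bruteGradient(d, 0.336, agg = "mean")
    expect_lt(max(abs(fastMean - slowMean)) / max(slowMean), 1e-12)
  }
})

test_that("gradientMap is shift-invariant and scales linearly with dose", {
  set.seed(17)
  d <- matrix(runif(100, 0, 50), 10, 10)
  g0 <- pixels(gradientMap(d, 0.336))
  expect_equal(pixels(gradientMap(d + 13.7, 0.336)), g0)
  expect_equal(pixels(gradientMap(3.2 * d, 0.336)), 3.2 * g0)
})

test_that("segmentRegions partitions pixels exactly at both thresholds", {
  # values straddling the 5% dose and 3 %/mm gradient thresholds,
  # including exact ties: dose >= 5 is high dose, gradient < 3 low gradient
  dose <- matrix(c(0, 4.999, 5, 5.001, 100), 5, 5)
  grad <- matrix(rep(c(0, 2.999, 3, 3.001, 40), each = 5), 5, 5)
  masks <- segmentRegions(dose, grad)
  want <- bruteClassify(dose, grad, 5, 3)
  expect_identical(regionMask(masks, "highDoseLowGradient"),
                   want == "HDLG")
  expect_identical(regionMask(masks, "highDoseHighGradient"),
                   want == "HDHG")
  expect_identical(regionMask(masks, "lowDoseLowGradient"),
                   want == "LDLG")
  expect_identical(regionMask(masks, "lowDoseHighGradient"),
                   want == "LDHG")
  expect_error(segmentRegions(dose, matrix(0, 2, 2)), "mismatched")
})

test_that("region masks partition any input (disjoint and exhaustive)", {
  set.seed(23)
  for (trial in 1:50) {
    n <- sample(4:16, 2)
    dose <- matrix(runif(prod(n), 0, 10), n[1L], n[2L])
    grad <- matrix(runif(prod(n), 0, 6), n[1L], n[2L])
    m <- segmentRegions(dose, grad)
    tot <- regionMask(m, "highDoseLowGradient") +
      regionMask(m, "highDoseHighGradient") +
      regionMask(m, "lowDoseLowGradient") +
      regionMask(m, "lowDoseHighGradient")
    expect_true(all(tot == 1L))
  }
})

test_that("doseDifferencePercent is signed and reference-normalized", {
  ref <- CompositeImage(matrix(c(1, 2, 2, 4), 2, 2), 0.336, 1L)
  expect_equal(doseDifferencePercent(ref, ref), matrix(0, 2, 2))
  cmp <- CompositeImage(matrix(c(1, 2, 2, 5), 2, 2), 0.336, 2L)
  expect_equal(doseDifferencePercent(ref, cmp),
               matrix(c(0, 0, 0, 25), 2, 2))
  # uniform 2% scaling: value at the reference maximum is exactly 2%
  scaled <- CompositeImage(1.02 * pixels(ref), 0.336, 2L)
  d <- doseDifferencePercent(ref, scaled)
  expect_equal(d[2, 2], 2)
  expect_equal(d, 2 * pixels(ref) / max(pixels(ref)))
  expect_error(doseDifferencePercent(ref, CompositeImage(matrix(1, 3, 3),
                                                         0.336, 2L)),
               "mismatched geometry")
  expect_error(doseDifferencePercent(matrix(0, 2, 2), matrix(1, 2, 2)),
               "empty delivery")
})

test_that("gdsaStatistic reproduces hand-computed ROI mean and sd", {
  # 6-pixel ROI holding {1,...,6}: mean 3.5, population sd sqrt(35/12)
  diffPct <- matrix(0, 5, 5)
  roi <- matrix(FALSE, 5, 5)
  roi[2:3, 2:4] <- TRUE
  diffPct[roi] <- 1:6
  dose <- matrix(0, 5, 5)
  dose[roi] <- 100
  masks <- segmentRegions(dose, matrix(0, 5, 5))
  expect_identical(regionMask(masks), roi)
  st <- gdsaStatistic(diffPct, masks)
  expect_equal(st$gdsa_mean_pct, 3.5)
  expect_equal(st$gdsa_std_pct, sqrt(35 / 12))
  expect_identical(st$roi_pixels, 6L)
  stS <- gdsaStatistic(diffPct, masks, sdType = "sample")
  expect_equal(stS$gdsa_std_pct, sqrt(3.5))
  # identity fraction: exactly zero with zero spread
  z <- gdsaStatistic(matrix(0, 5, 5), masks)
  expect_identical(z$gdsa_mean_pct, 0)
  expect_identical(z$gdsa_std_pct, 0)
  # empty ROI is an error, not a zero
  masksEmpty <- segmentRegions(matrix(1, 5, 5), matrix(10, 5, 5))
  expect_error(gdsaStatistic(diffPct, masksEmpty),
               "no high-dose low-gradient region")
})

test_that("uniform scaling obeys the closed-form GDSA value", {
  ref <- flatPlateau(n = 48L, half = 8)
  refPct <- normalizeToPercent(ref)
  masks <- segmentRegions(refPct, gradientMap(refPct, pixelPitch(ref)))
  roi <- regionMask(masks)
  r <- mean(pixels(ref)[roi]) / max(pixels(ref))
  for (alpha in c(0.005, 0.02, 0.035)) {
    cmp <- CompositeImage((1 + alpha) * pixels(ref), pixelPitch(ref), 2L)
    st <- gdsaStatistic(doseDifferencePercent(ref, cmp), masks)
    expect_equal(st$gdsa_mean_pct, 100 * alpha * r, tolerance = 1e-9)
    expect_equal(st$gdsa_std_pct, 0, tolerance = 1e-9)
  }
})

test_that("swapping reference and comparison negates the ROI mean when
           maxima are equal", {
  ref <- flatPlateau(n = 32L, half = 6)
  # perturb off-plateau pixels only, keeping both maxima equal
  px <- pixels(ref)
  set.seed(9)
  edge <- px < 0.5 * max(px)
  px2 <- px
  px2[edge] <- px[edge] * runif(sum(edge), 0.9, 1.1)
  cmp <- CompositeImage(px2, pixelPitch(ref), 2L)
  refPct <- normalizeToPercent(ref)
  masks <- segmentRegions(refPct, gradientMap(refPct, pixelPitch(ref)))
  a <- gdsaStatistic(doseDifferencePercent(ref, cmp), masks)
  b <- gdsaStatistic(doseDifferencePercent(cmp, ref), masks)
  expect_equal(a$gdsa_mean_pct, -b$gdsa_mean_pct, tolerance = 1e-12)
})

test_that("analyzeSeries flags by |GDSA| and keeps reference trivial", {
  ref <- flatPlateau(n = 48L, half = 8)
  mk <- function(f, scale) CompositeImage(scale * pixels(ref),
                                          pixelPitch(ref), f)
  series <- PatientSeries(list(mk(1L, 1), mk(2L, 1), mk(3L, 1.035),
                               mk(4L, 0.96)),
                          patientId = "t", siteLabel = "larynx")
  res <- analyzeSeries(series)
  expect_identical(res$fraction, 1:4)
  expect_true(res$is_reference[1L])
  expect_identical(res$gdsa_mean_pct[1:2], c(0, 0))
  expect_identical(res$flagged, c(FALSE, FALSE, TRUE, TRUE))
  expect_lt(res$gdsa_mean_pct[4L], 0)  # cooler delivery drives it negative

  # identical composites throughout: all zero, none flagged
  stable <- PatientSeries(lapply(1:5, mk, scale = 1))
  resS <- analyzeSeries(stable)
  expect_equal(resS$gdsa_mean_pct, rep(0, 5))
  expect_false(any(resS$flagged))

  # strictly increasing gains give a strictly increasing GDSA series
  set.seed(31)
  gains <- 1 + cumsum(runif(6, 0.001, 0.01))
  inc <- PatientSeries(c(list(mk(1L, 1)),
                         lapply(seq_along(gains),
                                function(k) mk(k + 1L, gains[k]))))
  resI <- analyzeSeries(inc)
  expect_true(all(diff(resI$gdsa_mean_pct) > 0))

  # a geometry-mismatched fraction is reported and skipped, not fatal
  bad <- PatientSeries(list(mk(1L, 1), mk(2L, 1.01),
                            CompositeImage(matrix(1, 8, 8), 0.336, 3L)))
  expect_warning(resB <- analyzeSeries(bad), "fraction 3 skipped")
  expect_identical(resB$fraction, 1:2)
})
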