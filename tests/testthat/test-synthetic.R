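test_that("generation is fully deterministic given the seed", {
  cfg <- scenarioConfig("mixed", n_fractions = 6, image_size = 64,
                        noise_sd_pct = 0.2, rotation_jitter_sd_deg = 0.5,
                        seed = 123)
  a <- generatePatient(cfg)
  b <- generatePatient(cfg)
  for (k in 1:6) {
    expect_identical(pixels(a$series@fractions[[k]]),
                     pixels(b$series@fractions[[k]]))
  }
  expect_identical(a$ground_truth, b$ground_truth)
  expect_identical(a$series@registrations, b$series@registrations)
})

test_that("reference composite has an exact plateau and a sound ROI", {
  cfg <- scenarioConfig("stable", image_size = 128, seed = 1)
  ref <- makeReferenceComposite(cfg)
  px <- pixels(ref)
  centre <- (dim(px) + 1) / 2
  expect_identical(px[centre[1], centre[2]], cfg$max_dose_cu)
  # the analytic plateau interior must classify high-dose low-gradient
  refPct <- normalizeToPercent(ref)
  masks <- segmentRegions(refPct, gradientMap(refPct, pixelPitch(ref)))
  half <- cfg$plateau_fraction * cfg$image_size / 2
  mid <- (cfg$image_size + 1) / 2
  inPlateau <- abs(seq_len(cfg$image_size) - mid) <= half - 1
  expect_true(all(regionMask(masks)[inPlateau, inPlateau]))
  # and the penumbral shoulder must be high-gradient
  expect_true(any(regionMask(masks, "highDoseHighGradient")))
  expect_error(makeReferenceComposite(
    scenarioConfig("stable", image_size = 8, plateau_fraction = 0.1,
                   seed = 1)),
    "plateau too small")
})

test_that("comparison composites follow the uniform-gain closed form", {
  cfg <- scenarioConfig("weight_loss", image_size = 96, seed = 5)
  ref <- makeReferenceComposite(cfg)
  refPct <- normalizeToPercent(ref)
  masks <- segmentRegions(refPct, gradientMap(refPct, pixelPitch(ref)))
  roi <- regionMask(masks)
  r <- mean(pixels(ref)[roi]) / max(pixels(ref))
  cmp0 <- makeComparisonComposite(ref, 0, cfg, 2L)
  expect_identical(pixels(cmp0), pixels(ref))
  cmp <- makeComparisonComposite(ref, 0.02, cfg, 3L)
  st <- gdsaStatistic(doseDifferencePercent(ref, cmp), masks)
  expect_equal(st$gdsa_mean_pct, 100 * 0.02 * r, tolerance = 1e-9)
  # a gain ramp across the field spreads the ROI distribution
  cfgRamp <- scenarioConfig("weight_loss", image_size = 96,
                            alpha_ramp = 0.3, seed = 5)
  cmpR <- makeComparisonComposite(ref, 0.02, cfgRamp, 3L)
  stR <- gdsaStatistic(doseDifferencePercent(ref, cmpR), masks)
  expect_gt(stR$gdsa_std_pct, 0)
  expect_equal(stR$gdsa_mean_pct, st$gdsa_mean_pct, tolerance = 1e-6)
})

test_that("with noise the GDSA mean stays centred on the closed form", {
  base <- scenarioConfig("weight_loss", image_size = 96,
                         noise_sd_pct = 0.2, seed = 1)
  ref0 <- makeReferenceComposite(
    scenarioConfig("weight_loss", image_size = 96, seed = 1))
  refPct <- normalizeToPercent(ref0)
  masks <- segmentRegions(refPct, gradientMap(refPct, pixelPitch(ref0)))
  roi <- regionMask(masks)
  r <- mean(pixels(ref0)[roi]) / max(pixels(ref0))
  alpha <- 0.02
  vals <- vapply(1:25, function(s) {
    cfg <- scenarioConfig("weight_loss", image_size = 96,
                          noise_sd_pct = 0.2, seed = s)
    cmp <- makeComparisonComposite(ref0, alpha, cfg, 2L)
    gdsaStatistic(doseDifferencePercent(ref0, cmp), masks)$gdsa_mean_pct
  }, numeric(1L))
  mcse <- sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals) - 100 * alpha * r), 3 * mcse + 1e-6)
})

test_that("registration series drift and jitter match ground truth", {
  cfg <- scenarioConfig("rotation_drift", n_fractions = 10, seed = 2)
  reg <- makeRegistrationSeries(cfg)
  rec <- analyzeRotations(reg$matrices, 1:10)
  # pitch drift 0.1 deg/fraction: fraction 10 recovered at 0.9 deg
  expect_equal(rec$pitch_deg, 0.1 * (0:9), tolerance = 1e-9)
  expect_equal(rec$roll_deg, 0.05 * (0:9), tolerance = 1e-9)
  expect_equal(rec$pitch_deg, reg$angles$pitch_deg, tolerance = 1e-9)

  # zero drift and jitter: identity matrices throughout
  cfg0 <- scenarioConfig("stable", n_fractions = 4, seed = 2)
  reg0 <- makeRegistrationSeries(cfg0)
  expect_equal(reg0$matrices[[4L]], diag(4))

  # jitter sd recovered within Monte-Carlo tolerance
  cfgJ <- scenarioConfig("stable", n_fractions = 200,
                         rotation_jitter_sd_deg = 0.5, seed = 6)
  recJ <- analyzeRotations(makeRegistrationSeries(cfgJ)$matrices, 1:200)
  expect_equal(sd(recJ$pitch_deg), 0.5, tolerance = 0.15)
  expect_equal(sd(recJ$yaw_deg), 0.5, tolerance = 0.15)
})

test_that("stable scenario produces no flags end-to-end", {
  pat <- generatePatient(scenarioConfig("stable", n_fractions = 8,
                                        image_size = 64, seed = 3))
  res <- analyzeSeries(pat$series)
  expect_equal(res$gdsa_mean_pct, rep(0, 8))
  expect_false(any(res$flagged))
  expect_equal(pat$ground_truth$alpha, rep(0, 8))
})

test_that("weight-loss scenario flags once the gain crosses threshold", {
  cfg <- scenarioConfig("weight_loss", n_fractions = 25, image_size = 64,
                        per_fraction_transmission_gain = 0.002, seed = 9)
  pat <- generatePatient(cfg)
  res <- analyzeSeries(pat$series)
  expect_true(all(diff(res$gdsa_mean_pct) > 0))
  expect_true(any(res$flagged))
  # flags exactly where the closed form predicts
  ref <- pat$series@fractions[[1L]]
  refPct <- normalizeToPercent(ref)
  masks <- segmentRegions(refPct, gradientMap(refPct, pixelPitch(ref)))
  r <- mean(pixels(ref)[regionMask(masks)]) / max(pixels(ref))
  predicted <- which(100 * pat$ground_truth$alpha * r >= 3)
  expect_identical(res$fraction[res$flagged], as.integer(predicted))
})

test_that("replan scenario flags before the re-baseline but not after", {
  cfg <- scenarioConfig("replan", n_fractions = 30, image_size = 64,
                        per_fraction_transmission_gain = 0.002, seed = 12)
  pat <- generatePatient(cfg)
  expect_identical(pat$reference_fractions, c(1L, 20L))
  res <- analyzeSeries(pat$series,
                       referenceFractions = pat$reference_fractions)
  pre <- res[res$fraction < 20, ]
  post <- res[res$fraction >= 20, ]
  expect_true(any(pre$flagged))
  expect_false(any(post$flagged))
  # the re-baseline restarts the trend from zero
  expect_equal(res$gdsa_mean_pct[res$fraction == 20], 0)
})
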