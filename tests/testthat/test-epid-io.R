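test_that("DICOM RT Image round-trips pixels, pitch and fraction metadata", {
  px <- matrix(as.numeric(c(0, 7, 13, 2, 5, 11, 3, 1, 9, 40, 17, 6, 8, 21,
                            2, 30)), 4, 4)
  img <- EpidImage(px, pixelPitchMm = 0.336, fractionIndex = 5L,
                   arcLabel = "arc2")
  f <- withr::local_tempfile(fileext = ".dcm")
  writeDicomRtImage(img, f)
  back <- readEpidImage(f)
  expect_identical(pixels(back), px)
  expect_equal(pixelPitch(back), 0.336)
  expect_identical(fractionIndex(back), 5L)
  expect_identical(back@arcLabel, "arc2")
})

test_that("DICOM rescale slope and intercept map stored values to CU", {
  # stored {2, 4} with slope 0.5 must read back as CU {1, 2}
  img <- EpidImage(matrix(c(1, 2, 1, 2), 2, 2), 0.336)
  f <- withr::local_tempfile(fileext = ".dcm")
  writeDicomRtImage(img, f, rescaleSlope = 0.5)
  back <- readEpidImage(f)
  expect_equal(pixels(back), pixels(img))
  # and with a non-zero intercept
  img2 <- EpidImage(matrix(c(11, 13, 15, 17), 2, 2), 1)
  f2 <- withr::local_tempfile(fileext = ".dcm")
  writeDicomRtImage(img2, f2, rescaleSlope = 2, rescaleIntercept = 11)
  expect_equal(pixels(readEpidImage(f2)), pixels(img2))
})

test_that("degenerate DICOM inputs raise distinct errors", {
  img <- EpidImage(matrix(as.numeric(1:16), 4, 4), 0.336)
  good <- withr::local_tempfile(fileext = ".dcm")
  writeDicomRtImage(img, good)
  truncated <- withr::local_tempfile(fileext = ".dcm")
  writeBin(readBin(good, raw(), n = 200L), truncated)
  expect_error(readEpidImage(truncated), "unreadable|truncated")
  expect_error(readEpidImage(withr::local_tempfile()), "file not found")

  # a structurally valid DICOM without any pixel-spacing tag
  nospacing <- withr::local_tempfile(fileext = ".dcm")
  body <- c(
    epidGDSA:::.dcmElement(0x0028, 0x0010, "US", epidGDSA:::.u16raw(2L)),
    epidGDSA:::.dcmElement(0x0028, 0x0011, "US", epidGDSA:::.u16raw(2L)),
    epidGDSA:::.dcmElement(0x7FE0, 0x0010, "OW",
                           writeBin(1:4, raw(), size = 2L,
                                    endian = "little"))
  )
  writeBin(c(epidGDSA:::.dcmFileMeta("1.2.840.10008.5.1.4.1.1.481.1",
                                     "2.25.0"), body), nospacing)
  expect_error(readEpidImage(nospacing), "pixel-spacing")

  # plain file that is neither DICOM nor portable
  junk <- withr::local_tempfile()
  writeLines("not an image", junk)
  expect_error(readEpidImage(junk), "unreadable")
})

test_that("portable array format round-trips exactly", {
  ints <- EpidImage(matrix(as.numeric(0:24), 5, 5), 0.336, 2L, "cw")
  f <- withr::local_tempfile()
  writePortableImage(ints, f)
  back <- readEpidImage(f)
  expect_identical(pixels(back), pixels(ints))
  expect_identical(fractionIndex(back), 2L)
  expect_identical(back@arcLabel, "cw")

  set.seed(11)
  floats <- EpidImage(matrix(rexp(36), 6, 6), 0.5)
  f2 <- withr::local_tempfile()
  writePortableImage(floats, f2)
  expect_equal(pixels(readEpidImage(f2)), pixels(floats),
               tolerance = 1e-9)
})

test_that("buildComposite sums arcs and enforces shared geometry", {
  one <- EpidImage(matrix(1, 3, 3), 0.336, 1L, "a1")
  # single arc: identity
  solo <- buildComposite(list(one))
  expect_identical(pixels(solo), pixels(one))
  expect_identical(nArcs(solo), 1L)
  # two all-ones arcs: all twos
  two <- buildComposite(list(one, EpidImage(matrix(1, 3, 3), 0.336, 1L,
                                            "a2")))
  expect_identical(pixels(two), matrix(2, 3, 3))
  expect_identical(nArcs(two), 2L)
  # permutation invariance
  set.seed(3)
  arcs <- lapply(1:4, function(k)
    EpidImage(matrix(runif(16), 4, 4), 0.336, 1L, paste0("a", k)))
  expect_equal(pixels(buildComposite(arcs)),
               pixels(buildComposite(rev(arcs))))
  # geometry / fraction mismatches
  expect_error(buildComposite(list(one, EpidImage(matrix(1, 3, 3), 0.34,
                                                  1L))),
               "mismatched geometry")
  expect_error(buildComposite(list(one, EpidImage(matrix(1, 2, 3), 0.336,
                                                  1L))),
               "mismatched geometry")
  expect_error(buildComposite(list(one, EpidImage(matrix(1, 3, 3), 0.336,
                                                  2L))),
               "different fractions")
  expect_error(buildComposite(list()), "no arc")
})

test_that("pixel pitch and isocentre projection follow panel geometry", {
  expect_equal(derivePixelPitch(430, 1280), 0.3359375)
  expect_equal(derivePixelPitch(430, 430), 1)
  expect_equal(derivePixelPitch(280, 1000), 0.28)
  expect_error(derivePixelPitch(-1, 10), "positive")
  expect_equal(round(projectedFieldSize(43, 100, 154)), 28)
})

test_that("results table writes one row per fraction and round-trips", {
  rec <- data.frame(patient_id = "p1", fraction = 1:3,
                    gdsa_mean_pct = c(0, 1.25, 3.5),
                    gdsa_std_pct = c(0, 0.4, 0.9),
                    roi_pixels = c(100L, 100L, 100L),
                    flagged = c(FALSE, FALSE, TRUE),
                    delta_deff_cm = c(0, NA, 1.4))
  f <- withr::local_tempfile(fileext = ".csv")
  writeResultsTable(rec, f)
  lines <- readLines(f)
  expect_length(lines, 4L)  # header + 3 fractions
  # absent measurements are empty fields, not "NA"
  expect_false(any(grepl("NA", lines)))
  back <- readResultsTable(f)
  expect_equal(back$gdsa_mean_pct, rec$gdsa_mean_pct)
  expect_identical(back$flagged, rec$flagged)
  expect_true(is.na(back$delta_deff_cm[2L]))
  expect_true(all(is.na(back$pitch_deg)))
  expect_error(writeResultsTable(data.frame(), f), "non-empty")
})
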