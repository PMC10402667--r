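#' Normalize a composite to percent of its own maximum
#'
#' @param image a [CompositeImage-class] or numeric matrix of dose values.
#'
#' @return Numeric matrix in percent; its maximum is exactly 100.
#' @examples
#' normalizeToPercent(matrix(c(1, 4, 2, 4), 2))
#' @export
normalizeToPercent <- function(image) {
  px <- if (is(image, "CompositeImage")) image@pixels else image
  stopifnot(is.matrix(px), is.numeric(px))
  mx <- max(px)
  if (mx <= 0) stop("empty delivery: composite has no dose", call. = FALSE)
  # (px / mx) first so the maximum is exactly 100
  100 * (px / mx)
}

#' Generalized dose-gradient map
#'
#' For each pixel the generalized gradient is the square root of the sum,
#' over its (up to four) nearest neighbours, of the squared dose
#' differences divided by the neighbour distance (the pixel pitch). With
#' the dose array in percent of the reference maximum the result is in
#' %/mm. Border pixels use only their existing neighbours; no padding is
#' applied.
#'
#' @param referencePct numeric matrix, dose in percent of the reference
#'   maximum (at least 2 x 2).
#' @param pixelPitchMm pixel pitch at the imager plane, mm.
#' @param agg \code{"sum"} (default) sums the squared neighbour terms
#'   inside the root; \code{"mean"} averages them over the number of
#'   existing neighbours, for sensitivity checks.
#'
#' @return A [GradientMap-class] with values in %/mm.
#' @seealso [segmentRegions()]
#' @export
gradientMap <- function(referencePct, pixelPitchMm, agg = c("sum", "mean")) {
  agg <- match.arg(agg)
  stopifnot(is.matrix(referencePct), is.numeric(referencePct))
  nr <- nrow(referencePct)
  nc <- ncol(referencePct)
  if (nr < 2L || nc < 2L)
    stop("degenerate array: need at least 2 rows and 2 columns",
         call. = FALSE)
  if (pixelPitchMm <= 0) stop("pixel pitch must be positive", call. = FALSE)
  ss <- matrix(0, nr, nc)
  nn <- matrix(0L, nr, nc)
  dv <- (referencePct[-1L, , drop = FALSE] -
         referencePct[-nr, , drop = FALSE])^2
  ss[-1L, ] <- ss[-1L, ] + dv
  ss[-nr, ] <- ss[-nr, ] + dv
  nn[-1L, ] <- nn[-1L, ] + 1L
  nn[-nr, ] <- nn[-nr, ] + 1L
  dh <- (referencePct[, -1L, drop = FALSE] -
         referencePct[, -nc, drop = FALSE])^2
  ss[, -1L] <- ss[, -1L] + dh
  ss[, -nc] <- ss[, -nc] + dh
  nn[, -1L] <- nn[, -1L] + 1L
  nn[, -nc] <- nn[, -nc] + 1L
  if (agg == "mean") ss <- ss / nn
  new("GradientMap", values = sqrt(ss) / pixelPitchMm,
      pixelPitchMm = as.numeric(pixelPitchMm))
}

#' Segment the reference into dose/gradient regions
#'
#' Classifies every pixel of the normalized reference by a dose threshold
#' (high dose: \code{referencePct >= doseThresholdPct}, inclusive) and a
#' gradient threshold (low gradient: \code{gradient <
#' gradientThresholdPctPerMm}, exclusive), producing the four-way
#' partition whose high-dose low-gradient cell is the GDSA region of
#' interest.
#'
#' @param referencePct numeric matrix, percent of reference maximum.
#' @param grad a [GradientMap-class] computed from \code{referencePct}.
#' @param doseThresholdPct dose threshold, percent (default 5).
#' @param gradientThresholdPctPerMm gradient threshold, %/mm (default 3).
#'
#' @return A [RegionMasks-class].
#' @export
segmentRegions <- function(referencePct, grad, doseThresholdPct = 5,
                           gradientThresholdPctPerMm = 3) {
  g <- if (is(grad, "GradientMap")) grad@values else grad
  if (!identical(dim(referencePct), dim(g)))
    stop("dose and gradient arrays have mismatched dimensions",
         call. = FALSE)
  highDose <- referencePct >= doseThresholdPct
  lowGrad <- g < gradientThresholdPctPerMm
  new("RegionMasks",
      highDoseLowGradient = highDose & lowGrad,
      highDoseHighGradient = highDose & !lowGrad,
      lowDoseLowGradient = !highDose & lowGrad,
      lowDoseHighGradient = !highDose & !lowGrad,
      doseThresholdPct = as.numeric(doseThresholdPct),
      gradientThresholdPctPerMm = as.numeric(gradientThresholdPctPerMm))
}

#' Pixel-wise dose difference in percent of the reference maximum
#'
#' Signed difference \code{100 * (comparison - reference) / max(reference)};
#' positive values mean the comparison fraction is hotter, as happens when
#' transmission increases with patient weight loss.
#'
#' @param reference,comparison [CompositeImage-class] objects (or numeric
#'   matrices) of identical geometry.
#'
#' @return Numeric matrix, percent of the reference maximum.
#' @export
doseDifferencePercent <- function(reference, comparison) {
  refPx <- if (is(reference, "CompositeImage")) reference@pixels
           else reference
  cmpPx <- if (is(comparison, "CompositeImage")) comparison@pixels
           else comparison
  if (is(reference, "CompositeImage") && is(comparison, "CompositeImage") &&
      reference@pixelPitchMm != comparison@pixelPitchMm)
    stop("mismatched geometry: pixel pitch differs", call. = FALSE)
  if (!identical(dim(refPx), dim(cmpPx)))
    stop("mismatched geometry: image dimensions differ", call. = FALSE)
  mx <- max(refPx)
  if (mx <= 0) stop("empty delivery: reference maximum is zero",
                    call. = FALSE)
  100 * (cmpPx - refPx) / mx
}

#' GDSA statistic of one comparison fraction
#'
#' The GDSA mean is the arithmetic mean of the percent dose-difference map
#' over the high-dose low-gradient region of the reference; its standard
#' deviation is that of the same pixel distribution (population form by
#' default, dividing by n).
#'
#' @param diffPct numeric matrix from [doseDifferencePercent()].
#' @param masks a [RegionMasks-class] from the reference fraction.
#' @param sdType \code{"population"} (default) or \code{"sample"}.
#'
#' @return A list with \code{gdsa_mean_pct}, \code{gdsa_std_pct} and
#'   \code{roi_pixels}.
#' @seealso [analyzeSeries()]
#' @export
gdsaStatistic <- function(diffPct, masks, sdType = c("population",
                                                     "sample")) {
  sdType <- match.arg(sdType)
  stopifnot(is(masks, "RegionMasks"))
  roi <- masks@highDoseLowGradient
  if (!identical(dim(diffPct), dim(roi)))
    stop("difference map and masks have mismatched dimensions",
         call. = FALSE)
  n <- sum(roi)
  if (n == 0L)
    stop("no high-dose low-gradient region: fraction cannot be analyzed",
         call. = FALSE)
  vals <- diffPct[roi]
  m <- mean(vals)
  v <- sum((vals - m)^2) / if (sdType == "population") n else max(n - 1L, 1L)
  list(gdsa_mean_pct = m, gdsa_std_pct = sqrt(v), roi_pixels = n)
}

#' Longitudinal GDSA analysis of a patient series
#'
#' Computes the normalized reference composite, its gradient map and
#' region masks once per reference segment, then the GDSA mean and
#' standard deviation of every other fraction against the reference of its
#' segment. A fraction is flagged when \code{|GDSA_mu| >=
#' flagThresholdPct} (inclusive). Reference fractions contribute the
#' trivial result (0, 0) for plotting continuity. Fractions whose geometry
#' does not match their reference are reported with a warning and skipped.
#'
#' @param series a [PatientSeries-class].
#' @param flagThresholdPct flag threshold on |GDSA_mu|, percent
#'   (default 3, the recommended dose-delivery accuracy tolerance).
#' @param doseThresholdPct,gradientThresholdPctPerMm segmentation
#'   thresholds, see [segmentRegions()].
#' @param referenceFractions integer vector of reference (re-baseline)
#'   fraction indices; defaults to the series' reference fraction. With
#'   more than one entry each fraction is compared against the latest
#'   reference not after it, reproducing mid-course replans.
#' @param agg neighbour aggregation of [gradientMap()].
#' @param sdType standard-deviation form of [gdsaStatistic()].
#'
#' @return data.frame with columns \code{patient_id}, \code{site},
#'   \code{fraction}, \code{reference_fraction}, \code{is_reference},
#'   \code{gdsa_mean_pct}, \code{gdsa_std_pct}, \code{roi_pixels},
#'   \code{flagged}, one row per analyzable fraction in fraction order.
#' @examples
#' pat <- generatePatient(scenarioConfig("stable", n_fractions = 3,
#'                                       image_size = 64, seed = 1))
#' analyzeSeries(pat$series)
#' @export
analyzeSeries <- function(series, flagThresholdPct = 3,
                          doseThresholdPct = 5,
                          gradientThresholdPctPerMm = 3,
                          referenceFractions = NULL,
                          agg = c("sum", "mean"),
                          sdType = c("population", "sample")) {
  stopifnot(is(series, "PatientSeries"))
  agg <- match.arg(agg)
  sdType <- match.arg(sdType)
  idx <- vapply(series@fractions, slot, integer(1L), "fractionIndex")
  if (is.null(referenceFractions))
    referenceFractions <- series@referenceFraction
  referenceFractions <- sort(unique(as.integer(referenceFractions)))
  if (!all(referenceFractions %in% idx))
    stop("reference fraction(s) absent from the series", call. = FALSE)

  # reference context (normalized image, masks, max dose) per segment
  ctx <- lapply(referenceFractions, function(rf) {
    ref <- series@fractions[[match(rf, idx)]]
    refPct <- normalizeToPercent(ref)
    grad <- gradientMap(refPct, ref@pixelPitchMm, agg = agg)
    masks <- segmentRegions(refPct, grad, doseThresholdPct,
                            gradientThresholdPctPerMm)
    if (!any(masks@highDoseLowGradient))
      stop("no high-dose low-gradient region in reference fraction ", rf,
           call. = FALSE)
    list(ref = ref, masks = masks)
  })
  names(ctx) <- as.character(referenceFractions)

  rows <- vector("list", length(idx))
  for (k in seq_along(idx)) {
    fr <- idx[k]
    segRefs <- referenceFractions[referenceFractions <= fr]
    rf <- if (length(segRefs)) max(segRefs) else min(referenceFractions)
    cx <- ctx[[as.character(rf)]]
    comp <- series@fractions[[k]]
    if (fr %in% referenceFractions) {
      rows[[k]] <- data.frame(
        fraction = fr, reference_fraction = rf, is_reference = TRUE,
        gdsa_mean_pct = 0, gdsa_std_pct = 0,
        roi_pixels = sum(cx$masks@highDoseLowGradient), flagged = FALSE)
      next
    }
    res <- tryCatch({
      diffPct <- doseDifferencePercent(cx$ref, comp)
      gdsaStatistic(diffPct, cx$masks, sdType = sdType)
    }, error = function(e) {
      warning("fraction ", fr, " skipped: ", conditionMessage(e),
              call. = FALSE)
      NULL
    })
    if (is.null(res)) next
    rows[[k]] <- data.frame(
      fraction = fr, reference_fraction = rf, is_reference = FALSE,
      gdsa_mean_pct = res$gdsa_mean_pct, gdsa_std_pct = res$gdsa_std_pct,
      roi_pixels = res$roi_pixels,
      flagged = abs(res$gdsa_mean_pct) >= flagThresholdPct)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1L))])
  out <- cbind(patient_id = series@patientId, site = series@siteLabel, out,
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
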