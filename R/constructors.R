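#' Construct a single-arc EPID image
#'
#' @param pixels numeric matrix of dose values in CU.
#' @param pixelPitchMm pixel spacing at the imager plane, mm.
#' @param fractionIndex positive integer fraction number.
#' @param arcLabel arc identifier.
#'
#' @return An [EpidImage-class] object.
#' @examples
#' img <- EpidImage(matrix(1, 4, 4), pixelPitchMm = 0.336, fractionIndex = 1)
#' pixelPitch(img)
#' @export
EpidImage <- function(pixels, pixelPitchMm, fractionIndex = 1L,
                      arcLabel = "arc1") {
  new("EpidImage", pixels = .asDoseMatrix(pixels),
      pixelPitchMm = as.numeric(pixelPitchMm),
      fractionIndex = .asCount(fractionIndex, "fractionIndex"),
      arcLabel = as.character(arcLabel))
}

#' Construct a per-fraction composite image
#'
#' Normally produced by [buildComposite()]; the direct constructor exists
#' for synthetic data and tests.
#'
#' @param pixels numeric matrix of summed dose values in CU.
#' @param pixelPitchMm pixel spacing, mm.
#' @param fractionIndex positive integer fraction number.
#' @param nArcs number of arcs summed into the composite.
#'
#' @return A [CompositeImage-class] object.
#' @export
CompositeImage <- function(pixels, pixelPitchMm, fractionIndex = 1L,
                           nArcs = 1L) {
  new("CompositeImage", pixels = .asDoseMatrix(pixels),
      pixelPitchMm = as.numeric(pixelPitchMm),
      fractionIndex = .asCount(fractionIndex, "fractionIndex"),
      nArcs = .asCount(nArcs, "nArcs"))
}

#' Construct an axial body-contour slice
#'
#' @param mask logical matrix; TRUE inside the body. Rows run anterior to
#'   posterior, columns patient-left to patient-right.
#' @param rowSpacingMm,colSpacingMm pixel spacings, mm.
#'
#' @return A [ContourSlice-class] object.
#' @export
ContourSlice <- function(mask, rowSpacingMm = 1, colSpacingMm = 1) {
  storage.mode(mask) <- "logical"
  new("ContourSlice", mask = mask,
      rowSpacingMm = as.numeric(rowSpacingMm),
      colSpacingMm = as.numeric(colSpacingMm))
}

#' Assemble a longitudinal patient series
#'
#' @param fractions list of [CompositeImage-class], one per imaged fraction,
#'   in strictly increasing fraction order.
#' @param patientId,siteLabel patient identifier and treatment-site label.
#' @param referenceFraction fraction index used as the GDSA reference
#'   (default: the first fraction present). Set to a later fraction to
#'   re-baseline after a replan.
#' @param contours optional list of [ContourSlice-class] (or NULL entries),
#'   parallel to \code{fractions}.
#' @param registrations optional list of 4x4 rigid registration matrices
#'   (or NULL entries), parallel to \code{fractions}.
#'
#' @return A [PatientSeries-class] object.
#' @seealso [analyzeSeries()], [generatePatient()]
#' @export
PatientSeries <- function(fractions, patientId = "patient",
                          siteLabel = "unspecified",
                          referenceFraction = NULL,
                          contours = list(), registrations = list()) {
  if (!length(fractions)) stop("'fractions' must not be empty")
  if (is.null(referenceFraction))
    referenceFraction <- fractions[[1L]]@fractionIndex
  new("PatientSeries", patientId = as.character(patientId),
      siteLabel = as.character(siteLabel),
      referenceFraction = .asCount(referenceFraction, "referenceFraction"),
      fractions = fractions, contours = contours,
      registrations = registrations)
}

.asDoseMatrix <- function(x) {
  if (!is.matrix(x)) stop("'pixels' must be a matrix")
  storage.mode(x) <- "double"
  x
}

.asCount <- function(x, what) {
  x <- as.integer(x)
  if (length(x) != 1L || is.na(x) || x < 1L)
    stop(sprintf("'%s' must be a single positive integer", what))
  x
}

# ---- accessors --------------------------------------------------------------

#' Pixel matrix of an image object
#' @param object an [EpidImage-class], [CompositeImage-class] or
#'   [GradientMap-class].
#' @return A numeric matrix (CU for images, %/mm for gradient maps).
#' @export
setGeneric("pixels", function(object) standardGeneric("pixels"))

#' @rdname pixels
#' @export
setMethod("pixels", "EpidImage", function(object) object@pixels)

#' @rdname pixels
#' @export
setMethod("pixels", "CompositeImage", function(object) object@pixels)

#' @rdname pixels
#' @export
setMethod("pixels", "GradientMap", function(object) object@values)

#' Pixel pitch at the imager plane (mm)
#' @param object an image-like object carrying a pixel pitch.
#' @return Positive scalar, mm.
#' @export
setGeneric("pixelPitch", function(object) standardGeneric("pixelPitch"))

#' @rdname pixelPitch
#' @export
setMethod("pixelPitch", "EpidImage", function(object) object@pixelPitchMm)

#' @rdname pixelPitch
#' @export
setMethod("pixelPitch", "CompositeImage", function(object) object@pixelPitchMm)

#' @rdname pixelPitch
#' @export
setMethod("pixelPitch", "GradientMap", function(object) object@pixelPitchMm)

#' Fraction index of a per-fraction object
#' @param object an [EpidImage-class] or [CompositeImage-class].
#' @return Positive integer.
#' @export
setGeneric("fractionIndex", function(object) standardGeneric("fractionIndex"))

#' @rdname fractionIndex
#' @export
setMethod("fractionIndex", "EpidImage", function(object) object@fractionIndex)

#' @rdname fractionIndex
#' @export
setMethod("fractionIndex", "CompositeImage",
          function(object) object@fractionIndex)

#' Number of arcs summed into a composite
#' @param object a [CompositeImage-class].
#' @return Positive integer.
#' @export
nArcs <- function(object) {
  stopifnot(is(object, "CompositeImage"))
  object@nArcs
}

#' Body mask of a contour slice
#' @param object a [ContourSlice-class].
#' @return Logical matrix.
#' @export
bodyMask <- function(object) {
  stopifnot(is(object, "ContourSlice"))
  object@mask
}

#' Region mask accessor
#'
#' @param object a [RegionMasks-class].
#' @param which one of "highDoseLowGradient" (the GDSA ROI),
#'   "highDoseHighGradient", "lowDoseLowGradient", "lowDoseHighGradient".
#' @return Logical matrix.
#' @export
regionMask <- function(object, which = "highDoseLowGradient") {
  stopifnot(is(object, "RegionMasks"))
  which <- match.arg(which, c("highDoseLowGradient", "highDoseHighGradient",
                              "lowDoseLowGradient", "lowDoseHighGradient"))
  slot(object, which)
}

#' Fractions of a patient series
#' @param object a [PatientSeries-class].
#' @return List of [CompositeImage-class], in fraction order.
#' @export
seriesFractions <- function(object) {
  stopifnot(is(object, "PatientSeries"))
  object@fractions
}

#' Reference fraction index of a patient series
#' @param object a [PatientSeries-class].
#' @return Positive integer.
#' @export
referenceFraction <- function(object) {
  stopifnot(is(object, "PatientSeries"))
  object@referenceFraction
}

# ---- show methods -----------------------------------------------------------

setMethod("show", "EpidImage", function(object) {
  cat(sprintf("EpidImage: %d x %d px, pitch %.4g mm, fraction %d, arc '%s'\n",
              nrow(object@pixels), ncol(object@pixels), object@pixelPitchMm,
              object@fractionIndex, object@arcLabel))
  cat(sprintf("  dose range [%.4g, %.4g] CU\n",
              min(object@pixels), max(object@pixels)))
})

setMethod("show", "CompositeImage", function(object) {
  cat(sprintf(
    "CompositeImage: %d x %d px, pitch %.4g mm, fraction %d (%d arc%s)\n",
    nrow(object@pixels), ncol(object@pixels), object@pixelPitchMm,
    object@fractionIndex, object@nArcs, if (object@nArcs > 1L) "s" else ""))
  cat(sprintf("  dose range [%.4g, %.4g] CU\n",
              min(object@pixels), max(object@pixels)))
})

setMethod("show", "GradientMap", function(object) {
  cat(sprintf("GradientMap: %d x %d px, pitch %.4g mm, max %.4g %%/mm\n",
              nrow(object@values), ncol(object@values), object@pixelPitchMm,
              max(object@values)))
})

setMethod("show", "RegionMasks", function(object) {
  cat(sprintf(
    "RegionMasks (%d x %d px; dose >= %g%%, gradient < %g %%/mm):\n",
    nrow(object@highDoseLowGradient), ncol(object@highDoseLowGradient),
    object@doseThresholdPct, object@gradientThresholdPctPerMm))
  cat(sprintf("  high-dose low-gradient (GDSA ROI): %d px\n",
              sum(object@highDoseLowGradient)))
  cat(sprintf("  high-dose high-gradient: %d px\n",
              sum(object@highDoseHighGradient)))
  cat(sprintf("  low-dose  low-gradient: %d px\n",
              sum(object@lowDoseLowGradient)))
  cat(sprintf("  low-dose  high-gradient: %d px\n",
              sum(object@lowDoseHighGradient)))
})

setMethod("show", "ContourSlice", function(object) {
  cat(sprintf(
    "ContourSlice: %d x %d px (%.3g x %.3g mm), %d body pixels\n",
    nrow(object@mask), ncol(object@mask), object@rowSpacingMm,
    object@colSpacingMm, sum(object@mask)))
})

setMethod("show", "PatientSeries", function(object) {
  idx <- vapply(object@fractions, slot, integer(1L), "fractionIndex")
  cat(sprintf(
    "PatientSeries '%s' (%s): %d fractions [%d..%d], reference %d\n",
    object@patientId, object@siteLabel, length(idx), min(idx), max(idx),
    object@referenceFraction))
  if (length(object@contours))
    cat(sprintf("  contour slices: %d\n",
                sum(!vapply(object@contours, is.null, logical(1L)))))
  if (length(object@registrations))
    cat(sprintf("  registration matrices: %d\n",
                sum(!vapply(object@registrations, is.null, logical(1L)))))
})
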