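#' @import methods
NULL

#' Single-arc transit EPID image
#'
#' One transit EPID acquisition for one treatment arc, in Calibrated Units
#' (CU; 1 CU is the panel signal of 1 MU under a reference 10 x 10 cm field).
#' Pixel pitch is the spacing at the imager plane, in mm.
#'
#' @slot pixels numeric matrix of dose values in CU; finite and non-negative.
#' @slot pixelPitchMm positive scalar, pixel spacing at the imager plane (mm).
#' @slot fractionIndex positive integer, treatment fraction the arc belongs to.
#' @slot arcLabel character scalar identifying the arc.
#'
#' @seealso [EpidImage()], [buildComposite()]
#' @export
setClass("EpidImage",
  representation(
    pixels = "matrix",
    pixelPitchMm = "numeric",
    fractionIndex = "integer",
    arcLabel = "character"
  )
)

setValidity("EpidImage", function(object) {
  msg <- .validImagePixels(object@pixels, object@pixelPitchMm)
  if (!is.null(msg)) return(msg)
  if (length(object@fractionIndex) != 1L || is.na(object@fractionIndex) ||
      object@fractionIndex < 1L)
    return("'fractionIndex' must be a single positive integer")
  if (length(object@arcLabel) != 1L)
    return("'arcLabel' must be a single string")
  TRUE
})

#' Per-fraction composite transit image
#'
#' The pixel-wise sum of all arc images delivered in one fraction, in CU.
#' The composite of the reference fraction defines the dose-gradient map and
#' the region segmentation; composites of later fractions are compared
#' against it.
#'
#' @slot pixels numeric matrix of summed dose values in CU.
#' @slot pixelPitchMm positive scalar, pixel spacing at the imager plane (mm).
#' @slot fractionIndex positive integer.
#' @slot nArcs positive integer, number of arcs summed into the composite.
#'
#' @seealso [buildComposite()], [analyzeSeries()]
#' @export
setClass("CompositeImage",
  representation(
    pixels = "matrix",
    pixelPitchMm = "numeric",
    fractionIndex = "integer",
    nArcs = "integer"
  )
)

setValidity("CompositeImage", function(object) {
  msg <- .validImagePixels(object@pixels, object@pixelPitchMm)
  if (!is.null(msg)) return(msg)
  if (length(object@fractionIndex) != 1L || is.na(object@fractionIndex) ||
      object@fractionIndex < 1L)
    return("'fractionIndex' must be a single positive integer")
  if (length(object@nArcs) != 1L || is.na(object@nArcs) || object@nArcs < 1L)
    return("'nArcs' must be a single positive integer")
  TRUE
})

.validImagePixels <- function(px, pitch) {
  if (!is.numeric(px)) return("'pixels' must be a numeric matrix")
  if (anyNA(px) || any(!is.finite(px)))
    return("'pixels' must be finite")
  if (any(px < 0))
    return("'pixels' must be non-negative (dose in CU)")
  if (length(pitch) != 1L || is.na(pitch) || pitch <= 0)
    return("'pixelPitchMm' must be a single positive number")
  NULL
}

#' Generalized dose-gradient map
#'
#' Per-pixel generalized gradient of the normalized reference composite, in
#' percent of the reference maximum per mm. At each pixel the squared
#' dose differences to the (up to four) nearest neighbours, divided by the
#' pixel pitch, are summed and the square root taken.
#'
#' @slot values numeric matrix, %/mm; finite and non-negative.
#' @slot pixelPitchMm positive scalar (mm).
#'
#' @seealso [gradientMap()], [segmentRegions()]
#' @export
setClass("GradientMap",
  representation(values = "matrix", pixelPitchMm = "numeric")
)

setValidity("GradientMap", function(object) {
  if (anyNA(object@values) || any(!is.finite(object@values)))
    return("'values' must be finite")
  if (any(object@values < 0))
    return("gradient magnitudes must be non-negative")
  if (length(object@pixelPitchMm) != 1L || object@pixelPitchMm <= 0)
    return("'pixelPitchMm' must be a single positive number")
  TRUE
})

#' Dose/gradient region segmentation
#'
#' The four-way partition of the reference image by a dose threshold
#' (default 5% of the reference maximum, inclusive for "high dose") and a
#' gradient threshold (default 3 %/mm, exclusive for "low gradient").
#' The four masks are pairwise disjoint and cover every pixel; the GDSA
#' statistic is evaluated over \code{highDoseLowGradient}.
#'
#' @slot highDoseLowGradient,highDoseHighGradient,lowDoseLowGradient,lowDoseHighGradient
#'   logical matrices of identical dimensions.
#' @slot doseThresholdPct scalar, percent of reference maximum.
#' @slot gradientThresholdPctPerMm scalar, %/mm.
#'
#' @seealso [segmentRegions()], [gdsaStatistic()]
#' @export
setClass("RegionMasks",
  representation(
    highDoseLowGradient = "matrix",
    highDoseHighGradient = "matrix",
    lowDoseLowGradient = "matrix",
    lowDoseHighGradient = "matrix",
    doseThresholdPct = "numeric",
    gradientThresholdPctPerMm = "numeric"
  )
)

setValidity("RegionMasks", function(object) {
  ms <- list(object@highDoseLowGradient, object@highDoseHighGradient,
             object@lowDoseLowGradient, object@lowDoseHighGradient)
  if (!all(vapply(ms, is.logical, logical(1L))))
    return("all four masks must be logical matrices")
  d <- dim(ms[[1L]])
  if (!all(vapply(ms, function(m) identical(dim(m), d), logical(1L))))
    return("masks must share dimensions")
  tot <- ms[[1L]] + ms[[2L]] + ms[[3L]] + ms[[4L]]
  if (any(tot != 1L))
    return("masks must partition the image (disjoint and exhaustive)")
  TRUE
})

#' Axial body-contour slice
#'
#' Boolean body mask on the axial CBCT slice through the treatment
#' isocentre. Rows run anterior to posterior, columns patient-left to
#' patient-right, so the row extent of the mask is the A-P separation and
#' the column extent the lateral separation.
#'
#' @slot mask logical matrix, TRUE inside the patient body; at least one
#'   TRUE pixel.
#' @slot rowSpacingMm,colSpacingMm positive scalars (mm per pixel).
#'
#' @seealso [extractBodyMask()], [measureSeparations()]
#' @export
setClass("ContourSlice",
  representation(
    mask = "matrix",
    rowSpacingMm = "numeric",
    colSpacingMm = "numeric"
  )
)

setValidity("ContourSlice", function(object) {
  if (!is.logical(object@mask)) return("'mask' must be a logical matrix")
  if (anyNA(object@mask)) return("'mask' must not contain NA")
  if (!any(object@mask)) return("'mask' must contain at least one body pixel")
  if (length(object@rowSpacingMm) != 1L || object@rowSpacingMm <= 0 ||
      length(object@colSpacingMm) != 1L || object@colSpacingMm <= 0)
    return("pixel spacings must be single positive numbers")
  TRUE
})

#' Longitudinal per-patient series
#'
#' Ordered per-fraction composites for one patient, with optional matched
#' body-contour slices and rigid registration matrices, and the designation
#' of the reference fraction (fraction 1 by default; settable to re-baseline
#' after a replan).
#'
#' @slot patientId character scalar.
#' @slot siteLabel character scalar, treatment-site category (free text).
#' @slot referenceFraction positive integer; must be one of the fraction
#'   indices present.
#' @slot fractions list of [CompositeImage-class] in strictly increasing
#'   fraction order.
#' @slot contours list of [ContourSlice-class] or NULLs, parallel to
#'   \code{fractions} (may be empty).
#' @slot registrations list of 4x4 numeric matrices or NULLs, parallel to
#'   \code{fractions} (may be empty).
#'
#' @seealso [PatientSeries()], [analyzeSeries()], [generatePatient()]
#' @export
setClass("PatientSeries",
  representation(
    patientId = "character",
    siteLabel = "character",
    referenceFraction = "integer",
    fractions = "list",
    contours = "list",
    registrations = "list"
  )
)

setValidity("PatientSeries", function(object) {
  if (length(object@patientId) != 1L) return("'patientId' must be a string")
  if (length(object@siteLabel) != 1L) return("'siteLabel' must be a string")
  if (length(object@fractions) < 1L)
    return("a series needs at least one fraction")
  if (!all(vapply(object@fractions, is, logical(1L), "CompositeImage")))
    return("'fractions' must be CompositeImage objects")
  idx <- vapply(object@fractions, slot, integer(1L), "fractionIndex")
  if (any(diff(idx) <= 0))
    return("fraction indices must be strictly increasing")
  if (!(object@referenceFraction %in% idx))
    return("'referenceFraction' must be one of the fraction indices")
  for (nm in c("contours", "registrations")) {
    l <- slot(object, nm)
    if (length(l) && length(l) != length(object@fractions))
      return(sprintf("'%s' must be empty or parallel to 'fractions'", nm))
  }
  TRUE
})
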