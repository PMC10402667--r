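#' Extract the body mask from an axial CT slice
#'
#' Thresholds the slice at \code{huThreshold}, keeps the largest
#' 4-connected component (discarding couch and immobilization artifacts)
#' and fills internal holes (air cavities), yielding the external body
#' contour as a solid mask.
#'
#' @param ctSlice numeric matrix of Hounsfield units; rows anterior to
#'   posterior, columns patient-left to patient-right.
#' @param huThreshold body-surface threshold in HU (default -300).
#' @param rowSpacingMm,colSpacingMm pixel spacings, mm.
#'
#' @return A [ContourSlice-class].
#' @seealso [measureSeparations()]
#' @export
extractBodyMask <- function(ctSlice, huThreshold = -300,
                            rowSpacingMm = 1, colSpacingMm = 1) {
  stopifnot(is.matrix(ctSlice), is.numeric(ctSlice))
  fg <- ctSlice >= huThreshold
  if (!any(fg)) stop("no body found above the HU threshold", call. = FALSE)
  lab <- EBImage::bwlabel(fg)
  counts <- tabulate(lab[lab > 0])
  body <- lab == which.max(counts)
  filled <- EBImage::fillHull(body) > 0
  ContourSlice(matrix(as.logical(filled), nrow(ctSlice)),
               rowSpacingMm = rowSpacingMm, colSpacingMm = colSpacingMm)
}

#' A-P and lateral body separations of a contour slice
#'
#' Separations are the bounding-box extents of the body mask along the
#' fixed image axes: the anterior-posterior separation spans the rows with
#' body pixels, the lateral separation the columns, each converted to cm
#' with the slice's pixel spacing (a single pixel counts as one spacing).
#'
#' @param contour a [ContourSlice-class].
#'
#' @return Named numeric vector \code{c(d_ap_cm, d_lat_cm)}.
#' @export
measureSeparations <- function(contour) {
  stopifnot(is(contour, "ContourSlice"))
  rows <- which(rowSums(contour@mask) > 0)
  cols <- which(colSums(contour@mask) > 0)
  c(d_ap_cm = (max(rows) - min(rows) + 1L) * contour@rowSpacingMm / 10,
    d_lat_cm = (max(cols) - min(cols) + 1L) * contour@colSpacingMm / 10)
}

#' Per-fraction separation change against the reference
#'
#' The change in A-P and lateral separation of fraction n is the absolute
#' difference between the reference separation and that fraction's
#' separation, in cm.
#'
#' @param ref,frac numeric vectors \code{c(d_ap_cm, d_lat_cm)} for the
#'   reference and the n-th fraction.
#'
#' @return Named numeric vector \code{c(delta_ap_cm, delta_lat_cm)}.
#' @examples
#' separationChange(c(20, 30), c(19, 28.5))  # 1.0, 1.5
#' @export
separationChange <- function(ref, frac) {
  stopifnot(length(ref) == 2L, length(frac) == 2L,
            all(ref >= 0), all(frac >= 0))
  c(delta_ap_cm = abs(ref[[1L]] - frac[[1L]]),
    delta_lat_cm = abs(ref[[2L]] - frac[[2L]]))
}

#' Effective separation change diameter
#'
#' Combines the A-P and lateral separation changes into one effective
#' diameter as their geometric mean, \code{sqrt(delta_lat * delta_ap)},
#' which keeps cm units and is zero whenever either axis is unchanged.
#'
#' @param deltaApCm,deltaLatCm absolute separation changes, cm.
#'
#' @return Effective separation change diameter, cm.
#' @examples
#' effectiveSeparationChange(3.91, 3.82)  # 3.864...
#' @export
effectiveSeparationChange <- function(deltaApCm, deltaLatCm) {
  if (any(deltaApCm < 0) || any(deltaLatCm < 0))
    stop("separation changes must be non-negative", call. = FALSE)
  sqrt(deltaLatCm * deltaApCm)
}

#' Flag a fraction by effective separation change
#'
#' TRUE when the effective separation change diameter strictly exceeds the
#' threshold (default 1 cm, below which uniform body change is unlikely to
#' matter dosimetrically).
#'
#' @param deltaEffCm effective separation change diameter, cm.
#' @param thresholdCm threshold, cm (default 1).
#'
#' @return Logical.
#' @export
flagSeparation <- function(deltaEffCm, thresholdCm = 1) {
  stopifnot(all(deltaEffCm >= 0))
  deltaEffCm > thresholdCm
}

#' Separation analysis of a longitudinal contour series
#'
#' Measures per-fraction A-P and lateral separations, their changes
#' against the reference fraction's contour, and the effective separation
#' change diameter.
#'
#' @param contours list of [ContourSlice-class] (NULL entries allowed for
#'   fractions without a usable CBCT).
#' @param fractionIndex integer vector of fraction indices parallel to
#'   \code{contours}.
#' @param referenceFraction fraction index of the reference contour.
#' @param thresholdCm flag threshold of [flagSeparation()].
#'
#' @return data.frame with one row per fraction with a contour: columns
#'   \code{fraction}, \code{d_ap_cm}, \code{d_lat_cm}, \code{delta_dap_cm},
#'   \code{delta_dlat_cm}, \code{delta_deff_cm}, \code{sep_flagged}.
#' @export
analyzeSeparations <- function(contours, fractionIndex,
                               referenceFraction = fractionIndex[1L],
                               thresholdCm = 1) {
  stopifnot(length(contours) == length(fractionIndex))
  keep <- !vapply(contours, is.null, logical(1L))
  contours <- contours[keep]
  fractionIndex <- fractionIndex[keep]
  if (!referenceFraction %in% fractionIndex)
    stop("reference fraction has no contour", call. = FALSE)
  seps <- t(vapply(contours, measureSeparations, numeric(2L)))
  ref <- seps[match(referenceFraction, fractionIndex), ]
  out <- do.call(rbind, lapply(seq_along(fractionIndex), function(k) {
    ch <- separationChange(ref, seps[k, ])
    eff <- effectiveSeparationChange(ch[["delta_ap_cm"]],
                                     ch[["delta_lat_cm"]])
    data.frame(fraction = fractionIndex[k],
               d_ap_cm = seps[k, "d_ap_cm"],
               d_lat_cm = seps[k, "d_lat_cm"],
               delta_dap_cm = ch[["delta_ap_cm"]],
               delta_dlat_cm = ch[["delta_lat_cm"]],
               delta_deff_cm = eff,
               sep_flagged = flagSeparation(eff, thresholdCm))
  }))
  rownames(out) <- NULL
  out
}
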