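#' Read a per-arc transit EPID image
#'
#' Reads one arc's transit EPID acquisition from either a DICOM RT Image
#' file or the package's portable array format (whitespace-delimited
#' numeric text plus a JSON sidecar named \code{<path>.json} holding
#' \code{pixel_pitch_mm}, \code{fraction_index} and \code{arc_label}).
#' DICOM stored values are mapped to Calibrated Units with the file's
#' rescale slope and intercept; the pixel pitch is taken from the
#' image-plane pixel spacing.
#'
#' @param path path to a DICOM RT Image or a portable array file.
#'
#' @return An [EpidImage-class].
#' @seealso [writeDicomRtImage()], [writePortableImage()],
#'   [buildComposite()]
#' @export
readEpidImage <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (.isDicomFile(path)) return(.readDicomEpidImage(path))
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) return(.readPortableEpidImage(path, sidecar))
  stop("unreadable file: neither DICOM nor portable array with sidecar: ",
       path, call. = FALSE)
}

#' Write an EPID image in the portable array format
#'
#' Writes the pixel matrix as plain whitespace-delimited text (one image
#' row per line) and a JSON sidecar \code{<path>.json} carrying the pixel
#' pitch, fraction index and arc label. The format exists so fixtures and
#' exchanged images stay human-readable.
#'
#' @param image an [EpidImage-class].
#' @param path output path for the array file.
#'
#' @return \code{path}, invisibly.
#' @export
writePortableImage <- function(image, path) {
  stopifnot(is(image, "EpidImage"))
  utils::write.table(format(image@pixels, digits = 17, trim = TRUE,
                            scientific = TRUE),
                     path, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  jsonlite::write_json(
    list(pixel_pitch_mm = image@pixelPitchMm,
         fraction_index = image@fractionIndex,
         arc_label = image@arcLabel),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

.readPortableEpidImage <- function(path, sidecar) {
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  px <- as.matrix(utils::read.table(path, header = FALSE))
  dimnames(px) <- NULL
  EpidImage(px, pixelPitchMm = meta$pixel_pitch_mm,
            fractionIndex = meta$fraction_index,
            arcLabel = if (is.null(meta$arc_label)) "arc1" else
              meta$arc_label)
}

#' Sum per-arc images into a fraction composite
#'
#' The per-fraction composite is the pixel-wise sum of all arc images of
#' that fraction, mirroring the integrating panel accumulating dose over
#' the whole delivery. All arcs must share fraction index, matrix
#' dimensions and pixel pitch.
#'
#' @param arcs list of [EpidImage-class] from one fraction.
#'
#' @return A [CompositeImage-class].
#' @examples
#' a1 <- EpidImage(matrix(1, 3, 3), 0.336, 1, "arc1")
#' a2 <- EpidImage(matrix(1, 3, 3), 0.336, 1, "arc2")
#' pixels(buildComposite(list(a1, a2)))[1, 1]  # 2
#' @export
buildComposite <- function(arcs) {
  if (!length(arcs)) stop("no arc images supplied", call. = FALSE)
  stopifnot(all(vapply(arcs, is, logical(1L), "EpidImage")))
  first <- arcs[[1L]]
  for (a in arcs[-1L]) {
    if (!identical(dim(a@pixels), dim(first@pixels)) ||
        a@pixelPitchMm != first@pixelPitchMm)
      stop("mismatched geometry across arc images", call. = FALSE)
    if (a@fractionIndex != first@fractionIndex)
      stop("arc images belong to different fractions", call. = FALSE)
  }
  total <- Reduce(`+`, lapply(arcs, slot, "pixels"))
  CompositeImage(total, pixelPitchMm = first@pixelPitchMm,
                 fractionIndex = first@fractionIndex,
                 nArcs = length(arcs))
}

#' Pixel pitch from panel size and matrix size
#'
#' The detector pixel pitch at the imager plane is the physical panel
#' extent divided by the number of pixels along it. For a 43 cm panel read
#' out as a 1280-pixel matrix this gives 0.336 mm (3 d.p.).
#'
#' @param panelSizeMm physical panel extent, mm.
#' @param matrixSize number of pixels along that extent.
#'
#' @return Pixel pitch in mm.
#' @examples
#' derivePixelPitch(430, 1280)  # 0.3359375
#' @export
derivePixelPitch <- function(panelSizeMm, matrixSize) {
  if (panelSizeMm <= 0 || matrixSize <= 0)
    stop("panel size and matrix size must be positive", call. = FALSE)
  panelSizeMm / matrixSize
}

#' Panel extent projected to the isocentre plane
#'
#' Scales a length at the imager plane back to the isocentre plane by the
#' ratio of source-axis distance to source-imager distance. A 43 cm panel
#' at SID 154 cm projects to about 28 cm at SAD 100 cm.
#'
#' @param panelSizeCm extent at the imager plane, cm.
#' @param sadCm source-axis distance, cm (default 100).
#' @param sidCm source-imager distance, cm (default 154).
#'
#' @return Projected extent in cm.
#' @export
projectedFieldSize <- function(panelSizeCm, sadCm = 100, sidCm = 154) {
  if (panelSizeCm <= 0 || sadCm <= 0 || sidCm <= 0)
    stop("all distances must be positive", call. = FALSE)
  panelSizeCm * sadCm / sidCm
}

.RESULTS_COLUMNS <- c("patient_id", "fraction", "gdsa_mean_pct",
                      "gdsa_std_pct", "roi_pixels", "flagged",
                      "delta_dap_cm", "delta_dlat_cm", "delta_deff_cm",
                      "pitch_deg", "roll_deg", "yaw_deg")

#' Write the per-fraction results table
#'
#' One CSV row per analyzed fraction with the GDSA statistic, separation
#' changes and rotation angles; measurements that were not made are left
#' as empty fields. Columns absent from \code{records} are filled with NA.
#'
#' @param records data.frame of per-fraction results (any subset of the
#'   standard columns, plus \code{patient_id} and \code{fraction}).
#' @param path output CSV path.
#'
#' @return \code{path}, invisibly.
#' @seealso [readResultsTable()], [analyzeSeries()]
#' @export
writeResultsTable <- function(records, path) {
  if (!is.data.frame(records) || !nrow(records))
    stop("'records' must be a non-empty data.frame", call. = FALSE)
  for (cn in .RESULTS_COLUMNS)
    if (!cn %in% names(records)) records[[cn]] <- NA
  records <- records[, .RESULTS_COLUMNS]
  utils::write.csv(records, path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8", quote = FALSE)
  invisible(path)
}

#' Read a per-fraction results table written by [writeResultsTable()]
#'
#' @param path CSV path.
#' @return data.frame with the standard result columns; empty fields
#'   become NA.
#' @export
readResultsTable <- function(path) {
  out <- utils::read.csv(path, na.strings = "", fileEncoding = "UTF-8")
  out$flagged <- as.logical(out$flagged)
  out
}
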