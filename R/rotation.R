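# Axis convention (supine patient, LPS-like): x = patient left-right,
# y = anterior-posterior (vertical), z = superior-inferior.
# pitch (theta) rotates about x, roll (zeta) about z, yaw (phi) about y;
# matrices compose extrinsically as R = Ry(yaw) %*% Rz(roll) %*% Rx(pitch).

#' Rigid transform from pitch/roll/yaw angles
#'
#' Builds the 4x4 homogeneous transform of the package's fixed convention:
#' pitch about the patient left-right axis, roll about the
#' superior-inferior axis, yaw about the anterior-posterior (vertical)
#' axis, composed extrinsically as yaw-roll-pitch.
#'
#' @param pitchDeg,rollDeg,yawDeg rotation angles in degrees.
#' @param translationMm length-3 translation, mm (default zero).
#'
#' @return A 4x4 numeric matrix.
#' @seealso [anglesFromMatrix()]
#' @export
matrixFromAngles <- function(pitchDeg, rollDeg, yawDeg,
                             translationMm = c(0, 0, 0)) {
  t <- pitchDeg * pi / 180
  z <- rollDeg * pi / 180
  p <- yawDeg * pi / 180
  rx <- rbind(c(1, 0, 0), c(0, cos(t), -sin(t)), c(0, sin(t), cos(t)))
  rz <- rbind(c(cos(z), -sin(z), 0), c(sin(z), cos(z), 0), c(0, 0, 1))
  ry <- rbind(c(cos(p), 0, sin(p)), c(0, 1, 0), c(-sin(p), 0, cos(p)))
  m <- diag(4)
  m[1:3, 1:3] <- ry %*% rz %*% rx
  m[1:3, 4L] <- translationMm
  m
}

#' Pitch/roll/yaw setup errors from a rigid registration matrix
#'
#' Decomposes the rotation block of a 4x4 homogeneous rigid transform into
#' pitch, roll and yaw under the package's fixed yaw-roll-pitch
#' convention (see [matrixFromAngles()]). The block must be a proper
#' rotation: orthonormal with determinant 1 within \code{tol}.
#'
#' @param matrix 4x4 (or 3x3) numeric matrix.
#' @param tol rigidity tolerance (default 1e-6).
#'
#' @return Named numeric vector \code{c(pitch_deg, roll_deg, yaw_deg)}.
#' @examples
#' anglesFromMatrix(matrixFromAngles(2, -1, 0.5))
#' @export
anglesFromMatrix <- function(matrix, tol = 1e-6) {
  stopifnot(is.matrix(matrix))
  r <- matrix[1:3, 1:3]
  if (max(abs(crossprod(r) - diag(3))) > tol ||
      abs(det(r) - 1) > tol)
    stop("not a rigid registration: rotation block is not orthonormal ",
         "with determinant 1", call. = FALSE)
  roll <- asin(max(-1, min(1, r[2L, 1L])))
  pitch <- atan2(-r[2L, 3L], r[2L, 2L])
  yaw <- atan2(-r[3L, 1L], r[1L, 1L])
  c(pitch_deg = pitch, roll_deg = roll, yaw_deg = yaw) * 180 / pi
}

#' Read a rigid registration matrix
#'
#' Accepts either a DICOM Spatial Registration file (the nested
#' frame-of-reference transformation matrix is extracted) or a plain-text
#' file holding 16 whitespace-delimited numbers as a 4x4 row-major matrix.
#'
#' @param path file path.
#'
#' @return A 4x4 numeric matrix.
#' @seealso [writeSpatialRegistration()], [anglesFromMatrix()]
#' @export
readRegistrationMatrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (.isDicomFile(path)) return(.readDicomRegistration(path))
  vals <- scan(path, what = numeric(), quiet = TRUE)
  if (length(vals) != 16L)
    stop("plain-text registration must hold 16 numbers (4x4 matrix)",
         call. = FALSE)
  matrix(vals, nrow = 4L, byrow = TRUE)
}

#' Write a registration matrix as plain text
#'
#' @param matrix 4x4 numeric matrix.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeRegistrationMatrix <- function(matrix, path) {
  stopifnot(is.matrix(matrix), all(dim(matrix) == c(4L, 4L)))
  utils::write.table(format(matrix, digits = 17, trim = TRUE), path,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Summary of rotational setup errors
#'
#' Per-axis absolute maximum, mean of absolute values and standard
#' deviation of the absolute-value distribution (population form), in
#' degrees — the form in which cohorts of setup rotations are reported.
#'
#' @param records data.frame with columns \code{pitch_deg},
#'   \code{roll_deg}, \code{yaw_deg} (one row per fraction).
#'
#' @return data.frame with columns \code{axis}, \code{max_abs_deg},
#'   \code{mean_abs_deg}, \code{sd_abs_deg}.
#' @export
summarizeRotations <- function(records) {
  stopifnot(is.data.frame(records), nrow(records) >= 1L,
            all(c("pitch_deg", "roll_deg", "yaw_deg") %in% names(records)))
  one <- function(axis) {
    a <- abs(records[[paste0(axis, "_deg")]])
    data.frame(axis = axis, max_abs_deg = max(a), mean_abs_deg = mean(a),
               sd_abs_deg = sqrt(mean((a - mean(a))^2)))
  }
  out <- rbind(one("pitch"), one("roll"), one("yaw"))
  rownames(out) <- NULL
  out
}

#' Rotation analysis of a longitudinal registration series
#'
#' Extracts pitch/roll/yaw from each fraction's registration matrix.
#'
#' @param registrations list of 4x4 matrices (NULL entries allowed).
#' @param fractionIndex integer vector parallel to \code{registrations}.
#'
#' @return data.frame with columns \code{fraction}, \code{pitch_deg},
#'   \code{roll_deg}, \code{yaw_deg}, one row per fraction with a matrix.
#' @export
analyzeRotations <- function(registrations, fractionIndex) {
  stopifnot(length(registrations) == length(fractionIndex))
  keep <- !vapply(registrations, is.null, logical(1L))
  rows <- lapply(which(keep), function(k) {
    ang <- anglesFromMatrix(registrations[[k]])
    data.frame(fraction = fractionIndex[k],
               pitch_deg = ang[["pitch_deg"]],
               roll_deg = ang[["roll_deg"]],
               yaw_deg = ang[["yaw_deg"]])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
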