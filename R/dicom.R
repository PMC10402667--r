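# Minimal DICOM codec: explicit-VR little-endian only, covering the subset
# this package needs — RT Image pixel data with geometry/rescale tags, and
# Spatial Registration matrices (nested SQ items). Not a general DICOM
# implementation.

.DCM_LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")
.DCM_TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"

.u16raw <- function(x) writeBin(as.integer(x), raw(), size = 2L,
                                endian = "little")
.u32raw <- function(x) writeBin(as.integer(x), raw(), size = 4L,
                                endian = "little")

.dcmPadString <- function(s, nul = FALSE) {
  r <- charToRaw(s)
  if (length(r) %% 2L) r <- c(r, if (nul) as.raw(0L) else charToRaw(" "))
  r
}

.dcmFormatDS <- function(x) {
  # DS values are at most 16 bytes each
  paste(vapply(x, function(v) formatC(v, digits = 10, format = "g"),
               character(1L)), collapse = "\\")
}

.dcmElement <- function(group, element, vr, valueRaw) {
  stopifnot(length(valueRaw) %% 2L == 0L)
  head <- c(.u16raw(group), .u16raw(element), charToRaw(vr))
  if (vr %in% .DCM_LONG_VRS) {
    c(head, raw(2L), .u32raw(length(valueRaw)), valueRaw)
  } else {
    c(head, .u16raw(length(valueRaw)), valueRaw)
  }
}

.dcmItem <- function(contentRaw) {
  c(.u16raw(0xFFFE), .u16raw(0xE000), .u32raw(length(contentRaw)), contentRaw)
}

.dcmFileMeta <- function(sopClassUID, sopInstanceUID) {
  body <- c(
    .dcmElement(0x0002, 0x0001, "OB", as.raw(c(0L, 1L))),
    .dcmElement(0x0002, 0x0002, "UI", .dcmPadString(sopClassUID, nul = TRUE)),
    .dcmElement(0x0002, 0x0003, "UI", .dcmPadString(sopInstanceUID, nul = TRUE)),
    .dcmElement(0x0002, 0x0010, "UI",
                .dcmPadString(.DCM_TS_EXPLICIT_LE, nul = TRUE))
  )
  c(raw(128L), charToRaw("DICM"),
    .dcmElement(0x0002, 0x0000, "UL", .u32raw(length(body))), body)
}

# ---- parsing ----------------------------------------------------------------

.dcmReadU16 <- function(bytes, pos) {
  readBin(bytes[pos:(pos + 1L)], "integer", size = 2L, signed = FALSE,
          endian = "little")
}

.dcmReadU32 <- function(bytes, pos) {
  v <- readBin(bytes[pos:(pos + 3L)], "integer", size = 4L, endian = "little")
  if (v < 0) v <- v + 2^32
  v
}

.dcmCheck <- function(cond) {
  if (!cond) stop("unreadable DICOM file: truncated or malformed",
                  call. = FALSE)
}

# Parses elements in bytes[pos..end]; returns flat named list
# ("GGGG,EEEE" -> list(vr, value)), descending into sequences.
.dcmParseElements <- function(bytes, pos, end, out = list()) {
  while (pos <= end) {
    .dcmCheck(pos + 7L <= end + 1L)
    group <- .dcmReadU16(bytes, pos)
    element <- .dcmReadU16(bytes, pos + 2L)
    if (group == 0xFFFE) {  # item / sequence delimiters at this level
      len <- .dcmReadU32(bytes, pos + 4L)
      pos <- pos + 8L
      if (element %in% c(0xE00D, 0xE0DD)) next
      .dcmCheck(FALSE)
    }
    vr <- rawToChar(bytes[(pos + 4L):(pos + 5L)])
    .dcmCheck(grepl("^[A-Z]{2}$", vr))
    if (vr %in% .DCM_LONG_VRS) {
      len <- .dcmReadU32(bytes, pos + 8L)
      pos <- pos + 12L
    } else {
      len <- .dcmReadU16(bytes, pos + 6L)
      pos <- pos + 8L
    }
    key <- sprintf("%04X,%04X", group, element)
    if (vr == "SQ") {
      sqEnd <- if (len == 2^32 - 1) end else pos + len - 1L
      .dcmCheck(sqEnd <= end)
      res <- .dcmParseSequence(bytes, pos, sqEnd,
                               undefined = (len == 2^32 - 1))
      out <- .dcmMerge(out, res$elements)
      pos <- res$pos
    } else {
      .dcmCheck(len != 2^32 - 1 && pos + len - 1L <= end)
      valueRaw <- if (len > 0L) bytes[pos:(pos + len - 1L)] else raw(0L)
      if (!key %in% names(out))
        out[[key]] <- list(vr = vr, value = .dcmDecode(vr, valueRaw))
      pos <- pos + len
    }
  }
  out
}

.dcmParseSequence <- function(bytes, pos, end, undefined) {
  out <- list()
  while (pos <= end) {
    .dcmCheck(pos + 7L <= length(bytes))
    group <- .dcmReadU16(bytes, pos)
    element <- .dcmReadU16(bytes, pos + 2L)
    .dcmCheck(group == 0xFFFE)
    len <- .dcmReadU32(bytes, pos + 4L)
    pos <- pos + 8L
    if (element == 0xE0DD) break       # sequence delimiter
    .dcmCheck(element == 0xE000)       # item
    itemEnd <- if (len == 2^32 - 1) {
      # undefined-length item: scan until its delimiter at this level
      end
    } else pos + len - 1L
    inner <- .dcmParseElements(bytes, pos, itemEnd)
    out <- .dcmMerge(out, inner)
    if (len == 2^32 - 1) {
      # .dcmParseElements consumed up to itemEnd; undefined items are only
      # supported when they are the last content of the sequence
      pos <- itemEnd + 1L
    } else {
      pos <- itemEnd + 1L
    }
  }
  list(elements = out, pos = pos)
}

.dcmMerge <- function(a, b) {
  for (k in names(b)) if (!k %in% names(a)) a[[k]] <- b[[k]]
  a
}

.dcmDecode <- function(vr, valueRaw) {
  n <- length(valueRaw)
  switch(vr,
    US = readBin(valueRaw, "integer", n = n %/% 2L, size = 2L,
                 signed = FALSE, endian = "little"),
    SS = readBin(valueRaw, "integer", n = n %/% 2L, size = 2L,
                 signed = TRUE, endian = "little"),
    UL = readBin(valueRaw, "integer", n = n %/% 4L, size = 4L,
                 endian = "little"),
    FL = readBin(valueRaw, "double", n = n %/% 4L, size = 4L,
                 endian = "little"),
    FD = readBin(valueRaw, "double", n = n %/% 8L, size = 8L,
                 endian = "little"),
    DS = as.numeric(strsplit(trimws(rawToChar(valueRaw)), "\\",
                             fixed = TRUE)[[1L]]),
    IS = as.integer(strsplit(trimws(rawToChar(valueRaw)), "\\",
                             fixed = TRUE)[[1L]]),
    OW = valueRaw,
    OB = valueRaw,
    # string-like VRs (UI pads with NUL)
    trimws(rawToChar(valueRaw[valueRaw != as.raw(0L)]))
  )
}

.dcmReadFile <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  bytes <- readBin(path, raw(), n = file.size(path))
  start <- 1L
  if (length(bytes) >= 132L &&
      rawToChar(bytes[129:132]) == "DICM") {
    # skip the file meta group (always explicit LE)
    pos <- 133L
    meta <- list()
    repeat {
      .dcmCheck(pos + 7L <= length(bytes))
      group <- .dcmReadU16(bytes, pos)
      if (group != 0x0002) break
      vr <- rawToChar(bytes[(pos + 4L):(pos + 5L)])
      if (vr %in% .DCM_LONG_VRS) {
        len <- .dcmReadU32(bytes, pos + 8L)
        pos <- pos + 12L + len
      } else {
        len <- .dcmReadU16(bytes, pos + 6L)
        valueRaw <- if (len > 0L) bytes[pos + 8L + seq_len(len) - 1L]
                    else raw(0L)
        meta[[sprintf("%04X,%04X", group, .dcmReadU16(bytes, pos + 2L))]] <-
          list(vr = vr, value = .dcmDecode(vr, valueRaw))
        pos <- pos + 8L + len
      }
    }
    ts <- meta[["0002,0010"]]
    if (!is.null(ts) && !identical(ts$value, .DCM_TS_EXPLICIT_LE))
      stop("unsupported DICOM transfer syntax: ", ts$value, call. = FALSE)
    start <- pos
  }
  .dcmCheck(length(bytes) >= start)
  .dcmParseElements(bytes, start, length(bytes))
}

.dcmGet <- function(elements, key, default = NULL) {
  el <- elements[[key]]
  if (is.null(el)) default else el$value
}

# ---- RT Image write/read ----------------------------------------------------

#' Write an EPID image as a DICOM RT Image file
#'
#' Serializes an [EpidImage-class] as a DICOM RT Image (explicit VR little
#' endian, 16-bit unsigned pixel data) with the image-plane pixel spacing
#' and linear rescale parameters needed to recover dose in CU. Intended for
#' generating synthetic fixtures and for interchange; it writes only the
#' tags this package reads back.
#'
#' @param image an [EpidImage-class].
#' @param path output file path.
#' @param rescaleSlope,rescaleIntercept linear map from stored integers to
#'   CU (\code{CU = slope * stored + intercept}). By default an exact slope
#'   is chosen so the stored 16-bit integers round-trip the pixel values.
#'
#' @return \code{path}, invisibly.
#' @seealso [readEpidImage()]
#' @export
writeDicomRtImage <- function(image, path, rescaleSlope = NULL,
                              rescaleIntercept = 0) {
  stopifnot(is(image, "EpidImage"))
  px <- image@pixels
  if (is.null(rescaleSlope)) {
    mx <- max(px - rescaleIntercept)
    rescaleSlope <- if (mx == 0) 1 else if (mx <= 65535 &&
      all((px - rescaleIntercept) == round(px - rescaleIntercept))) 1
      else mx / 65535
  }
  stored <- round((px - rescaleIntercept) / rescaleSlope)
  if (any(stored < 0) || any(stored > 65535))
    stop("pixel values do not fit 16-bit storage with the given rescale",
         call. = FALSE)
  # DICOM PixelData is row-major
  pixelRaw <- writeBin(as.integer(t(stored)), raw(), size = 2L,
                       endian = "little")
  body <- c(
    .dcmElement(0x0008, 0x0016, "UI",
                .dcmPadString("1.2.840.10008.5.1.4.1.1.481.1", nul = TRUE)),
    .dcmElement(0x0008, 0x0060, "CS", .dcmPadString("RTIMAGE")),
    .dcmElement(0x0020, 0x0013, "IS",
                .dcmPadString(as.character(image@fractionIndex))),
    .dcmElement(0x3002, 0x0002, "SH", .dcmPadString(image@arcLabel)),
    .dcmElement(0x0028, 0x0002, "US", .u16raw(1L)),
    .dcmElement(0x0028, 0x0004, "CS", .dcmPadString("MONOCHROME2")),
    .dcmElement(0x0028, 0x0010, "US", .u16raw(nrow(px))),
    .dcmElement(0x0028, 0x0011, "US", .u16raw(ncol(px))),
    .dcmElement(0x0028, 0x0100, "US", .u16raw(16L)),
    .dcmElement(0x0028, 0x0101, "US", .u16raw(16L)),
    .dcmElement(0x0028, 0x0102, "US", .u16raw(15L)),
    .dcmElement(0x0028, 0x0103, "US", .u16raw(0L)),
    .dcmElement(0x0028, 0x1052, "DS",
                .dcmPadString(.dcmFormatDS(rescaleIntercept))),
    .dcmElement(0x0028, 0x1053, "DS",
                .dcmPadString(.dcmFormatDS(rescaleSlope))),
    .dcmElement(0x3002, 0x0011, "DS",
                .dcmPadString(.dcmFormatDS(c(image@pixelPitchMm,
                                             image@pixelPitchMm)))),
    .dcmElement(0x7FE0, 0x0010, "OW", pixelRaw)
  )
  out <- c(.dcmFileMeta("1.2.840.10008.5.1.4.1.1.481.1",
                        paste0("2.25.", format(image@fractionIndex))), body)
  writeBin(out, path)
  invisible(path)
}

.readDicomEpidImage <- function(path) {
  el <- .dcmReadFile(path)
  rows <- .dcmGet(el, "0028,0010")
  cols <- .dcmGet(el, "0028,0011")
  pixelRaw <- .dcmGet(el, "7FE0,0010")
  if (is.null(rows) || is.null(cols) || is.null(pixelRaw))
    stop("unreadable DICOM file: no image pixel data", call. = FALSE)
  nFrames <- .dcmGet(el, "0028,0008", 1L)
  if (as.integer(nFrames[1L]) != 1L || length(pixelRaw) != 2L * rows * cols)
    stop("pixel data is not a single 2-D frame", call. = FALSE)
  spacing <- .dcmGet(el, "3002,0011", .dcmGet(el, "0028,0030"))
  if (is.null(spacing))
    stop("missing pixel-spacing metadata", call. = FALSE)
  signed <- identical(.dcmGet(el, "0028,0103", 0L)[1L], 1L)
  stored <- readBin(pixelRaw, "integer", n = rows * cols, size = 2L,
                    signed = signed, endian = "little")
  slope <- .dcmGet(el, "0028,1053", 1)[1L]
  intercept <- .dcmGet(el, "0028,1052", 0)[1L]
  px <- matrix(slope * stored + intercept, nrow = rows, byrow = TRUE)
  EpidImage(px, pixelPitchMm = spacing[1L],
            fractionIndex = .dcmGet(el, "0020,0013", 1L)[1L],
            arcLabel = .dcmGet(el, "3002,0002", "arc1"))
}

# ---- Spatial Registration write/read ---------------------------------------

#' Write a rigid registration matrix as a DICOM Spatial Registration file
#'
#' Stores the 4x4 homogeneous frame-of-reference transformation matrix in
#' the standard nested Registration / Matrix Registration / Matrix sequence
#' layout, row-major, with matrix type RIGID.
#'
#' @param matrix 4x4 numeric homogeneous rigid transform.
#' @param path output file path.
#'
#' @return \code{path}, invisibly.
#' @seealso [readRegistrationMatrix()]
#' @export
writeSpatialRegistration <- function(matrix, path) {
  stopifnot(is.matrix(matrix), all(dim(matrix) == c(4L, 4L)))
  matrixItem <- .dcmItem(c(
    .dcmElement(0x0070, 0x030C, "CS", .dcmPadString("RIGID")),
    .dcmElement(0x3006, 0x00C6, "DS",
                .dcmPadString(.dcmFormatDS(as.numeric(t(matrix)))))
  ))
  matrixSeq <- .dcmElement(0x0070, 0x030A, "SQ", matrixItem)
  matrixRegItem <- .dcmItem(
    .dcmElement(0x0070, 0x0309, "SQ", .dcmItem(matrixSeq))
  )
  regSeq <- .dcmElement(0x0070, 0x0308, "SQ", matrixRegItem)
  body <- c(
    .dcmElement(0x0008, 0x0016, "UI",
                .dcmPadString("1.2.840.10008.5.1.4.1.1.66.1", nul = TRUE)),
    .dcmElement(0x0008, 0x0060, "CS", .dcmPadString("REG")),
    regSeq
  )
  out <- c(.dcmFileMeta("1.2.840.10008.5.1.4.1.1.66.1", "2.25.1"), body)
  writeBin(out, path)
  invisible(path)
}

.readDicomRegistration <- function(path) {
  el <- .dcmReadFile(path)
  vals <- .dcmGet(el, "3006,00C6")
  if (is.null(vals) || length(vals) != 16L)
    stop("no frame-of-reference transformation matrix found", call. = FALSE)
  matrix(vals, nrow = 4L, byrow = TRUE)
}

.isDicomFile <- function(path) {
  if (!file.exists(path) || file.size(path) < 132L) return(FALSE)
  bytes <- readBin(path, raw(), n = 132L)
  rawToChar(bytes[129:132]) == "DICM"
}
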