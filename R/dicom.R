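# Minimal DICOM part-10 I/O (explicit VR, little endian).
#
# The toolkit audits header tags and compares pixel content; it never needs
# the full standard. This layer covers exactly the tag set the quality
# checks read, writes standard-conformant part-10 files for the synthetic
# generator, and refuses anything it cannot parse rather than guessing.

DICOM_DICT <- local({
  d <- rbind(
    c(0x0002L, 0x0001L, "OB", "FileMetaInformationVersion"),
    c(0x0002L, 0x0002L, "UI", "MediaStorageSOPClassUID"),
    c(0x0002L, 0x0003L, "UI", "MediaStorageSOPInstanceUID"),
    c(0x0002L, 0x0010L, "UI", "TransferSyntaxUID"),
    c(0x0002L, 0x0012L, "UI", "ImplementationClassUID"),
    c(0x0008L, 0x0016L, "UI", "SOPClassUID"),
    c(0x0008L, 0x0018L, "UI", "SOPInstanceUID"),
    c(0x0008L, 0x0020L, "DA", "StudyDate"),
    c(0x0008L, 0x0060L, "CS", "Modality"),
    c(0x0008L, 0x0070L, "LO", "Manufacturer"),
    c(0x0010L, 0x0010L, "PN", "PatientName"),
    c(0x0010L, 0x0020L, "LO", "PatientID"),
    c(0x0010L, 0x0030L, "DA", "PatientBirthDate"),
    c(0x0010L, 0x0040L, "CS", "PatientSex"),
    c(0x0010L, 0x1010L, "AS", "PatientAge"),
    c(0x0018L, 0x0020L, "CS", "ScanningSequence"),
    c(0x0018L, 0x0050L, "DS", "SliceThickness"),
    c(0x0018L, 0x0087L, "DS", "MagneticFieldStrength"),
    c(0x0018L, 0x1210L, "SH", "ConvolutionKernel"),
    c(0x0020L, 0x0013L, "IS", "InstanceNumber"),
    c(0x0028L, 0x0002L, "US", "SamplesPerPixel"),
    c(0x0028L, 0x0004L, "CS", "PhotometricInterpretation"),
    c(0x0028L, 0x0010L, "US", "Rows"),
    c(0x0028L, 0x0011L, "US", "Columns"),
    c(0x0028L, 0x0030L, "DS", "PixelSpacing"),
    c(0x0028L, 0x0100L, "US", "BitsAllocated"),
    c(0x0028L, 0x0101L, "US", "BitsStored"),
    c(0x0028L, 0x0102L, "US", "HighBit"),
    c(0x0028L, 0x0103L, "US", "PixelRepresentation"),
    c(0x0028L, 0x0301L, "CS", "BurnedInAnnotation"),
    c(0x0028L, 0x1052L, "DS", "RescaleIntercept"),
    c(0x0028L, 0x1053L, "DS", "RescaleSlope"),
    c(0x7FE0L, 0x0010L, "OB", "PixelData"))
  data.frame(group = as.integer(d[, 1]), element = as.integer(d[, 2]),
             vr = d[, 3], name = d[, 4], stringsAsFactors = FALSE)
})

TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
SOP_CLASS_CT <- "1.2.840.10008.5.1.4.1.1.2"
SOP_CLASS_MR <- "1.2.840.10008.5.1.4.1.1.4"
SOP_CLASS_SECONDARY_CAPTURE <- "1.2.840.10008.5.1.4.1.1.7"

STRING_VRS <- c("UI", "CS", "LO", "SH", "DA", "PN", "AS", "IS", "DS", "LT", "ST", "UT")
LONG_FORM_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")

dict_lookup <- function(group, element) {
  i <- which(DICOM_DICT$group == group & DICOM_DICT$element == element)
  if (length(i) == 0) NULL else DICOM_DICT[i[1], ]
}

dict_by_name <- function(name) {
  i <- which(DICOM_DICT$name == name)
  if (length(i) == 0) stopf("unknown DICOM attribute name: %s", name)
  DICOM_DICT[i[1], ]
}

uint16_raw <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
uint32_raw <- function(x) {
  # avoid signed 32-bit overflow for lengths >= 2^31 (never reached here)
  writeBin(as.integer(x), raw(), size = 4, endian = "little")
}

encode_value <- function(vr, value) {
  if (vr %in% c("OB", "OW")) {
    v <- if (is.raw(value)) value else as.raw(value)
    if (length(v) %% 2 == 1) v <- c(v, as.raw(0))
    return(v)
  }
  if (vr == "US") return(uint16_raw(value))
  s <- if (vr == "DS") {
    paste(vapply(value, function(x) format(x, digits = 10, scientific = FALSE,
                                           trim = TRUE), ""), collapse = "\\")
  } else {
    paste(as.character(value), collapse = "\\")
  }
  v <- charToRaw(s)
  if (length(v) %% 2 == 1) v <- c(v, if (vr == "UI") as.raw(0) else charToRaw(" "))
  v
}

encode_element <- function(group, element, vr, value) {
  payload <- if (vr == "UL") uint32_raw(value) else encode_value(vr, value)
  head <- c(uint16_raw(group), uint16_raw(element), charToRaw(vr))
  if (vr %in% LONG_FORM_VRS) {
    c(head, as.raw(c(0, 0)), uint32_raw(length(payload)), payload)
  } else {
    if (length(payload) > 65534) stopf("value too long for short-form VR %s", vr)
    c(head, uint16_raw(length(payload)), payload)
  }
}

#' Write a minimal DICOM part-10 file
#'
#' Writes an explicit-VR little-endian part-10 file holding the given header
#' attributes and (optionally) an 8- or 16-bit monochrome image. Only
#' attributes in the toolkit's dictionary are supported; this is the writer
#' the synthetic repository generator uses.
#'
#' @param path output file path.
#' @param attributes named list of header attribute values (dictionary
#'   names, e.g. `Modality`, `PatientID`, `StudyDate`, `SliceThickness`).
#' @param pixels optional integer matrix (rows x columns) of intensities;
#'   written as unsigned 8-bit when all values fit in 0..255, else 16-bit.
#' @return `path`, invisibly.
#' @export
dicom_write <- function(path, attributes = list(), pixels = NULL) {
  attrs <- attributes
  if (!is.null(pixels)) {
    pixels <- round(pixels)
    attrs$Rows <- nrow(pixels)
    attrs$Columns <- ncol(pixels)
    attrs$SamplesPerPixel <- attrs$SamplesPerPixel %||% 1L
    attrs$PhotometricInterpretation <- attrs$PhotometricInterpretation %||% "MONOCHROME2"
    bits <- if (max(pixels) <= 255 && min(pixels) >= 0) 8L else 16L
    attrs$BitsAllocated <- bits
    attrs$BitsStored <- bits
    attrs$HighBit <- bits - 1L
    attrs$PixelRepresentation <- 0L
  }
  attrs$SOPClassUID <- attrs$SOPClassUID %||% SOP_CLASS_CT
  attrs$SOPInstanceUID <- attrs$SOPInstanceUID %||%
    attrs$MediaStorageSOPInstanceUID %||% "1.2.826.0.1.999999.1"
  msuid <- attrs$MediaStorageSOPInstanceUID %||% attrs$SOPInstanceUID
  attrs$MediaStorageSOPInstanceUID <- NULL

  # file meta group (always explicit VR LE)
  meta <- c(
    encode_element(0x0002L, 0x0001L, "OB", as.raw(c(0, 1))),
    encode_element(0x0002L, 0x0002L, "UI", attrs$SOPClassUID),
    encode_element(0x0002L, 0x0003L, "UI", msuid),
    encode_element(0x0002L, 0x0010L, "UI", TS_EXPLICIT_LE),
    encode_element(0x0002L, 0x0012L, "UI", "1.2.826.0.1.3680043.10.9999.1"))
  header <- c(raw(128), charToRaw("DICM"),
              encode_element(0x0002L, 0x0000L, "UL", length(meta)), meta)

  # dataset, ascending tag order
  ds_names <- names(attrs)
  rows <- do.call(rbind, lapply(ds_names, function(nm) dict_by_name(nm)))
  ord <- order(rows$group * 2^16 + rows$element)
  body <- raw(0)
  for (i in ord) {
    nm <- ds_names[i]
    body <- c(body, encode_element(rows$group[i], rows$element[i],
                                   rows$vr[i], attrs[[nm]]))
  }
  if (!is.null(pixels)) {
    vals <- as.vector(t(pixels))  # row-major, as pixel data is stored
    payload <- if (attrs$BitsAllocated == 8) as.raw(vals) else
      writeBin(as.integer(vals), raw(), size = 2, endian = "little")
    body <- c(body, encode_element(0x7FE0L, 0x0010L,
                                   if (attrs$BitsAllocated == 8) "OB" else "OW",
                                   payload))
  }
  writeBin(c(header, body), path)
  invisible(path)
}

read_u16 <- function(r, off) as.integer(r[off + 1]) + 256L * as.integer(r[off + 2])
read_u32 <- function(r, off) {
  as.numeric(r[off + 1]) + 256 * as.numeric(r[off + 2]) +
    65536 * as.numeric(r[off + 3]) + 16777216 * as.numeric(r[off + 4])
}

decode_value <- function(vr, payload) {
  if (vr %in% c("OB", "OW", "UN", "SQ")) return(payload)
  if (vr == "US") {
    n <- length(payload) / 2
    return(vapply(seq_len(n), function(i) read_u16(payload, 2 * (i - 1)), 0L))
  }
  if (vr == "UL") return(read_u32(payload, 0))
  s <- rawToChar(payload[payload != as.raw(0)])
  s <- trimws(s)
  if (vr %in% c("DS", "IS")) {
    vals <- suppressWarnings(as.numeric(strsplit(s, "\\\\")[[1]]))
    return(vals)
  }
  s
}

#' Read a DICOM part-10 file
#'
#' Parses an explicit-VR little-endian part-10 file and returns the decoded
#' header attributes (dictionary names) plus the raw pixel payload. Files
#' using other transfer syntaxes, or lacking the `DICM` magic, raise an
#' error naming the path.
#'
#' @param path file path.
#' @return object of class `qc_dicom`: a list with `path`, `attributes`
#'   (named list; absent tags are simply absent, never defaulted) and the
#'   raw `pixel_data` payload (or `NULL`).
#' @seealso [dicom_pixels()] to decode the image matrix.
#' @export
dicom_read <- function(path) {
  r <- readBin(path, "raw", n = file.size(path))
  if (length(r) < 132 || rawToChar(r[129:132]) != "DICM")
    stopf("not a DICOM part-10 file: %s", path)
  off <- 132L
  attrs <- list()
  pixel_raw <- NULL
  n <- length(r)
  while (off < n) {
    group <- read_u16(r, off); element <- read_u16(r, off + 2L)
    vr <- rawToChar(r[(off + 5L):(off + 6L)])
    if (!grepl("^[A-Z]{2}$", vr))
      stopf("unsupported (implicit VR?) encoding in %s at offset %d", path, off)
    if (vr %in% LONG_FORM_VRS) {
      len <- read_u32(r, off + 8L)
      start <- off + 12L
    } else {
      len <- read_u16(r, off + 6L)
      start <- off + 8L
    }
    payload <- if (len > 0) r[(start + 1L):(start + len)] else raw(0)
    entry <- dict_lookup(group, element)
    if (group == 0x7FE0L && element == 0x0010L) {
      pixel_raw <- payload
    } else if (!is.null(entry)) {
      attrs[[entry$name]] <- decode_value(vr, payload)
    } # unknown tags are skipped by length
    off <- start + len
  }
  ts <- attrs$TransferSyntaxUID
  if (!is.null(ts) && !identical(ts, TS_EXPLICIT_LE))
    stopf("unsupported transfer syntax %s in %s", ts, path)
  structure(list(path = path, attributes = attrs, pixel_data = pixel_raw),
            class = "qc_dicom")
}

#' Decode the pixel matrix of a read DICOM file
#'
#' @param d object returned by [dicom_read()].
#' @param rescale apply `RescaleSlope`/`RescaleIntercept` when present.
#' @return numeric matrix (`Rows` x `Columns`), or `NULL` when the file has
#'   no pixel data.
#' @export
dicom_pixels <- function(d, rescale = TRUE) {
  a <- d$attributes
  if (is.null(d$pixel_data) || is.null(a$Rows)) return(NULL)
  bits <- a$BitsAllocated %||% 8L
  nr <- a$Rows; nc <- a$Columns
  vals <- if (bits == 8) as.integer(d$pixel_data[seq_len(nr * nc)]) else {
    readBin(d$pixel_data, "integer", n = nr * nc, size = 2,
            signed = FALSE, endian = "little")
  }
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  if (rescale) {
    slope <- a$RescaleSlope %||% 1
    inter <- a$RescaleIntercept %||% 0
    m <- m * slope + inter
  }
  m
}

#' @export
print.qc_dicom <- function(x, ...) {
  a <- x$attributes
  cat(sprintf("<qc_dicom> %s\n  modality %s, %sx%s, UID %s\n", x$path,
              a$Modality %||% "?", a$Rows %||% "?", a$Columns %||% "?",
              a$MediaStorageSOPInstanceUID %||% a$SOPInstanceUID %||% "?"))
  invisible(x)
}
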