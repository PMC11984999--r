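# Single-frame DICOM codec: explicit-VR little-endian, uncompressed 16-bit
# monochrome pixel data, and the attribute set the harmonization pipeline
# consumes. Not a general DICOM implementation (no sequences, no encapsulated
# transfer syntaxes).

TRANSFER_SYNTAX_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
MAMMO_SOP_CLASS <- "1.2.840.10008.5.1.4.1.1.1.2"

# the attribute set driving pre-processing, by (group, element)
DICOM_REQUIRED <- data.frame(
  group = c(0x0028, 0x0028, 0x2050, 0x0028, 0x0028, 0x0028, 0x0020),
  element = c(0x1052, 0x1053, 0x0020, 0x1041, 0x0004, 0x0030, 0x0062),
  name = c("Rescale Intercept", "Rescale Slope", "Presentation LUT Shape",
           "Pixel Intensity Relationship Sign", "Photometric Interpretation",
           "Pixel Spacing", "Image Laterality"),
  stringsAsFactors = FALSE)

#' DICOM metadata governing pre-processing
#'
#' The attribute set that decides every harmonization step: the stored-value
#' rescale transform, the three inversion-triggering attributes, pixel
#' spacing and image laterality.
#'
#' @param rescale_intercept,rescale_slope numeric; the linear transform from
#'   stored values to output units (codes `(0028,1052)` / `(0028,1053)`).
#' @param presentation_lut_shape `"IDENTITY"` or `"INVERSE"` (`(2050,0020)`).
#' @param pixel_intensity_relationship_sign integer -1 or +1 (`(0028,1041)`).
#' @param photometric_interpretation `"MONOCHROME1"` or `"MONOCHROME2"`
#'   (`(0028,0004)`).
#' @param pixel_spacing `(row_mm, col_mm)`, both positive (`(0028,0030)`).
#' @param laterality `"L"` or `"R"` (`(0020,0062)`).
#' @return an object of class `fm_dicom_meta`.
#' @export
dicom_meta <- function(rescale_intercept = 0, rescale_slope = 1,
                       presentation_lut_shape = "IDENTITY",
                       pixel_intensity_relationship_sign = -1L,
                       photometric_interpretation = "MONOCHROME2",
                       pixel_spacing = c(0.703125, 0.703125),
                       laterality = "L") {
  if (!laterality %in% c("L", "R"))
    stop_fm("laterality must be 'L' or 'R', got '%s'", laterality)
  if (!pixel_intensity_relationship_sign %in% c(-1L, 1L))
    stop_fm("pixel intensity relationship sign must be -1 or +1")
  if (!photometric_interpretation %in% c("MONOCHROME1", "MONOCHROME2"))
    stop_fm("unknown Photometric Interpretation '%s'",
            photometric_interpretation)
  if (!presentation_lut_shape %in% c("IDENTITY", "INVERSE"))
    stop_fm("Presentation LUT Shape must be IDENTITY or INVERSE")
  if (any(pixel_spacing <= 0)) stop_fm("pixel spacing must be positive")
  if (rescale_slope == 0) stop_fm("rescale slope must be non-zero")
  structure(list(rescale_intercept = as.numeric(rescale_intercept),
                 rescale_slope = as.numeric(rescale_slope),
                 presentation_lut_shape = presentation_lut_shape,
                 pixel_intensity_relationship_sign =
                   as.integer(pixel_intensity_relationship_sign),
                 photometric_interpretation = photometric_interpretation,
                 pixel_spacing = as.numeric(pixel_spacing),
                 laterality = laterality),
            class = "fm_dicom_meta")
}

#' @export
print.fm_dicom_meta <- function(x, ...) {
  cat(sprintf(paste0("<fm_dicom_meta slope=%s intercept=%s %s %s sign=%+d ",
                     "spacing=[%s] laterality=%s>\n"),
              format(x$rescale_slope), format(x$rescale_intercept),
              x$photometric_interpretation, x$presentation_lut_shape,
              x$pixel_intensity_relationship_sign,
              paste(format(x$pixel_spacing), collapse = ", "), x$laterality))
  invisible(x)
}

ds_string <- function(x) format(x, scientific = FALSE, trim = TRUE)

uint16_le <- function(x) writeBin(as.integer(x), raw(), size = 2,
                                  endian = "little")
uint32_le <- function(x) writeBin(as.integer(x), raw(), size = 4,
                                  endian = "little")

dicom_element <- function(group, element, vr, value) {
  if (vr %in% c("US", "SS")) {
    val <- writeBin(as.integer(value), raw(), size = 2, endian = "little")
  } else if (vr == "UL") {
    val <- uint32_le(value)
  } else if (vr == "OW") {
    val <- writeBin(as.integer(value), raw(), size = 2, endian = "little")
  } else { # string VRs
    val <- charToRaw(as.character(value))
    if (length(val) %% 2 == 1)
      val <- c(val, if (vr == "UI") as.raw(0) else charToRaw(" "))
  }
  head_ <- c(uint16_le(group), uint16_le(element), charToRaw(vr))
  if (vr %in% c("OB", "OW", "SQ", "UN", "UT")) {
    c(head_, as.raw(c(0, 0)), uint32_le(length(val)), val)
  } else {
    c(head_, uint16_le(length(val)), val)
  }
}

#' Write an image record as a DICOM file
#'
#' Emits a standards-shaped single-frame file: 128-byte preamble, `DICM`
#' magic, an explicit-little-endian file meta group, the pre-processing
#' attribute set, patient/hospital identifiers, and 16-bit unsigned pixel
#' data. Stored values must be integers in `[0, 65535]`.
#'
#' @param record an `fm_image` with populated `meta`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dicom <- function(record, path) {
  stopifnot(inherits(record, "fm_image"))
  if (!inherits(record$meta, "fm_dicom_meta"))
    stop_fm("record has no populated DicomMeta; cannot write DICOM")
  px <- record$pixels
  if (any(px != round(px)) || any(px < 0) || any(px > 65535))
    stop_fm("pixel values must be integers in [0, 65535] for 16-bit storage")
  m <- record$meta
  # content-derived instance UID keeps file bytes deterministic
  checksum <- (sum(px) + nrow(px) * 7 + ncol(px) * 13) %% 1e8
  instance_uid <- sprintf("1.2.826.0.1.3680043.9.7484.%.0f", checksum)

  meta_elems <- c(
    dicom_element(0x0002, 0x0002, "UI", MAMMO_SOP_CLASS),
    dicom_element(0x0002, 0x0003, "UI", instance_uid),
    dicom_element(0x0002, 0x0010, "UI", TRANSFER_SYNTAX_EXPLICIT_LE))
  comments <- sprintf("BIRADS=%s", ifelse(is.na(record$birads), "NA",
                                          record$birads))
  body <- c(
    dicom_element(0x0008, 0x0016, "UI", MAMMO_SOP_CLASS),
    dicom_element(0x0008, 0x0018, "UI", instance_uid),
    dicom_element(0x0008, 0x0080, "LO", ifelse(is.na(record$hospital_id), "",
                                               record$hospital_id)),
    dicom_element(0x0010, 0x0020, "LO", ifelse(is.na(record$patient_id), "",
                                               record$patient_id)),
    dicom_element(0x0020, 0x0062, "CS", m$laterality),
    dicom_element(0x0020, 0x4000, "LT", comments),
    dicom_element(0x0028, 0x0002, "US", 1L),
    dicom_element(0x0028, 0x0004, "CS", m$photometric_interpretation),
    dicom_element(0x0028, 0x0010, "US", nrow(px)),
    dicom_element(0x0028, 0x0011, "US", ncol(px)),
    dicom_element(0x0028, 0x0030, "DS",
                  paste(ds_string(m$pixel_spacing), collapse = "\\")),
    dicom_element(0x0028, 0x0100, "US", 16L),
    dicom_element(0x0028, 0x0101, "US", 16L),
    dicom_element(0x0028, 0x0102, "US", 15L),
    dicom_element(0x0028, 0x0103, "US", 0L),
    dicom_element(0x0028, 0x1041, "SS", m$pixel_intensity_relationship_sign),
    dicom_element(0x0028, 0x1052, "DS", ds_string(m$rescale_intercept)),
    dicom_element(0x0028, 0x1053, "DS", ds_string(m$rescale_slope)),
    dicom_element(0x2050, 0x0020, "CS", m$presentation_lut_shape),
    dicom_element(0x7FE0, 0x0010, "OW", as.vector(t(px))))

  out <- c(raw(128), charToRaw("DICM"),
           dicom_element(0x0002, 0x0000, "UL", length(meta_elems)),
           meta_elems, body)
  writeBin(out, path)
  invisible(path)
}

parse_dicom_elements <- function(bytes) {
  long_vrs <- c("OB", "OW", "SQ", "UN", "UT")
  pos <- 133L # after preamble + "DICM"
  n <- length(bytes)
  elems <- list()
  while (pos + 7 <= n) {
    group <- readBin(bytes[pos:(pos + 1)], "integer", size = 2,
                     endian = "little", signed = FALSE)
    element <- readBin(bytes[(pos + 2):(pos + 3)], "integer", size = 2,
                       endian = "little", signed = FALSE)
    vr <- rawToChar(bytes[(pos + 4):(pos + 5)])
    if (vr %in% long_vrs) {
      len <- readBin(bytes[(pos + 8):(pos + 11)], "integer", size = 4,
                     endian = "little")
      vstart <- pos + 12L
    } else {
      len <- readBin(bytes[(pos + 6):(pos + 7)], "integer", size = 2,
                     endian = "little", signed = FALSE)
      vstart <- pos + 8L
    }
    raw_val <- if (len > 0) bytes[vstart:(vstart + len - 1L)] else raw(0)
    value <- switch(vr,
      US = readBin(raw_val, "integer", n = len / 2, size = 2,
                   endian = "little", signed = FALSE),
      SS = readBin(raw_val, "integer", n = len / 2, size = 2,
                   endian = "little", signed = TRUE),
      UL = readBin(raw_val, "integer", n = len / 4, size = 4,
                   endian = "little"),
      OW = readBin(raw_val, "integer", n = len / 2, size = 2,
                   endian = "little", signed = FALSE),
      trimws(rawToChar(raw_val), whitespace = "[ \\x00]"))
    elems[[sprintf("%04X,%04X", group, element)]] <- value
    pos <- vstart + len
  }
  elems
}

#' Read a DICOM file into an image record
#'
#' Parses an explicit-little-endian single-frame file and validates that the
#' complete pre-processing attribute set is present; a missing attribute
#' raises an error naming its `(group, element)` code.
#'
#' @param path file path.
#' @return an `fm_image` with pixels, metadata and identifiers.
#' @export
read_dicom <- function(path) {
  bytes <- readBin(path, raw(), file.size(path))
  if (length(bytes) < 132 || rawToChar(bytes[129:132]) != "DICM")
    stop_fm("'%s' is not a DICOM file (missing DICM magic)", path)
  el <- parse_dicom_elements(bytes)

  for (i in seq_len(nrow(DICOM_REQUIRED))) {
    key <- sprintf("%04X,%04X", DICOM_REQUIRED$group[i],
                   DICOM_REQUIRED$element[i])
    if (is.null(el[[key]]))
      stop_fm("missing mandatory DICOM attribute (%04x, %04x) %s",
              DICOM_REQUIRED$group[i], DICOM_REQUIRED$element[i],
              DICOM_REQUIRED$name[i])
  }
  for (key in c("0028,0010", "0028,0011", "7FE0,0010"))
    if (is.null(el[[key]]))
      stop_fm("missing mandatory DICOM attribute (%s)", key)

  rows <- el[["0028,0010"]]; cols <- el[["0028,0011"]]
  pixels <- matrix(el[["7FE0,0010"]], nrow = rows, ncol = cols, byrow = TRUE)
  spacing <- as.numeric(strsplit(el[["0028,0030"]], "\\\\")[[1]])
  meta <- dicom_meta(
    rescale_intercept = as.numeric(el[["0028,1052"]]),
    rescale_slope = as.numeric(el[["0028,1053"]]),
    presentation_lut_shape = el[["2050,0020"]],
    pixel_intensity_relationship_sign = el[["0028,1041"]],
    photometric_interpretation = el[["0028,0004"]],
    pixel_spacing = spacing,
    laterality = el[["0020,0062"]])
  birads <- NA_integer_
  if (!is.null(el[["0020,4000"]])) {
    b <- sub("^BIRADS=", "", el[["0020,4000"]])
    if (grepl("^[0-9]+$", b)) birads <- as.integer(b)
  }
  fm_image(pixels = pixels, meta = meta,
           patient_id = if (!is.null(el[["0010,0020"]]) &&
                            nzchar(el[["0010,0020"]])) el[["0010,0020"]]
                        else NA_character_,
           hospital_id = if (!is.null(el[["0008,0080"]]) &&
                             nzchar(el[["0008,0080"]])) el[["0008,0080"]]
                         else NA_character_,
           birads = birads)
}
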