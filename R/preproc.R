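#' Apply the DICOM rescale transform
#'
#' `output = slope * stored + intercept`, element-wise; the standard linear
#' map from stored pixel values to output units.
#'
#' @param pixels numeric matrix of stored values.
#' @param slope,intercept rescale slope (non-zero) and intercept.
#' @return numeric matrix, same shape.
#' @export
apply_rescale <- function(pixels, slope, intercept) {
  if (slope == 0) stop_fm("rescale slope 0 is a degenerate transform")
  pixels * slope + intercept
}

#' Decide whether presentation inversion is needed
#'
#' An image is displayed inverted (and must be normalized) when the Pixel
#' Intensity Relationship Sign equals +1, or the Photometric Interpretation
#' is `MONOCHROME1`, or the Presentation LUT Shape is `INVERSE`.
#'
#' @param meta an [dicom_meta()] object.
#' @return logical.
#' @export
should_invert <- function(meta) {
  stopifnot(inherits(meta, "fm_dicom_meta"))
  if (!meta$photometric_interpretation %in% c("MONOCHROME1", "MONOCHROME2"))
    stop_fm("unknown Photometric Interpretation '%s'",
            meta$photometric_interpretation)
  meta$pixel_intensity_relationship_sign == 1L ||
    meta$photometric_interpretation == "MONOCHROME1" ||
    meta$presentation_lut_shape == "INVERSE"
}

#' Invert pixel values against the image maximum
#'
#' Each pixel is subtracted from the maximum pixel value of the image (not
#' the theoretical bit-depth maximum), so the output minimum is always 0.
#'
#' @param pixels non-empty numeric matrix.
#' @return inverted matrix, same shape.
#' @export
invert_pixels <- function(pixels) {
  if (length(pixels) == 0) stop_fm("cannot invert an empty pixel array")
  max(pixels) - pixels
}

#' Align image laterality breast-left
#'
#' Horizontally (column-reversing) flips the image iff `laterality == "R"`,
#' so the breast is always attached to the left border.
#'
#' @param pixels numeric or logical matrix.
#' @param laterality `"L"` or `"R"`.
#' @return matrix, flipped if needed.
#' @export
align_laterality <- function(pixels, laterality) {
  if (!laterality %in% c("L", "R"))
    stop_fm("laterality must be 'L' or 'R', got '%s'", laterality)
  if (laterality == "R") pixels[, ncol(pixels):1, drop = FALSE] else pixels
}

#' Pixel-spacing-aware resize
#'
#' If the spacing is anisotropic the image is first resampled to isotropic
#' spacing at the coarser of the two spacings (preserving the physical
#' aspect ratio), then rescaled to `target_size`.
#'
#' @param pixels numeric matrix.
#' @param spacing `(row_mm, col_mm)`, both positive.
#' @param target_size `(rows, cols)`, at least 8x8.
#' @param method interpolation, `"bilinear"` or `"nearest"` (for masks).
#' @return matrix of shape `target_size`.
#' @export
resize_with_spacing <- function(pixels, spacing, target_size = c(512, 512),
                                method = "bilinear") {
  if (any(spacing <= 0)) stop_fm("pixel spacing must be positive")
  if (any(target_size < 8)) stop_fm("target size must be at least 8x8")
  if (abs(spacing[1] - spacing[2]) > 1e-9 * max(spacing)) {
    iso <- max(spacing)
    inter <- round(c(nrow(pixels) * spacing[1], ncol(pixels) * spacing[2]) / iso)
    pixels <- resize2d(pixels, pmax(inter, 1), method = method)
  }
  resize2d(pixels, target_size, method = method)
}

#' Percentile intensity windowing
#'
#' Clamps intensities to the `[lo, hi]` percentile window (removing hot
#' pixels and dead-pixel outliers), optionally mapping the window to
#' `[0, 1]` as display windowing does. The mapping is what actually
#' harmonizes hospital-specific detector ranges onto one scale.
#'
#' @param pixels numeric matrix.
#' @param probs two percentiles in `[0, 1]`, default `c(0.005, 0.995)`.
#' @param rescale map the window to `[0, 1]` after clamping.
#' @return clamped (and possibly rescaled) matrix.
#' @export
clip_percentiles <- function(pixels, probs = c(0.005, 0.995),
                             rescale = FALSE) {
  q <- quantile(pixels, probs, names = FALSE)
  out <- pmin(pmax(pixels, q[1]), q[2])
  if (rescale && q[2] > q[1]) out <- (out - q[1]) / (q[2] - q[1])
  out
}

#' Full metadata-driven harmonization of one record
#'
#' Applies, in order: rescale transform, inversion decision and application,
#' percentile windowing onto `[0, 1]` (which aligns hospital-specific
#' detector ranges onto one intensity scale), laterality alignment,
#' spacing-aware resize. The
#' ground-truth mask (when present) is carried through flip and resize with
#' nearest-neighbour interpolation so it stays binary and aligned. The
#' returned record's metadata is rewritten to the post-harmonization
#' convention (slope 1, intercept 0, MONOCHROME2, IDENTITY, sign -1,
#' laterality L, isotropic unit spacing scaled to the resize), which makes
#' the operation idempotent on its own output.
#'
#' @param record an `fm_image` with complete metadata.
#' @param target_size output `(rows, cols)`, default `c(512, 512)`.
#' @param clip percentile window passed to [clip_percentiles()], or `NULL`
#'   to skip windowing.
#' @return the harmonized `fm_image`; the applied steps are recorded in
#'   `attr(, "provenance")`.
#' @export
preprocess <- function(record, target_size = c(512, 512),
                       clip = c(0.005, 0.995)) {
  stopifnot(inherits(record, "fm_image"))
  if (!inherits(record$meta, "fm_dicom_meta"))
    stop_fm("record has no DicomMeta; preprocessing is metadata-driven")
  m <- record$meta
  steps <- character(0)
  px <- apply_rescale(record$pixels, m$rescale_slope, m$rescale_intercept)
  steps <- c(steps, sprintf("rescale(slope=%s, intercept=%s)",
                            format(m$rescale_slope),
                            format(m$rescale_intercept)))
  if (should_invert(m)) {
    px <- invert_pixels(px)
    steps <- c(steps, "invert(max - x)")
  }
  if (!is.null(clip)) {
    px <- clip_percentiles(px, clip, rescale = TRUE)
    steps <- c(steps, sprintf("window(percentiles=[%g, %g] -> [0, 1])",
                              clip[1], clip[2]))
  }
  mask <- record$mask
  if (m$laterality == "R") {
    px <- align_laterality(px, "R")
    if (!is.null(mask)) mask <- align_laterality(mask, "R")
    steps <- c(steps, "flip_horizontal(laterality=R)")
  }
  old_size <- dim(px)
  px <- resize_with_spacing(px, m$pixel_spacing, target_size)
  if (!is.null(mask))
    mask <- resize_with_spacing(mask, m$pixel_spacing, target_size,
                                method = "nearest")
  steps <- c(steps, sprintf("resize(%dx%d -> %dx%d, spacing=[%s])",
                            old_size[1], old_size[2], target_size[1],
                            target_size[2],
                            paste(format(m$pixel_spacing), collapse = ", ")))

  # record isotropic output spacing: after the final resize the grid is the
  # model input raster, and an isotropic tag makes preprocess() idempotent
  new_spacing <- rep(max(m$pixel_spacing) *
                       mean(old_size / target_size), 2)
  out <- fm_image(pixels = px,
                  meta = dicom_meta(rescale_intercept = 0, rescale_slope = 1,
                                    presentation_lut_shape = "IDENTITY",
                                    pixel_intensity_relationship_sign = -1L,
                                    photometric_interpretation = "MONOCHROME2",
                                    pixel_spacing = pmax(new_spacing, 1e-6),
                                    laterality = "L"),
                  patient_id = record$patient_id,
                  hospital_id = record$hospital_id,
                  birads = record$birads, flags = record$flags, mask = mask)
  attr(out, "provenance") <- steps
  out
}
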