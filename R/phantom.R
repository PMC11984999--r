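#' Hospital heterogeneity profile
#'
#' Describes one synthetic "hospital": its raw detector intensity range, the
#' photometric convention its scanners emit, per-image artifact rates and the
#' pixel spacing. Disjoint intensity ranges and mixed photometric conventions
#' across profiles reproduce the non-IID heterogeneity that breaks naive
#' federated training.
#'
#' @param hospital_id character label.
#' @param intensity_range numeric `(low, high)` raw pixel units, `low < high`.
#' @param photometric `"MONOCHROME1"` (low values display bright) or
#'   `"MONOCHROME2"`.
#' @param label_prob probability an image carries a printed laterality/view
#'   label in the background.
#' @param clip_prob probability of surgical-clip spots inside the breast.
#' @param implant_prob per-patient probability of a bright implant disk.
#' @param mis_scan_prob per-patient probability the breast is truncated.
#' @param spacing_mm pixel spacing `(row_mm, col_mm)`, both positive.
#' @return an object of class `fm_hospital_profile`.
#' @export
hospital_profile <- function(hospital_id,
                             intensity_range = c(0, 4095),
                             photometric = c("MONOCHROME2", "MONOCHROME1"),
                             label_prob = 0.5, clip_prob = 0.2,
                             implant_prob = 0.05, mis_scan_prob = 0.05,
                             spacing_mm = c(0.703125, 0.703125)) {
  photometric <- match.arg(photometric)
  probs <- c(label_prob, clip_prob, implant_prob, mis_scan_prob)
  if (intensity_range[1] >= intensity_range[2])
    stop_fm("intensity_range must satisfy low < high")
  if (any(probs < 0 | probs > 1))
    stop_fm("artifact probabilities must lie in [0, 1]")
  if (any(spacing_mm <= 0)) stop_fm("spacing_mm must be positive")
  structure(list(hospital_id = as.character(hospital_id),
                 intensity_range = as.numeric(intensity_range),
                 photometric = photometric,
                 label_prob = label_prob, clip_prob = clip_prob,
                 implant_prob = implant_prob, mis_scan_prob = mis_scan_prob,
                 spacing_mm = as.numeric(spacing_mm)),
            class = "fm_hospital_profile")
}

#' Phantom specification
#'
#' Geometry and class label of one phantom mammogram. The lesion burden
#' (count and brightness) is a deterministic, non-decreasing function of the
#' BIRADS class so that the class signal is learnable and parameter recovery
#' by the classifier is meaningful: class `b` carries `2 * (b - 1)` lesions
#' whose brightness increases with `b`.
#'
#' @param image_size `(rows, cols)`, each at least 32.
#' @param laterality `"L"` or `"R"` — which border the breast touches.
#' @param birads integer 1-5.
#' @param seed integer; the single source of randomness for this phantom.
#' @return an object of class `fm_phantom_spec`.
#' @export
phantom_spec <- function(image_size = c(128, 128), laterality = c("L", "R"),
                         birads = 1, seed = 1) {
  laterality <- match.arg(laterality)
  if (!birads %in% 1:5) stop_fm("birads must be an integer in 1..5")
  if (any(image_size < 32))
    stop_fm("image_size %dx%d too small to host the breast phantom (minimum 32)",
            image_size[1], image_size[2])
  structure(list(image_size = as.integer(image_size), laterality = laterality,
                 birads = as.integer(birads),
                 n_lesions = 2L * (as.integer(birads) - 1L),
                 lesion_radius_frac = c(0.045, 0.060),
                 lesion_brightness = 0.12 + 0.06 * (as.integer(birads) - 1L),
                 seed = as.integer(seed)),
            class = "fm_phantom_spec")
}

smooth_noise <- function(rows, cols, sigma) {
  n <- EBImage::gblur(matrix(runif(rows * cols), rows, cols), sigma = sigma)
  rng <- range(n)
  if (diff(rng) == 0) return(matrix(0.5, rows, cols))
  (n - rng[1]) / diff(rng)
}

disk_indices <- function(rows, cols, cy, cx, radius) {
  r0 <- max(1, floor(cy - radius)); r1 <- min(rows, ceiling(cy + radius))
  c0 <- max(1, floor(cx - radius)); c1 <- min(cols, ceiling(cx + radius))
  rr <- r0:r1; cc <- c0:c1
  d2 <- outer((rr - cy)^2, (cc - cx)^2, `+`)
  cbind(rep(rr, times = length(cc))[d2 <= radius^2],
        rep(cc, each = length(rr))[d2 <= radius^2])
}

#' Generate one phantom mammogram
#'
#' Builds a smooth, textured half-elliptical breast blob attached to the
#' left (laterality `"L"`) or right (`"R"`) image border, inserts lesions
#' according to the BIRADS class, and adds artifacts (printed label, surgical
#' clips, implant, truncated scan) by drawing from the profile's rates. The
#' ground-truth mask marks exactly the breast region and never the printed
#' label. Raw stored pixel values fall inside the profile's intensity range;
#' under `MONOCHROME1` the stored values are presentation-inverted (breast
#' dark) as a real scanner would emit them.
#'
#' @param spec a [phantom_spec()].
#' @param profile a [hospital_profile()].
#' @param patient_id optional patient identifier stored on the record.
#' @param force_flags optional named list overriding the stochastic artifact
#'   draws (`label`, `clips`, `implant`, `mis_scan` as logicals); used by the
#'   cohort generator to hold patient-level flags fixed across images.
#' @return an `fm_image` record: integer-valued pixel matrix, `fm_dicom_meta`,
#'   ids, BIRADS label, artifact flags (with recorded geometry) and the
#'   ground-truth logical mask.
#' @export
generate_phantom <- function(spec, profile, patient_id = NA_character_,
                             force_flags = list()) {
  stopifnot(inherits(spec, "fm_phantom_spec"),
            inherits(profile, "fm_hospital_profile"))
  rows <- spec$image_size[1]; cols <- spec$image_size[2]
  withr::with_seed(spec$seed, {
    draw <- function(name, prob) {
      if (!is.null(force_flags[[name]])) force_flags[[name]] else runif(1) < prob
    }
    cy <- rows * (0.5 + runif(1, -0.05, 0.05))
    a  <- rows * runif(1, 0.38, 0.44)   # vertical semi-axis
    b  <- cols * runif(1, 0.50, 0.58)   # horizontal semi-axis
    rr <- matrix(seq_len(rows), rows, cols)
    cc <- matrix(seq_len(cols), rows, cols, byrow = TRUE)
    mask <- ((rr - cy) / a)^2 + ((cc - 1) / b)^2 <= 1

    flags <- list(label = draw("label", profile$label_prob),
                  clips = draw("clips", profile$clip_prob),
                  implant = draw("implant", profile$implant_prob),
                  mis_scan = draw("mis_scan", profile$mis_scan_prob),
                  label_box = NULL, clip_centers = NULL, implant_center = NULL)
    if (flags$mis_scan) mask[rr > cy + 0.35 * a] <- FALSE

    rel <- 0.02 + 0.04 * smooth_noise(rows, cols, sigma = rows / 24)
    tex <- smooth_noise(rows, cols, sigma = rows / 16)
    rel[mask] <- 0.50 + 0.35 * tex[mask]

    inner <- mask & ((rr - cy) / a)^2 + ((cc - 1) / b)^2 <= 0.6
    place_in <- function(region, radius) {
      ok <- which(region, arr.ind = TRUE)
      ok <- ok[ok[, 1] > radius + 1 & ok[, 1] < rows - radius &
               ok[, 2] > radius + 1 & ok[, 2] < cols - radius, , drop = FALSE]
      if (nrow(ok) == 0) return(NULL)
      ok[sample.int(nrow(ok), 1), ]
    }
    if (spec$n_lesions > 0) {
      for (i in seq_len(spec$n_lesions)) {
        rad <- runif(1, spec$lesion_radius_frac[1], spec$lesion_radius_frac[2]) * rows
        ctr <- place_in(inner, rad)
        if (is.null(ctr)) next
        px <- disk_indices(rows, cols, ctr[1], ctr[2], rad)
        px <- px[mask[px], , drop = FALSE]
        rel[px] <- pmin(1, rel[px] + spec$lesion_brightness)
      }
    }
    if (flags$clips) {
      k <- sample(2:5, 1)
      centers <- matrix(NA_real_, 0, 2)
      for (i in seq_len(k)) {
        rad <- runif(1, 0.010, 0.018) * rows
        ctr <- place_in(inner, rad)
        if (is.null(ctr)) next
        px <- disk_indices(rows, cols, ctr[1], ctr[2], rad)
        px <- px[mask[px], , drop = FALSE]
        rel[px] <- 0.98
        centers <- rbind(centers, ctr)
      }
      flags$clips <- nrow(centers) > 0
      if (flags$clips) flags$clip_centers <- centers
    }
    if (flags$implant) {
      rad <- 0.14 * rows
      ctr <- place_in(inner, rad)
      if (!is.null(ctr)) {
        px <- disk_indices(rows, cols, ctr[1], ctr[2], rad)
        px <- px[mask[px], , drop = FALSE]
        rel[px] <- 0.95
        flags$implant_center <- ctr
      } else flags$implant <- FALSE
    }
    if (flags$label) {
      placed <- FALSE
      for (try in 1:100) {
        h <- round(runif(1, 0.06, 0.15) * rows)
        w <- round(runif(1, 0.06, 0.15) * cols)
        r0 <- sample.int(rows - h, 1)
        c0 <- sample.int(cols - w, 1)
        box <- c(r0, r0 + h - 1, c0, c0 + w - 1)
        # keep clearance around the breast so the label sits in open background
        gap <- max(2L, round(0.03 * rows))
        halo <- c(max(1, box[1] - gap), min(rows, box[2] + gap),
                  max(1, box[3] - gap), min(cols, box[4] + gap))
        if (!any(mask[halo[1]:halo[2], halo[3]:halo[4]])) { placed <- TRUE; break }
      }
      if (placed) {
        glyph <- matrix(sample(c(0.85, 1.0), h * w, replace = TRUE), h, w)
        rel[box[1]:box[2], box[3]:box[4]] <- glyph
        flags$label_box <- box
      } else flags$label <- FALSE
    }

    if (spec$laterality == "R") {
      rel <- rel[, cols:1]; mask <- mask[, cols:1]
      if (!is.null(flags$label_box)) {
        bx <- flags$label_box
        flags$label_box <- c(bx[1], bx[2], cols - bx[4] + 1, cols - bx[3] + 1)
      }
      if (!is.null(flags$clip_centers))
        flags$clip_centers[, 2] <- cols - flags$clip_centers[, 2] + 1
      if (!is.null(flags$implant_center))
        flags$implant_center[2] <- cols - flags$implant_center[2] + 1
    }

    lo <- profile$intensity_range[1]; hi <- profile$intensity_range[2]
    if (profile$photometric == "MONOCHROME1") rel <- 1 - rel
    pixels <- round(lo + rel * (hi - lo))

    meta <- dicom_meta(rescale_intercept = 0, rescale_slope = 1,
                       presentation_lut_shape = "IDENTITY",
                       pixel_intensity_relationship_sign = -1L,
                       photometric_interpretation = profile$photometric,
                       pixel_spacing = profile$spacing_mm,
                       laterality = spec$laterality)
    fm_image(pixels = pixels, meta = meta, patient_id = patient_id,
             hospital_id = profile$hospital_id, birads = spec$birads,
             flags = flags, mask = mask)
  })
}

#' Image record constructor
#'
#' @param pixels numeric matrix of stored pixel values.
#' @param meta a [dicom_meta()] object.
#' @param patient_id,hospital_id character identifiers.
#' @param birads integer BIRADS label (or `NA`).
#' @param flags named list of artifact flags and recorded geometry.
#' @param mask optional logical matrix, same shape as `pixels`.
#' @return an object of class `fm_image`.
#' @export
fm_image <- function(pixels, meta = NULL, patient_id = NA_character_,
                     hospital_id = NA_character_, birads = NA_integer_,
                     flags = list(), mask = NULL) {
  stopifnot(is.matrix(pixels))
  if (!is.null(mask) && !identical(dim(mask), dim(pixels)))
    stop_fm("mask shape %s does not match pixels %s",
            paste(dim(mask), collapse = "x"), paste(dim(pixels), collapse = "x"))
  structure(list(pixels = pixels, meta = meta, patient_id = patient_id,
                 hospital_id = hospital_id, birads = birads, flags = flags,
                 mask = mask),
            class = "fm_image")
}

#' @export
print.fm_image <- function(x, ...) {
  cat(sprintf("<fm_image %dx%d patient=%s hospital=%s BIRADS=%s mask=%s>\n",
              nrow(x$pixels), ncol(x$pixels), x$patient_id, x$hospital_id,
              x$birads, if (is.null(x$mask)) "none" else "yes"))
  invisible(x)
}

#' Generate a multi-hospital phantom cohort
#'
#' Draws `n_patients` patients, assigns each to a hospital profile and a
#' BIRADS class, and generates `images_per_patient` phantoms per patient.
#' All images of one patient share hospital, BIRADS label and the
#' patient-level artifact flags (implant, mis-scan), mirroring how real
#' exclusion criteria operate at the patient level.
#'
#' @param n_patients number of patients (>= 1).
#' @param images_per_patient images per patient.
#' @param profiles list of [hospital_profile()] objects (non-empty).
#' @param birads_distribution probability vector over BIRADS 1-5.
#' @param seed integer master seed.
#' @param image_size `(rows, cols)` passed to every [phantom_spec()].
#' @param hospital_weights probability of assigning a patient to each
#'   profile (defaults to uniform); real data providers are rarely equal
#'   in size.
#' @return list with `records` (list of `fm_image`) and `manifest`
#'   (data.frame: patient_id, hospital_id, birads, implant_flag,
#'   mis_scan_flag, image_index).
#' @export
generate_cohort <- function(n_patients, images_per_patient = 1,
                            profiles, birads_distribution = rep(0.2, 5),
                            seed = 1, image_size = c(128, 128),
                            hospital_weights = NULL) {
  if (n_patients < 1) stop_fm("n_patients must be >= 1")
  if (length(profiles) == 0) stop_fm("profiles list must be non-empty")
  if (abs(sum(birads_distribution) - 1) > 1e-6)
    stop_fm("birads_distribution must sum to 1")
  if (is.null(hospital_weights))
    hospital_weights <- rep(1 / length(profiles), length(profiles))
  if (length(hospital_weights) != length(profiles) ||
      any(hospital_weights < 0))
    stop_fm("hospital_weights must be non-negative, one per profile")
  records <- vector("list", n_patients * images_per_patient)
  rows <- vector("list", length(records))
  withr::with_seed(derive_seed(seed, 101L), {
    hosp_idx <- sample.int(length(profiles), n_patients, replace = TRUE,
                           prob = hospital_weights)
    birads <- sample.int(5, n_patients, replace = TRUE, prob = birads_distribution)
    implant <- runif(n_patients) < vapply(profiles[hosp_idx],
                                          `[[`, 0, "implant_prob")
    mis_scan <- runif(n_patients) < vapply(profiles[hosp_idx],
                                           `[[`, 0, "mis_scan_prob")
    lateralities <- matrix(sample(c("L", "R"), n_patients * images_per_patient,
                                  replace = TRUE),
                           n_patients, images_per_patient)
  })
  idx <- 0
  for (p in seq_len(n_patients)) {
    pid <- sprintf("P%04d", p)
    profile <- profiles[[hosp_idx[p]]]
    for (i in seq_len(images_per_patient)) {
      idx <- idx + 1
      spec <- phantom_spec(image_size = image_size,
                           laterality = lateralities[p, i],
                           birads = birads[p],
                           seed = derive_seed(seed, p, i))
      records[[idx]] <- generate_phantom(
        spec, profile, patient_id = pid,
        force_flags = list(implant = implant[p], mis_scan = mis_scan[p]))
      rows[[idx]] <- data.frame(patient_id = pid,
                                hospital_id = profile$hospital_id,
                                birads = birads[p],
                                implant_flag = implant[p],
                                mis_scan_flag = mis_scan[p],
                                image_index = idx,
                                stringsAsFactors = FALSE)
    }
  }
  list(records = records, manifest = do.call(rbind, rows))
}
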