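#' Masked mammogram container
#'
#' @param image numeric intensity matrix.
#' @param mask logical matrix of the same shape.
#' @param provenance `"kmeans"` or `"ground_truth"`.
#' @param quality_score float in `[0, 1]`.
#' @param source_id identifier of the source image (used for leakage-safe
#'   grouping of augmentation variants).
#' @param label_box optional fake-label rectangle `(r0, r1, c0, c1)`.
#' @return object of class `fm_masked`.
#' @export
masked_mammogram <- function(image, mask, provenance = c("kmeans", "ground_truth"),
                             quality_score = 1, source_id = NA_character_,
                             label_box = NULL) {
  provenance <- match.arg(provenance)
  if (!identical(dim(image), dim(mask)))
    stop_fm("image and mask shapes differ")
  structure(list(image = image, mask = mask, provenance = provenance,
                 quality_score = quality_score, source_id = source_id,
                 label_box = label_box),
            class = "fm_masked")
}

#' Fake-label augmentation configuration
#'
#' @param n_variants variants per accepted mammogram (default 5: the
#'   original plus four fake-label copies).
#' @param label_size_range rectangle side as a fraction of the image side,
#'   within `(0, 0.5)`.
#' @param label_intensity_quantile quantile of the breast pixels used as the
#'   label brightness (labels print near-white).
#' @param seed integer seed.
#' @return object of class `fm_aug_config`.
#' @export
augmentation_config <- function(n_variants = 5L,
                                label_size_range = c(0.05, 0.20),
                                label_intensity_quantile = 0.99,
                                seed = 1L) {
  if (n_variants < 1) stop_fm("n_variants must be >= 1")
  if (any(label_size_range <= 0) || any(label_size_range >= 0.5))
    stop_fm("label_size_range must lie within (0, 0.5)")
  structure(list(n_variants = as.integer(n_variants),
                 label_size_range = label_size_range,
                 label_intensity_quantile = label_intensity_quantile,
                 seed = as.integer(seed)),
            class = "fm_aug_config")
}

#' Unsupervised breast mask by intensity K-means
#'
#' Clusters pixel intensities into `k` groups, takes the pixels of the
#' brightest cluster(s) — every cluster whose centre exceeds the darkest
#' centre's midpoint to the brightest, which for `k = 2` is simply the
#' bright cluster — then keeps the largest connected component and fills
#' its holes. On mammograms the breast-plus-tissue compartment is bright
#' and border-attached while printed labels form separate components that
#' the largest-component step discards.
#'
#' @param image numeric matrix with at least 2 distinct values.
#' @param k number of intensity clusters (default 2).
#' @param seed seed for the clustering starts.
#' @return logical mask.
#' @export
kmeans_mask <- function(image, k = 2L, seed = 1L) {
  v <- as.vector(image)
  if (length(unique(v)) < 2)
    stop_fm("constant image: K-means has no cluster separation")
  km <- withr::with_seed(derive_seed(seed, 7L),
                         kmeans(v, centers = k, nstart = 3, iter.max = 50))
  ord <- order(km$centers)           # ties broken by lowest cluster index
  bright <- km$centers[ord[k]]
  dark <- km$centers[ord[1]]
  keep <- which(km$centers >= (bright + dark) / 2)
  binary <- matrix(km$cluster %in% keep, nrow(image), ncol(image))
  fill_holes(largest_component(binary))
}

#' Automated mask quality filter
#'
#' A stand-in for visual inspection of bootstrap masks. Accepts a candidate
#' iff its area fraction lies in `[min_area, max_area]`, it touches exactly
#' one vertical (left/right) image border, and its solidity (area over
#' convex-hull area) is at least `min_solidity`. The quality score is the
#' product of the per-criterion scores (binary for area and border,
#' `min(1, solidity / min_solidity)` for solidity).
#'
#' @param candidate an [masked_mammogram()].
#' @param min_area,max_area area-fraction window (defaults 0.08, 0.75).
#' @param min_solidity solidity threshold (default 0.85).
#' @return list: `accept` (logical), `quality_score`, `reasons` (character
#'   vector of failed criteria, empty on acceptance).
#' @export
quality_filter <- function(candidate, min_area = 0.08, max_area = 0.75,
                           min_solidity = 0.85) {
  stopifnot(inherits(candidate, "fm_masked"))
  m <- candidate$mask
  frac <- mean(m)
  reasons <- character(0)
  s_area <- as.numeric(frac >= min_area && frac <= max_area)
  if (s_area == 0)
    reasons <- c(reasons, sprintf("area fraction %.3f outside [%g, %g]",
                                  frac, min_area, max_area))
  left <- any(m[, 1]); right <- any(m[, ncol(m)])
  s_border <- as.numeric(xor(left, right))
  if (s_border == 0)
    reasons <- c(reasons, if (left && right)
      "mask touches both vertical borders" else
      "mask touches no vertical border")
  sol <- mask_solidity(m)
  s_sol <- min(1, sol / min_solidity)
  if (sol < min_solidity)
    reasons <- c(reasons, sprintf("solidity %.3f below %g", sol, min_solidity))
  list(accept = length(reasons) == 0,
       quality_score = s_area * s_border * s_sol,
       reasons = reasons)
}

mask_solidity <- function(mask) {
  pts <- which(mask, arr.ind = TRUE)
  if (nrow(pts) < 3) return(0)
  hull <- pts[chull(pts), , drop = FALSE]
  # shoelace area of the pixel-centre hull polygon
  x <- hull[, 1]; y <- hull[, 2]
  area <- abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
  if (area == 0) return(0)
  min(1, nrow(pts) / area)
}

#' Augment a masked mammogram with fake printed labels
#'
#' Returns `n_variants` copies: the first is the unmodified original, each
#' further one adds a single bright rectangle placed entirely in the
#' background (rejection-sampled until disjoint from the breast mask). The
#' mask of every variant equals the original mask — labels are non-breast
#' by construction, which is what teaches the segmenter to exclude them.
#'
#' @param sample an [masked_mammogram()] with non-empty mask.
#' @param cfg an [augmentation_config()].
#' @return list of `fm_masked` of length `cfg$n_variants`; variants carry
#'   their label rectangle in `$label_box`.
#' @export
augment_with_fake_labels <- function(sample, cfg = augmentation_config()) {
  stopifnot(inherits(sample, "fm_masked"), inherits(cfg, "fm_aug_config"))
  if (!any(sample$mask)) stop_fm("mask is empty; nothing to augment")
  rows <- nrow(sample$image); cols <- ncol(sample$image)
  brightness <- quantile(sample$image[sample$mask],
                         cfg$label_intensity_quantile, names = FALSE)
  out <- vector("list", cfg$n_variants)
  out[[1]] <- sample
  if (cfg$n_variants == 1) return(out)
  withr::with_seed(derive_seed(cfg$seed, 23L), {
    for (v in 2:cfg$n_variants) {
      placed <- FALSE
      for (try in 1:200) {
        h <- max(2, round(runif(1, cfg$label_size_range[1],
                                cfg$label_size_range[2]) * rows))
        w <- max(2, round(runif(1, cfg$label_size_range[1],
                                cfg$label_size_range[2]) * cols))
        if (h >= rows || w >= cols) next
        r0 <- sample.int(rows - h, 1); c0 <- sample.int(cols - w, 1)
        box <- c(r0, r0 + h - 1, c0, c0 + w - 1)
        if (!any(sample$mask[box[1]:box[2], box[3]:box[4]])) {
          placed <- TRUE; break
        }
      }
      if (!placed)
        stop_fm("no background room for a fake label on source '%s'",
                sample$source_id)
      img <- sample$image
      img[box[1]:box[2], box[3]:box[4]] <- brightness
      out[[v]] <- masked_mammogram(img, sample$mask,
                                   provenance = sample$provenance,
                                   quality_score = sample$quality_score,
                                   source_id = sample$source_id,
                                   label_box = box)
    }
  })
  out
}

#' Build the augmented unsupervised learning dataset (AULD)
#'
#' The full bootstrap: K-means mask per image, automated quality filtering,
#' then fake-label augmentation of every accepted sample. The result is the
#' training corpus for the supervised breast-area segmenter; its size is
#' `accepted * n_variants`.
#'
#' @param images list of numeric matrices (or `fm_image` records, whose
#'   pixels are used) — typically preprocessed mammograms.
#' @param k intensity clusters for [kmeans_mask()].
#' @param cfg an [augmentation_config()].
#' @param ... thresholds forwarded to [quality_filter()].
#' @return list: `samples` (list of `fm_masked`), `manifest` (data.frame:
#'   source_id, variant, quality_score, has_label, label box coords),
#'   `rejected` (data.frame: source_id, reasons).
#' @export
build_auld <- function(images, k = 2L, cfg = augmentation_config(), ...) {
  if (length(images) == 0) stop_fm("need at least one input image")
  samples <- list(); manifest <- list(); rejected <- list()
  for (i in seq_along(images)) {
    img <- if (inherits(images[[i]], "fm_image")) images[[i]]$pixels
           else images[[i]]
    sid <- sprintf("img%04d", i)
    mask <- tryCatch(kmeans_mask(img, k = k, seed = derive_seed(cfg$seed, i)),
                     error = function(e) NULL)
    if (is.null(mask)) {
      rejected[[length(rejected) + 1]] <-
        data.frame(source_id = sid, reason = "kmeans failed",
                   stringsAsFactors = FALSE)
      next
    }
    cand <- masked_mammogram(img, mask, provenance = "kmeans",
                             source_id = sid)
    qf <- quality_filter(cand, ...)
    if (!qf$accept) {
      rejected[[length(rejected) + 1]] <-
        data.frame(source_id = sid, reason = paste(qf$reasons, collapse = "; "),
                   stringsAsFactors = FALSE)
      next
    }
    cand$quality_score <- qf$quality_score
    vcfg <- cfg; vcfg$seed <- derive_seed(cfg$seed, i, 57L)
    variants <- augment_with_fake_labels(cand, vcfg)
    for (v in seq_along(variants)) {
      samples[[length(samples) + 1]] <- variants[[v]]
      bx <- variants[[v]]$label_box
      manifest[[length(manifest) + 1]] <- data.frame(
        source_id = sid, variant = v,
        quality_score = qf$quality_score,
        has_label = !is.null(bx),
        box_r0 = ifelse(is.null(bx), NA, bx[1]),
        box_r1 = ifelse(is.null(bx), NA, bx[2]),
        box_c0 = ifelse(is.null(bx), NA, bx[3]),
        box_c1 = ifelse(is.null(bx), NA, bx[4]),
        stringsAsFactors = FALSE)
    }
  }
  if (length(samples) == 0) {
    rej <- do.call(rbind, rejected)
    stop_fm("no masks passed the quality filter:\n%s",
            paste(sprintf("  %s: %s", rej$source_id, rej$reason),
                  collapse = "\n"))
  }
  list(samples = samples, manifest = do.call(rbind, manifest),
       rejected = if (length(rejected)) do.call(rbind, rejected)
                  else data.frame(source_id = character(0),
                                  reason = character(0)))
}
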