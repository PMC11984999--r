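test_that("the rescale transform is the standard linear map", {
  m <- matrix(c(100, 2000, 0, 50), 2, 2)
  expect_identical(apply_rescale(m, 1, 0), m)
  expect_equal(apply_rescale(matrix(100), 1, -1024)[1], -924)
  expect_equal(apply_rescale(matrix(2000), 0.001, 0)[1], 2)
  expect_error(apply_rescale(m, 0, 5), "degenerate")
})

test_that("the inversion decision follows the three-attribute rule", {
  meta <- function(sign, photo, lut)
    dicom_meta(pixel_intensity_relationship_sign = sign,
               photometric_interpretation = photo,
               presentation_lut_shape = lut)
  expect_true(should_invert(meta(1L, "MONOCHROME2", "IDENTITY")))
  expect_true(should_invert(meta(-1L, "MONOCHROME1", "IDENTITY")))
  expect_true(should_invert(meta(-1L, "MONOCHROME2", "INVERSE")))
  expect_false(should_invert(meta(-1L, "MONOCHROME2", "IDENTITY")))
  bad <- meta(-1L, "MONOCHROME2", "IDENTITY")
  bad$photometric_interpretation <- "PALETTE COLOR"
  expect_error(should_invert(bad), "unknown Photometric")
})

test_that("inversion subtracts from the image maximum", {
  expect_equal(invert_pixels(matrix(c(0, 10, 5, 2), 2, 2)),
               matrix(c(10, 0, 5, 8), 2, 2))
  expect_equal(invert_pixels(matrix(7, 1, 2)), matrix(0, 1, 2))
  expect_error(invert_pixels(matrix(numeric(0), 0, 0)), "empty")
  # involution on images whose minimum is 0
  for (i in 1:20) {
    x <- matrix(sample(0:50, 36, replace = TRUE), 6, 6)
    x[1] <- 0
    expect_equal(invert_pixels(invert_pixels(x)), x)
  }
  # inversion reverses intensity rank order
  x <- matrix(runif(25), 5, 5)
  expect_equal(rank(invert_pixels(x)), rank(-x))
})

test_that("laterality alignment flips only right-sided images", {
  m <- matrix(1:3, 1, 3)
  expect_identical(align_laterality(m, "L"), m)
  expect_equal(align_laterality(m, "R"), matrix(3:1, 1, 3))
  x <- matrix(runif(24), 4, 6)
  expect_equal(align_laterality(align_laterality(x, "R"), "R"), x)
  expect_error(align_laterality(m, "B"), "laterality")
})

test_that("spacing-aware resize restores physical isotropy", {
  # isotropic spacing: plain resize
  x <- matrix(runif(64 * 64), 64, 64)
  expect_equal(resize_with_spacing(x, c(0.703125, 0.703125), c(32, 32)),
               resize2d(x, c(32, 32)))
  # anisotropic (1.0, 0.5) on 100x200: physical extent is 100mm x 100mm, so
  # a centred square must come out square after correction
  img <- matrix(0, 100, 200)
  img[41:60, 81:120] <- 1 # 20mm x 20mm physically
  out <- resize_with_spacing(img, c(1.0, 0.5), c(100, 100))
  expect_equal(dim(out), c(100, 100))
  blob <- out > 0.5
  expect_equal(diff(range(which(rowSums(blob) > 0))),
               diff(range(which(colSums(blob) > 0))), tolerance = 0.15)
  expect_error(resize_with_spacing(x, c(0, 1), c(32, 32)), "positive")
  expect_error(resize_with_spacing(x, c(1, 1), c(4, 4)), "at least 8x8")
})

test_that("preprocess normalizes presentation, orientation and geometry", {
  profs <- two_hospital_profiles(label_prob = c(1, 1))
  rec1 <- generate_phantom(phantom_spec(c(96, 96), "R", 3, seed = 4),
                           profs[[1]]) # MONOCHROME1, right
  out <- preprocess(rec1, target_size = c(128, 128))
  expect_equal(dim(out$pixels), c(128, 128))
  expect_equal(dim(out$mask), c(128, 128))
  # presentation normalized: breast brighter than background
  expect_gt(mean(out$pixels[out$mask]), mean(out$pixels[!out$mask]))
  # orientation normalized: breast mass on the left
  expect_gt(sum(out$mask[, 1:64]) / sum(out$mask), 0.5)
  # provenance records the applied steps in order
  steps <- attr(out, "provenance")
  expect_true(any(grepl("invert", steps)))
  expect_true(any(grepl("flip", steps)))
  expect_lt(grep("rescale", steps), grep("resize", steps))
})

test_that("preprocess defaults to the 512x512 model input geometry", {
  rec <- generate_phantom(phantom_spec(c(64, 64), "L", 1, seed = 6),
                          clean_profile())
  expect_equal(dim(preprocess(rec)$pixels), c(512, 512))
})

test_that("preprocess is idempotent on its own output", {
  rec <- generate_phantom(phantom_spec(c(96, 96), "R", 2, seed = 12),
                          two_hospital_profiles()[[1]])
  # exact idempotence without windowing
  once <- preprocess(rec, target_size = c(96, 96), clip = NULL)
  twice <- preprocess(once, target_size = c(96, 96), clip = NULL)
  expect_equal(twice$pixels, once$pixels)
  # near-idempotence with the default percentile window: the second pass may
  # re-window interpolated tails, but only marginally
  once <- preprocess(rec, target_size = c(96, 96))
  twice <- preprocess(once, target_size = c(96, 96))
  expect_lt(max(abs(twice$pixels - once$pixels)), 0.02)
})

test_that("the ground-truth mask stays aligned through preprocessing", {
  profs <- two_hospital_profiles(label_prob = c(0, 0), clip_prob = c(0, 0))
  for (seed in 1:4) {
    rec <- generate_phantom(phantom_spec(c(96, 96),
                                         c("L", "R")[1 + seed %% 2], 2,
                                         seed = seed), profs[[1 + seed %% 2]])
    out <- preprocess(rec, target_size = c(128, 128))
    thresholded <- out$pixels > 0.25 # windowed output: background sits near 0
    expect_gte(dice_iou(thresholded, out$mask)$dice, 0.95)
  }
})
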