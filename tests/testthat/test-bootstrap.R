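test_that("kmeans_mask matches a threshold oracle on two-level images", {
  withr::with_seed(5, {
    for (i in 1:5) {
      tl <- two_level_image(48, noise_sd = 0.02)
      km <- kmeans_mask(tl$image, k = 2, seed = i)
      # oracle: best single threshold by Dice against the K-means result
      cand <- quantile(tl$image, seq(0.05, 0.95, 0.05))
      best <- max(vapply(cand, function(th) {
        dice_iou(km, tl$image > th)$dice
      }, 0))
      expect_gte(best, 0.99)
      # and the mask recovers the known blob
      expect_gte(dice_iou(km, tl$mask)$dice, 0.98)
    }
  })
})

test_that("kmeans_mask rejects constant images", {
  expect_error(kmeans_mask(matrix(3, 32, 32)), "constant image")
})

test_that("kmeans_mask excludes printed labels on phantoms", {
  prof <- hospital_profile("H", c(0, 4095), label_prob = 1)
  for (seed in 1:5) {
    rec <- generate_phantom(phantom_spec(c(64, 64), "L", 3, seed = seed), prof)
    if (!rec$flags$label) next
    pp <- preprocess(rec, target_size = c(64, 64))
    km <- kmeans_mask(pp$pixels)
    # the label is bright but not attached to the breast component
    lab <- pp$pixels > 0.8 & !pp$mask
    expect_lt(sum(km & lab) / max(1, sum(lab)), 0.05)
  }
})

test_that("the quality filter reproduces its acceptance criteria", {
  rec <- generate_phantom(phantom_spec(c(64, 64), "L", 2, seed = 3),
                          clean_profile())
  ok <- quality_filter(masked_mammogram(rec$pixels, rec$mask))
  expect_true(ok$accept)
  expect_gt(ok$quality_score, 0.9)

  allones <- masked_mammogram(rec$pixels, matrix(TRUE, 64, 64))
  r <- quality_filter(allones)
  expect_false(r$accept)
  expect_match(paste(r$reasons, collapse = " "), "area fraction")

  both <- matrix(FALSE, 64, 64)
  both[30:34, ] <- TRUE # band touching both vertical borders
  r2 <- quality_filter(masked_mammogram(rec$pixels, both))
  expect_false(r2$accept)
  expect_match(paste(r2$reasons, collapse = " "), "both vertical borders")
})

test_that("fake-label augmentation keeps its pixel-level contracts", {
  rec <- generate_phantom(phantom_spec(c(64, 64), "L", 2, seed = 9),
                          clean_profile())
  s <- masked_mammogram(rec$pixels, rec$mask, source_id = "s1")
  aug <- augment_with_fake_labels(s, augmentation_config(seed = 4))
  expect_length(aug, 5)
  expect_identical(aug[[1]]$image, s$image)
  for (v in 2:5) {
    changed <- which(aug[[v]]$image != s$image, arr.ind = TRUE)
    bx <- aug[[v]]$label_box
    expect_false(is.null(bx))
    # changed pixels all inside the recorded rectangle...
    expect_true(all(changed[, 1] >= bx[1] & changed[, 1] <= bx[2]))
    expect_true(all(changed[, 2] >= bx[3] & changed[, 2] <= bx[4]))
    # ...and disjoint from the breast mask; masks unchanged
    expect_false(any(s$mask[changed]))
    expect_identical(aug[[v]]$mask, s$mask)
  }
})

test_that("augmentation errors when the background cannot host a label", {
  img <- matrix(runif(32 * 32), 32, 32)
  full <- masked_mammogram(img, matrix(TRUE, 32, 32), source_id = "x")
  expect_error(augment_with_fake_labels(full), "no background room")
})

test_that("build_auld composes bootstrap, filter and augmentation", {
  profs <- two_hospital_profiles()
  co <- generate_cohort(8, 1, profs, seed = 19, image_size = c(64, 64))
  pre <- lapply(co$records, preprocess, target_size = c(64, 64))
  auld <- build_auld(pre, cfg = augmentation_config(seed = 2))
  expect_equal(nrow(auld$manifest) %% 5, 0)
  expect_equal(nrow(auld$manifest), length(auld$samples))
  expect_true(all(auld$manifest$variant %in% 1:5))
  # deterministic: identical manifest on a rerun
  auld2 <- build_auld(pre, cfg = augmentation_config(seed = 2))
  expect_identical(auld$manifest, auld2$manifest)
  # single accepted image yields exactly n_variants samples
  one <- build_auld(pre[1], cfg = augmentation_config(seed = 2))
  expect_equal(nrow(one$manifest), 5)
})

test_that("build_auld reports per-image reasons when nothing is accepted", {
  bad <- replicate(3, {
    m <- matrix(0.05, 48, 48)
    m[, 20:28] <- 0.9 # bright band touching neither/both border patterns
    m + matrix(runif(48 * 48, 0, 0.01), 48, 48)
  }, simplify = FALSE)
  expect_error(build_auld(bad), "no masks passed")
})
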