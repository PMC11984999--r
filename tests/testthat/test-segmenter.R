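test_that("dice and iou follow their set formulas", {
  a <- matrix(FALSE, 4, 4); a[1:2, 1:2] <- TRUE
  expect_equal(dice_iou(a, a), list(dice = 1, iou = 1))
  b <- matrix(FALSE, 4, 4); b[3:4, 3:4] <- TRUE
  expect_equal(dice_iou(a, b), list(dice = 0, iou = 0))
  c_ <- matrix(FALSE, 4, 4); c_[2:3, 1:2] <- TRUE # |A|=4, |B|=4, overlap 2
  expect_equal(dice_iou(a, c_), list(dice = 0.5, iou = 1 / 3))
  e <- matrix(FALSE, 4, 4)
  expect_equal(dice_iou(e, e), list(dice = 1, iou = 1))
  expect_error(dice_iou(a, matrix(FALSE, 3, 3)), "shapes differ")
})

test_that("dice_iou matches brute-force counting on random mask pairs", {
  withr::with_seed(11, {
    for (i in 1:1000) {
      a <- matrix(runif(64) < 0.4, 8, 8)
      b <- matrix(runif(64) < 0.4, 8, 8)
      m <- dice_iou(a, b)
      inter <- 0; na <- 0; nb <- 0; uni <- 0
      for (j in 1:64) { # element-wise enumeration, no set algebra
        inter <- inter + (a[j] && b[j])
        na <- na + a[j]; nb <- nb + b[j]
        uni <- uni + (a[j] || b[j])
      }
      if (na + nb == 0) {
        expect_equal(c(m$dice, m$iou), c(1, 1))
      } else {
        expect_identical(m$dice, 2 * inter / (na + nb))
        expect_identical(m$iou, inter / uni)
      }
      # algebraic identity linking the two metrics
      expect_lt(abs(m$iou - m$dice / (2 - m$dice)), 1e-12)
    }
  })
})

test_that("split_auld produces the 1000/300/remainder protocol sizes", {
  # synthetic 1550-sample manifest: 310 sources x 5 variants
  man <- data.frame(source_id = rep(sprintf("img%04d", 1:310), each = 5),
                    variant = rep(1:5, 310))
  auld <- list(manifest = man)
  sp <- split_auld(auld, seg_train_config(seed = 3))
  expect_length(sp$train, 1000)
  expect_length(sp$val, 300)
  expect_length(sp$test, 250)
  # variants of one source never straddle sets
  for (set in sp) {
    src <- unique(man$source_id[set])
    expect_true(all(table(man$source_id[set]) == 5))
    expect_length(set, 5 * length(src))
  }
  expect_identical(sp, split_auld(auld, seg_train_config(seed = 3)))
  expect_false(identical(sp$train,
                         split_auld(auld, seg_train_config(seed = 4))$train))
  expect_error(split_auld(list(manifest = man[1:20, ]),
                          seg_train_config()), "at least")
})

test_that("a one-pair UNet memorizes its sample and keeps the best checkpoint", {
  tl <- withr::with_seed(2, two_level_image(32, noise_sd = 0.02))
  s <- masked_mammogram(tl$image, tl$mask, source_id = "a")
  cfg <- seg_train_config(n_train = 1, n_val = 1, epochs = 30, lr = 3e-3,
                          batch_size = 1, seed = 5, depth = 2, base = 4)
  fit <- train_unet(list(s), list(s), cfg)
  expect_equal(nrow(fit$history), 30)
  expect_gte(max(fit$history$val_dice), 0.95)
  # returned checkpoint is at least as good as the final epoch
  expect_lte(min(fit$history$val_loss), tail(fit$history$val_loss, 1))
  pred <- predict_mask(fit, tl$image)
  expect_equal(dim(pred), dim(tl$image))
  expect_gte(dice_iou(pred, tl$mask)$dice, 0.95)
})

test_that("training aborts on a non-finite loss", {
  tl <- two_level_image(32)
  img <- tl$image
  img[5, 5] <- NaN # a corrupt pixel poisons the loss
  s <- masked_mammogram(img, tl$mask, source_id = "a")
  cfg <- seg_train_config(n_train = 1, n_val = 1, epochs = 2, lr = 1e-3,
                          batch_size = 1, seed = 5, depth = 1, base = 2)
  expect_error(train_unet(list(s), list(s), cfg), "non-finite|abort")
})

test_that("predict_mask may return an empty mask on background-only input", {
  cfg <- seg_train_config(depth = 1, base = 2, seed = 1)
  ucfg <- fedmammo:::unet_config(depth = 1, base = 2)
  params <- fedmammo:::unet_init_params(ucfg, seed = 1)
  params$out_b <- -50 # force negative logits everywhere
  fit <- structure(list(params = params, config = ucfg), class = "fm_unet_fit")
  pred <- predict_mask(fit, matrix(runif(32 * 32), 32, 32))
  expect_false(any(pred))
  expect_equal(dim(pred), c(32, 32))
})

test_that("clean_and_crop zeroes non-breast pixels and fixes the geometry", {
  prof <- hospital_profile("H", c(0, 4095), label_prob = 1)
  rec <- generate_phantom(phantom_spec(c(64, 64), "L", 2, seed = 21), prof)
  expect_true(rec$flags$label)
  out <- clean_and_crop(rec$pixels, rec$mask)
  expect_equal(dim(out), c(256, 256))
  # the label lies outside the mask, hence is gone: no near-label-intensity
  # pixels outside the (rescaled) breast region bounding box
  bx <- rec$flags$label_box
  lab_level <- min(rec$pixels[bx[1]:bx[2], bx[3]:bx[4]])
  out_small <- clean_and_crop(rec$pixels, rec$mask, out_size = c(64, 64))
  expect_lt(sum(out_small >= lab_level) / sum(rec$pixels >= lab_level), 0.6)
  # full-image mask: crop is the identity before resize
  full <- matrix(TRUE, 64, 64)
  expect_equal(clean_and_crop(rec$pixels, full, out_size = c(64, 64)),
               resize2d(rec$pixels, c(64, 64)))
  expect_error(clean_and_crop(rec$pixels, full & FALSE), "empty mask")
})
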