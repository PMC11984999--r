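#' Segmentation training configuration
#'
#' @param n_train,n_val training and validation sizes (defaults 1000 / 300;
#'   whatever remains becomes the test set).
#' @param epochs training epochs.
#' @param lr Adam learning rate.
#' @param batch_size images per gradient step.
#' @param seed integer seed (weights and shuffles).
#' @param depth,base UNet scale, see [unet_config()].
#' @return list of class `fm_seg_config`.
#' @export
seg_train_config <- function(n_train = 1000L, n_val = 300L, epochs = 15L,
                             lr = 1e-3, batch_size = 4L, seed = 1L,
                             depth = 2L, base = 8L) {
  if (n_train < 1 || n_val < 1) stop_fm("n_train and n_val must be >= 1")
  structure(list(n_train = as.integer(n_train), n_val = as.integer(n_val),
                 epochs = as.integer(epochs), lr = lr,
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 depth = as.integer(depth), base = as.integer(base)),
            class = "fm_seg_config")
}

#' Split the AULD into train / validation / test
#'
#' Sizes are `n_train`, `n_val` and the remainder. All augmentation variants
#' of one source image land in the same set (otherwise near-duplicates of a
#' training image would leak into validation), which requires the set sizes
#' to be multiples of the per-source variant count.
#'
#' @param auld result of [build_auld()] (needs `$samples` and `$manifest`).
#' @param cfg an [seg_train_config()].
#' @return list of three integer index vectors: `train`, `val`, `test`.
#' @export
split_auld <- function(auld, cfg = seg_train_config()) {
  man <- auld$manifest
  if (nrow(man) < cfg$n_train + cfg$n_val + 1)
    stop_fm("AULD has %d samples; need at least n_train + n_val + 1 = %d",
            nrow(man), cfg$n_train + cfg$n_val + 1)
  sources <- unique(man$source_id)
  sources <- withr::with_seed(derive_seed(cfg$seed, 31L), sample(sources))
  sizes <- vapply(sources, function(s) sum(man$source_id == s), 0L)
  cum <- cumsum(sizes)
  k_train <- match(cfg$n_train, cum)
  if (is.na(k_train))
    stop_fm("n_train = %d is not attainable with variant grouping (group sizes %s)",
            cfg$n_train, paste(unique(sizes), collapse = ","))
  k_val <- match(cfg$n_train + cfg$n_val, cum)
  if (is.na(k_val))
    stop_fm("n_val = %d is not attainable with variant grouping", cfg$n_val)
  set_of <- function(src) which(man$source_id %in% src)
  list(train = set_of(sources[seq_len(k_train)]),
       val = set_of(sources[(k_train + 1):k_val]),
       test = if (k_val < length(sources))
         set_of(sources[(k_val + 1):length(sources)]) else integer(0))
}

scale_unit <- function(img) {
  rng <- range(img)
  if (!all(is.finite(rng))) return(img) # non-finite values propagate to the loss check
  if (diff(rng) == 0) return(img * 0)
  (img - rng[1]) / diff(rng)
}

#' Train the breast-area UNet
#'
#' Adam on a Dice + binary-cross-entropy loss, one pass over the shuffled
#' training set per epoch and a validation pass (loss and hard Dice) after
#' each. Images are min-max scaled to `[0, 1]` per image before entering
#' the network. Returns the checkpoint with the lowest validation loss.
#'
#' @param train,val lists of `fm_masked` samples.
#' @param cfg an [seg_train_config()].
#' @param verbose print per-epoch progress.
#' @return object of class `fm_unet_fit`: `params` (best checkpoint),
#'   `final_params`, `config`, and `history` (data.frame with one row per
#'   epoch: train_loss, val_loss, val_dice).
#' @export
train_unet <- function(train, val, cfg = seg_train_config(), verbose = FALSE) {
  if (length(train) == 0 || length(val) == 0)
    stop_fm("train and validation sets must be non-empty")
  ucfg <- unet_config(depth = cfg$depth, base = cfg$base)
  params <- unet_init_params(ucfg, seed = derive_seed(cfg$seed, 41L))
  state <- adam_init(params)
  history <- list()
  best <- list(loss = Inf, params = params)
  xs <- lapply(train, function(s) scale_unit(s$image))
  ts <- lapply(train, function(s) s$mask * 1)
  vxs <- lapply(val, function(s) scale_unit(s$image))
  vts <- lapply(val, function(s) s$mask * 1)
  for (epoch in seq_len(cfg$epochs)) {
    ord <- withr::with_seed(derive_seed(cfg$seed, 43L, epoch),
                            sample.int(length(xs)))
    ep_loss <- 0
    for (start in seq(1, length(ord), by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1, length(ord))]
      acc <- NULL
      bl <- 0
      for (j in idx) {
        fwd <- unet_forward(params, ucfg, xs[[j]], want_cache = TRUE)
        lg <- seg_loss_grad(fwd$logits, ts[[j]])
        if (!is.finite(lg$loss))
          stop_fm("non-finite training loss at epoch %d; aborting (lr = %g)",
                  epoch, cfg$lr)
        g <- unet_backward(params, ucfg, fwd, lg$dlogits)
        acc <- if (is.null(acc)) g else grads_add(acc, g)
        bl <- bl + lg$loss
      }
      acc <- grads_scale(acc, 1 / length(idx))
      st <- adam_step(params, acc, state, cfg$lr)
      params <- st$params; state <- st$state
      ep_loss <- ep_loss + bl
    }
    val_loss <- 0; val_dice <- 0
    for (j in seq_along(vxs)) {
      fwd <- unet_forward(params, ucfg, vxs[[j]])
      lg <- seg_loss_grad(fwd$logits, vts[[j]])
      val_loss <- val_loss + lg$loss
      hard <- fwd$logits > 0
      val_dice <- val_dice + dice_iou(hard, vts[[j]] > 0.5)$dice
    }
    val_loss <- val_loss / length(vxs); val_dice <- val_dice / length(vxs)
    history[[epoch]] <- data.frame(epoch = epoch,
                                   train_loss = ep_loss / length(xs),
                                   val_loss = val_loss, val_dice = val_dice)
    if (val_loss < best$loss) best <- list(loss = val_loss, params = params,
                                           dice = val_dice)
    if (verbose)
      message(sprintf("epoch %2d  train %.4f  val %.4f  dice %.4f", epoch,
                      ep_loss / length(xs), val_loss, val_dice))
  }
  structure(list(params = best$params, final_params = params,
                 config = ucfg, train_config = cfg,
                 history = do.call(rbind, history)),
            class = "fm_unet_fit")
}

#' @export
print.fm_unet_fit <- function(x, ...) {
  h <- x$history
  cat(sprintf(paste0("<fm_unet_fit depth=%d base=%d params=%d epochs=%d ",
                     "best val loss=%.4f val dice=%.4f>\n"),
              x$config$depth, x$config$base, n_params(x$params),
              nrow(h), min(h$val_loss), h$val_dice[which.min(h$val_loss)]))
  invisible(x)
}

#' Predict a breast mask
#'
#' Sigmoid probability map thresholded at 0.5, then largest connected
#' component with holes filled. An all-background prediction yields an
#' empty mask (callers flag it downstream).
#'
#' @param fit an `fm_unet_fit`.
#' @param image numeric matrix (any intensity scale; min-max scaled
#'   internally). Height/width must be divisible by `2^depth`.
#' @return logical mask, same shape as `image`.
#' @export
predict_mask <- function(fit, image) {
  stopifnot(inherits(fit, "fm_unet_fit"))
  fwd <- unet_forward(fit$params, fit$config, scale_unit(image))
  binary <- fwd$logits > 0       # sigmoid(logit) > 0.5
  if (!any(binary)) return(binary)
  fill_holes(largest_component(binary))
}

#' @export
predict.fm_unet_fit <- function(object, newdata, ...) {
  predict_mask(object, newdata)
}

#' Mask-apply and peripheral crop
#'
#' Zeroes every pixel outside the mask, crops to the mask bounding box plus
#' a margin (clamped to the image bounds), and resizes to `out_size` — the
#' geometry expected by the downstream classifier.
#'
#' @param image numeric matrix.
#' @param mask logical matrix, same shape, non-empty.
#' @param margin pixels of context kept around the bounding box.
#' @param out_size output `(rows, cols)`, default `c(256, 256)`.
#' @return numeric matrix of shape `out_size`.
#' @export
clean_and_crop <- function(image, mask, margin = 4L, out_size = c(256, 256)) {
  if (!identical(dim(image), dim(mask)))
    stop_fm("image and mask shapes differ")
  if (!any(mask))
    stop_fm("empty mask: fall back to the uncleaned image for this record")
  cleaned <- image * (mask * 1)
  rows <- range(which(rowSums(mask) > 0))
  cols <- range(which(colSums(mask) > 0))
  r0 <- max(1, rows[1] - margin); r1 <- min(nrow(image), rows[2] + margin)
  c0 <- max(1, cols[1] - margin); c1 <- min(ncol(image), cols[2] + margin)
  resize2d(cleaned[r0:r1, c0:c1, drop = FALSE], out_size)
}
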