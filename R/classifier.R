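#' Classifier training configuration
#'
#' Defaults mirror the reference training recipe: cross-entropy loss, Adam,
#' batch size 10, 100 epochs, learning rate 1e-8. Note the 1e-8 learning
#' rate is kept for fidelity to that recipe but is impractically small at
#' desk scale — examples and tests override it to 1e-3.
#'
#' @param lr Adam learning rate (> 0).
#' @param batch_size images per gradient step (>= 1).
#' @param epochs training epochs (>= 1).
#' @param seed integer seed (weights and shuffles).
#' @return list of class `fm_train_config`.
#' @export
train_config <- function(lr = 1e-8, batch_size = 10L, epochs = 100L,
                         seed = 1L) {
  if (lr <= 0 || batch_size < 1 || epochs < 1)
    stop_fm("lr must be > 0; batch_size and epochs must be >= 1")
  structure(list(loss = "cross-entropy", optimizer = "adam", lr = lr,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed)),
            class = "fm_train_config")
}

#' Normalization statistics from the training set only
#'
#' Global minimum and maximum over all training pixels. By contract this
#' function is only ever handed the training partition; validation and test
#' images are normalized with these statistics, never their own.
#'
#' @param train_images list of numeric matrices (or a dataset from
#'   [make_dataset()]).
#' @return object of class `fm_norm`: `pixel_min`, `pixel_max`.
#' @export
compute_norm_stats <- function(train_images) {
  if (!is.null(train_images$x)) train_images <- train_images$x
  if (length(train_images) == 0) stop_fm("training set is empty")
  lo <- min(vapply(train_images, min, 0))
  hi <- max(vapply(train_images, max, 0))
  if (lo == hi)
    stop_fm("constant training set (min = max = %g): normalization undefined", lo)
  structure(list(pixel_min = lo, pixel_max = hi), class = "fm_norm")
}

#' Min/max normalization with clamping
#'
#' `(x - min) / (max - min)`, clamped to `[0, 1]` so that out-of-range test
#' pixels (possible under hospital shift) cannot blow up the input
#' distribution.
#'
#' @param image numeric matrix.
#' @param stats an [compute_norm_stats()] result.
#' @return matrix with values in `[0, 1]`.
#' @export
normalize_image <- function(image, stats) {
  if (!inherits(stats, "fm_norm")) stop_fm("stats must be an fm_norm object")
  pmin(pmax((image - stats$pixel_min) /
              (stats$pixel_max - stats$pixel_min), 0), 1)
}

#' Build the BIRADS classification model
#'
#' A small convolutional stack with global average pooling and a linear
#' head. The parameter count stays far below 2 million so each federated
#' round stays communication-light.
#'
#' @param n_classes output classes (default 5, BIRADS 1-5 after filtering).
#' @param input_size expected `(rows, cols)` input, default `c(256, 256)`.
#' @param channels conv block widths.
#' @param seed weight initialization seed.
#' @return object of class `fm_cnn`: `params`, `config`, `input_size`.
#' @export
build_model <- function(n_classes = 5L, input_size = c(256, 256),
                        channels = c(8L, 16L, 32L), seed = 1L) {
  cfg <- cnn_config(channels = channels, n_classes = n_classes)
  params <- cnn_init_params(cfg, seed = derive_seed(seed, 151L))
  np <- n_params(params)
  if (np >= 2e6)
    stop_fm("model has %d parameters; the communication budget requires < 2e6", np)
  structure(list(params = params, config = cfg,
                 input_size = as.integer(input_size)),
            class = "fm_cnn")
}

#' @export
print.fm_cnn <- function(x, ...) {
  cat(sprintf("<fm_cnn %s channels=[%s] classes=%d params=%d>\n",
              paste(x$input_size, collapse = "x"),
              paste(x$config$channels, collapse = ","),
              x$config$n_classes, n_params(x$params)))
  invisible(x)
}

#' Assemble a labeled dataset from image records
#'
#' @param records list of `fm_image`.
#' @param manifest data.frame with an `image_index` column selecting
#'   records and a `birads` column giving labels.
#' @param input_size resize target; `NULL` keeps native size.
#' @param norm optional [compute_norm_stats()] result applied to every image.
#' @return list: `x` (list of matrices), `y` (integer labels).
#' @export
make_dataset <- function(records, manifest, input_size = NULL, norm = NULL) {
  xs <- lapply(manifest$image_index, function(i) {
    img <- records[[i]]$pixels
    if (!is.null(input_size)) img <- resize2d(img, input_size)
    if (!is.null(norm)) img <- normalize_image(img, norm)
    img
  })
  list(x = xs, y = as.integer(manifest$birads))
}

# shared epoch loop: runs `epochs` passes over `data`, with the shuffle of
# global epoch g drawn from derive_seed(seed, 83, g). Both centralized and
# federated training call this, which is what makes single-client FedAvg
# bit-identical to centralized training.
cnn_run_epochs <- function(params, state, model_cfg, data, cfg, epochs,
                           global_epoch0 = 0L) {
  losses <- numeric(epochs)
  n <- length(data$x)
  for (e in seq_len(epochs)) {
    g <- global_epoch0 + e
    ord <- withr::with_seed(derive_seed(cfg$seed, 83L, g), sample.int(n))
    ep_loss <- 0
    for (start in seq(1, n, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1, n)]
      acc <- NULL; bl <- 0
      for (j in idx) {
        lg <- cnn_loss_grad(params, model_cfg, data$x[[j]], data$y[j])
        if (!is.finite(lg$loss))
          stop_fm("non-finite training loss at global epoch %d; aborting", g)
        acc <- if (is.null(acc)) lg$grads else grads_add(acc, lg$grads)
        bl <- bl + lg$loss
      }
      st <- adam_step(params, grads_scale(acc, 1 / length(idx)), state, cfg$lr)
      params <- st$params; state <- st$state
      ep_loss <- ep_loss + bl
    }
    losses[e] <- ep_loss / n
  }
  list(params = params, state = state, losses = losses)
}

cnn_eval_loss <- function(params, model_cfg, data) {
  tot <- 0
  for (j in seq_along(data$x)) {
    fwd <- cnn_forward(params, model_cfg, data$x[[j]])
    p <- softmax(fwd$logits)
    tot <- tot - log(max(p[data$y[j]], 1e-12))
  }
  tot / length(data$x)
}

#' Centralized training loop
#'
#' Exactly `cfg$epochs` iterations of train-one-epoch-then-validate.
#' Returns both the final model and the best-validation-loss checkpoint.
#'
#' @param model an [build_model()] result.
#' @param train,val datasets from [make_dataset()] (already normalized).
#' @param cfg an [train_config()].
#' @param verbose print per-epoch progress.
#' @return object of class `fm_cnn_fit`: `params` (final), `best_params`,
#'   `config`, `history` (one row per epoch: train_loss, val_loss).
#' @export
train_centralized <- function(model, train, val, cfg = train_config(),
                              verbose = FALSE) {
  stopifnot(inherits(model, "fm_cnn"))
  params <- model$params
  state <- adam_init(params)
  history <- list()
  best <- list(loss = Inf, params = params)
  for (epoch in seq_len(cfg$epochs)) {
    r <- cnn_run_epochs(params, state, model$config, train, cfg, 1L,
                        global_epoch0 = epoch - 1L)
    params <- r$params; state <- r$state
    val_loss <- cnn_eval_loss(params, model$config, val)
    history[[epoch]] <- data.frame(epoch = epoch, train_loss = r$losses,
                                   val_loss = val_loss)
    if (val_loss < best$loss) best <- list(loss = val_loss, params = params)
    if (verbose)
      message(sprintf("epoch %3d  train %.4f  val %.4f", epoch, r$losses,
                      val_loss))
  }
  structure(list(params = params, best_params = best$params,
                 config = model$config, input_size = model$input_size,
                 train_config = cfg, history = do.call(rbind, history)),
            class = "fm_cnn_fit")
}

#' @export
print.fm_cnn_fit <- function(x, ...) {
  cat(sprintf("<fm_cnn_fit params=%d epochs=%d final val loss=%.4f>\n",
              n_params(x$params), nrow(x$history),
              tail(x$history$val_loss, 1)))
  invisible(x)
}

#' Predict class labels
#'
#' @param object an `fm_cnn_fit` (or `fm_cnn`).
#' @param newdata dataset from [make_dataset()] or list of matrices.
#' @param ... unused.
#' @return integer vector of 1-based class predictions.
#' @export
predict.fm_cnn_fit <- function(object, newdata, ...) {
  xs <- if (!is.null(newdata$x)) newdata$x else newdata
  vapply(xs, function(x) {
    which.max(cnn_forward(object$params, object$config, x)$logits)
  }, 0L)
}

#' Per-test-set macro F1 evaluation
#'
#' @param fit an `fm_cnn_fit`.
#' @param test_sets named list of datasets from [make_dataset()], all
#'   non-empty.
#' @return named list, one entry per test set: `f1` (macro F1 over classes
#'   present in the truth) and `confusion` (matrix, rows = truth).
#' @export
evaluate_f1 <- function(fit, test_sets) {
  if (is.null(names(test_sets)) || any(!nzchar(names(test_sets))))
    stop_fm("test_sets must be a named list")
  lapply(test_sets, function(ds) {
    if (length(ds$x) == 0) stop_fm("empty test set")
    pred <- predict(fit, ds)
    list(f1 = macro_f1(ds$y, pred),
         confusion = confusion_matrix(ds$y, pred,
                                      classes = seq_len(fit$config$n_classes)))
  })
}
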