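test_that("normalization statistics come from the training partition only", {
  train <- list(matrix(0:49, 5, 10), matrix(50:99, 5, 10), matrix(100, 1, 1))
  st <- compute_norm_stats(train)
  expect_equal(st$pixel_min, 0)
  expect_equal(st$pixel_max, 100)
  # a wild validation image cannot move the statistics
  val <- c(train, list(matrix(200, 1, 1)))
  expect_identical(compute_norm_stats(train), st)
  expect_false(identical(compute_norm_stats(val)$pixel_max, st$pixel_max))
  expect_error(compute_norm_stats(list(matrix(5, 2, 2))), "constant")
})

test_that("normalization maps the training range onto [0, 1] and clamps", {
  st <- compute_norm_stats(list(matrix(c(0, 100), 1, 2)))
  expect_equal(normalize_image(matrix(0), st)[1], 0)
  expect_equal(normalize_image(matrix(100), st)[1], 1)
  expect_equal(normalize_image(matrix(50), st)[1], 0.5)
  # out-of-range test pixel clamps to 1 instead of 1.5
  expect_equal(normalize_image(matrix(150), st)[1], 1)
  expect_equal(normalize_image(matrix(-20), st)[1], 0)
  expect_error(normalize_image(matrix(1), list(a = 1)), "fm_norm")
})

test_that("the classifier model meets its interface contracts", {
  model <- build_model(n_classes = 5, input_size = c(256, 256), seed = 2)
  expect_lt(fedmammo:::n_params(model$params), 2e6)
  fwd <- fedmammo:::cnn_forward(model$params, model$config,
                                matrix(runif(256 * 256), 256, 256))
  expect_length(fwd$logits, 5)
  expect_true(all(is.finite(fwd$logits)))
  expect_error(build_model(n_classes = 1), "n_classes")
})

test_that("centralized training runs its exact epoch protocol", {
  ds <- tiny_dataset(8, size = 16, seed = 3)
  model <- build_model(input_size = c(16, 16), channels = c(2L, 2L), seed = 4)
  cfg <- train_config(lr = 1e-3, batch_size = 4, epochs = 3, seed = 5)
  fit <- train_centralized(model, ds, ds, cfg)
  expect_equal(nrow(fit$history), 3)
  expect_equal(fit$history$epoch, 1:3)
  # determinism: same seed gives bit-identical weights
  fit2 <- train_centralized(model, ds, ds, cfg)
  expect_identical(fit$params, fit2$params)
})

test_that("loss decreases on a one-batch dataset at a workable rate", {
  ds <- tiny_dataset(6, n_classes = 3, size = 16, seed = 7)
  model <- build_model(n_classes = 3, input_size = c(16, 16),
                       channels = c(4L, 4L), seed = 8)
  cfg <- train_config(lr = 1e-3, batch_size = 6, epochs = 5, seed = 9)
  fit <- train_centralized(model, ds, ds, cfg)
  expect_lt(tail(fit$history$train_loss, 1), fit$history$train_loss[1])
})

test_that("macro F1 evaluation matches hand-computed cases", {
  # perfect predictions
  expect_equal(macro_f1(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5)), 1)
  # constant prediction on a balanced 2-class set of 10+10
  truth <- rep(c(1, 2), each = 10)
  expect_equal(macro_f1(truth, rep(1, 20)), (2 * 10 / (10 + 20)) / 2)
  # invariant to shuffling
  withr::with_seed(5, {
    truth <- sample(1:5, 60, replace = TRUE)
    pred <- sample(1:5, 60, replace = TRUE)
    ord <- sample(60)
    expect_equal(macro_f1(truth, pred), macro_f1(truth[ord], pred[ord]))
  })
})

test_that("macro F1 and confusion matrices match a from-scratch oracle", {
  withr::with_seed(13, {
    for (i in 1:1000) {
      k <- sample(2:5, 1)
      n <- sample(5:30, 1)
      truth <- sample.int(k, n, replace = TRUE)
      pred <- sample.int(k, n, replace = TRUE)
      cm <- confusion_matrix(truth, pred, classes = 1:k)
      # oracle: tabulate pairs by brute force
      oracle <- matrix(0L, k, k)
      for (j in seq_len(n)) oracle[truth[j], pred[j]] <-
          oracle[truth[j], pred[j]] + 1L
      expect_equal(unname(unclass(cm)), oracle)
      # macro F1 from the oracle matrix, classes present in truth
      present <- sort(unique(truth))
      f1s <- vapply(present, function(cl) {
        tp <- oracle[cl, cl]
        prec <- if (sum(oracle[, cl]) == 0) 0 else tp / sum(oracle[, cl])
        rec <- if (sum(oracle[cl, ]) == 0) 0 else tp / sum(oracle[cl, ])
        if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
      }, 0)
      expect_equal(macro_f1(truth, pred), mean(f1s))
    }
  })
})

test_that("evaluate_f1 reports per-named-set scores and confusions", {
  fit <- constant_prediction_fit(1)
  ds <- tiny_dataset(20, size = 16, seed = 21)
  ds$y <- rep(c(1L, 2L), each = 10)
  out <- evaluate_f1(fit, list(A = ds))
  expect_equal(out$A$f1, 1 / 3)
  expect_equal(dim(out$A$confusion), c(5, 5))
  expect_equal(sum(out$A$confusion), 20)
  expect_equal(unname(out$A$confusion[1, 1]), 10L)
  expect_error(evaluate_f1(fit, list(A = list(x = list(), y = integer(0)))),
               "empty test set")
})

test_that("centralized training recovers the lesion-BIRADS signal", {
  # 300-patient single-hospital cohort with the generator's deterministic
  # lesion-burden class signal; chance macro F1 is about 0.2 for 5 classes
  co <- generate_cohort(300, 1, list(clean_profile()), seed = 21,
                        image_size = c(64, 64))
  imgs <- lapply(co$records, function(r)
    resize2d(preprocess(r, c(64, 64))$pixels, c(64, 64)))
  sp <- patientwise_split(co$manifest, split_spec(seed = 3))
  mk <- function(m) list(x = imgs[m$image_index], y = as.integer(m$birads))
  tr <- mk(sp$train); va <- mk(sp$val); te <- mk(sp$test)
  norm <- compute_norm_stats(tr)
  nrm <- function(d) { d$x <- lapply(d$x, normalize_image, norm); d }
  tr <- nrm(tr); va <- nrm(va); te <- nrm(te)
  model <- build_model(input_size = c(64, 64), seed = 5)
  fit <- train_centralized(model, tr, va,
                           train_config(lr = 1e-3, batch_size = 10,
                                        epochs = 50, seed = 9))
  expect_gte(macro_f1(te$y, predict(fit, te)), 0.6)
})
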