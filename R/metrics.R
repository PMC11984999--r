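#' Dice and IoU overlap metrics
#'
#' `dice = 2|A∩B| / (|A| + |B|)`, `iou = |A∩B| / |A∪B|`. Two empty masks
#' are defined as perfect agreement (both metrics 1), so the metrics are
#' total on all binary mask pairs.
#'
#' @param pred,truth logical matrices of identical shape.
#' @return list with elements `dice` and `iou`, both in `[0, 1]`.
#' @export
dice_iou <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth)))
    stop_fm("mask shapes differ: %s vs %s",
            paste(dim(pred), collapse = "x"),
            paste(dim(truth), collapse = "x"))
  a <- sum(pred); b <- sum(truth); inter <- sum(pred & truth)
  if (a + b == 0) return(list(dice = 1, iou = 1))
  list(dice = 2 * inter / (a + b), iou = inter / (a + b - inter))
}

#' Confusion matrix for integer class labels
#'
#' @param truth,pred integer vectors of equal length.
#' @param classes class values defining the matrix order; defaults to the
#'   sorted union of observed values.
#' @return square integer matrix, rows = truth, cols = predicted.
#' @export
confusion_matrix <- function(truth, pred, classes = sort(unique(c(truth, pred)))) {
  stopifnot(length(truth) == length(pred))
  cm <- matrix(0L, length(classes), length(classes),
               dimnames = list(truth = classes, pred = classes))
  for (i in seq_along(truth)) {
    r <- match(truth[i], classes); c <- match(pred[i], classes)
    cm[r, c] <- cm[r, c] + 1L
  }
  cm
}

#' Macro-averaged F1 score
#'
#' Per-class F1 is averaged without weighting over the classes present in
#' the truth labels; classes the model predicts but that never occur in the
#' truth do not contribute. A class with no true or predicted positives
#' scores 0, the conservative convention under heavy class imbalance.
#'
#' @param truth,pred integer class vectors.
#' @return macro F1 in `[0, 1]`.
#' @export
macro_f1 <- function(truth, pred) {
  classes <- sort(unique(truth))
  f1 <- vapply(classes, function(k) {
    tp <- sum(truth == k & pred == k)
    fp <- sum(truth != k & pred == k)
    fn <- sum(truth == k & pred != k)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, 0)
  mean(f1)
}
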