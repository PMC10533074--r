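DICE_EPS <- 1.0

check_same_shape <- function(a, b) {
  da <- dim(a) %||% length(a)
  db <- dim(b) %||% length(b)
  if (!identical(as.integer(da), as.integer(db))) {
    stop("mask shapes differ: ", paste(da, collapse = "x"), " vs ",
         paste(db, collapse = "x"), call. = FALSE)
  }
}

check_binary <- function(m, what = "mask") {
  if (!all(m %in% c(0, 1))) {
    stop(what, " must be binary (values 0/1)", call. = FALSE)
  }
}

#' Pixel-level confusion counts
#'
#' Tallies true/false positives and negatives between a predicted binary
#' mask and the ground truth. A foreground pixel predicted foreground is a
#' true positive; a background pixel predicted foreground is a false
#' positive, and so on.
#'
#' @param pred Predicted binary mask (0/1).
#' @param truth Ground-truth binary mask, same shape.
#' @return A list with `tp`, `fp`, `tn`, `fn` (their sum is the pixel count).
#' @export
#' @examples
#' confusion_counts(matrix(c(1, 1, 0, 0), 2), matrix(c(1, 0, 1, 0), 2))
confusion_counts <- function(pred, truth) {
  check_same_shape(pred, truth)
  check_binary(pred, "pred")
  check_binary(truth, "truth")
  tp <- sum(pred == 1 & truth == 1)
  fp <- sum(pred == 1 & truth == 0)
  fn <- sum(pred == 0 & truth == 1)
  tn <- sum(pred == 0 & truth == 0)
  list(tp = tp, fp = fp, tn = tn, fn = fn)
}

ratio_or_flagged_zero <- function(num, den) {
  if (den == 0) structure(0, undefined = TRUE) else num / den
}

#' Confusion-count metrics: accuracy, precision, recall
#'
#' `accuracy` is `(TP + TN) / (TP + TN + FP + FN)`, `precision` is
#' `TP / (TP + FP)` and `recall` is `TP / (TP + FN)`. A zero denominator
#' (e.g. no predicted positives for precision) yields 0 with attribute
#' `undefined = TRUE` rather than an error.
#'
#' @param counts A confusion-count list from [confusion_counts()].
#' @return A number in `[0, 1]`.
#' @export
accuracy <- function(counts) {
  with(counts, ratio_or_flagged_zero(tp + tn, tp + tn + fp + fn))
}

#' @rdname accuracy
#' @export
precision <- function(counts) {
  with(counts, ratio_or_flagged_zero(tp, tp + fp))
}

#' @rdname accuracy
#' @export
recall <- function(counts) {
  with(counts, ratio_or_flagged_zero(tp, tp + fn))
}

#' Dice similarity coefficient and intersection over union
#'
#' Set-overlap scores between a predicted binary mask Y and the ground truth
#' X: `DSC = 2|X n Y| / (|X| + |Y|)` and `IoU = |X n Y| / |X u Y|`. The two
#' are linked by `DSC = 2 IoU / (1 + IoU)`. When both masks are empty the
#' value is 1 by convention (the limit of perfect agreement, needed for
#' all-background tiles).
#'
#' @param pred Predicted binary mask.
#' @param truth Ground-truth binary mask, same shape.
#' @return A number in `[0, 1]`.
#' @export
#' @examples
#' dice_coefficient(matrix(c(1, 1, 0, 0), 2), matrix(c(1, 0, 1, 0), 2))
dice_coefficient <- function(pred, truth) {
  check_same_shape(pred, truth)
  check_binary(pred, "pred")
  check_binary(truth, "truth")
  num <- 2 * sum(pred * truth)
  den <- sum(pred) + sum(truth)
  if (den == 0) 1 else num / den
}

#' @rdname dice_coefficient
#' @export
iou <- function(pred, truth) {
  check_same_shape(pred, truth)
  check_binary(pred, "pred")
  check_binary(truth, "truth")
  inter <- sum(pred * truth)
  union <- sum(pred) + sum(truth) - inter
  if (union == 0) 1 else inter / union
}

#' Smoothed Dice loss
#'
#' The Dice coefficient turned into a training loss:
#' `1 - (2 sum(p t) + eps) / (sum(p) + sum(t) + eps)`, where `p` is the
#' predicted probability map and `t` the binary truth. The smoothing
#' constant (default 1) stabilizes the all-empty case and is used only in
#' the loss, never in the reported metric; on binary inputs with `eps -> 0`
#' the loss equals `1 - DSC`.
#'
#' @param pred_prob Probability map in `[0, 1]`.
#' @param truth Binary ground-truth mask, same shape.
#' @param eps Smoothing constant.
#' @return A number in `[0, 1]`.
#' @export
dice_loss <- function(pred_prob, truth, eps = DICE_EPS) {
  check_same_shape(pred_prob, truth)
  stopifnot(all(pred_prob >= 0 & pred_prob <= 1))
  1 - (2 * sum(pred_prob * truth) + eps) /
    (sum(pred_prob) + sum(truth) + eps)
}

#' Pixel-wise area under the ROC curve
#'
#' The probability that a randomly chosen foreground pixel receives a higher
#' predicted score than a randomly chosen background pixel (Mann-Whitney
#' statistic over flattened pixels; ties count one half), identical to the
#' trapezoidal area under the ROC curve. Single-class truth makes the AUC
#' undefined; 0.5 is returned with attribute `undefined = TRUE`.
#'
#' @param pred_prob Probability/score map.
#' @param truth Binary ground-truth mask, same shape.
#' @return A number in `[0, 1]`.
#' @export
#' @examples
#' auc_pixelwise(c(0.9, 0.4, 0.6, 0.1), c(1, 1, 0, 0))  # 0.75
auc_pixelwise <- function(pred_prob, truth) {
  check_same_shape(pred_prob, truth)
  check_binary(truth, "truth")
  n1 <- sum(truth == 1)
  n0 <- sum(truth == 0)
  if (n1 == 0 || n0 == 0) return(structure(0.5, undefined = TRUE))
  r <- rank(as.vector(pred_prob))
  (sum(r[truth == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Full segmentation metric suite for one prediction
#'
#' Thresholds the probability map at `threshold` for the count-based metrics
#' (accuracy, precision, recall, Dice, IoU) and uses the raw probabilities
#' for the pixel-wise AUC.
#'
#' @param pred_prob Probability map in `[0, 1]`.
#' @param truth Binary ground-truth mask, same shape.
#' @param threshold Binarization threshold for the count-based metrics.
#' @return A one-row `data.frame` with columns `acc`, `pre`, `rec`, `dsc`,
#'   `iou`, `auc`.
#' @export
segmentation_metrics <- function(pred_prob, truth, threshold = 0.5) {
  pred <- (pred_prob >= threshold) * 1
  cc <- confusion_counts(pred, truth)
  data.frame(acc = as.numeric(accuracy(cc)),
             pre = as.numeric(precision(cc)),
             rec = as.numeric(recall(cc)),
             dsc = dice_coefficient(pred, truth),
             iou = iou(pred, truth),
             auc = as.numeric(auc_pixelwise(pred_prob, truth)))
}

#' Evaluate predictions over a whole set
#'
#' Applies [segmentation_metrics()] per image and appends a `mean` row.
#' AUC is pooled within each image and averaged across images.
#'
#' @param pred_probs List of probability maps.
#' @param truths List of binary masks, same shapes.
#' @param threshold Binarization threshold.
#' @return A `data.frame` with one row per image plus a final `"mean"` row
#'   (column `image`).
#' @export
evaluate_predictions <- function(pred_probs, truths, threshold = 0.5) {
  stopifnot(length(pred_probs) == length(truths), length(truths) > 0L)
  rows <- lapply(seq_along(pred_probs), function(i) {
    cbind(image = as.character(i),
          segmentation_metrics(pred_probs[[i]], truths[[i]], threshold))
  })
  out <- do.call(rbind, rows)
  means <- colMeans(out[, -1, drop = FALSE])
  rbind(out, cbind(image = "mean", as.data.frame(as.list(means))))
}
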