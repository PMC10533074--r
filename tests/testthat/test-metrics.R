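test_that("confusion counts match the hand-tallied toy fixture", {
  cc <- confusion_counts(toy_pred(), toy_truth())
  expect_equal(cc, list(tp = 3L, fp = 1L, tn = 11L, fn = 1L))
  expect_equal(with(cc, tp + fp + tn + fn), 16L)

  perfect <- confusion_counts(toy_truth(), toy_truth())
  expect_equal(perfect$tp, 4L)
  expect_equal(perfect$tn, 12L)
  expect_equal(perfect$fp + perfect$fn, 0L)

  inverted <- confusion_counts(1 - toy_truth(), toy_truth())
  expect_equal(inverted$tp, 0L)
  expect_equal(inverted$tn, 0L)

  expect_error(confusion_counts(matrix(0, 2, 2), matrix(0, 3, 3)),
               "shapes differ")
  expect_error(confusion_counts(matrix(0.5, 2, 2), matrix(0, 2, 2)),
               "binary")
})

test_that("accuracy, precision and recall follow their confusion-count formulas", {
  cc <- confusion_counts(toy_pred(), toy_truth())
  expect_equal(as.numeric(accuracy(cc)), 0.875)
  expect_equal(as.numeric(precision(cc)), 0.75)
  expect_equal(as.numeric(recall(cc)), 0.75)

  perfect <- confusion_counts(toy_truth(), toy_truth())
  expect_equal(as.numeric(accuracy(perfect)), 1)
  expect_equal(as.numeric(precision(perfect)), 1)
  expect_equal(as.numeric(recall(perfect)), 1)

  none <- list(tp = 0, fp = 0, tn = 5, fn = 2)
  p <- precision(none)
  expect_equal(as.numeric(p), 0)
  expect_true(isTRUE(attr(p, "undefined")))
})

test_that("Dice and IoU agree with their set formulas and conventions", {
  expect_equal(dice_coefficient(toy_pred(), toy_truth()), 0.75)  # 6/8
  expect_equal(iou(toy_pred(), toy_truth()), 0.6)                # 3/5
  expect_equal(dice_coefficient(toy_truth(), toy_truth()), 1)
  disjoint <- matrix(0, 4, 4)
  disjoint[4, 4] <- 1
  truth <- matrix(0, 4, 4)
  truth[1, 1] <- 1
  expect_equal(dice_coefficient(disjoint, truth), 0)
  expect_equal(iou(disjoint, truth), 0)
  empty <- matrix(0, 4, 4)
  expect_equal(dice_coefficient(empty, empty), 1)  # both-empty convention
  expect_equal(iou(empty, empty), 1)
})

test_that("set-formula and confusion-count formulations agree on random masks", {
  set.seed(31)
  for (i in 1:30) {
    pred <- random_binary_mask()
    truth <- random_binary_mask()
    cc <- confusion_counts(pred, truth)
    dsc <- dice_coefficient(pred, truth)
    j <- iou(pred, truth)
    expect_equal(dsc, with(cc, 2 * tp / (2 * tp + fp + fn)))
    expect_equal(j, with(cc, tp / (tp + fp + fn)))
    # DSC = 2 IoU / (1 + IoU) and IoU <= DSC
    expect_equal(dsc, 2 * j / (1 + j))
    expect_lte(j, dsc)
  }
})

test_that("Dice loss complements the Dice coefficient on binary masks", {
  pred <- toy_pred()
  truth <- toy_truth()
  expect_equal(dice_loss(pred, truth, eps = 0),
               1 - dice_coefficient(pred, truth))
  # |X| = 2, |Y| = 2, overlap 1 -> 1 - 2/4 = 0.5
  x <- matrix(0, 2, 2)
  x[1, 1] <- 1
  x[1, 2] <- 1
  y <- matrix(0, 2, 2)
  y[1, 1] <- 1
  y[2, 1] <- 1
  expect_equal(dice_loss(x, y, eps = 0), 0.5)
  expect_equal(dice_loss(truth, truth, eps = 0), 0)
  # smoothing keeps the perfect case near zero and the disjoint case near one
  expect_lt(dice_loss(truth, truth), 0.05)
  expect_gt(dice_loss(1 - truth, truth), 0.9)
  set.seed(5)
  for (i in 1:20) {
    p <- random_binary_mask()
    t <- random_binary_mask()
    expect_equal(dice_loss(p, t, eps = 0) + dice_coefficient(p, t), 1)
  }
})

test_that("pixel-wise AUC equals the Mann-Whitney statistic", {
  expect_equal(auc_pixelwise(c(0.9, 0.4, 0.6, 0.1), c(1, 1, 0, 0)), 0.75)
  truth <- toy_truth()
  expect_equal(as.numeric(auc_pixelwise(truth, truth)), 1)
  const <- auc_pixelwise(matrix(0.3, 4, 4), truth)
  expect_equal(as.numeric(const), 0.5)
  single <- auc_pixelwise(matrix(runif(16), 4, 4), matrix(1, 4, 4))
  expect_equal(as.numeric(single), 0.5)
  expect_true(isTRUE(attr(single, "undefined")))
})

test_that("metrics are invariant to a shared spatial permutation", {
  set.seed(17)
  pred_prob <- matrix(runif(64), 8, 8)
  truth <- random_binary_mask(8)
  perm <- sample(64)
  m1 <- segmentation_metrics(pred_prob, truth)
  m2 <- segmentation_metrics(matrix(pred_prob[perm], 8, 8),
                             matrix(truth[perm], 8, 8))
  expect_equal(m1, m2)
})

test_that("batch evaluation reports per-image rows plus a mean row", {
  preds <- list(toy_truth(), toy_pred())
  truths <- list(toy_truth(), toy_truth())
  out <- evaluate_predictions(preds, truths)
  expect_equal(nrow(out), 3L)
  expect_equal(out$image, c("1", "2", "mean"))
  expect_equal(out$dsc[1], 1)
  expect_equal(out$dsc[3], mean(out$dsc[1:2]))
  # perfect oracle predictions score 1 everywhere
  oracle <- evaluate_predictions(list(toy_truth()), list(toy_truth()))
  expect_true(all(oracle[1, -1] == 1))
})
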