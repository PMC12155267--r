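toy_gt <- matrix(c(1, 1, 0, 0), 2, 2, byrow = TRUE)    # top row person
toy_pred <- matrix(c(1, 0, 0, 0), 2, 2, byrow = TRUE)  # one person pixel missed

test_that("hand-counted 2x2 example matches all pixel metrics", {
  expect_equal(global_accuracy(toy_pred, toy_gt), 0.75)
  expect_equal(mean_accuracy(toy_pred, toy_gt), (1 / 2 + 2 / 2) / 2)
  iou <- iou_per_class(toy_pred, toy_gt)
  expect_equal(unname(iou["person"]), 1 / 2)
  expect_equal(unname(iou["background"]), 2 / 3)
  expect_equal(mean_iou(toy_pred, toy_gt), 7 / 12)
  # balanced classes: weighted IoU equals the hand-weighted sum and mean IoU
  expect_equal(weighted_iou(toy_pred, toy_gt),
               (2 * (1 / 2) + 2 * (2 / 3)) / 4)
  expect_equal(weighted_iou(toy_pred, toy_gt), mean_iou(toy_pred, toy_gt))
})

test_that("all metrics are exactly one on identical masks and degrade to zero", {
  set.seed(2)
  m <- matrix(rbinom(100, 1, 0.5), 10, 10)
  expect_equal(global_accuracy(m, m), 1)
  expect_equal(mean_accuracy(m, m), 1)
  expect_equal(mean_iou(m, m), 1)
  expect_equal(weighted_iou(m, m), 1)
  expect_equal(mean_bf_score(m, m, tol = 0), 1)
  expect_equal(global_accuracy(1 - m, m), 0)
  # fully-missed person class on a balanced ground truth
  gt <- matrix(c(rep(1, 50), rep(0, 50)), 10, 10)
  expect_equal(mean_accuracy(matrix(0, 10, 10), gt), 0.5)
  # disjoint person predictions: person IoU 0
  a <- matrix(0, 4, 4); a[1, 1] <- 1
  b <- matrix(0, 4, 4); b[4, 4] <- 1
  expect_equal(unname(iou_per_class(a, b)["person"]), 0)
})

test_that("shape mismatches and absent classes are rejected", {
  expect_error(global_accuracy(matrix(0, 2, 2), matrix(0, 3, 3)), "shape")
  expect_error(mean_accuracy(matrix(0, 2, 2), matrix(0, 2, 2)), "absent")
})

test_that("weighted IoU follows ground-truth class weights on an imbalanced grid", {
  gt <- matrix(0, 4, 4); gt[1, ] <- 1          # 4 person, 12 background
  pred <- gt; pred[1, 1] <- 0; pred[2, 1] <- 1
  w_oracle <- oracle_weighted_iou(pred, gt)
  expect_equal(weighted_iou(pred, gt), w_oracle)
  expect_false(isTRUE(all.equal(weighted_iou(pred, gt), mean_iou(pred, gt))))
})

test_that("boundary F1 respects the distance tolerance", {
  gt <- matrix(0, 12, 12); gt[4:9, 4:9] <- 1
  pred <- matrix(0, 12, 12); pred[5:10, 4:9] <- 1   # shifted 1 px down
  expect_equal(unname(boundary_f1(pred, gt, tol = 2)["person"]), 1)
  expect_lt(unname(boundary_f1(pred, gt, tol = 0)["person"]), 1)
})

test_that("all five metrics match brute-force enumeration on random mask pairs", {
  set.seed(11)
  for (rep in 1:100) {
    p <- random_mask_pair(10, 10)
    if (!all(c(0, 1) %in% p$gt)) next
    expect_equal(global_accuracy(p$pred, p$gt),
                 oracle_global_accuracy(p$pred, p$gt))
    expect_equal(mean_accuracy(p$pred, p$gt),
                 mean(c(oracle_class_recall(p$pred, p$gt, 0),
                        oracle_class_recall(p$pred, p$gt, 1))))
    expect_equal(mean_iou(p$pred, p$gt),
                 mean(c(oracle_iou(p$pred, p$gt, 0),
                        oracle_iou(p$pred, p$gt, 1))))
    expect_equal(weighted_iou(p$pred, p$gt), oracle_weighted_iou(p$pred, p$gt))
  }
})

test_that("boundary F1 matches the brute-force boundary matcher", {
  set.seed(13)
  for (rep in 1:20) {
    p <- random_mask_pair(8, 8)
    for (tol in c(0, 1, 2)) {
      expect_equal(
        unname(boundary_f1(p$pred, p$gt, tol = tol)),
        c(oracle_boundary_f1(p$pred, p$gt, 0, tol),
          oracle_boundary_f1(p$pred, p$gt, 1, tol)),
        tolerance = 1e-12,
        info = sprintf("rep %d tol %g", rep, tol))
    }
  }
})

test_that("the report bundle collects the five headline fields", {
  s <- generate_subject(synth_spec(rows = 300, cols = 200, height_px = 250))
  rep <- seg_metrics(s$mask, s$mask)
  expect_s3_class(rep, "seg_metrics")
  vals <- unlist(rep[c("global_accuracy", "mean_accuracy", "mean_iou",
                       "weighted_iou", "mean_bf_score")])
  expect_true(all(vals == 1))
})
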