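mk_det <- function(image, class, xc, yc, w, h, conf) {
  data.frame(image = image, class = class, xc = xc, yc = yc, w = w, h = h, conf = conf)
}
mk_gt <- function(image, class, xc, yc, w, h) {
  data.frame(image = image, class = class, xc = xc, yc = yc, w = w, h = h)
}

test_that("greedy matching follows the confidence-then-IoU protocol", {
  g <- mk_gt("a", 0, 5, 5, 2, 2)
  d <- mk_det("a", 0, 5.4, 5, 2, 2, 0.9)  # IoU = 1.6/2.4 = 2/3
  m <- match_detections(d, g, 0.5)
  expect_true(m$tp)
  expect_true(m$gt_matched)
  # two detections over one gt: the higher-confidence one wins
  d2 <- mk_det("a", c(0, 0), c(5.2, 5.1), 5, 2, 2, c(0.5, 0.8))
  m2 <- match_detections(d2, g, 0.5)
  expect_equal(m2$order, c(2L, 1L))
  expect_equal(m2$tp, c(TRUE, FALSE))
  # no detections: everything is a miss
  m3 <- match_detections(d[0, ], g, 0.5)
  expect_equal(sum(m3$gt_matched), 0)
})

test_that("precision and recall follow the zero-denominator convention", {
  expect_equal(precision_recall(2, 1, 0), c(precision = 2 / 3, recall = 1))
  expect_equal(precision_recall(4, 0, 0), c(precision = 1, recall = 1))
  expect_equal(precision_recall(0, 0, 3), c(precision = 0, recall = 0))
  expect_error(precision_recall(-1, 0, 0), "nonnegative")
})

test_that("101-point average precision matches hand-computed cases", {
  expect_equal(average_precision(TRUE, 1), 1.0)
  expect_equal(average_precision(c(TRUE, FALSE, TRUE), 2), (51 + 50 * 2 / 3) / 101)
  expect_equal(average_precision(c(FALSE, FALSE), 3), 0.0)
  expect_error(average_precision(c(TRUE), 0), "num_gt")
})

test_that("AP depends on confidence ranks only", {
  set.seed(5)
  pr <- random_eval_problem()
  r1 <- map_range(pr$dets, pr$gts)
  pr$dets$conf <- pr$dets$conf * 0.37 + 1e-4   # monotone rescale
  r2 <- map_range(pr$dets, pr$gts)
  expect_equal(r1$ap_matrix, r2$ap_matrix, tolerance = 1e-12)
})

test_that("single detection at IoU 0.6 passes exactly three thresholds", {
  g <- mk_gt("a", 0, 5, 5, 2, 2)
  # width-aligned offset: IoU = (2 - dx) / (2 + dx) = 0.6 at dx = 0.5
  d <- mk_det("a", 0, 5.5, 5, 2, 2, 0.9)
  expect_equal(ag_value(iou(bbox(5.5, 5, 2, 2), bbox(5, 5, 2, 2))), 0.6)
  r <- map_range(d, g, classes = 0)
  expect_equal(r$map50, 1.0)
  expect_equal(r$map, 0.3)
})

test_that("mAP@0.5:0.95 never exceeds mAP@0.5 and is 1 for perfect detections", {
  set.seed(6)
  for (i in 1:10) {
    pr <- random_eval_problem()
    r <- map_range(pr$dets, pr$gts)
    expect_lte(r$map, r$map50 + 1e-12)
  }
  gts <- mk_gt("a", c(0, 1), c(3, 6), c(3, 6), 1.5, 1.5)
  dets <- cbind(gts, conf = 0.8)
  r <- map_range(dets, gts, classes = 0:1)
  expect_equal(r$map50, 1.0)
  expect_equal(r$map, 1.0)
})

test_that("map_range agrees with the brute-force evaluator on random problems", {
  set.seed(17)
  th <- seq(0.5, 0.95, by = 0.05)
  for (i in 1:25) {
    pr <- random_eval_problem()
    cls <- sort(unique(pr$gts$class))
    a <- map_range(pr$dets, pr$gts, classes = cls)
    b <- brute_force_map(pr$dets, pr$gts, cls, th)
    expect_lt(max(abs(a$ap_matrix - b$ap)), 1e-9)
  }
})

test_that("confusion matrix routes hits, misses and ghosts correctly", {
  gts <- mk_gt("a", c(0, 1, 2), c(2, 5, 8), c(2, 5, 8), 1, 1)
  dets <- rbind(mk_det("a", c(0, 1), c(2, 5), c(2, 5), 1, 1, 0.9),  # two hits
                mk_det("a", 1, 12, 12, 1, 1, 0.8))                   # ghost of class 1
  cm <- confusion_matrix(dets, gts, num_classes = 3)
  expect_equal(unname(diag(cm)[1:2]), c(1, 1))
  expect_equal(unname(cm[4, 3]), 1)  # missed class-2 gt -> background row
  expect_equal(unname(cm[2, 4]), 1)  # spurious class-1 det -> background column
  # column sums over true classes equal gt counts per class
  expect_equal(unname(colSums(cm)[1:3]), c(1, 1, 1))
  cmn <- confusion_matrix(dets, gts, num_classes = 3, normalize = TRUE)
  expect_true(all(colSums(cmn)[1:3] == 1))
})

test_that("confusion-matrix column sums equal gt counts on random problems", {
  set.seed(23)
  for (i in 1:10) {
    pr <- random_eval_problem(nc = 4)
    cm <- confusion_matrix(pr$dets, pr$gts, num_classes = 4, conf_thresh = 0)
    cnt <- table(factor(pr$gts$class, levels = 0:3))
    expect_equal(unname(colSums(cm)[1:4]), as.numeric(cnt))
  }
})
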