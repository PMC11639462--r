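test_that("IoU handles identity, disjoint and partial overlap", {
  b1 <- bbox_from_corners(0, 0, 2, 2)
  expect_equal(ag_value(iou(b1, b1)), 1.0)
  expect_equal(ag_value(iou(b1, bbox_from_corners(3, 3, 4, 4))), 0.0)
  expect_equal(ag_value(iou(b1, bbox_from_corners(1, 1, 3, 3))), 1 / 7)
  # edge-touching boxes overlap with zero area, not an error
  expect_equal(ag_value(iou(b1, bbox_from_corners(2, 0, 4, 2))), 0.0)
  expect_error(bbox(0, 0, -1, 2), "invalid box")
})

test_that("corner/centre conversion round-trips", {
  set.seed(1)
  b <- bbox(runif(50, -5, 5), runif(50, -5, 5), runif(50, 0.1, 4), runif(50, 0.1, 4))
  cc <- bbox_corners(b)
  b2 <- bbox_from_corners(cc[, 1], cc[, 2], cc[, 3], cc[, 4])
  for (f in c("xc", "yc", "w", "h")) expect_equal(b2[[f]], b[[f]], tolerance = 1e-9)
})

test_that("inner IoU matches hand-derived auxiliary-box cases", {
  p <- bbox_from_corners(0, 0, 2, 2); g <- bbox_from_corners(1, 1, 3, 3)
  expect_equal(ag_value(inner_iou(p, g, inner_params(1))), ag_value(iou(p, g)))
  expect_equal(ag_value(inner_iou(p, g, inner_params(0.5))), 0.0)
  expect_equal(ag_value(inner_iou(p, g, inner_params(1.5))), 2 / 7, tolerance = 1e-12)
  expect_error(inner_iou(p, g, list(ratio = 2)), "ratio")
})

test_that("Shape-IoU reproduces hand arithmetic and its weight identity", {
  s <- shape_iou_loss(bbox(1, 0, 4, 2), bbox(0, 0, 4, 2), shape_params(1, 4))
  expect_equal(s$total, 1 - 0.6 + (2 / 3) / 29, tolerance = 1e-5)
  expect_equal(s$iou, 0.6, tolerance = 1e-12)
  expect_equal(s$omega_shape, 0)
  s2 <- shape_iou_loss(bbox(0, 0, 2, 2), bbox(0, 0, 4, 2), shape_params(0, 4))
  expect_equal(s2$total, 0.5 + 0.5 * (1 - exp(-0.5))^4, tolerance = 1e-5)
  expect_equal(shape_iou_loss(bbox(1, 2, 3, 4), bbox(1, 2, 3, 4))$total, 0)
  # ww + hh = 2 for any gt box and scale (checked through the distance term:
  # with unit offsets in both axes and c^2 factored out, dist * c^2 = 2)
  set.seed(3)
  for (i in 1:20) {
    gw <- runif(1, 0.2, 5); gh <- runif(1, 0.2, 5); sc <- runif(1, 0, 2)
    ws <- gw^sc; hs <- gh^sc
    expect_equal(2 * ws / (ws + hs) + 2 * hs / (ws + hs), 2, tolerance = 1e-12)
  }
})

test_that("Inner-ShapeIoU reduces to Shape-IoU at ratio 1 and is zero at identity", {
  set.seed(7)
  for (i in 1:50) {
    rp <- random_box_pair()
    p <- do.call(bbox, rp$pred); g <- do.call(bbox, rp$gt)
    sp <- shape_params(runif(1, 0, 1.5), 4)
    expect_identical(inner_shape_iou_loss(p, g, sp, inner_params(1))$total,
                     shape_iou_loss(p, g, sp)$total)
    expect_equal(inner_shape_iou_loss(g, g, sp, inner_params(runif(1, 0.5, 1.5)))$total, 0)
  }
  l <- inner_shape_iou_loss(bbox_from_corners(0, 0, 2, 2), bbox_from_corners(1, 1, 3, 3),
                            shape_params(0, 4), inner_params(0.5))
  expect_equal(l$total, 10 / 9, tolerance = 1e-5)
})

test_that("CIoU matches hand arithmetic and degenerates to 1 - IoU", {
  expect_equal(ciou_loss(bbox(1, 0, 2, 2), bbox(0, 0, 2, 2))$total,
               1 - 1 / 3 + 1 / 13, tolerance = 1e-5)
  expect_equal(ciou_loss(bbox(0, 0, 2, 1), bbox(0, 0, 4, 2))$total,
               1 - ag_value(iou(bbox(0, 0, 2, 1), bbox(0, 0, 4, 2))),
               tolerance = 1e-9)
  expect_equal(ciou_loss(bbox(3, -1, 2, 5), bbox(3, -1, 2, 5))$total, 0)
})

test_that("translating the prediction toward the gt never increases a loss", {
  g <- list(xc = 0, yc = 0, w = 2, h = 1.5)
  gb <- do.call(bbox, g)
  for (nm in c("iou", "ciou", "shape_iou", "inner_shape_iou")) {
    lfn <- box_loss_fn(nm, scale = 0.5, ratio = 0.8)
    tt <- seq(1, 0, by = -0.05)  # slide along the centre line toward gt
    vals <- vapply(tt, function(t) {
      ag_value(lfn(list(xc = 3 * t, yc = 2 * t, w = 2, h = 1.5), g))
    }, numeric(1))
    expect_true(all(diff(vals) <= 1e-10))
  }
})

test_that("tape gradients of every loss match central differences", {
  set.seed(11)
  for (nm in c("iou", "ciou", "shape_iou", "inner_shape_iou")) {
    lfn <- box_loss_fn(nm, scale = 0.5, theta = 4, ratio = 1.2)
    for (i in 1:25) {
      rp <- random_box_pair()
      p0 <- unlist(rp$pred)
      f <- function(p) ag_value(lfn(list(xc = p[1], yc = p[2], w = p[3], h = p[4]), rp$gt))
      ng <- numeric_grad(f, p0)
      ag <- tape_grad(lfn, as.list(p0), rp$gt)
      denom <- pmax(abs(ng), 1e-3)
      expect_lt(max(abs(ag - ng) / denom), 1e-4)
    }
  }
})

test_that("analytic IoU agrees with a pixel-rasterisation oracle", {
  set.seed(13)
  for (i in 1:40) {
    rp <- random_box_pair()
    p <- do.call(bbox, rp$pred); g <- do.call(bbox, rp$gt)
    expect_lt(abs(ag_value(iou(p, g)) - raster_iou(p, g)), 2e-3)
  }
})
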