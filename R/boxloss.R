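# Bounding-box geometry and the regression-loss family: IoU, CIoU (baseline),
# Shape-IoU, Inner-IoU and the combined Inner-ShapeIoU. All functions are
# vectorised over n box pairs and run unchanged on agTensor components, so the
# training loop differentiates through them.

#' Axis-aligned bounding boxes in centre form
#'
#' @param xc,yc box centre coordinates
#' @param w,h box width and height (must be > 0)
#' @return object of class `bbox`: parallel vectors xc, yc, w, h
#' @examples
#' b <- bbox(1, 1, 2, 2)
#' bbox_corners(b)
#' @export
bbox <- function(xc, yc, w, h) {
  stopifnot(length(xc) == length(yc), length(w) == length(h),
            length(xc) == length(w))
  if (any(!is.finite(c(xc, yc, w, h)))) stop("box coordinates must be finite")
  if (any(w <= 0) || any(h <= 0)) stop("invalid box: width and height must be positive")
  structure(list(xc = as.double(xc), yc = as.double(yc),
                 w = as.double(w), h = as.double(h)), class = "bbox")
}

#' @export
print.bbox <- function(x, ...) {
  cat("<bbox:", length(x$xc), "box(es)>\n")
  print(data.frame(xc = x$xc, yc = x$yc, w = x$w, h = x$h), ...)
  invisible(x)
}

#' @export
length.bbox <- function(x) length(x$xc)

#' Corner view (x1, y1, x2, y2) of centre-form boxes
#' @param b a `bbox`
#' @return matrix with columns x1, y1, x2, y2
#' @export
bbox_corners <- function(b) {
  cbind(x1 = b$xc - b$w / 2, y1 = b$yc - b$h / 2,
        x2 = b$xc + b$w / 2, y2 = b$yc + b$h / 2)
}

#' Build boxes from corner coordinates
#' @param x1,y1,x2,y2 corner coordinates, x2 > x1 and y2 > y1
#' @return a `bbox`
#' @export
bbox_from_corners <- function(x1, y1, x2, y2) {
  bbox((x1 + x2) / 2, (y1 + y2) / 2, x2 - x1, y2 - y1)
}

#' Shape-IoU loss parameters
#' @param scale nonnegative exponent tied to typical target size (default 0)
#' @param theta shape-cost power (default 4)
#' @export
shape_params <- function(scale = 0, theta = 4) {
  if (scale < 0) stop("scale must be >= 0")
  if (theta <= 0) stop("theta must be > 0")
  list(scale = scale, theta = theta)
}

#' Inner-IoU parameters
#' @param ratio auxiliary-box scaling factor, within [0.5, 1.5] (default 1)
#' @export
inner_params <- function(ratio = 1) {
  if (ratio < 0.5 || ratio > 1.5) stop("ratio must lie in [0.5, 1.5]")
  list(ratio = ratio)
}

# --- differentiable cores on box components ---------------------------------

iou_core <- function(px, py, pw, ph, gx, gy, gw, gh) {
  ix <- ag_pmax(ag_pmin(px + pw / 2, gx + gw / 2) - ag_pmax(px - pw / 2, gx - gw / 2), 0)
  iy <- ag_pmax(ag_pmin(py + ph / 2, gy + gh / 2) - ag_pmax(py - ph / 2, gy - gh / 2), 0)
  inter <- ix * iy
  inter / (pw * ph + gw * gh - inter)
}

# squared diagonal of the minimal box enclosing both boxes
encl_diag2 <- function(px, py, pw, ph, gx, gy, gw, gh) {
  cw <- ag_pmax(px + pw / 2, gx + gw / 2) - ag_pmin(px - pw / 2, gx - gw / 2)
  chh <- ag_pmax(py + ph / 2, gy + gh / 2) - ag_pmin(py - ph / 2, gy - gh / 2)
  cw * cw + chh * chh
}

inner_iou_core <- function(px, py, pw, ph, gx, gy, gw, gh, ratio) {
  iou_core(px, py, pw * ratio, ph * ratio, gx, gy, gw * ratio, gh * ratio)
}

shape_iou_core <- function(px, py, pw, ph, gx, gy, gw, gh, scale, theta) {
  iou <- iou_core(px, py, pw, ph, gx, gy, gw, gh)
  ws <- ag_value(gw)^scale
  hs <- ag_value(gh)^scale
  ww <- 2 * ws / (ws + hs)   # gt-only weights: constants w.r.t. the prediction
  hh <- 2 * hs / (ws + hs)
  c2 <- encl_diag2(px, py, pw, ph, gx, gy, gw, gh)
  dist <- (hh * (px - gx)^2 + ww * (py - gy)^2) / c2
  dw <- ag_abs(pw - gw) / ag_pmax(pw, gw)
  dh <- ag_abs(ph - gh) / ag_pmax(ph, gh)
  omega <- (1 - ag_exp(-dw))^theta + (1 - ag_exp(-dh))^theta
  list(iou = iou, distance = dist, omega = omega,
       total = 1 - iou + dist + 0.5 * omega)
}

ciou_core <- function(px, py, pw, ph, gx, gy, gw, gh) {
  iou <- iou_core(px, py, pw, ph, gx, gy, gw, gh)
  c2 <- encl_diag2(px, py, pw, ph, gx, gy, gw, gh)
  d2 <- (px - gx)^2 + (py - gy)^2
  v <- (4 / pi^2) * (atan(ag_value(gw) / ag_value(gh)) - my_atan2(pw, ph))^2
  alpha <- v / (1 - iou + v + 1e-12)
  list(iou = iou, total = 1 - iou + d2 / c2 + alpha * v)
}

# atan(w/h) through the tape (h > 0 so plain atan of the ratio is safe)
my_atan2 <- function(w, h) {
  r <- w / h
  rv <- ag_value(r)
  ag_node(atan(rv), list(r), function(g) list(g / (1 + rv * rv)))
}

inner_shape_core <- function(px, py, pw, ph, gx, gy, gw, gh, scale, theta, ratio) {
  s <- shape_iou_core(px, py, pw, ph, gx, gy, gw, gh, scale, theta)
  if (ratio == 1) {
    # IoU - IoU_inner vanishes identically; keep the identity exact
    s$inner_iou <- s$iou
    return(s)
  }
  ii <- inner_iou_core(px, py, pw, ph, gx, gy, gw, gh, ratio)
  s$inner_iou <- ii
  s$total <- s$total + s$iou - ii
  s
}

# --- public operations -------------------------------------------------------

unpack2 <- function(pred, gt) {
  stopifnot(inherits(pred, "bbox"), inherits(gt, "bbox"))
  if (length(pred) != length(gt) && length(pred) != 1L && length(gt) != 1L)
    stop("pred and gt must have matching length (or length 1)")
  list(px = pred$xc, py = pred$yc, pw = pred$w, ph = pred$h,
       gx = gt$xc, gy = gt$yc, gw = gt$w, gh = gt$h)
}

#' Intersection over union of two boxes
#'
#' Overlap area divided by union area; 0 for disjoint or degenerate
#' (edge/corner touching) overlap.
#' @param a,b `bbox` objects of equal length
#' @return IoU values in [0, 1]
#' @examples
#' iou(bbox_from_corners(0, 0, 2, 2), bbox_from_corners(1, 1, 3, 3))  # 1/7
#' @export
iou <- function(a, b) {
  u <- unpack2(a, b)
  iou_core(u$px, u$py, u$pw, u$ph, u$gx, u$gy, u$gw, u$gh)
}

#' Inner-IoU: IoU of centre-scaled auxiliary boxes
#'
#' Each box's width and height are scaled by `ratio` about its own centre and
#' plain IoU is computed on the auxiliary pair. `ratio = 1` reduces to [iou()].
#' @param pred,gt `bbox` objects
#' @param p parameters from [inner_params()]
#' @export
inner_iou <- function(pred, gt, p = inner_params()) {
  p <- do.call(inner_params, p["ratio"])  # re-validate
  u <- unpack2(pred, gt)
  inner_iou_core(u$px, u$py, u$pw, u$ph, u$gx, u$gy, u$gw, u$gh, p$ratio)
}

breakdown <- function(parts) {
  structure(lapply(parts, ag_value), class = "loss_breakdown")
}

#' @export
print.loss_breakdown <- function(x, ...) {
  cat("<loss breakdown>\n")
  print(data.frame(lapply(unclass(x), function(v) round(v, 6))), ...)
  invisible(x)
}

#' Shape-IoU bounding-box regression loss
#'
#' `1 - IoU + distance + 0.5 * omega`, where the centre-distance term is
#' weighted by the ground-truth box's normalised side lengths (exponent
#' `scale`), normalised by the squared diagonal of the minimal enclosing box,
#' and the shape cost `omega` penalises relative width/height mismatch raised
#' to the power `theta`.
#' @param pred,gt `bbox` objects
#' @param p parameters from [shape_params()]
#' @return a `loss_breakdown` with fields iou, distance_shape, omega_shape, total
#' @export
shape_iou_loss <- function(pred, gt, p = shape_params()) {
  p <- do.call(shape_params, p[c("scale", "theta")])
  u <- unpack2(pred, gt)
  s <- shape_iou_core(u$px, u$py, u$pw, u$ph, u$gx, u$gy, u$gw, u$gh,
                      p$scale, p$theta)
  breakdown(list(iou = s$iou, distance_shape = s$distance,
                 omega_shape = s$omega, total = s$total))
}

#' Inner-ShapeIoU loss: Shape-IoU with the auxiliary-box correction
#'
#' `L = L_shape + IoU - IoU_inner`. With `ratio = 1` the correction vanishes
#' and the loss equals [shape_iou_loss()] exactly.
#' @param pred,gt `bbox` objects
#' @param sp shape parameters from [shape_params()]
#' @param ip inner parameters from [inner_params()]
#' @export
inner_shape_iou_loss <- function(pred, gt, sp = shape_params(), ip = inner_params()) {
  sp <- do.call(shape_params, sp[c("scale", "theta")])
  ip <- do.call(inner_params, ip["ratio"])
  u <- unpack2(pred, gt)
  s <- inner_shape_core(u$px, u$py, u$pw, u$ph, u$gx, u$gy, u$gw, u$gh,
                        sp$scale, sp$theta, ip$ratio)
  breakdown(list(iou = s$iou, inner_iou = s$inner_iou,
                 distance_shape = s$distance, omega_shape = s$omega,
                 total = s$total))
}

#' Complete-IoU (CIoU) loss, the baseline regression loss
#'
#' `1 - IoU + d^2/c^2 + alpha * v` with `v` the aspect-ratio consistency term.
#' @param pred,gt `bbox` objects
#' @export
ciou_loss <- function(pred, gt) {
  u <- unpack2(pred, gt)
  s <- ciou_core(u$px, u$py, u$pw, u$ph, u$gx, u$gy, u$gw, u$gh)
  breakdown(list(iou = s$iou, total = s$total))
}

#' Select a box regression loss by name (training-config interface)
#'
#' @param name one of "ciou", "shape_iou", "inner_shape_iou", "iou"
#' @param scale,theta,ratio loss hyper-parameters (see [shape_params()],
#'   [inner_params()])
#' @return function(pred_components, gt_components) -> total loss vector,
#'   where components are lists with fields xc, yc, w, h (possibly agTensors)
#' @export
box_loss_fn <- function(name = "ciou", scale = 0, theta = 4, ratio = 1) {
  name <- match.arg(name, c("ciou", "shape_iou", "inner_shape_iou", "iou"))
  sp <- shape_params(scale, theta); ip <- inner_params(ratio)
  function(p, g) {
    switch(name,
      iou = 1 - iou_core(p$xc, p$yc, p$w, p$h, g$xc, g$yc, g$w, g$h),
      ciou = ciou_core(p$xc, p$yc, p$w, p$h, g$xc, g$yc, g$w, g$h)$total,
      shape_iou = shape_iou_core(p$xc, p$yc, p$w, p$h, g$xc, g$yc, g$w, g$h,
                                 sp$scale, sp$theta)$total,
      inner_shape_iou = inner_shape_core(p$xc, p$yc, p$w, p$h,
                                         g$xc, g$yc, g$w, g$h,
                                         sp$scale, sp$theta, ip$ratio)$total)
  }
}
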