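# Independent oracles used across the suite. These deliberately avoid the
# package's analytic code paths: rasterised IoU, a naive double-loop
# evaluator, dense 2-D convolution by explicit loops, and central-difference
# numerical gradients.

# IoU by rasterisation: count grid-cell centres inside each box
raster_iou <- function(a, b, n = 600L) {
  ca <- bbox_corners(a); cb <- bbox_corners(b)
  x0 <- min(ca[1], cb[1]); x1 <- max(ca[3], cb[3])
  y0 <- min(ca[2], cb[2]); y1 <- max(ca[4], cb[4])
  xs <- x0 + (seq_len(n) - 0.5) / n * (x1 - x0)
  ys <- y0 + (seq_len(n) - 0.5) / n * (y1 - y0)
  gx <- matrix(xs, n, n); gy <- matrix(ys, n, n, byrow = TRUE)
  ina <- gx > ca[1] & gx < ca[3] & gy > ca[2] & gy < ca[4]
  inb <- gx > cb[1] & gx < cb[3] & gy > cb[2] & gy < cb[4]
  sum(ina & inb) / sum(ina | inb)
}

# random overlapping-ish box pair (components list)
random_box_pair <- function() {
  g <- list(xc = runif(1, -2, 2), yc = runif(1, -2, 2),
            w = runif(1, 0.5, 3), h = runif(1, 0.5, 3))
  p <- list(xc = g$xc + runif(1, -0.8, 0.8) * g$w,
            yc = g$yc + runif(1, -0.8, 0.8) * g$h,
            w = g$w * exp(runif(1, -0.6, 0.6)),
            h = g$h * exp(runif(1, -0.6, 0.6)))
  list(pred = p, gt = g)
}

# central-difference gradient of f at 4-vector p
numeric_grad <- function(f, p, eps = 1e-6) {
  vapply(1:4, function(j) {
    p1 <- p; p1[j] <- p1[j] + eps
    p2 <- p; p2[j] <- p2[j] - eps
    (f(p1) - f(p2)) / (2 * eps)
  }, numeric(1))
}

# tape gradient of a box loss w.r.t. the prediction (xc, yc, w, h)
tape_grad <- function(lfn, p, g) {
  leaves <- lapply(p, ag_leaf)
  l <- lfn(list(xc = leaves[[1]], yc = leaves[[2]], w = leaves[[3]], h = leaves[[4]]), g)
  ag_backward(l)
  vapply(leaves, function(x) as.numeric(x$grad %||% 0), numeric(1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# naive dense 2-D convolution (single channel bank, groups = C depthwise)
naive_depthwise_conv <- function(x, k) {
  r <- (nrow(k) - 1L) %/% 2L
  d <- dim(x)
  out <- array(0, dim = d)
  # reflect padding
  ri <- c(rev(seq_len(r) + 1L), seq_len(d[1]), d[1] - seq_len(r))
  ci <- c(rev(seq_len(r) + 1L), seq_len(d[2]), d[2] - seq_len(r))
  for (cc in seq_len(d[3])) for (n in seq_len(d[4])) {
    xp <- x[ri, ci, cc, n]
    for (i in seq_len(d[1])) for (j in seq_len(d[2]))
      out[i, j, cc, n] <- sum(xp[i:(i + 2 * r), j:(j + 2 * r)] * k)
  }
  out
}

# brute-force detection evaluator: explicit matching + explicit 101-point AP
brute_force_map <- function(dets, gts, classes, thresholds) {
  ap <- matrix(0, length(classes), length(thresholds))
  for (ci in seq_along(classes)) {
    cl <- classes[ci]
    dc <- dets[dets$class == cl, , drop = FALSE]
    gc_ <- gts[gts$class == cl, , drop = FALSE]
    for (ti in seq_along(thresholds)) {
      th <- thresholds[ti]
      flags <- logical(0); confs <- numeric(0)
      for (img in unique(c(dc$image, gc_$image))) {
        di <- dc[dc$image == img, , drop = FALSE]
        gi <- gc_[gc_$image == img, , drop = FALSE]
        di <- di[order(-di$conf), , drop = FALSE]
        used <- logical(nrow(gi))
        for (i in seq_len(nrow(di))) {
          best <- -1; bj <- 0
          for (j in seq_len(nrow(gi))) {
            if (used[j]) next
            ix <- min(di$xc[i] + di$w[i] / 2, gi$xc[j] + gi$w[j] / 2) -
              max(di$xc[i] - di$w[i] / 2, gi$xc[j] - gi$w[j] / 2)
            iy <- min(di$yc[i] + di$h[i] / 2, gi$yc[j] + gi$h[j] / 2) -
              max(di$yc[i] - di$h[i] / 2, gi$yc[j] - gi$h[j] / 2)
            inter <- max(ix, 0) * max(iy, 0)
            v <- inter / (di$w[i] * di$h[i] + gi$w[j] * gi$h[j] - inter)
            if (v > best) { best <- v; bj <- j }
          }
          hit <- bj > 0 && best >= th
          if (hit) used[bj] <- TRUE
          flags <- c(flags, hit); confs <- c(confs, di$conf[i])
        }
      }
      o <- order(-confs)
      flags <- flags[o]
      ng <- nrow(gc_)
      if (ng == 0 || !length(flags)) { ap[ci, ti] <- 0; next }
      tpc <- cumsum(flags)
      rec <- tpc / ng
      prec <- tpc / seq_along(flags)
      s <- 0
      for (r in seq(0, 1, by = 0.01)) {
        ok <- rec >= r - 1e-12
        s <- s + (if (any(ok)) max(prec[ok]) else 0)   # p_interp(r) = max prec over rec >= r
      }
      ap[ci, ti] <- s / 101
    }
  }
  list(ap = ap, map50 = mean(ap[, which(abs(thresholds - 0.5) < 1e-9)]),
       map = mean(ap))
}

# random evaluation problem: a few images, jittered copies of gts as dets
random_eval_problem <- function(nc = 3L, nimg = 3L) {
  gts <- NULL; dets <- NULL
  for (img in seq_len(nimg)) {
    ng <- sample(0:4, 1)
    if (ng) {
      g <- data.frame(image = paste0("i", img),
                      class = sample(0:(nc - 1), ng, replace = TRUE),
                      xc = runif(ng, 2, 8), yc = runif(ng, 2, 8),
                      w = runif(ng, 0.5, 2), h = runif(ng, 0.5, 2))
      gts <- rbind(gts, g)
      nd <- sample(0:(ng + 2), 1)
      if (nd) {
        src <- sample(seq_len(ng), nd, replace = TRUE)
        d <- data.frame(image = paste0("i", img),
                        class = ifelse(runif(nd) < 0.8, g$class[src],
                                       sample(0:(nc - 1), nd, replace = TRUE)),
                        xc = g$xc[src] + rnorm(nd, 0, 0.4),
                        yc = g$yc[src] + rnorm(nd, 0, 0.4),
                        w = g$w[src] * exp(rnorm(nd, 0, 0.2)),
                        h = g$h[src] * exp(rnorm(nd, 0, 0.2)),
                        conf = runif(nd))
        dets <- rbind(dets, d)
      }
    }
  }
  if (is.null(gts)) return(random_eval_problem(nc, nimg))
  if (is.null(dets)) dets <- data.frame(image = character(0), class = integer(0),
                                        xc = numeric(0), yc = numeric(0),
                                        w = numeric(0), h = numeric(0),
                                        conf = numeric(0))
  list(dets = dets, gts = gts)
}
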