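# Training: anchor-free decoding, task-aligned assignment, the composite
# detection loss (BCE classification + selectable box-regression loss +
# distribution-focal term, weighted 0.5 / 7.5 / 1.5), and a momentum-SGD
# loop. The box-loss term is the only piece that changes between the
# baseline (CIoU) and the improved (Inner-ShapeIoU) configurations.

# fixed expectation weights turning per-side bin distributions into distances
dfl_expect <- function(reg, reg_max) {
  probs <- ag_softmax_blocks(reg, reg_max)
  w <- array(0, dim = c(1L, 1L, reg_max, 4L))
  for (s in 1:4) w[1L, 1L, , s] <- 0:(reg_max - 1L)
  list(dist = ag_conv2d(probs, w, groups = 4L, count = FALSE), probs = probs)
}

# anchor centres (pixels) for one level grid
anchor_points <- function(h, w, stride) {
  cbind(x = rep((seq_len(w) - 0.5) * stride, each = h),
        y = rep((seq_len(h) - 0.5) * stride, times = w))
}

# flat index of (h, w, c, n) positions in an (H,W,C,N) array
flat_idx <- function(d, h, w, c, n) {
  h + d[1L] * ((w - 1L) + d[2L] * ((c - 1L) + d[3L] * (n - 1L)))
}

# task-aligned assignment for one image (all quantities numeric)
tal_assign <- function(scores, pboxes, anchors, gt, topk = 10L,
                       alpha = 0.5, beta = 6) {
  A <- nrow(anchors); G <- nrow(gt)
  if (G == 0L) return(data.frame(anchor = integer(0), gt = integer(0), tscore = numeric(0)))
  in_gt <- outer(seq_len(A), seq_len(G), function(a, g) {
    anchors[a, 1L] > gt$x1[g] & anchors[a, 1L] < gt$x2[g] &
      anchors[a, 2L] > gt$y1[g] & anchors[a, 2L] < gt$y2[g]
  })
  ious <- outer(seq_len(A), seq_len(G), function(a, g) {
    ag_value(iou_core((pboxes[a, 1L] + pboxes[a, 3L]) / 2, (pboxes[a, 2L] + pboxes[a, 4L]) / 2,
                      pmax(pboxes[a, 3L] - pboxes[a, 1L], 1e-9),
                      pmax(pboxes[a, 4L] - pboxes[a, 2L], 1e-9),
                      (gt$x1[g] + gt$x2[g]) / 2, (gt$y1[g] + gt$y2[g]) / 2,
                      gt$x2[g] - gt$x1[g], gt$y2[g] - gt$y1[g]))
  })
  cls_s <- scores[cbind(rep(seq_len(A), G), rep(gt$class + 1L, each = A))]
  metric <- matrix(cls_s, A, G)^alpha * ious^beta * in_gt
  mask <- matrix(FALSE, A, G)
  k <- min(topk, A)
  for (g in seq_len(G)) {
    top <- order(-metric[, g])[seq_len(k)]
    mask[top[metric[top, g] > 0], g] <- TRUE
  }
  # resolve anchors claimed by several gts: keep the highest metric
  multi <- which(rowSums(mask) > 1L)
  for (a in multi) {
    g_keep <- which.max(metric[a, ] * mask[a, ])
    mask[a, ] <- FALSE; mask[a, g_keep] <- TRUE
  }
  out <- which(mask, arr.ind = TRUE)
  if (!nrow(out)) return(data.frame(anchor = integer(0), gt = integer(0), tscore = numeric(0)))
  tsc <- numeric(nrow(out))
  for (g in unique(out[, 2L])) {
    sel <- out[, 2L] == g
    mmax <- max(metric[out[sel, 1L], g])
    imax <- max(ious[mask[, g], g])
    tsc[sel] <- metric[out[sel, 1L], g] / max(mmax, 1e-9) * imax
  }
  data.frame(anchor = out[, 1L], gt = out[, 2L], tscore = tsc)
}

#' Composite detection loss on one batch of head outputs
#'
#' @param outs per-level head outputs (from [model_forward()], train mode)
#' @param gts list (per image) of ground-truth data.frames with columns
#'   class, xc, yc, w, h in pixels
#' @param model the detector (for strides, nc, reg_max and the loss spec)
#' @return list with agTensor `total` and numeric components
#' @keywords internal
detection_loss <- function(outs, gts, model) {
  nc <- model$cfg$nc; rm_ <- model$cfg$reg_max
  ls <- model$cfg$loss
  lfn <- box_loss_fn(ls$name, scale = ls$scale %||% 0,
                     theta = ls$theta %||% 4, ratio = ls$ratio %||% 1)
  strides <- model$strides
  nlv <- length(outs)
  N <- dim(ag_value(outs[[1L]]$cls))[4L]
  dec <- lapply(outs, function(o) dfl_expect(o$reg, rm_))
  # per-level flat views (numeric) for assignment
  cls_flat <- list(); dist_flat <- list(); anch <- list(); lvl_of <- list()
  for (l in seq_len(nlv)) {
    d <- dim(ag_value(outs[[l]]$cls))
    anch[[l]] <- anchor_points(d[1L], d[2L], strides[l])
    lvl_of[[l]] <- rep(l, d[1L] * d[2L])
  }
  anchors <- do.call(rbind, anch)
  lvl <- unlist(lvl_of)
  stride_a <- strides[lvl]
  A <- nrow(anchors)
  cls_t <- matrix(0, A * N, nc)          # BCE targets, images stacked
  box_rows <- list()
  for (n in seq_len(N)) {
    sc <- do.call(rbind, lapply(seq_len(nlv), function(l) {
      v <- ag_value(outs[[l]]$cls)
      matrix(v[, , , n], ncol = nc)      # (H*W) x nc, h fastest
    }))
    di <- do.call(rbind, lapply(seq_len(nlv), function(l) {
      v <- ag_value(dec[[l]]$dist)
      matrix(v[, , , n], ncol = 4L)
    }))
    pb <- cbind(anchors[, 1L] - di[, 1L] * stride_a,
                anchors[, 2L] - di[, 2L] * stride_a,
                anchors[, 1L] + di[, 3L] * stride_a,
                anchors[, 2L] + di[, 4L] * stride_a)
    g <- gts[[n]]
    gt <- if (nrow(g)) data.frame(class = g$class,
                                  x1 = g$xc - g$w / 2, y1 = g$yc - g$h / 2,
                                  x2 = g$xc + g$w / 2, y2 = g$yc + g$h / 2)
          else data.frame(class = integer(0), x1 = numeric(0), y1 = numeric(0),
                          x2 = numeric(0), y2 = numeric(0))
    asg <- tal_assign(1 / (1 + exp(-sc)), pb, anchors, gt)
    if (nrow(asg)) {
      ai <- (n - 1L) * A + asg$anchor
      cls_t[cbind(ai, gt$class[asg$gt] + 1L)] <- asg$tscore
      box_rows[[n]] <- cbind(n = n, asg$anchor, asg$gt, asg$tscore)
    }
  }
  # classification BCE over every anchor and class
  tsum <- max(sum(cls_t), 1)
  cls_loss <- 0
  at <- 0L
  for (l in seq_len(nlv)) {
    d <- dim(ag_value(outs[[l]]$cls))
    hw <- d[1L] * d[2L]
    rows <- unlist(lapply(seq_len(N), function(n) (n - 1L) * A + at + seq_len(hw)))
    tgt <- array(0, dim = d)
    for (c in seq_len(nc)) tgt[, , c, ] <- cls_t[rows, c]
    cls_loss <- cls_loss + ag_bce_logits(outs[[l]]$cls, tgt)
    at <- at + hw
  }
  cls_loss <- cls_loss * (1 / tsum)
  br <- do.call(rbind, box_rows)
  box_loss <- 0; dfl_loss <- 0
  if (!is.null(br) && nrow(br)) {
    n_i <- br[, 1L]; a_i <- br[, 2L]; g_i <- br[, 3L]; tw <- br[, 4L]
    st <- stride_a[a_i]
    ax <- anchors[a_i, 1L]; ay <- anchors[a_i, 2L]
    # gather the four predicted side distances through the tape
    lv <- lvl[a_i]
    off <- c(0L, cumsum(vapply(seq_len(nlv), function(l)
      prod(dim(ag_value(outs[[l]]$cls))[1:2]), numeric(1))))
    sides <- vector("list", 4L)
    for (s in 1:4) {
      parts <- list()
      for (l in seq_len(nlv)) {
        sel <- which(lv == l)
        if (!length(sel)) next
        d <- dim(ag_value(dec[[l]]$dist))
        hwp <- a_i[sel] - off[l]
        hh <- (hwp - 1L) %% d[1L] + 1L
        ww <- (hwp - 1L) %/% d[1L] + 1L
        parts[[l]] <- list(sel = sel,
                           g = ag_gather(dec[[l]]$dist, flat_idx(d, hh, ww, s, n_i[sel])))
      }
      sides[[s]] <- stitch_vector(Filter(Negate(is.null), parts), length(a_i))
    }
    lft <- sides[[1L]]; top <- sides[[2L]]; rgt <- sides[[3L]]; btm <- sides[[4L]]
    px <- ax + (rgt - lft) / 2 * st
    py <- ay + (btm - top) / 2 * st
    pw <- (lft + rgt) * st
    ph <- (top + btm) * st
    gsel <- do.call(rbind, lapply(seq_len(N), function(n) {
      k <- which(n_i == n)
      if (!length(k)) return(NULL)
      g <- gts[[n]][g_i[k], ]
      cbind(k, g$xc, g$yc, g$w, g$h)
    }))
    gsel <- gsel[order(gsel[, 1L]), , drop = FALSE]
    gcmp <- list(xc = gsel[, 2L], yc = gsel[, 3L], w = gsel[, 4L], h = gsel[, 5L])
    pcmp <- list(xc = px, yc = py, w = ag_pmax(pw, 1e-7), h = ag_pmax(ph, 1e-7))
    lvec <- lfn(pcmp, gcmp)
    box_loss <- ag_sum(lvec * tw) * (1 / tsum)
    # distribution-focal term on the four side distances (stride units)
    tl <- cbind((ax - (gcmp$xc - gcmp$w / 2)) / st, (ay - (gcmp$yc - gcmp$h / 2)) / st,
                ((gcmp$xc + gcmp$w / 2) - ax) / st, ((gcmp$yc + gcmp$h / 2) - ay) / st)
    tl <- pmin(pmax(tl, 0), rm_ - 1 - 0.01)
    dfl <- 0
    for (s in 1:4) {
      tfl <- floor(tl[, s]); tce <- tfl + 1
      wfl <- tce - tl[, s]; wce <- tl[, s] - tfl
      pr_fl <- gather_bins(dec, lvl, a_i, n_i, s, tfl, rm_, outs)
      pr_ce <- gather_bins(dec, lvl, a_i, n_i, s, pmin(tce, rm_ - 1), rm_, outs)
      dfl <- dfl - ag_sum((wfl * ag_log(ag_pmax(pr_fl, 1e-9)) +
                           wce * ag_log(ag_pmax(pr_ce, 1e-9))) * tw)
    }
    dfl_loss <- dfl * (1 / (4 * tsum))
  }
  total <- 7.5 * box_loss + 0.5 * cls_loss + 1.5 * dfl_loss
  list(total = total,
       box = ag_value(box_loss), cls = ag_value(cls_loss),
       dfl = ag_value(dfl_loss))
}

# stitch per-level ag gathers into one ordered vector via scatter permutation
stitch_vector <- function(parts, n_total) {
  if (length(parts) == 1L && length(parts[[1L]]$sel) == n_total &&
      all(parts[[1L]]$sel == seq_len(n_total))) return(parts[[1L]]$g)
  acc <- NULL
  for (p in parts) {
    emb <- ag_scatter(p$g, p$sel, n_total)
    acc <- if (is.null(acc)) emb else acc + emb
  }
  acc
}

# place a short vector into a zero vector of length n at positions idx
ag_scatter <- function(x, idx, n) {
  xv <- ag_value(x)
  v <- numeric(n); v[idx] <- xv
  ag_node(v, list(x), function(g) list(g[idx]))
}

# gather per-anchor bin probabilities for one box side
gather_bins <- function(dec, lvl, a_i, n_i, side, bins, reg_max, outs) {
  nlv <- length(dec)
  off <- c(0L, cumsum(vapply(seq_len(nlv), function(l)
    prod(dim(ag_value(outs[[l]]$cls))[1:2]), numeric(1))))
  lv <- lvl[a_i]
  parts <- list()
  for (l in seq_len(nlv)) {
    sel <- which(lv == l)
    if (!length(sel)) next
    d <- dim(ag_value(dec[[l]]$probs))
    hwp <- a_i[sel] - off[l]
    hh <- (hwp - 1L) %% d[1L] + 1L
    ww <- (hwp - 1L) %/% d[1L] + 1L
    ch <- (side - 1L) * reg_max + bins[sel] + 1L
    parts[[length(parts) + 1L]] <-
      list(sel = sel, g = ag_gather(dec[[l]]$probs, flat_idx(d, hh, ww, ch, n_i[sel])))
  }
  stitch_vector(parts, length(a_i))
}

load_training_data <- function(data, split = "train") {
  if (is.character(data)) data <- read_dataset_config(data)
  files <- dataset_split_files(data, split)
  imgs <- lapply(files$image, load_image)
  labs <- lapply(files$label, read_yolo_labels)
  s <- dim(imgs[[1L]])[1L]
  labs <- lapply(labs, function(l) {
    data.frame(class = l$class, xc = l$xc * s, yc = l$yc * s,
               w = l$w * s, h = l$h * s)
  })
  list(images = imgs, labels = labs, size = s, nc = data$nc)
}

#' Train a detector
#'
#' Momentum SGD by default (an Adam option exists for fast desk-scale
#' convergence). Constant learning rate for the first 80% of steps, then
#' decayed by 10x. Gradients are clipped to a global norm of 10.
#' Deterministic for a fixed seed in single-threaded mode.
#' @param model an `aviscan_model` (updated in place through its parameter
#'   environments and also returned)
#' @param data a data.yaml path, a dataset config list, or an in-memory list
#'   with `images` (list of (H,W,3,1) arrays) and `labels` (list of
#'   pixel-coordinate data.frames class/xc/yc/w/h)
#' @param epochs,batch_size,lr,momentum optimisation hyper-parameters
#' @param optimizer "sgd" (momentum SGD, default) or "adam"
#' @param seed RNG seed controlling shuffling
#' @param verbose print per-epoch losses
#' @return invisible list with the model and a per-step loss history
#' @export
train_model <- function(model, data, epochs = 20L, batch_size = 8L,
                        lr = 0.01, momentum = 0.9, optimizer = c("sgd", "adam"),
                        seed = 1L, verbose = FALSE) {
  optimizer <- match.arg(optimizer)
  if (is.character(data) || !is.null(data$train)) data <- load_training_data(data)
  imgs <- data$images; labs <- data$labels
  n <- length(imgs)
  if (!n) stop("empty dataset")
  ps <- module_params(model$net)
  vel <- lapply(ps, function(p) array(0, dim = dim(p$value) %||% length(p$value)))
  mom2 <- if (optimizer == "adam") vel else NULL
  hist <- list()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  total_steps <- epochs * ceiling(n / batch_size)
  step <- 0L
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    for (b0 in seq(1L, n, by = batch_size)) {
      sel <- ord[b0:min(b0 + batch_size - 1L, n)]
      d1 <- dim(imgs[[sel[1L]]])
      x <- array(0, dim = c(d1[1L], d1[2L], 3L, length(sel)))
      for (j in seq_along(sel)) x[, , , j] <- imgs[[sel[j]]][, , , 1L]
      outs <- model_forward(model, x, train = TRUE)
      l <- detection_loss(outs, labs[sel], model)
      if (!is.finite(ag_value(l$total))) {
        bad_p <- sum(vapply(ps, function(p) sum(!is.finite(p$value)), numeric(1)))
        bad_o <- sum(vapply(outs, function(o)
          sum(!is.finite(ag_value(o$cls))) + sum(!is.finite(ag_value(o$reg))), numeric(1)))
        ngt <- sum(vapply(labs[sel], nrow, integer(1)))
        stop("non-finite loss at step ", step, " (box=", l$box, " cls=", l$cls,
             " dfl=", l$dfl, "; non-finite params=", bad_p,
             " outputs=", bad_o, " gts=", ngt, ")")
      }
      for (p in ps) p$grad <- NULL
      ag_backward(l$total)
      gn <- sqrt(sum(vapply(ps, function(p)
        if (is.null(p$grad)) 0 else sum(p$grad^2), numeric(1))))
      clip <- if (gn > 10) 10 / gn else 1
      lr_t <- if (step / total_steps < 0.8) lr else lr * 0.1
      for (k in seq_along(ps)) {
        p <- ps[[k]]
        if (is.null(p$grad)) next
        g <- clip * p$grad
        if (optimizer == "sgd") {
          vel[[k]] <- momentum * vel[[k]] + g
          p$value <- p$value - lr_t * vel[[k]]
        } else {
          vel[[k]] <- 0.9 * vel[[k]] + 0.1 * g
          mom2[[k]] <- 0.999 * mom2[[k]] + 0.001 * g * g
          mh <- vel[[k]] / (1 - 0.9^(step + 1))
          vh <- mom2[[k]] / (1 - 0.999^(step + 1))
          p$value <- p$value - lr_t * mh / (sqrt(vh) + 1e-8)
        }
        p$grad <- NULL
      }
      step <- step + 1L
      hist[[step]] <- c(step = step, total = ag_value(l$total),
                        box = l$box, cls = l$cls, dfl = l$dfl)
    }
    if (verbose) {
      h <- hist[[step]]
      message(sprintf("epoch %d/%d  loss %.4f (box %.4f cls %.4f dfl %.4f)",
                      ep, epochs, h["total"], h["box"], h["cls"], h["dfl"]))
    }
  }
  invisible(list(model = model, history = as.data.frame(do.call(rbind, hist))))
}

# --- checkpointing -----------------------------------------------------------

collect_state <- function(m, prefix = "") {
  out <- list()
  if (!is.null(m$state$running_mean)) {
    out[[paste0(prefix, "running_mean")]] <- m$state$running_mean
    out[[paste0(prefix, "running_var")]] <- m$state$running_var
  }
  for (cn in names(m$children))
    out <- c(out, collect_state(m$children[[cn]], paste0(prefix, cn, ".")))
  out
}

restore_state <- function(m, st, prefix = "") {
  if (!is.null(m$state$running_mean)) {
    m$state$running_mean <- st[[paste0(prefix, "running_mean")]]
    m$state$running_var <- st[[paste0(prefix, "running_var")]]
  }
  for (cn in names(m$children))
    restore_state(m$children[[cn]], st, paste0(prefix, cn, "."))
  invisible(NULL)
}

#' Save model weights and configuration to a checkpoint file
#' @param model an `aviscan_model`
#' @param path output .rds path
#' @export
save_checkpoint <- function(model, path) {
  ps <- module_params(model$net)
  saveRDS(list(cfg = model$cfg,
               params = lapply(ps, function(p) p$value),
               state = collect_state(model$net)), path)
  invisible(path)
}

#' Load a checkpoint saved by [save_checkpoint()]
#' @param path checkpoint path
#' @return an `aviscan_model` with restored weights
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  model <- build_model(ck$cfg)
  ps <- module_params(model$net)
  stopifnot(identical(names(ps), names(ck$params)))
  for (k in seq_along(ps)) ps[[k]]$value <- ck$params[[k]]
  restore_state(model$net, ck$state)
  model
}
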