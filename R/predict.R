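# Inference: decode head outputs to boxes, confidence filtering, per-class
# non-maximum suppression, and dataset-level evaluation via the metric kit.

nms_class <- function(boxes, scores, iou_thresh) {
  ord <- order(-scores)
  keep <- integer(0)
  while (length(ord)) {
    i <- ord[1L]
    keep <- c(keep, i)
    if (length(ord) == 1L) break
    rest <- ord[-1L]
    ious <- ag_value(iou_core(boxes[i, 1L], boxes[i, 2L], boxes[i, 3L], boxes[i, 4L],
                              boxes[rest, 1L], boxes[rest, 2L],
                              boxes[rest, 3L], boxes[rest, 4L]))
    ord <- rest[ious <= iou_thresh]
  }
  keep
}

decode_outputs <- function(model, outs) {
  nc <- model$cfg$nc; rm_ <- model$cfg$reg_max
  res <- list()
  for (l in seq_along(outs)) {
    d <- dim(ag_value(outs[[l]]$cls))
    s <- model$strides[l]
    ap <- anchor_points(d[1L], d[2L], s)
    dist <- ag_value(dfl_expect(outs[[l]]$reg, rm_)$dist)
    di <- matrix(dist[, , , 1L], ncol = 4L)
    sc <- 1 / (1 + exp(-matrix(ag_value(outs[[l]]$cls)[, , , 1L], ncol = nc)))
    res[[l]] <- list(scores = sc,
                     boxes = cbind(xc = ap[, 1L] + (di[, 3L] - di[, 1L]) / 2 * s,
                                   yc = ap[, 2L] + (di[, 4L] - di[, 2L]) / 2 * s,
                                   w = (di[, 1L] + di[, 3L]) * s,
                                   h = (di[, 2L] + di[, 4L]) * s))
  }
  list(scores = do.call(rbind, lapply(res, `[[`, "scores")),
       boxes = do.call(rbind, lapply(res, `[[`, "boxes")))
}

#' Run detection on images
#'
#' @param model a trained `aviscan_model`
#' @param images character vector of image paths, or a list of (H,W,3,1)
#'   arrays, or a single such array
#' @param conf confidence threshold
#' @param iou_nms IoU threshold for per-class non-maximum suppression
#' @param max_det maximum detections per image
#' @return data.frame image, class, xc, yc, w, h (pixels), conf
#' @export
predict_model <- function(model, images, conf = 0.25, iou_nms = 0.45,
                          max_det = 300L) {
  if (is.array(images)) images <- list(images)
  paths <- NULL
  if (is.character(images)) {
    paths <- images
    images <- lapply(images, load_image)
  }
  out <- list()
  for (i in seq_along(images)) {
    outs <- ag_no_grad(model_forward(model, images[[i]], train = FALSE))
    dc <- decode_outputs(model, outs)
    best <- apply(dc$scores, 1L, max)
    sel <- which(best >= conf)
    dets <- NULL
    if (length(sel)) {
      cls <- max.col(dc$scores[sel, , drop = FALSE]) - 1L
      sc <- best[sel]
      bx <- dc$boxes[sel, , drop = FALSE]
      keep_all <- integer(0)
      for (c in unique(cls)) {
        kc <- which(cls == c)
        keep <- nms_class(bx[kc, , drop = FALSE], sc[kc], iou_nms)
        keep_all <- c(keep_all, kc[keep])
      }
      if (length(keep_all) > max_det)
        keep_all <- keep_all[order(-sc[keep_all])[seq_len(max_det)]]
      dets <- data.frame(image = if (is.null(paths)) i else basename(paths[i]),
                         class = cls[keep_all],
                         xc = bx[keep_all, 1L], yc = bx[keep_all, 2L],
                         w = bx[keep_all, 3L], h = bx[keep_all, 4L],
                         conf = sc[keep_all])
    }
    out[[i]] <- dets
  }
  res <- do.call(rbind, out)
  if (is.null(res)) res <- data.frame(image = character(0), class = integer(0),
                                      xc = numeric(0), yc = numeric(0),
                                      w = numeric(0), h = numeric(0),
                                      conf = numeric(0))
  res
}

#' Evaluate a detector on a dataset split
#'
#' Runs inference at a low confidence threshold and scores the detections
#' against the split's YOLO labels with [map_range()].
#' @param model a trained `aviscan_model`
#' @param data data.yaml path or dataset config list
#' @param split dataset split to evaluate (default "val")
#' @param conf confidence floor for candidate detections
#' @param iou_nms NMS IoU threshold
#' @return list with `metrics` (an `eval_result`), `dets` and `gts`
#' @export
evaluate_model <- function(model, data, split = "val", conf = 0.005,
                           iou_nms = 0.6) {
  if (is.character(data)) data <- read_dataset_config(data)
  files <- dataset_split_files(data, split)
  dets <- list(); gts <- list()
  for (i in seq_len(nrow(files))) {
    img <- load_image(files$image[i])
    s <- dim(img)[1L]
    d <- predict_model(model, img, conf = conf, iou_nms = iou_nms)
    if (nrow(d)) d$image <- basename(files$image[i])
    dets[[i]] <- d
    g <- read_yolo_labels(files$label[i])
    if (nrow(g)) {
      gts[[i]] <- data.frame(image = basename(files$image[i]), class = g$class,
                             xc = g$xc * s, yc = g$yc * s, w = g$w * s, h = g$h * s)
    }
  }
  dets <- do.call(rbind, dets)
  if (is.null(dets) || !nrow(dets))
    dets <- data.frame(image = character(0), class = integer(0), xc = numeric(0),
                       yc = numeric(0), w = numeric(0), h = numeric(0),
                       conf = numeric(0))
  gts <- do.call(rbind, gts)
  if (is.null(gts)) stop("no ground-truth labels found for split ", split)
  classes <- 0:(data$nc - 1L)
  metrics <- map_range(dets, gts, classes = classes)
  list(metrics = metrics, dets = dets, gts = gts)
}
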