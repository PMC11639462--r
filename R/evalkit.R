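# Detection evaluation: greedy IoU matching, precision/recall, average
# precision with 101-point interpolation, mAP over IoU thresholds, and a
# confusion matrix with a background row/column.
#
# Detections are data.frames with columns image, class, xc, yc, w, h, conf;
# ground truths the same without conf. Class ids are 0-based, matching YOLO
# label files. Coordinates may be normalised or in pixels (IoU is
# scale-invariant) but must be consistent between the two tables.

det_frame <- function(d) {
  need <- c("image", "class", "xc", "yc", "w", "h")
  if (!all(need %in% names(d))) stop("missing columns: ",
                                     paste(setdiff(need, names(d)), collapse = ", "))
  d
}

pair_iou <- function(a, b) {
  # IoU matrix between two box tables (rows of a x rows of b)
  outer(seq_len(nrow(a)), seq_len(nrow(b)), function(i, j) {
    ag_value(iou_core(a$xc[i], a$yc[i], a$w[i], a$h[i],
                      b$xc[j], b$yc[j], b$w[j], b$h[j]))
  })
}

#' Greedily match detections to ground truths within one image and class
#'
#' Detections are taken in order of decreasing confidence; each claims the
#' highest-IoU still-unmatched ground truth provided the IoU reaches the
#' threshold, and is a true positive; otherwise a false positive. Each ground
#' truth can be matched at most once.
#' @param dets detection data.frame (single image, single class)
#' @param gts ground-truth data.frame (same slice)
#' @param iou_thresh minimum IoU for a match
#' @return list with `order` (row indices of dets by decreasing confidence),
#'   `tp` (logical, aligned with `order`), `gt_matched` (logical per gt row)
#' @export
match_detections <- function(dets, gts, iou_thresh = 0.5) {
  nd <- nrow(dets); ng <- nrow(gts)
  ord <- if (nd) order(-dets$conf) else integer(0)
  tp <- logical(nd)
  gt_matched <- logical(ng)
  if (nd && ng) {
    m <- pair_iou(dets, gts)
    for (i in seq_len(nd)) {
      di <- ord[i]
      ious <- m[di, ]
      ious[gt_matched] <- -1
      j <- which.max(ious)
      if (length(j) && ious[j] >= iou_thresh) {
        tp[i] <- TRUE
        gt_matched[j] <- TRUE
      }
    }
  }
  list(order = ord, tp = tp, gt_matched = gt_matched)
}

#' Precision and recall from TP/FP/FN counts
#'
#' Zero denominators yield 0 by convention.
#' @param tp,fp,fn nonnegative counts
#' @return named vector c(precision, recall)
#' @export
precision_recall <- function(tp, fp, fn) {
  if (tp < 0 || fp < 0 || fn < 0) stop("counts must be nonnegative")
  c(precision = if (tp + fp > 0) tp / (tp + fp) else 0,
    recall = if (tp + fn > 0) tp / (tp + fn) else 0)
}

#' Average precision from ranked TP/FP flags
#'
#' Area under the interpolated precision envelope. The default 101-point rule
#' averages the envelope precision over the recall grid 0, 0.01, ..., 1;
#' `interpolation = "all"` integrates over every recall step instead.
#' @param tp logical flags ordered by decreasing confidence
#' @param num_gt number of ground truths of this class
#' @param interpolation "101" (default) or "all"
#' @return AP in [0, 1]
#' @export
average_precision <- function(tp, num_gt, interpolation = c("101", "all")) {
  interpolation <- match.arg(interpolation)
  if (num_gt == 0) {
    if (length(tp)) stop("num_gt is 0 but detections were supplied")
    return(0)
  }
  if (!length(tp)) return(0)
  ctp <- cumsum(tp)
  recall <- ctp / num_gt
  precision <- ctp / seq_along(tp)
  envelope <- rev(cummax(rev(precision)))
  if (interpolation == "101") {
    grid <- seq(0, 1, by = 0.01)
    p_at <- vapply(grid, function(r) {
      ok <- recall >= r - 1e-12
      if (any(ok)) max(envelope[ok]) else 0
    }, numeric(1))
    mean(p_at)
  } else {
    r_prev <- c(0, recall[-length(recall)])
    sum((recall - r_prev) * envelope)
  }
}

class_ap <- function(dets, gts, cls, iou_thresh, interpolation) {
  dc <- dets[dets$class == cls, , drop = FALSE]
  gc_ <- gts[gts$class == cls, , drop = FALSE]
  num_gt <- nrow(gc_)
  if (!nrow(dc)) return(list(ap = 0, tp = logical(0), conf = numeric(0), num_gt = num_gt))
  tp_all <- logical(0); conf_all <- numeric(0)
  for (img in unique(c(dc$image, gc_$image))) {
    di <- dc[dc$image == img, , drop = FALSE]
    gi <- gc_[gc_$image == img, , drop = FALSE]
    m <- match_detections(di, gi, iou_thresh)
    tp_all <- c(tp_all, m$tp)
    conf_all <- c(conf_all, di$conf[m$order])
  }
  o <- order(-conf_all)
  list(ap = average_precision(tp_all[o], num_gt, interpolation),
       tp = tp_all[o], conf = conf_all[o], num_gt = num_gt)
}

#' Evaluate detections: per-class AP, mAP@0.5 and mAP@0.5:0.95
#'
#' Scalar precision/recall per class are reported at the confidence cutoff
#' that maximises F1 on the 0.5-IoU ranking.
#' @param dets detection data.frame (columns image, class, xc, yc, w, h, conf)
#' @param gts ground-truth data.frame (columns image, class, xc, yc, w, h)
#' @param classes integer vector of class ids to evaluate (default: all in gts)
#' @param thresholds IoU thresholds (default 0.5 to 0.95 step 0.05)
#' @param interpolation AP integration rule, see [average_precision()]
#' @return `eval_result`: per-class table plus mAP aggregates
#' @export
map_range <- function(dets, gts, classes = NULL,
                      thresholds = seq(0.5, 0.95, by = 0.05),
                      interpolation = "101") {
  det_frame(dets); det_frame(gts)
  if (is.null(classes)) classes <- sort(unique(gts$class))
  if (!length(classes)) stop("no classes to evaluate")
  ap_mat <- matrix(0, nrow = length(classes), ncol = length(thresholds),
                   dimnames = list(classes, thresholds))
  prec <- rec <- numeric(length(classes))
  for (ci in seq_along(classes)) {
    for (ti in seq_along(thresholds)) {
      r <- class_ap(dets, gts, classes[ci], thresholds[ti], interpolation)
      ap_mat[ci, ti] <- r$ap
      if (thresholds[ti] == 0.5 && length(r$tp)) {
        ctp <- cumsum(r$tp)
        p <- ctp / seq_along(r$tp)
        rc <- if (r$num_gt > 0) ctp / r$num_gt else rep(0, length(ctp))
        f1 <- ifelse(p + rc > 0, 2 * p * rc / (p + rc), 0)
        best <- which.max(f1)
        prec[ci] <- p[best]; rec[ci] <- rc[best]
      }
    }
  }
  i50 <- which(abs(thresholds - 0.5) < 1e-9)
  per_class <- data.frame(class = classes,
                          precision = prec, recall = rec,
                          ap50 = if (length(i50)) ap_mat[, i50] else NA_real_,
                          ap = rowMeans(ap_mat))
  structure(list(per_class = per_class,
                 ap_matrix = ap_mat,
                 map50 = if (length(i50)) mean(ap_mat[, i50]) else NA_real_,
                 map = mean(rowMeans(ap_mat)),
                 thresholds = thresholds),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat("Detection evaluation over", nrow(x$per_class), "class(es)\n")
  print(transform(x$per_class,
                  precision = round(precision, 4), recall = round(recall, 4),
                  ap50 = round(ap50, 4), ap = round(ap, 4)))
  cat(sprintf("mAP@0.5 = %.4f   mAP@0.5:0.95 = %.4f\n", x$map50, x$map))
  invisible(x)
}

#' Detection confusion matrix with a background class
#'
#' Rows are predicted classes, columns are true classes; the extra last
#' row/column is background. A ground truth whose best detection misses the
#' IoU threshold counts as (background row, its class column); a detection
#' matching no ground truth counts as (its class row, background column).
#' Matching is class-agnostic greedy by decreasing IoU among detections above
#' the confidence cutoff.
#' @param dets,gts detection / ground-truth data.frames
#' @param num_classes number of real classes m (matrix is (m+1) x (m+1))
#' @param conf_thresh confidence cutoff (default 0.25)
#' @param iou_thresh IoU cutoff (default 0.45)
#' @param normalize divide each column by its sum (columns with no counts kept 0)
#' @export
confusion_matrix <- function(dets, gts, num_classes,
                             conf_thresh = 0.25, iou_thresh = 0.45,
                             normalize = FALSE) {
  det_frame(dets); det_frame(gts)
  m <- num_classes
  cm <- matrix(0, m + 1L, m + 1L)
  lab <- c(paste0("class", 0:(m - 1L)), "background")
  dimnames(cm) <- list(predicted = lab, truth = lab)
  dets <- dets[dets$conf >= conf_thresh, , drop = FALSE]
  for (img in unique(c(dets$image, gts$image))) {
    di <- dets[dets$image == img, , drop = FALSE]
    gi <- gts[gts$image == img, , drop = FALSE]
    dm <- logical(nrow(di)); gm <- logical(nrow(gi))
    if (nrow(di) && nrow(gi)) {
      ious <- pair_iou(di, gi)
      cand <- which(ious >= iou_thresh, arr.ind = TRUE)
      if (nrow(cand)) {
        cand <- cand[order(-ious[cand]), , drop = FALSE]
        for (r in seq_len(nrow(cand))) {
          i <- cand[r, 1L]; j <- cand[r, 2L]
          if (!dm[i] && !gm[j]) {
            dm[i] <- TRUE; gm[j] <- TRUE
            cm[di$class[i] + 1L, gi$class[j] + 1L] <-
              cm[di$class[i] + 1L, gi$class[j] + 1L] + 1L
          }
        }
      }
    }
    if (nrow(gi)) for (j in which(!gm))
      cm[m + 1L, gi$class[j] + 1L] <- cm[m + 1L, gi$class[j] + 1L] + 1L
    if (nrow(di)) for (i in which(!dm))
      cm[di$class[i] + 1L, m + 1L] <- cm[di$class[i] + 1L, m + 1L] + 1L
  }
  if (normalize) {
    cs <- colSums(cm)
    cs[cs == 0] <- 1
    cm <- sweep(cm, 2L, cs, "/")
  }
  cm
}
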