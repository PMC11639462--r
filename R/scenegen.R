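# Synthetic surveillance-scene generator. Emulates the structure of a wetland
# bird-monitoring dataset — five classes, dense small targets, partial
# occlusion, wide scale variation, cluttered background — with procedurally
# rendered blobs whose box statistics are controlled, so the detection and
# evaluation machinery can be exercised without any restricted footage.

#' Scene generation parameters
#'
#' @param image_size square image side in pixels
#' @param num_classes number of object classes (distinct hue + silhouette each;
#'   the last class is rendered light and low-contrast, mimicking pale swans)
#' @param objects_range min/max objects per image
#' @param scale_range object size as a fraction of the image side
#' @param occlusion occluded-pair fraction: this fraction of objects is placed
#'   in deliberately overlapping pairs
#' @param clutter background clutter amplitude in [0, 1]
#' @param seed RNG seed for reproducible scenes
#' @export
scene_spec <- function(image_size = 640L, num_classes = 5L,
                       objects_range = c(1L, 12L), scale_range = c(0.02, 0.4),
                       occlusion = 0.2, clutter = 0.5, seed = 1L) {
  stopifnot(image_size >= 16, num_classes >= 1,
            objects_range[1] >= 0, objects_range[2] >= objects_range[1],
            scale_range[1] > 0, scale_range[2] <= 1,
            occlusion >= 0, occlusion <= 1)
  list(image_size = as.integer(image_size), num_classes = as.integer(num_classes),
       objects_range = as.integer(objects_range), scale_range = scale_range,
       occlusion = occlusion, clutter = clutter, seed = as.integer(seed))
}

#' Dataset generation parameters
#' @param total total number of images
#' @param ratios train/val/test split ratios (must sum to 1)
#' @param dir target directory
#' @export
dataset_spec <- function(total, ratios = c(0.7, 0.2, 0.1), dir = tempfile("aviscan_ds_")) {
  stopifnot(total >= length(ratios), abs(sum(ratios) - 1) < 1e-9)
  list(total = as.integer(total), ratios = ratios, dir = dir)
}

#' Deterministic split sizes under floor-then-carry allocation
#'
#' Each split receives floor(n * ratio); leftover items go to the later splits
#' in order (val first, then test).
#' @param n item count
#' @param ratios split ratios summing to 1
#' @return integer vector of split sizes summing to n
#' @export
split_dataset <- function(n, ratios = c(0.7, 0.2, 0.1)) {
  if (n < length(ratios)) stop("need at least one item per split")
  sizes <- floor(n * ratios)
  left <- n - sum(sizes)
  if (left > 0) {
    idx <- seq(length(ratios) - left + 1L, length(ratios))
    sizes[idx] <- sizes[idx] + 1L
  }
  as.integer(sizes)
}

class_hue <- function(cls, m) (cls - 1) / max(m, 1)

# render one blob; returns updated image and the tight normalised box, or NULL
render_object <- function(img, cls, spec) {
  s <- spec$image_size
  half <- stats::runif(1, spec$scale_range[1], spec$scale_range[2]) * s / 2
  asp <- exp(stats::runif(1, -0.5, 0.5))
  a <- min(half * asp, s / 2 - 1); b <- min(half / asp, s / 2 - 1)
  cx <- stats::runif(1, a, s - a); cy <- stats::runif(1, b, s - b)
  render_object_at(img, cls, spec, cx, cy, a, b)
}

render_object_at <- function(img, cls, spec, cx, cy, a, b) {
  s <- spec$image_size
  phi <- stats::runif(1, 0, pi)
  wob <- stats::runif(2, 0, 0.25)          # silhouette harmonics per instance
  kk <- 2L + (cls %% 3L)                   # class-specific lobe count
  x0 <- max(1L, floor(cx - (a + b))); x1 <- min(s, ceiling(cx + a + b))
  y0 <- max(1L, floor(cy - (a + b))); y1 <- min(s, ceiling(cy + a + b))
  if (x1 <= x0 || y1 <= y0) return(NULL)
  xs <- x0:x1; ys <- y0:y1
  gx <- outer(ys - cy, xs - cx, function(yy, xx) xx)
  gy <- outer(ys - cy, xs - cx, function(yy, xx) yy)
  u <- (gx * cos(phi) + gy * sin(phi)) / a
  v <- (-gx * sin(phi) + gy * cos(phi)) / b
  ang <- atan2(v, u)
  rad <- 1 + wob[1] * cos(kk * ang) + wob[2] * sin((kk + 1L) * ang)
  inside <- (u * u + v * v) <= rad * rad
  if (!any(inside)) return(NULL)
  pale <- cls == spec$num_classes          # last class: pale, low contrast
  col <- grDevices::hsv(class_hue(cls, spec$num_classes),
                        if (pale) 0.08 else 0.85,
                        if (pale) 0.95 else 0.75)
  rgb <- as.numeric(grDevices::col2rgb(col)) / 255
  shade <- 0.85 + 0.15 * cos(ang)          # simple lambertian-ish shading
  for (ch in 1:3) {
    plane <- img[ys, xs, ch]
    plane[inside] <- rgb[ch] * shade[inside]
    img[ys, xs, ch] <- plane
  }
  rows <- range(which(apply(inside, 1, any)))
  cols <- range(which(apply(inside, 2, any)))
  # tight box around rendered pixels; half-open pixel convention, normalised
  x1b <- (x0 - 1 + cols[1] - 1) / s; x2b <- (x0 - 1 + cols[2]) / s
  y1b <- (y0 - 1 + rows[1] - 1) / s; y2b <- (y0 - 1 + rows[2]) / s
  list(img = img,
       box = data.frame(class = cls - 1L,
                        xc = (x1b + x2b) / 2, yc = (y1b + y2b) / 2,
                        w = x2b - x1b, h = y2b - y1b))
}

scene_background <- function(spec) {
  s <- spec$image_size
  base <- c(0.35, 0.42, 0.38)              # muted wetland tones
  img <- array(0, dim = c(s, s, 3))
  fx <- stats::runif(3, 0.5, 3); fy <- stats::runif(3, 0.5, 3)
  ph <- stats::runif(3, 0, 2 * pi)
  gx <- matrix(seq(0, 1, length.out = s), s, s, byrow = TRUE)
  gy <- matrix(seq(0, 1, length.out = s), s, s)
  tex <- 0
  for (i in 1:3) tex <- tex + sin(2 * pi * (fx[i] * gx + fy[i] * gy) + ph[i]) / 3
  noise <- matrix(stats::runif(s * s, -1, 1), s, s)
  for (ch in 1:3) {
    img[, , ch] <- pmin(pmax(base[ch] + spec$clutter * (0.12 * tex + 0.06 * noise), 0), 1)
  }
  img
}

#' Generate one synthetic scene with ground-truth boxes
#'
#' @param spec a [scene_spec()]
#' @return list with `image` ((H,W,3) array in [0,1]) and `boxes`
#'   (data.frame class, xc, yc, w, h — normalised centre format)
#' @export
generate_scene <- function(spec = scene_spec()) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)
  img <- scene_background(spec)
  n <- if (spec$objects_range[2] > spec$objects_range[1])
    sample(spec$objects_range[1]:spec$objects_range[2], 1L) else spec$objects_range[1]
  n_pairs <- floor(spec$occlusion * n / 2)
  boxes <- NULL
  placed <- 0L
  i <- 0L
  while (placed < n && i < 10L * max(n, 1L)) {
    i <- i + 1L
    cls <- sample.int(spec$num_classes, 1L)
    r <- render_object(img, cls, spec)
    if (is.null(r)) next
    img <- r$img
    boxes <- rbind(boxes, r$box)
    placed <- placed + 1L
    if (n_pairs > 0 && placed < n) {
      # constructive occluder: second object overlapping the one just placed
      s <- spec$image_size
      bb <- r$box
      a2 <- bb$w * s / 2 * stats::runif(1, 0.6, 1)
      b2 <- bb$h * s / 2 * stats::runif(1, 0.6, 1)
      cx2 <- bb$xc * s + bb$w * s * stats::runif(1, 0.15, 0.4) * sample(c(-1, 1), 1)
      cy2 <- bb$yc * s + bb$h * s * stats::runif(1, 0.15, 0.4) * sample(c(-1, 1), 1)
      cls2 <- sample.int(spec$num_classes, 1L)
      r2 <- render_object_at(img, cls2, spec, cx2, cy2, a2, b2)
      if (!is.null(r2)) {
        img <- r2$img
        boxes <- rbind(boxes, r2$box)
        placed <- placed + 1L
        n_pairs <- n_pairs - 1L
      }
    }
  }
  if (placed < n) message("scene: placed ", placed, " of ", n, " requested objects")
  if (is.null(boxes)) boxes <- data.frame(class = integer(0), xc = numeric(0),
                                          yc = numeric(0), w = numeric(0), h = numeric(0))
  list(image = img, boxes = boxes)
}

#' Generate a dataset directory tree with images and YOLO labels
#'
#' Writes `images/<split>/*.png`, `labels/<split>/*.txt` and a `data.yaml`
#' config (names plus split directories). Split assignment shuffles image ids
#' deterministically (seeded) and cuts by [split_dataset()].
#' @param dspec a [dataset_spec()]
#' @param sspec a [scene_spec()]; per-image seeds are derived from its seed
#' @return invisible list with dataset dir, yaml path, per-split counts
#' @export
generate_dataset <- function(dspec, sspec = scene_spec()) {
  splits <- c("train", "val", "test")
  sizes <- split_dataset(dspec$total, dspec$ratios)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(sspec$seed)
  ids <- sample.int(dspec$total)
  assign_split <- rep(splits, times = sizes)
  for (sp in splits) {
    dir.create(file.path(dspec$dir, "images", sp), recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(dspec$dir, "labels", sp), recursive = TRUE, showWarnings = FALSE)
  }
  for (k in seq_len(dspec$total)) {
    id <- ids[k]; sp <- assign_split[k]
    sc <- generate_scene(modifyList(sspec, list(seed = (sspec$seed + 7919L * id) %% .Machine$integer.max)))
    nm <- sprintf("img%05d", id)
    png::writePNG(sc$image, file.path(dspec$dir, "images", sp, paste0(nm, ".png")))
    write_yolo_labels(sc$boxes, file.path(dspec$dir, "labels", sp, paste0(nm, ".txt")))
  }
  cfg <- list(path = dspec$dir,
              train = "images/train", val = "images/val", test = "images/test",
              nc = sspec$num_classes,
              names = paste0("class", seq_len(sspec$num_classes) - 1L))
  yaml_path <- file.path(dspec$dir, "data.yaml")
  yaml::write_yaml(cfg, yaml_path)
  invisible(list(dir = dspec$dir, yaml = yaml_path,
                 counts = stats::setNames(sizes, splits)))
}
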