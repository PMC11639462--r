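# YOLO-format label files and dataset configuration I/O.

#' Write boxes to a YOLO label file
#'
#' One line per object: `class xc yc w h`, coordinates normalised to [0, 1].
#' @param boxes data.frame with columns class, xc, yc, w, h
#' @param path output file
#' @export
write_yolo_labels <- function(boxes, path) {
  lines <- sprintf("%d %.6f %.6f %.6f %.6f",
                   as.integer(boxes$class), boxes$xc, boxes$yc, boxes$w, boxes$h)
  writeLines(lines, path)
  invisible(path)
}

#' Read a YOLO label file
#' @param path label file (one `class xc yc w h` line per object)
#' @return data.frame with columns class, xc, yc, w, h
#' @export
read_yolo_labels <- function(path) {
  if (!file.exists(path) || file.size(path) == 0)
    return(data.frame(class = integer(0), xc = numeric(0), yc = numeric(0),
                      w = numeric(0), h = numeric(0)))
  m <- utils::read.table(path, col.names = c("class", "xc", "yc", "w", "h"))
  m$class <- as.integer(m$class)
  m
}

#' Read a dataset configuration (YAML with names and split directories)
#' @param path data.yaml path
#' @return list with path, train/val/test, nc, names
#' @export
read_dataset_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$path)) cfg$path <- dirname(normalizePath(path))
  cfg
}

#' List image/label file pairs of one dataset split
#' @param cfg config from [read_dataset_config()]
#' @param split "train", "val" or "test"
#' @export
dataset_split_files <- function(cfg, split = "train") {
  img_dir <- file.path(cfg$path, cfg[[split]])
  imgs <- sort(list.files(img_dir, pattern = "\\.(png|jpg|jpeg)$", full.names = TRUE))
  labs <- file.path(sub("images", "labels", img_dir),
                    sub("\\.(png|jpg|jpeg)$", ".txt", basename(imgs)))
  data.frame(image = imgs, label = labs, stringsAsFactors = FALSE)
}

#' Load an image file as a feature map
#' @param path PNG image path
#' @return (H,W,3,1) array in [0, 1]
#' @export
load_image <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  if (dim(img)[3L] > 3L) img <- img[, , 1:3, drop = FALSE]
  array(img, dim = c(dim(img)[1:2], 3L, 1L))
}
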