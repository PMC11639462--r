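# Model assembly: baseline detector (C2f/SPPF backbone, PAN neck, decoupled
# anchor-free heads) and the bird variant with RFAConv downsampling, the
# DyASF-P2 neck and the LSDECD head, plus parameter/FLOP accounting.

#' Model configuration
#'
#' @param variant "baseline" (all improvement flags off) or "bird" (all on);
#'   individual flags can still be overridden for ablations
#' @param nc number of classes
#' @param depth_mult,width_mult compound scaling factors (nano: 0.33 / 0.25)
#' @param rfaconv replace backbone downsampling convolutions with
#'   receptive-field attention convolution
#' @param dyasf_p2 use the DyASF-P2 four-level fusion neck
#' @param lsdecd use the lightweight shared detail-enhanced head
#' @param loss box-loss spec, e.g. `list(name = "inner_shape_iou", ratio = 1,
#'   scale = 0, theta = 4)`
#' @param input_size training/inference square input size
#' @param reg_max regression bin count
#' @param ssff_sigma Gaussian smoothing scale inside SSFF
#' @param head_width shared channel width of the LSDECD head; default is the
#'   width-multiplier-scaled 64 (16 at nano scale)
#' @export
model_config <- function(variant = c("baseline", "bird"), nc = 5L,
                         depth_mult = 0.33, width_mult = 0.25,
                         rfaconv = NULL, dyasf_p2 = NULL, lsdecd = NULL,
                         loss = NULL, input_size = 640L, reg_max = 16L,
                         ssff_sigma = 1, head_width = NULL) {
  variant <- match.arg(variant)
  on_ <- variant == "bird"
  cfg <- list(variant = variant, nc = as.integer(nc),
              depth_mult = depth_mult, width_mult = width_mult,
              rfaconv = rfaconv %||% on_,
              dyasf_p2 = dyasf_p2 %||% on_,
              lsdecd = lsdecd %||% on_,
              loss = loss %||% if (on_)
                list(name = "inner_shape_iou", ratio = 1, scale = 0, theta = 4)
              else list(name = "ciou"),
              input_size = as.integer(input_size),
              reg_max = as.integer(reg_max), ssff_sigma = ssff_sigma,
              head_width = head_width)
  class(cfg) <- "model_config"
  cfg
}

# full-scale base width scaled by the compound width multiplier, kept a
# multiple of 4
scale_w <- function(w, width_mult) {
  max(4L, as.integer(round(w * width_mult / 4)) * 4L)
}

mod_backbone <- function(chs, depths, rfa = FALSE) {
  down <- function(ci, co) if (rfa) rfa_conv(ci, co, 3L, 2L) else
    mod_conv(ci, co, 3L, stride = 2L)
  kids <- list(stem = mod_conv(3L, chs[1L], 3L, stride = 2L),
               d1 = down(chs[1L], chs[2L]), b1 = mod_c2f(chs[2L], chs[2L], depths[1L], TRUE),
               d2 = down(chs[2L], chs[3L]), b2 = mod_c2f(chs[3L], chs[3L], depths[2L], TRUE),
               d3 = down(chs[3L], chs[4L]), b3 = mod_c2f(chs[4L], chs[4L], depths[3L], TRUE),
               d4 = down(chs[4L], chs[5L]), b4 = mod_c2f(chs[5L], chs[5L], depths[4L], TRUE),
               sppf = mod_sppf(chs[5L], chs[5L]))
  new_module("backbone", children = kids, fn = function(self, x, train) {
    k <- self$children
    x <- module_forward(k$stem, x, train)
    p2 <- module_forward(k$b1, module_forward(k$d1, x, train), train)
    p3 <- module_forward(k$b2, module_forward(k$d2, p2, train), train)
    p4 <- module_forward(k$b3, module_forward(k$d3, p3, train), train)
    p5 <- module_forward(k$sppf,
            module_forward(k$b4, module_forward(k$d4, p4, train), train), train)
    list(p2 = p2, p3 = p3, p4 = p4, p5 = p5)
  })
}

mod_pan_neck <- function(ch3, ch4, ch5, depth = 1L) {
  kids <- list(
    t1 = mod_c2f(ch4 + ch5, ch4, depth),       # top-down to P4
    t2 = mod_c2f(ch3 + ch4, ch3, depth),       # top-down to P3
    d1 = mod_conv(ch3, ch3, 3L, stride = 2L),
    b1 = mod_c2f(ch3 + ch4, ch4, depth),       # bottom-up to P4
    d2 = mod_conv(ch4, ch4, 3L, stride = 2L),
    b2 = mod_c2f(ch4 + ch5, ch5, depth))       # bottom-up to P5
  new_module("pan", children = kids, fn = function(self, feats, train) {
    k <- self$children
    u4 <- module_forward(k$t1,
            ag_concat(list(ag_upsample_nearest(feats$p5, 2L), feats$p4)), train)
    u3 <- module_forward(k$t2,
            ag_concat(list(ag_upsample_nearest(u4, 2L), feats$p3)), train)
    n4 <- module_forward(k$b1,
            ag_concat(list(module_forward(k$d1, u3, train), u4)), train)
    n5 <- module_forward(k$b2,
            ag_concat(list(module_forward(k$d2, n4, train), feats$p5)), train)
    list(u3, n4, n5)
  })
}

mod_dyasf_neck <- function(ch2, ch3, ch4, ch5, W, T3, T4, sigma = 1) {
  kids <- list(
    tfe3 = mod_tfe(ch2, ch3, ch4, T3),
    merge3 = mod_conv(3L * T3, W[2L], 1L),
    ssff3 = mod_ssff(c(ch5, ch4, ch3), W[2L], sigma),
    c2f3 = mod_c2f(W[2L], W[2L], 1L),
    up2 = mod_dysample(W[2L], 2L),
    p2merge = mod_conv(W[2L] + ch2, W[1L], 1L),
    ssff2 = mod_ssff(c(ch4, ch3, ch2), W[1L], sigma),
    c2f2 = mod_c2f(W[1L], W[1L], 1L),
    tfe4 = mod_tfe(W[2L], ch4, ch5, T4),
    merge4 = mod_conv(3L * T4, W[3L], 1L),
    c2f4 = mod_c2f(W[3L], W[3L], 1L),
    down5 = mod_conv(W[3L], W[3L], 3L, stride = 2L),
    p5merge = mod_conv(W[3L] + ch5, W[4L], 1L),
    c2f5 = mod_c2f(W[4L], W[4L], 1L))
  new_module("dyasf", children = kids, fn = function(self, feats, train) {
    k <- self$children
    build_neck(feats, self, train)
  })
}

#' Wire the DyASF-P2 neck over backbone features
#'
#' Two TFE and two DySSFF blocks plus the added P2 level produce four fused
#' maps (strides 4/8/16/32) feeding four heads.
#' @param feats named list p2..p5 of backbone feature maps
#' @param m neck module (from the model builder)
#' @param train training mode
#' @return list of four feature maps, shallowest (P2) first
#' @export
build_neck <- function(feats, m, train = FALSE) {
  k <- m$children
  t3 <- module_forward(k$merge3,
          tfe_fuse(k$tfe3, feats$p2, feats$p3, feats$p4, train), train)
  s3 <- ssff_fuse(k$ssff3, list(feats$p5, feats$p4, feats$p3), train)
  f3 <- module_forward(k$c2f3, t3 + s3, train)
  p2m <- module_forward(k$p2merge,
           ag_concat(list(dysample(f3, k$up2), feats$p2)), train)
  s2 <- ssff_fuse(k$ssff2, list(feats$p4, feats$p3, feats$p2), train)
  f2 <- module_forward(k$c2f2, p2m + s2, train)
  t4 <- module_forward(k$merge4,
          tfe_fuse(k$tfe4, f3, feats$p4, feats$p5, train), train)
  f4 <- module_forward(k$c2f4, t4, train)
  f5 <- module_forward(k$c2f5,
          module_forward(k$p5merge,
            ag_concat(list(module_forward(k$down5, f4, train), feats$p5)), train), train)
  list(f2, f3, f4, f5)
}

mod_detect <- function(in_channels, nc, reg_max = 16L) {
  c2 <- max(16L, in_channels[1L] %/% 4L, 4L * reg_max)
  c3 <- max(in_channels[1L], min(nc, 100L))
  kids <- list()
  for (i in seq_along(in_channels)) {
    ci <- in_channels[i]
    kids[[paste0("box", i)]] <- mod_seq(
      mod_conv(ci, c2, 3L), mod_conv(c2, c2, 3L),
      mod_conv(c2, 4L * reg_max, 1L, bias = TRUE, norm = "none", act = "none"))
    kids[[paste0("cls", i)]] <- mod_seq(
      mod_conv(ci, c3, 3L), mod_conv(c3, c3, 3L),
      mod_conv(c3, nc, 1L, bias = TRUE, norm = "none", act = "none"))
  }
  new_module("detect", children = kids, fn = function(self, levels, train) {
    lapply(seq_along(levels), function(i) {
      list(cls = module_forward(self$children[[paste0("cls", i)]], levels[[i]], train),
           reg = module_forward(self$children[[paste0("box", i)]], levels[[i]], train))
    })
  }, nl = length(in_channels), nc = nc, reg_max = reg_max)
}

#' Build a detector from a configuration
#'
#' @param cfg a [model_config()]
#' @param init_seed RNG seed for weight initialisation
#' @return an `aviscan_model`
#' @export
build_model <- function(cfg, init_seed = 1L) {
  stopifnot(inherits(cfg, "model_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(init_seed)
  wm <- cfg$width_mult
  chs <- vapply(c(64L, 128L, 256L, 512L, 1024L),
                scale_w, integer(1), width_mult = wm)
  depths <- pmax(1L, as.integer(round(c(3L, 6L, 6L, 3L) * cfg$depth_mult)))
  backbone <- mod_backbone(chs, depths, rfa = cfg$rfaconv)
  if (cfg$dyasf_p2) {
    W <- vapply(c(336L, 384L, 512L, 640L), scale_w, integer(1), width_mult = wm)
    T3 <- scale_w(192L, wm); T4 <- scale_w(256L, wm)
    neck <- mod_dyasf_neck(chs[2L], chs[3L], chs[4L], chs[5L], W, T3, T4,
                           sigma = cfg$ssff_sigma)
    head_ch <- W
    strides <- c(4L, 8L, 16L, 32L)
  } else {
    neck <- mod_pan_neck(chs[3L], chs[4L], chs[5L])
    head_ch <- chs[3:5]
    strides <- c(8L, 16L, 32L)
  }
  head <- if (cfg$lsdecd) mod_lsdecd(head_ch, cfg$nc, cfg$reg_max,
                                     width = cfg$head_width %||% scale_w(64L, wm))
          else mod_detect(head_ch, cfg$nc, cfg$reg_max)
  net <- new_module("net",
                    children = list(backbone = backbone, neck = neck, head = head),
                    fn = function(self, x, train) {
                      feats <- module_forward(self$children$backbone, x, train)
                      fused <- module_forward(self$children$neck, feats, train)
                      module_forward(self$children$head, fused, train)
                    })
  structure(list(cfg = cfg, net = net, strides = strides),
            class = "aviscan_model")
}

#' @export
print.aviscan_model <- function(x, ...) {
  cat(sprintf("<aviscan detector: %s, nc=%d, %s/%s/%s, loss=%s>\n",
              x$cfg$variant, x$cfg$nc,
              if (x$cfg$rfaconv) "RFAConv" else "conv",
              if (x$cfg$dyasf_p2) "DyASF-P2" else "PAN",
              if (x$cfg$lsdecd) "LSDECD" else "detect",
              x$cfg$loss$name))
  cat(sprintf("  parameters: %s\n", format(count_params(x), big.mark = ",")))
  invisible(x)
}

#' Forward pass of a detector
#' @param model an `aviscan_model`
#' @param x (H,W,3,N) image array in [0,1]
#' @param train training mode
#' @return per-level list of cls/reg maps
#' @export
model_forward <- function(model, x, train = FALSE) {
  d <- dim(ag_value(x))
  if (d[1L] %% 32L != 0L || d[2L] %% 32L != 0L)
    stop("input height/width must be divisible by 32 (the deepest stride)")
  module_forward(model$net, x, train)
}

#' Count floating-point operations of one forward pass
#'
#' Convention: 2 x multiply-accumulates summed over parameterised convolution
#' and affine layers at the given input size; pooling, activations,
#' normalisation and fixed-kernel operations are not counted.
#' @param model an `aviscan_model`
#' @param input_size square input side (default: the model's configured size)
#' @return FLOP count (numeric)
#' @export
count_flops <- function(model, input_size = NULL) {
  s <- input_size %||% model$cfg$input_size
  x <- array(0, dim = c(s, s, 3L, 1L))
  flops_begin()
  ag_no_grad(model_forward(model, x, train = FALSE))
  flops_end()
}
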