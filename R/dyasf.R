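# DyASF-P2 neck components: Gaussian scale-space smoothing, dynamic
# upsampling (DySample), scale-sequence feature fusion (SSFF), triple feature
# encoding (TFE), and the four-level neck with the added P2 small-object
# layer.

#' Discrete 2-D Gaussian kernel
#'
#' Samples `exp(-(w^2+h^2)/(2 sigma^2)) / (2 pi sigma^2)` on an odd grid of
#' radius `radius` and (by default) renormalises it to sum to 1.
#' @param sigma standard deviation (> 0)
#' @param radius kernel radius; default `ceiling(2.5 * sigma)` (size 2r+1)
#' @param normalize renormalise to unit sum (default TRUE)
#' @export
gaussian_kernel <- function(sigma = 1, radius = NULL, normalize = TRUE) {
  if (sigma <= 0) stop("sigma must be > 0")
  if (is.null(radius)) radius <- max(1L, ceiling(2.5 * sigma))
  g <- seq(-radius, radius)
  k <- outer(g, g, function(w, h) exp(-(w^2 + h^2) / (2 * sigma^2))) / (2 * pi * sigma^2)
  if (normalize) k <- k / sum(k)
  k
}

# reflect-padding (edge mirror without repeating the border pixel)
reflect_idx <- function(n, r) {
  if (n == 1L) return(rep(1L, n + 2L * r))
  i <- c(rev(seq_len(r) + 1L), seq_len(n), n - seq_len(r))
  i[i < 1L] <- 2L - i[i < 1L]
  i[i > n] <- 2L * n - i[i > n]
  i
}

ag_pad_reflect <- function(x, r) {
  xv <- ag_value(x)
  d <- dim(xv)
  ri <- reflect_idx(d[1L], r); ci <- reflect_idx(d[2L], r)
  y <- xv[ri, ci, , , drop = FALSE]
  ag_node(y, list(x), function(g) {
    dp <- dim(g)
    g1 <- rowsum(matrix(g, nrow = dp[1L]), group = ri, reorder = TRUE)
    g1 <- array(g1, dim = c(d[1L], dp[2L], dp[3L], dp[4L]))
    g2 <- aperm(g1, c(2L, 1L, 3L, 4L))
    g2 <- rowsum(matrix(g2, nrow = dp[2L]), group = ci, reorder = TRUE)
    g2 <- array(g2, dim = c(d[2L], d[1L], d[3L], d[4L]))
    list(aperm(g2, c(2L, 1L, 3L, 4L)))
  })
}

#' Gaussian smoothing of a feature map
#'
#' Per-channel 2-D convolution with the normalised kernel; reflect padding
#' keeps the spatial size and preserves constants exactly.
#' @param x (H,W,C,N) input
#' @param sigma,radius kernel parameters, see [gaussian_kernel()]
#' @export
gaussian_smooth <- function(x, sigma = 1, radius = NULL) {
  k <- gaussian_kernel(sigma, radius)
  r <- (nrow(k) - 1L) %/% 2L
  C <- dim(ag_value(x))[3L]
  w <- array(rep(k, C), dim = c(nrow(k), nrow(k), 1L, C))
  ag_conv2d(ag_pad_reflect(x, r), w, stride = 1L, pad = 0L, groups = C,
            count = FALSE)
}

#' Construct a dynamic upsampling (DySample) module
#'
#' A 1 x 1 convolution predicts content-dependent offsets for each output
#' sub-pixel; sampling positions are the regular bilinear grid plus
#' `scope`-scaled offsets, read by bilinear interpolation. With all offset
#' weights zero it reduces exactly to bilinear upsampling.
#' @param channels input channel count (must be divisible by `groups`)
#' @param factor integer upsampling factor >= 2
#' @param groups offset groups sharing a sampling grid (default 4)
#' @param scope offset range factor in input-pixel units (default 0.25)
#' @export
mod_dysample <- function(channels, factor = 2L, groups = 4L, scope = 0.25) {
  if (factor < 2L) stop("factor must be >= 2")
  if (channels %% groups != 0L) groups <- 1L
  f <- as.integer(factor)
  co <- 2L * groups * f * f
  m <- new_module("dysample",
                  params = list(w_off = winit(c(1L, 1L, channels, co), channels),
                                b_off = rep(0, co)),
                  fn = NULL, factor = f, groups = groups, scope = scope,
                  channels = channels)
  m$fn <- function(self, x, train) dysample(x, self)
  m
}

# rearrange an (H,W,f^2,N) slot tensor to (fH,fW,N); slot = ki + f*kj
dys_grid_index <- function(h, w, n, f) {
  r <- seq_len(f * h) - 1L; q <- seq_len(f * w) - 1L
  hi <- r %/% f; ki <- r %% f
  wj <- q %/% f; kj <- q %% f
  h_r <- rep(hi, times = f * w * n); s_r <- rep(ki, times = f * w * n)
  w_q <- rep(rep(wj, each = f * h), times = n)
  s_q <- rep(rep(kj, each = f * h), times = n)
  nn <- rep(seq_len(n) - 1L, each = f * f * h * w)
  slot <- s_r + f * s_q
  1L + h_r + h * (w_q + w * (slot + f * f * nn))
}

#' Dynamic content-aware upsampling
#' @param x (H,W,C,N) input
#' @param m module from [mod_dysample()] matching C and the desired factor
#' @return (fH,fW,C,N) upsampled map
#' @export
dysample <- function(x, m) {
  st <- m$state
  f <- st$factor; g <- st$groups
  d <- dim(ag_value(x))
  if (d[3L] != st$channels) stop("channel mismatch in dysample")
  off <- ag_conv2d(x, m$params$w_off, m$params$b_off)
  ho <- f * d[1L]; wo <- f * d[2L]
  base_y <- array(rep((seq_len(ho) - 0.5) / f - 0.5, times = wo * d[4L]),
                  dim = c(ho, wo, d[4L]))
  base_x <- array(rep(rep((seq_len(wo) - 0.5) / f - 0.5, each = ho), times = d[4L]),
                  dim = c(ho, wo, d[4L]))
  idx <- dys_grid_index(d[1L], d[2L], d[4L], f)
  outs <- vector("list", g)
  cg <- d[3L] %/% g
  f2 <- f * f
  for (gi in seq_len(g)) {
    c0 <- (gi - 1L) * 2L * f2
    oy <- ag_permute(ag_channels(off, c0 + 1L, c0 + f2), idx, c(ho, wo, d[4L]))
    ox <- ag_permute(ag_channels(off, c0 + f2 + 1L, c0 + 2L * f2), idx, c(ho, wo, d[4L]))
    cy <- base_y + st$scope * oy
    cx <- base_x + st$scope * ox
    xg <- ag_channels(x, (gi - 1L) * cg + 1L, gi * cg)
    outs[[gi]] <- ag_grid_sample(xg, cy, cx)
  }
  if (g == 1L) outs[[1L]] else ag_concat(outs)
}

#' Construct a scale-sequence feature fusion (SSFF) module
#'
#' Deeper pyramid levels are channel-aligned, dynamically upsampled to the
#' shallowest (reference) level's size, Gaussian-smoothed, stacked along a
#' scale axis of depth 3 and reduced by a 3-D convolution (kernel 3 along
#' scale, 1 x 1 spatially — computed as its exact channel-stacked 2-D
#' equivalent) back to one feature map at reference size.
#' @param cins channel counts, deepest level first
#' @param width fusion width (output channels)
#' @param sigma Gaussian smoothing scale per level (default 1)
#' @export
mod_ssff <- function(cins, width, sigma = 1) {
  stopifnot(length(cins) == 3L)
  kids <- list(al1 = mod_conv(cins[1L], width, 1L),
               al2 = mod_conv(cins[2L], width, 1L),
               al3 = mod_conv(cins[3L], width, 1L),
               up1 = mod_dysample(width, 4L),
               up2 = mod_dysample(width, 2L),
               fuse = mod_conv(3L * width, width, 1L))  # the 3x1x1 scale conv
  new_module("ssff", children = kids, fn = NULL, sigma = sigma,
             width = width)
}

#' Fuse three pyramid levels with an SSFF module
#' @param m module from [mod_ssff()]
#' @param levels list of three feature maps, deepest (smallest) first
#' @param train training mode
#' @return fused map at the shallowest level's size
#' @export
ssff_fuse <- function(m, levels, train = FALSE) {
  stopifnot(length(levels) == 3L)
  sg <- m$state$sigma
  a1 <- module_forward(m$children$al1, levels[[1L]], train)
  a2 <- module_forward(m$children$al2, levels[[2L]], train)
  a3 <- module_forward(m$children$al3, levels[[3L]], train)
  u1 <- gaussian_smooth(dysample(a1, m$children$up1), sg)
  u2 <- gaussian_smooth(dysample(a2, m$children$up2), sg)
  stacked <- ag_concat(list(u1, u2, a3))   # scale axis folded into channels
  module_forward(m$children$fuse, stacked, train)
}

#' Construct a triple-feature-encoding (TFE) module
#'
#' Channel counts of the three branches are adjusted to the fusion width
#' before encoding; the large branch is downsampled by the element-wise mean
#' of 2x2 max pooling and average pooling, the small branch upsampled by
#' nearest neighbour, and the three size-aligned maps are concatenated along
#' channels (output width 3 x `width`).
#' @param cl,cm,cs channel counts of the large/medium/small branches
#' @param width per-branch channel width after adjustment
#' @export
mod_tfe <- function(cl, cm, cs, width) {
  new_module("tfe",
             children = list(l = mod_conv(cl, width, 1L),
                             m = mod_conv(cm, width, 1L),
                             s = mod_conv(cs, width, 1L)),
             fn = NULL, width = width)
}

#' Triple feature encoding of consecutive pyramid levels
#' @param m module from [mod_tfe()]
#' @param large,medium,small feature maps at consecutive scales (large =
#'   highest resolution); output is at the medium size with 3 x width channels
#' @param train training mode
#' @export
tfe_fuse <- function(m, large, medium, small, train = FALSE) {
  dl <- dim(ag_value(large)); dm <- dim(ag_value(medium))
  if (dl[1L] != 2L * dm[1L]) stop("large branch must be at twice the medium resolution")
  l <- module_forward(m$children$l, large, train)
  l <- 0.5 * (ag_maxpool(l, 2L, 2L) + ag_avgpool(l, 2L, 2L))
  md <- module_forward(m$children$m, medium, train)
  s <- ag_upsample_nearest(module_forward(m$children$s, small, train), 2L)
  ag_concat(list(l, md, s))
}
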