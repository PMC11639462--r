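# Receptive-Field Attention convolution. Each input channel is expanded into
# k^2 receptive-field slots by a grouped k x k convolution; a parallel branch
# average-pools each receptive field, exchanges information with a grouped
# 1 x 1 convolution and softmax-normalises the k^2 slots of every channel at
# every site. The attention-weighted slots are laid out spatially and
# re-aggregated by a k x k convolution with stride k, so the block is a
# drop-in replacement for a standard convolution of the same kernel/stride.

#' Construct a receptive-field attention convolution block
#'
#' @param in_channels,out_channels channel counts
#' @param k odd kernel size >= 3
#' @param stride convolution stride
#' @export
rfa_conv <- function(in_channels, out_channels, k = 3L, stride = 1L) {
  if (k < 3L || k %% 2L == 0L) stop("kernel size must be odd and >= 3")
  c <- in_channels
  m <- new_module("rfaconv",
    params = list(
      w_att = winit(c(1L, 1L, 1L, c * k * k), 1),
      w_gen = winit(c(k, k, 1L, c * k * k), k * k),
      gen_gamma = rep(1, c * k * k), gen_beta = rep(0, c * k * k)),
    children = list(out = mod_conv(c, out_channels, k, stride = k, pad = 0L)),
    fn = NULL, k = k, stride = stride, cin = c)
  m$state$running_mean <- rep(0, c * k * k)
  m$state$running_var <- rep(1, c * k * k)
  m$fn <- function(self, x, train) rfaconv_forward(self, x, train)
  m
}

# slot-expansion layout: expanded channel = slot + k^2 * (channel - 1),
# slot = ki + k * kj (0-based within-kernel row/col)
rfa_rearrange_index <- function(hp, wp, c, n, k) {
  kh <- k * hp; kw <- k * wp
  r <- seq_len(kh) - 1L
  q <- seq_len(kw) - 1L
  hi <- r %/% k; ki <- r %% k
  wj <- q %/% k; kj <- q %% k
  ck2 <- c * k * k
  # input linear index for out (r, q, ch, n)
  s_r <- rep(ki, times = kw * c * n)
  h_r <- rep(hi, times = kw * c * n)
  s_q <- rep(rep(kj, each = kh), times = c * n)
  w_q <- rep(rep(wj, each = kh), times = c * n)
  cc <- rep(rep(seq_len(c) - 1L, each = kh * kw), times = n)
  nn <- rep(seq_len(n) - 1L, each = kh * kw * c)
  slot <- s_r + k * s_q
  ch <- slot + k * k * cc
  1L + h_r + hp * (w_q + wp * (ch + ck2 * nn))
}

#' Receptive-field attention weights
#'
#' Average pooling aggregates each k x k receptive field, a grouped 1 x 1
#' convolution exchanges information within each channel's slots, and softmax
#' normalises the k^2 slots per channel at each site.
#' @param m block from [rfa_conv()]
#' @param x (H,W,C,N) input
#' @return (H',W',C*k^2,N) attention map; slots of one channel are consecutive
#' @export
rfa_weights <- function(m, x) {
  k <- m$state$k
  pooled <- ag_avgpool(x, k, m$state$stride, pad = k %/% 2L)
  logits <- ag_conv2d(pooled, m$params$w_att, groups = m$state$cin)
  ag_softmax_blocks(logits, k * k)
}

#' Forward pass of the receptive-field attention convolution
#' @param m block from [rfa_conv()]
#' @param x (H,W,C,N) input
#' @param train training mode
#' @return (H',W',out_channels,N) feature map
#' @export
rfaconv_forward <- function(m, x, train = FALSE) {
  k <- m$state$k
  att <- rfa_weights(m, x)
  feat <- ag_conv2d(x, m$params$w_gen, stride = m$state$stride,
                    pad = k %/% 2L, groups = m$state$cin)
  feat <- ag_batchnorm(feat, m$params$gen_gamma, m$params$gen_beta, m$state,
                       training = train)
  feat <- ag_relu(feat)
  wf <- att * feat
  d <- dim(ag_value(wf))
  idx <- rfa_rearrange_index(d[1L], d[2L], m$state$cin, d[4L], k)
  big <- ag_permute(wf, idx, c(k * d[1L], k * d[2L], m$state$cin, d[4L]))
  module_forward(m$children$out, big, train)
}
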