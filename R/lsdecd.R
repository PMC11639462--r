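# Lightweight shared detail-enhanced detection head (LSDECD).
#
# Detail-enhanced convolution (DEConv) runs five parallel k x k branches —
# a vanilla convolution plus central/angular/horizontal/vertical difference
# convolutions — and sums their outputs. Each difference branch stores a raw
# kernel bank and convolves with a linearly transformed kernel:
#
#   central    e[i,j] = w[i,j] - sum(w) at the centre tap only
#              (e = w, then e[centre] -= sum over all taps)
#   horizontal e[i,j] = w[i,j] - w[i, j-1]   (cyclic in j)
#   vertical   e[i,j] = w[i,j] - w[i-1, j]   (cyclic in i)
#   angular    e[i,j] = w[i,j] - rot90(w)[i,j]
#
# Every transformation has zero tap sum, so each difference branch
# annihilates constant inputs. All transformations are linear in the raw
# kernels, so the five branches fuse exactly into one equivalent kernel.

de_transform_matrix <- function(k, kind) {
  k2 <- k * k
  I <- diag(k2)
  idx <- function(i, j) i + k * j + 1L  # 0-based (row i, col j) -> flat, row-fastest
  M <- I
  if (kind == "cd") {
    ctr <- idx(k %/% 2L, k %/% 2L)
    M[ctr, ] <- M[ctr, ] - 1
  } else if (kind == "hd") {
    S <- matrix(0, k2, k2)
    for (i in 0:(k - 1L)) for (j in 0:(k - 1L))
      S[idx(i, j), idx(i, (j - 1L) %% k)] <- 1
    M <- I - S
  } else if (kind == "vd") {
    S <- matrix(0, k2, k2)
    for (i in 0:(k - 1L)) for (j in 0:(k - 1L))
      S[idx(i, j), idx((i - 1L) %% k, j)] <- 1
    M <- I - S
  } else if (kind == "ad") {
    S <- matrix(0, k2, k2)
    for (i in 0:(k - 1L)) for (j in 0:(k - 1L))
      S[idx(i, j), idx(j, k - 1L - i)] <- 1  # 90-degree rotation source
    M <- I - S
  }
  M
}

# apply a fixed linear tap transformation to a kernel bank (ag-differentiable)
ag_kernel_transform <- function(w, M) {
  wv <- ag_value(w)
  d <- dim(wv)
  v <- array(M %*% matrix(wv, nrow = d[1L] * d[2L]), dim = d)
  ag_node(v, list(w), function(g) {
    list(array(crossprod(M, matrix(g, nrow = d[1L] * d[2L])), dim = d))
  })
}

#' Construct a detail-enhanced convolution (five parallel kernel banks)
#' @param cin,cout channel counts
#' @param k kernel size (default 3)
#' @export
mod_deconv <- function(cin, cout, k = 3L) {
  fan <- cin * k * k
  banks <- c("vanilla", "cd", "ad", "hd", "vd")
  params <- stats::setNames(lapply(banks, function(b)
    winit(c(k, k, cin, cout), fan * 5)), paste0("w_", banks))
  m <- new_module("deconv", params = params, fn = NULL, k = k,
                  cin = cin, cout = cout)
  m$fn <- function(self, x, train) deconv_forward(x, self)
  m
}

de_kernels <- function(m) {
  lapply(stats::setNames(nm = c("vanilla", "cd", "ad", "hd", "vd")),
         function(b) m$params[[paste0("w_", b)]])
}

#' Forward pass of a detail-enhanced convolution
#'
#' Sum of the five parallel branch outputs; each difference branch convolves
#' with its transformed kernel (see the tap arithmetic at the top of the
#' implementation file).
#' @param x (H,W,C,N) input
#' @param kb a [mod_deconv()] module, or a plain list with elements
#'   vanilla, cd, ad, hd, vd (raw kernel banks of equal shape (k,k,cin,cout))
#' @export
deconv_forward <- function(x, kb) {
  if (inherits(kb, "ag_module")) kb <- de_kernels(kb)
  k <- dim(ag_value(kb$vanilla))[1L]
  pad <- k %/% 2L
  out <- ag_conv2d(x, kb$vanilla, stride = 1L, pad = pad)
  for (b in c("cd", "ad", "hd", "vd")) {
    e <- ag_kernel_transform(kb[[b]], de_transform_matrix(k, b))
    out <- out + ag_conv2d(x, e, stride = 1L, pad = pad)
  }
  out
}

#' Fuse the five DEConv branches into one equivalent kernel bank
#'
#' By linearity, one convolution with the fused kernel reproduces the
#' five-branch sum for every input. The result is returned in the same
#' five-bank shape with everything folded into `vanilla` (the difference
#' banks zero), so fusing an already-fused bank is a no-op.
#' @param kb a [mod_deconv()] module or plain kernel-bank list
#' @return kernel-bank list with `vanilla` = fused kernel
#' @export
deconv_fuse <- function(kb) {
  if (inherits(kb, "ag_module")) kb <- lapply(de_kernels(kb), ag_value)
  k <- dim(kb$vanilla)[1L]
  fused <- kb$vanilla
  for (b in c("cd", "ad", "hd", "vd")) {
    d <- dim(kb[[b]])
    fused <- fused + array(de_transform_matrix(k, b) %*%
                             matrix(kb[[b]], nrow = k * k), dim = d)
  }
  zero <- array(0, dim = dim(fused))
  list(vanilla = fused, cd = zero, ad = zero, hd = zero, vd = zero)
}

mod_deconv_gn <- function(ch, gn_groups = 16L) {
  gg <- gn_pick(ch, gn_groups)
  m <- new_module("deconv_gn",
                  params = list(gamma = rep(1, ch), beta = rep(0, ch)),
                  children = list(de = mod_deconv(ch, ch)),
                  fn = NULL, gn_groups = gg)
  m$fn <- function(self, x, train) {
    ag_silu(ag_groupnorm(module_forward(self$children$de, x, train),
                         self$params$gamma, self$params$beta, self$state$gn_groups))
  }
  m
}

#' Construct the lightweight shared detail-enhanced detection head
#'
#' Per level: a level-specific 1x1 group-normalised convolution aligns the
#' neck output to the shared width. Two shared DEConv+GN blocks (one
#' parameter set used at every level) aggregate detail; decoupled per-level
#' 1x1 classification and regression convolutions produce the outputs, with
#' a per-level learnable scale (init 1) applied to the regression features
#' before the regression convolution.
#' @param in_channels integer vector of neck output widths (3 or 4 levels)
#' @param nc number of classes
#' @param reg_max regression bin count per box side (default 16)
#' @param width shared channel width (default 16)
#' @param gn_groups group-normalisation groups (default 16, or channels if fewer)
#' @export
mod_lsdecd <- function(in_channels, nc, reg_max = 16L, width = 16L,
                       gn_groups = 16L) {
  nl <- length(in_channels)
  if (!nl %in% c(3L, 4L)) stop("head supports 3 or 4 levels")
  kids <- list()
  params <- list()
  for (i in seq_len(nl)) {
    kids[[paste0("align", i)]] <- mod_conv(in_channels[i], width, 1L,
                                           norm = "gn", gn_groups = gn_groups)
    params[[paste0("scale", i)]] <- 1
    params[[paste0("w_cls", i)]] <- winit(c(1L, 1L, width, nc), width)
    params[[paste0("b_cls", i)]] <- rep(0, nc)
    params[[paste0("w_reg", i)]] <- winit(c(1L, 1L, width, 4L * reg_max), width)
    params[[paste0("b_reg", i)]] <- rep(0, 4L * reg_max)
  }
  kids$de1 <- mod_deconv_gn(width, gn_groups)
  kids$de2 <- mod_deconv_gn(width, gn_groups)
  m <- new_module("lsdecd", params = params, children = kids, fn = NULL,
                  nc = nc, reg_max = reg_max, nl = nl, width = width)
  m$fn <- function(self, x, train) lsdecd_forward(x, self, train)
  m
}

#' Forward pass of the LSDECD head
#' @param levels list of neck feature maps (shallowest first)
#' @param m head from [mod_lsdecd()]
#' @param train training mode
#' @return per level, a list with `cls` (nc channels, logits) and `reg`
#'   (4*reg_max channels of box-side bin logits)
#' @export
lsdecd_forward <- function(levels, m, train = FALSE) {
  if (length(levels) != m$state$nl) stop("level count does not match head config")
  lapply(seq_along(levels), function(i) {
    t <- module_forward(m$children[[paste0("align", i)]], levels[[i]], train)
    t <- module_forward(m$children$de2,
                        module_forward(m$children$de1, t, train), train)
    cls <- ag_conv2d(t, m$params[[paste0("w_cls", i)]], m$params[[paste0("b_cls", i)]])
    reg <- ag_conv2d(m$params[[paste0("scale", i)]] * t,
                     m$params[[paste0("w_reg", i)]], m$params[[paste0("b_reg", i)]])
    list(cls = cls, reg = reg)
  })
}
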