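# Network-level operations built on the Rcpp kernels, each differentiable
# through the tape. Feature maps are (H, W, C, N) double arrays.

as_nchw4 <- function(x) {
  v <- ag_value(x)
  d <- dim(v)
  if (is.null(d) || length(d) == 3L) stop("feature maps must be 4-D (H,W,C,N); use fmap()")
  x
}

#' Build a feature map array
#'
#' @param data numeric vector/array of values
#' @param h,w,c spatial size and channel count
#' @param n batch size
#' @return (H,W,C,N) array
#' @export
fmap <- function(data, h, w, c, n = 1L) {
  array(as.double(data), dim = c(h, w, c, n))
}

count_flops_add <- function(fl) {
  if (!is.null(.aviscan$flops)) .aviscan$flops <- .aviscan$flops + fl
  invisible(NULL)
}

#' Start/stop FLOP accounting (2 x multiply-accumulate, conv and affine only)
#' @keywords internal
flops_begin <- function() .aviscan$flops <- 0
flops_end <- function() { fl <- .aviscan$flops; .aviscan$flops <- NULL; fl }

#' 2-D convolution (grouped, strided, zero-padded)
#'
#' @param x (H,W,C,N) array or agTensor
#' @param w (k,k,Cin/groups,Cout) kernel
#' @param b optional bias vector (length Cout)
#' @param stride,pad,groups convolution hyper-parameters
#' @param count include this layer in FLOP accounting (FALSE for fixed-kernel
#'   convolutions such as Gaussian smoothing)
#' @return (H',W',Cout,N) output
#' @export
ag_conv2d <- function(x, w, b = NULL, stride = 1L, pad = 0L, groups = 1L,
                      count = TRUE) {
  xv <- ag_value(as_nchw4(x)); wv <- ag_value(w)
  bv <- if (is.null(b)) NULL else as.double(ag_value(b))
  y <- cpp_conv2d(xv, wv, bv, as.integer(stride), as.integer(pad), as.integer(groups))
  dy <- dim(y)
  k <- dim(wv)[1L]
  if (count)
    count_flops_add(2 * (dim(wv)[3L]) * k * k * dy[3L] * dy[1L] * dy[2L] * dy[4L])
  ag_node(y, list(x, w, b), function(g) {
    bw <- cpp_conv2d_bwd(xv, wv, g, as.integer(stride), as.integer(pad),
                         as.integer(groups), is_ag(x))
    list(if (is_ag(x)) bw$gx else NULL,
         if (is_ag(w)) bw$gw else NULL,
         if (!is.null(b) && is_ag(b)) bw$gb else NULL)
  })
}

#' Max pooling
#' @param x (H,W,C,N) input
#' @param k,stride,pad pooling window, stride and zero padding
#' @export
ag_maxpool <- function(x, k, stride = k, pad = 0L) {
  xv <- ag_value(as_nchw4(x))
  r <- cpp_pool2d(xv, as.integer(k), as.integer(stride), as.integer(pad), 0L)
  ag_node(r$y, list(x), function(g) {
    list(cpp_pool2d_bwd(g, dim(xv), as.integer(k), as.integer(stride),
                        as.integer(pad), 0L, r$argmax))
  })
}

#' Average pooling (padding taps excluded from the divisor)
#' @param x (H,W,C,N) input
#' @param k,stride,pad pooling window, stride and zero padding
#' @export
ag_avgpool <- function(x, k, stride = k, pad = 0L) {
  xv <- ag_value(as_nchw4(x))
  r <- cpp_pool2d(xv, as.integer(k), as.integer(stride), as.integer(pad), 1L)
  ag_node(r$y, list(x), function(g) {
    list(cpp_pool2d_bwd(g, dim(xv), as.integer(k), as.integer(stride),
                        as.integer(pad), 1L, integer(0)))
  })
}

#' Nearest-neighbour upsampling by an integer factor
#' @param x (H,W,C,N) input
#' @param factor integer >= 2
#' @export
ag_upsample_nearest <- function(x, factor) {
  xv <- ag_value(as_nchw4(x))
  d <- dim(xv)
  f <- as.integer(factor)
  hi <- rep(seq_len(d[1L]), each = f)
  wi <- rep(seq_len(d[2L]), each = f)
  y <- xv[hi, wi, , , drop = FALSE]
  ag_node(y, list(x), function(g) {
    # sum over each f x f block: fold (fH, fW, C, N) -> (f, H, f, W, CN)
    gr <- array(g, dim = c(f, d[1L], f, d[2L], d[3L] * d[4L]))
    gx <- apply(gr, c(2L, 4L, 5L), sum)
    list(array(gx, dim = d))
  })
}

#' Bilinear sampling of a feature map at continuous positions
#'
#' Positions are 0-based pixel coordinates in the input grid, border-clamped.
#' @param x (H,W,C,N) input
#' @param cy,cx (H',W',N) arrays (or agTensors) of row/column positions
#' @export
ag_grid_sample <- function(x, cy, cx) {
  xv <- ag_value(as_nchw4(x)); cyv <- ag_value(cy); cxv <- ag_value(cx)
  y <- cpp_grid_sample(xv, cyv, cxv)
  ag_node(y, list(x, cy, cx), function(g) {
    bw <- cpp_grid_sample_bwd(xv, cyv, cxv, g)
    list(if (is_ag(x)) bw$gx else NULL,
         if (is_ag(cy)) bw$gcy else NULL,
         if (is_ag(cx)) bw$gcx else NULL)
  })
}

#' Plain bilinear upsampling by an integer factor
#'
#' Sampling positions follow the half-pixel (align_corners = FALSE) convention,
#' the reference against which zero-offset dynamic upsampling must agree.
#' @param x (H,W,C,N) input
#' @param factor integer >= 2
#' @export
ag_upsample_bilinear <- function(x, factor) {
  d <- dim(ag_value(as_nchw4(x)))
  f <- factor
  ho <- d[1L] * f; wo <- d[2L] * f
  yy <- (seq_len(ho) - 0.5) / f - 0.5
  xx <- (seq_len(wo) - 0.5) / f - 0.5
  cy <- array(rep(yy, times = wo), dim = c(ho, wo, 1L))[, , rep(1L, d[4L]), drop = FALSE]
  dim(cy) <- c(ho, wo, d[4L])
  cx <- array(rep(xx, each = ho), dim = c(ho, wo, 1L))[, , rep(1L, d[4L]), drop = FALSE]
  dim(cx) <- c(ho, wo, d[4L])
  ag_grid_sample(x, cy, cx)
}

bc_channel <- function(v, d) {
  # broadcast a per-channel vector to (H,W,C,N)
  array(rep(rep(v, each = d[1L] * d[2L]), times = d[4L]), dim = d)
}

#' Batch normalisation over (H,W,N) per channel
#'
#' @param x (H,W,C,N) input
#' @param gamma,beta per-channel affine parameters (agTensors during training)
#' @param state environment holding running_mean / running_var
#' @param training logical; batch statistics when TRUE, running stats otherwise
#' @param momentum running-statistics update rate
#' @param eps variance floor
#' @export
ag_batchnorm <- function(x, gamma, beta, state, training = TRUE,
                         momentum = 0.1, eps = 1e-5) {
  xv <- ag_value(as_nchw4(x))
  d <- dim(xv)
  hw <- d[1L] * d[2L]; C <- d[3L]; N <- d[4L]
  m <- hw * N
  xm <- matrix(xv, nrow = hw * C, ncol = N)
  per_c <- function(a) {
    s <- matrix(colSums(matrix(a, nrow = hw, ncol = C * N)), C, N)
    rowSums(s) / m
  }
  if (training) {
    mu <- per_c(xv)
    varr <- per_c(xv * xv) - mu^2
    varr[varr < 0] <- 0
    state$running_mean <- (1 - momentum) * state$running_mean + momentum * mu
    ub <- if (m > 1) m / (m - 1) else 1
    state$running_var <- (1 - momentum) * state$running_var + momentum * varr * ub
  } else {
    mu <- state$running_mean
    varr <- state$running_var
  }
  sd_ <- sqrt(varr + eps)
  xhat <- (xv - bc_channel(mu, d)) / bc_channel(sd_, d)
  gv <- ag_value(gamma); bv <- ag_value(beta)
  y <- xhat * bc_channel(gv, d) + bc_channel(bv, d)
  ag_node(y, list(x, gamma, beta), function(g) {
    dgamma <- per_c(g * xhat) * m
    dbeta <- per_c(g) * m
    gx <- NULL
    if (is_ag(x)) {
      if (training) {
        gx <- bc_channel(gv / sd_, d) *
          (g - bc_channel(dbeta / m, d) - xhat * bc_channel(dgamma / m, d))
      } else {
        gx <- g * bc_channel(gv / sd_, d)
      }
    }
    list(gx,
         if (is_ag(gamma)) dgamma else NULL,
         if (is_ag(beta)) dbeta else NULL)
  })
}

#' Group normalisation over (H,W,Cg) per image and channel group
#'
#' @param x (H,W,C,N) input
#' @param gamma,beta per-channel affine parameters
#' @param groups number of channel groups (must divide C)
#' @param eps variance floor
#' @export
ag_groupnorm <- function(x, gamma, beta, groups, eps = 1e-5) {
  xv <- ag_value(as_nchw4(x))
  d <- dim(xv)
  hw <- d[1L] * d[2L]; C <- d[3L]; N <- d[4L]
  if (C %% groups != 0L) stop("groups must divide the channel count")
  cg <- C %/% groups
  m <- hw * cg
  # stats per (group, image)
  xg <- matrix(xv, nrow = hw * cg, ncol = groups * N)
  mu <- colMeans(xg)
  varr <- colMeans(xg * xg) - mu^2
  varr[varr < 0] <- 0
  sd_ <- sqrt(varr + eps)
  bc_g <- function(v) array(rep(v, each = hw * cg), dim = d)
  xhat <- (xv - bc_g(mu)) / bc_g(sd_)
  gv <- ag_value(gamma); bv <- ag_value(beta)
  y <- xhat * bc_channel(gv, d) + bc_channel(bv, d)
  ag_node(y, list(x, gamma, beta), function(g) {
    per_c <- function(a) {
      s <- matrix(colSums(matrix(a, nrow = hw, ncol = C * N)), C, N)
      rowSums(s)
    }
    dgamma <- per_c(g * xhat)
    dbeta <- per_c(g)
    gx <- NULL
    if (is_ag(x)) {
      gg <- g * bc_channel(gv, d)  # dL/dxhat
      ggm <- matrix(gg, nrow = hw * cg, ncol = groups * N)
      xhm <- matrix(xhat, nrow = hw * cg, ncol = groups * N)
      mean_g <- colMeans(ggm)
      mean_gx <- colMeans(ggm * xhm)
      gx <- (gg - bc_g(mean_g) - xhat * bc_g(mean_gx)) / bc_g(sd_)
    }
    list(gx,
         if (is_ag(gamma)) dgamma else NULL,
         if (is_ag(beta)) dbeta else NULL)
  })
}

#' Softmax over consecutive channel blocks
#'
#' Channels are partitioned into blocks of `gsize` consecutive channels;
#' softmax is applied within each block independently at each spatial site.
#' @param x (H,W,C,N) input with C a multiple of gsize
#' @param gsize block size (e.g. k^2 receptive-field slots, or reg_max bins)
#' @export
ag_softmax_blocks <- function(x, gsize) {
  xv <- ag_value(as_nchw4(x))
  d <- dim(xv)
  if (d[3L] %% gsize != 0L) stop("channel count not a multiple of gsize")
  nb <- d[3L] %/% gsize
  hw <- d[1L] * d[2L]
  xr <- array(xv, dim = c(hw, gsize, nb * d[4L]))
  mx <- xr[, 1L, , drop = FALSE]
  for (j in 2:gsize) mx <- pmax(mx, xr[, j, , drop = FALSE])
  ex <- exp(xr - array(mx[, rep(1L, gsize), ], dim = dim(xr)))
  ssum <- ex[, 1L, , drop = FALSE]
  for (j in 2:gsize) ssum <- ssum + ex[, j, , drop = FALSE]
  yr <- ex / array(ssum[, rep(1L, gsize), ], dim = dim(xr))
  y <- array(yr, dim = d)
  ag_node(y, list(x), function(g) {
    gr <- array(g, dim = c(hw, gsize, nb * d[4L]))
    dot <- (gr * yr)[, 1L, , drop = FALSE]
    for (j in 2:gsize) dot <- dot + (gr * yr)[, j, , drop = FALSE]
    gx <- yr * (gr - array(dot[, rep(1L, gsize), ], dim = dim(yr)))
    list(array(gx, dim = d))
  })
}

#' Summed binary cross-entropy on logits
#'
#' @param x logits (any shape)
#' @param target same-shape targets in [0,1]
#' @param weight optional same-shape (or scalar) weights
#' @return scalar loss (sum, not mean)
#' @export
ag_bce_logits <- function(x, target, weight = NULL) {
  xv <- ag_value(x); tv <- ag_value(target)
  wv <- if (is.null(weight)) 1 else ag_value(weight)
  l <- pmax(xv, 0) - xv * tv + log1p(exp(-abs(xv)))
  ag_node(sum(wv * l), list(x), function(g) {
    s <- 1 / (1 + exp(-xv))
    list(g * wv * (s - tv))
  })
}
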