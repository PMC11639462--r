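# The tape engine underpins every trainable module; these tests pin its
# gradients against central differences and a hand-rolled convolution.

naive_conv_full <- function(x, w, b = NULL, stride = 1, pad = 0, groups = 1) {
  d <- dim(x); k <- dim(w)[1]; Cg <- dim(w)[3]; Cout <- dim(w)[4]
  Ho <- (d[1] + 2 * pad - k) %/% stride + 1
  Wo <- (d[2] + 2 * pad - k) %/% stride + 1
  Coutg <- Cout / groups
  xp <- array(0, c(d[1] + 2 * pad, d[2] + 2 * pad, d[3], d[4]))
  xp[pad + seq_len(d[1]), pad + seq_len(d[2]), , ] <- x
  y <- array(0, c(Ho, Wo, Cout, d[4]))
  for (n in seq_len(d[4])) for (co in seq_len(Cout)) {
    g <- (co - 1) %/% Coutg
    for (ho in seq_len(Ho)) for (wo in seq_len(Wo)) {
      acc <- if (is.null(b)) 0 else b[co]
      for (ci in seq_len(Cg)) for (ki in seq_len(k)) for (kj in seq_len(k))
        acc <- acc + xp[(ho - 1) * stride + ki, (wo - 1) * stride + kj,
                        g * Cg + ci, n] * w[ki, kj, ci, co]
      y[ho, wo, co, n] <- acc
    }
  }
  y
}

test_that("compiled convolution matches a naive loop implementation", {
  set.seed(1)
  cases <- list(list(s = 1, p = 1, g = 1), list(s = 2, p = 1, g = 2),
                list(s = 2, p = 0, g = 6))
  for (cs in cases) {
    x <- fmap(rnorm(6 * 9 * 7 * 2), 9, 7, 6, 2)
    w <- array(rnorm(3 * 3 * (6 / cs$g) * 12), c(3, 3, 6 / cs$g, 12))
    b <- rnorm(12)
    expect_equal(ag_value(ag_conv2d(x, w, b, cs$s, cs$p, cs$g)),
                 naive_conv_full(x, w, b, cs$s, cs$p, cs$g), tolerance = 1e-12)
  }
})

numgrad_at <- function(f, v, idx, eps = 1e-6) {
  vapply(idx, function(i) {
    v1 <- v; v1[i] <- v1[i] + eps
    v2 <- v; v2[i] <- v2[i] - eps
    (f(v1) - f(v2)) / (2 * eps)
  }, numeric(1))
}

test_that("conv, pooling, grid-sample and norm gradients match central differences", {
  set.seed(2)
  x <- fmap(rnorm(4 * 6 * 6), 6, 6, 4)
  w <- array(rnorm(3 * 3 * 4 * 5), c(3, 3, 4, 5))
  idx <- sample(length(x), 5)
  # conv wrt input
  xl <- ag_leaf(x)
  ag_backward(ag_sum(ag_conv2d(xl, w, stride = 1, pad = 1)^2))
  ng <- numgrad_at(function(v) sum(ag_value(ag_conv2d(v, w, stride = 1, pad = 1))^2), x, idx)
  expect_equal(xl$grad[idx], ng, tolerance = 1e-5)
  # max pool
  xl <- ag_leaf(x)
  ag_backward(ag_sum(ag_maxpool(xl, 2L, 2L)^2))
  ng <- numgrad_at(function(v) sum(ag_value(ag_maxpool(v, 2L, 2L))^2), x, idx)
  expect_equal(xl$grad[idx], ng, tolerance = 1e-5)
  # average pool with padding
  xl <- ag_leaf(x)
  ag_backward(ag_sum(ag_avgpool(xl, 3L, 2L, 1L)^2))
  ng <- numgrad_at(function(v) sum(ag_value(ag_avgpool(v, 3L, 2L, 1L))^2), x, idx)
  expect_equal(xl$grad[idx], ng, tolerance = 1e-5)
  # grid sample wrt input and coordinates
  cy <- array(runif(8 * 8, 0.4, 4.6), c(8, 8, 1))
  cx <- array(runif(8 * 8, 0.4, 4.6), c(8, 8, 1))
  xl <- ag_leaf(x); cyl <- ag_leaf(cy)
  ag_backward(ag_sum(ag_grid_sample(xl, cyl, cx)^2))
  ng <- numgrad_at(function(v) sum(ag_value(ag_grid_sample(v, cy, cx))^2), x, idx)
  expect_equal(xl$grad[idx], ng, tolerance = 1e-5)
  ngc <- numgrad_at(function(v) sum(ag_value(ag_grid_sample(x, v, cx))^2), cy, 1:5)
  expect_equal(cyl$grad[1:5], ngc, tolerance = 1e-4)
  # batch norm (training statistics) wrt input and gamma
  gm <- rep(1.3, 4); bt <- rep(0.2, 4)
  st <- new.env(); st$running_mean <- rep(0, 4); st$running_var <- rep(1, 4)
  xl <- ag_leaf(x); gl <- ag_leaf(gm)
  ag_backward(ag_sum(ag_batchnorm(xl, gl, bt, st, training = TRUE)^2))
  f <- function(v) {
    s2 <- new.env(); s2$running_mean <- rep(0, 4); s2$running_var <- rep(1, 4)
    sum(ag_value(ag_batchnorm(v, gm, bt, s2, training = TRUE))^2)
  }
  expect_equal(xl$grad[idx], numgrad_at(f, x, idx), tolerance = 1e-4)
  # group norm wrt input
  xl <- ag_leaf(x)
  ag_backward(ag_sum(ag_groupnorm(xl, gm, bt, groups = 2)^2))
  fg <- function(v) sum(ag_value(ag_groupnorm(v, gm, bt, groups = 2))^2)
  expect_equal(xl$grad[idx], numgrad_at(fg, x, idx), tolerance = 1e-4)
})

test_that("block softmax normalises and backpropagates correctly", {
  set.seed(3)
  x <- fmap(rnorm(12 * 4 * 4), 4, 4, 12)
  y <- ag_value(ag_softmax_blocks(x, 4L))
  sums <- apply(array(y, c(16, 4, 3)), c(1, 3), sum)
  expect_equal(max(abs(sums - 1)), 0, tolerance = 1e-12)
  xl <- ag_leaf(x)
  tgt <- fmap(runif(12 * 4 * 4), 4, 4, 12)
  ag_backward(ag_sum(ag_softmax_blocks(xl, 4L) * tgt))
  idx <- sample(length(x), 6)
  ng <- numgrad_at(function(v) sum(ag_value(ag_softmax_blocks(v, 4L)) * tgt), x, idx)
  expect_equal(xl$grad[idx], ng, tolerance = 1e-5)
})

test_that("upsampling ops and BCE agree with their definitions", {
  set.seed(4)
  x <- fmap(rnorm(3 * 4 * 5), 4, 5, 3)
  yn <- ag_value(ag_upsample_nearest(x, 2L))
  expect_equal(dim(yn), c(8L, 10L, 3L, 1L))
  expect_equal(yn[3, 5, 2, 1], x[2, 3, 2, 1])
  xl <- ag_leaf(x)
  ag_backward(ag_sum(ag_upsample_nearest(xl, 2L)^2))
  idx <- sample(length(x), 4)
  ng <- numgrad_at(function(v) sum(ag_value(ag_upsample_nearest(v, 2L))^2), x, idx)
  expect_equal(xl$grad[idx], ng, tolerance = 1e-5)
  # bilinear upsampling of a linear ramp is exact in the interior
  r <- fmap(rep(seq_len(6), times = 6), 6, 6, 1)
  rb <- ag_value(ag_upsample_bilinear(r, 2L))
  expect_equal(rb[4, 6, 1, 1], r[2, 3, 1, 1] + 0.25 * (r[3, 3, 1, 1] - r[2, 3, 1, 1]),
               tolerance = 1e-9)
  # BCE with logits: value and gradient
  z <- rnorm(10); t <- runif(10)
  zl <- ag_leaf(z)
  l <- ag_bce_logits(zl, t)
  p <- 1 / (1 + exp(-z))
  expect_equal(ag_value(l), -sum(t * log(p) + (1 - t) * log(1 - p)), tolerance = 1e-9)
  ag_backward(l)
  expect_equal(zl$grad, p - t, tolerance = 1e-9)
})

test_that("the tape handles reuse, scalar broadcast and detached inference", {
  a <- ag_leaf(c(1, 2, 3))
  b <- a * a + 2 * a          # node reuse: a appears three times
  l <- ag_sum(b)
  ag_backward(l)
  expect_equal(as.numeric(a$grad), 2 * c(1, 2, 3) + 2)
  expect_equal(ag_value(ag_pmax(2, 3)), 3)  # plain numerics pass through
  y <- ag_no_grad(ag_leaf(c(1, 2)) * 5)
  expect_false(is_ag(y))
})
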