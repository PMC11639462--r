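rand_banks <- function(cin = 3, cout = 4, k = 3) {
  lapply(stats::setNames(nm = c("vanilla", "cd", "ad", "hd", "vd")), function(b)
    array(rnorm(k * k * cin * cout), dim = c(k, k, cin, cout)))
}

test_that("DEConv reduces to the vanilla branch when difference banks vanish", {
  set.seed(1)
  kb <- rand_banks()
  for (b in c("cd", "ad", "hd", "vd")) kb[[b]][] <- 0
  x <- fmap(rnorm(3 * 7 * 7), 7, 7, 3)
  y <- ag_value(deconv_forward(x, kb))
  yv <- ag_value(ag_conv2d(x, kb$vanilla, pad = 1))
  expect_equal(y, yv, tolerance = 1e-12)
})

test_that("the central-difference branch annihilates constant inputs", {
  set.seed(2)
  kb <- rand_banks()
  for (b in c("vanilla", "ad", "hd", "vd")) kb[[b]][] <- 0
  x <- fmap(rep(2.5, 3 * 9 * 9), 9, 9, 3)
  y <- ag_value(deconv_forward(x, kb))
  expect_lt(max(abs(y[3:7, 3:7, , ])), 1e-12)  # interior (borders see zero padding)
})

test_that("fused kernel reproduces the five-branch sum on random inputs", {
  set.seed(3)
  for (i in 1:20) {
    kb <- rand_banks()
    fused <- deconv_fuse(kb)
    x <- fmap(rnorm(3 * 6 * 6), 6, 6, 3)
    y5 <- ag_value(deconv_forward(x, kb))
    y1 <- ag_value(ag_conv2d(x, fused$vanilla, pad = 1))
    expect_lt(max(abs(y5 - y1)), 1e-5)
  }
})

test_that("fusion is idempotent and preserves a vanilla-only bank", {
  set.seed(4)
  kb <- rand_banks()
  f1 <- deconv_fuse(kb)
  f2 <- deconv_fuse(f1)
  expect_equal(f2, f1, tolerance = 1e-12)
  kb0 <- rand_banks()
  for (b in c("cd", "ad", "hd", "vd")) kb0[[b]][] <- 0
  expect_equal(deconv_fuse(kb0)$vanilla, kb0$vanilla, tolerance = 1e-12)
})

test_that("fused equivalence survives gradient updates of the banks", {
  set.seed(5)
  m <- mod_deconv(2, 2)
  x <- fmap(rnorm(2 * 6 * 6), 6, 6, 2)
  tgt <- fmap(rnorm(2 * 6 * 6), 6, 6, 2)
  ps <- module_params(m)
  for (it in 1:5) {
    y <- deconv_forward(x, m)
    l <- ag_sum((y - tgt)^2)
    for (p in ps) p$grad <- NULL
    ag_backward(l)
    for (p in ps) p$value <- p$value - 0.01 * p$grad
  }
  fused <- deconv_fuse(m)
  y5 <- ag_value(deconv_forward(x, m))
  y1 <- ag_value(ag_conv2d(x, fused$vanilla, pad = 1))
  expect_lt(max(abs(y5 - y1)), 1e-5)
})

test_that("the two DEConv blocks are shared across head levels", {
  set.seed(6)
  h3 <- mod_lsdecd(c(8, 16, 32), nc = 5, width = 16)
  h4 <- mod_lsdecd(c(8, 8, 16, 32), nc = 5, width = 16)
  shared <- function(h) {
    ps <- module_params(h)
    sum(vapply(ps[grepl("^de[12]\\.", names(ps))], function(p) length(p$value), numeric(1)))
  }
  # identical shared-block parameter count regardless of the level count
  expect_equal(shared(h3), shared(h4))
  # per-level additions: the 1x1 align conv (+GN), the output convs, the scale
  extra <- count_params(h4) - count_params(h3)
  expect_equal(extra, (16 * 8 + 2 * 16) + (16 * 5 + 5) + (16 * 64 + 64) + 1)
})

test_that("head outputs have nc and 4*reg_max channels; scales start as identity", {
  set.seed(7)
  h <- mod_lsdecd(c(8, 16, 32), nc = 5, reg_max = 16, width = 16)
  expect_equal(h$params$scale1$value, 1)
  lv <- list(fmap(rnorm(8 * 16 * 16), 16, 16, 8),
             fmap(rnorm(16 * 8 * 8), 8, 8, 16),
             fmap(rnorm(32 * 4 * 4), 4, 4, 32))
  outs <- lsdecd_forward(lv, h)
  for (o in outs) {
    expect_equal(dim(ag_value(o$cls))[3], 5L)
    expect_equal(dim(ag_value(o$reg))[3], 64L)
  }
  # scale = 1 is the identity on the regression features: doubling it changes
  # the regression map but the initial forward equals an unscaled buildout
  h$params$scale2$value <- 2
  outs2 <- lsdecd_forward(lv, h)
  expect_false(isTRUE(all.equal(ag_value(outs2[[2]]$reg), ag_value(outs[[2]]$reg))))
  expect_equal(ag_value(outs2[[1]]$cls), ag_value(outs[[1]]$cls))
})

test_that("group normalisation ignores per-group input rescaling", {
  set.seed(8)
  x <- fmap(rnorm(8 * 6 * 6), 6, 6, 8)
  g <- rep(1, 8); b <- rep(0, 8)
  y1 <- ag_value(ag_groupnorm(x, g, b, groups = 4))
  xs <- x
  xs[, , 1:2, ] <- xs[, , 1:2, ] * 7        # rescale one whole group
  y2 <- ag_value(ag_groupnorm(xs, g, b, groups = 4))
  expect_equal(y1, y2, tolerance = 1e-4)  # equal up to the variance floor eps
})
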