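empty_module <- function() {
  structure(list(type = "empty", params = list(), children = list(),
                 state = new.env(), fn = function(self, x, train) x),
            class = "ag_module")
}

test_that("parameter counting is exact on closed-form layers", {
  conv <- mod_conv(3, 8, 3L, bias = TRUE, norm = "none", act = "none")
  expect_equal(count_params(conv), 3 * 8 * 9 + 8)
  aff <- mod_conv(10, 5, 1L, bias = TRUE, norm = "none", act = "none")
  expect_equal(count_params(aff), 10 * 5 + 5)
  expect_equal(count_params(empty_module()), 0)
})

test_that("FLOP accounting follows the 2xMAC convolution convention", {
  conv <- mod_conv(3, 8, 3L, norm = "none", act = "none")
  x32 <- fmap(rep(0, 3 * 32 * 32), 32, 32, 3)
  aviscan:::flops_begin()
  module_forward(conv, x32)
  expect_equal(aviscan:::flops_end(), 2 * 3 * 9 * 8 * 32 * 32)  # 442,368
  # doubling H and W quadruples conv FLOPs
  x64 <- fmap(rep(0, 3 * 64 * 64), 64, 64, 3)
  aviscan:::flops_begin()
  module_forward(conv, x64)
  expect_equal(aviscan:::flops_end(), 4 * 442368)
  # pooling and fixed-kernel ops are not counted
  aviscan:::flops_begin()
  ag_maxpool(x32, 2L, 2L)
  gaussian_smooth(x32, 1)
  expect_equal(aviscan:::flops_end(), 0)
})

test_that("every ablation combination builds and runs a forward pass", {
  x <- array(runif(96 * 96 * 3), c(96, 96, 3, 1))
  for (a in c(FALSE, TRUE)) for (b in c(FALSE, TRUE)) for (d in c(FALSE, TRUE)) {
    cfg <- model_config("baseline", rfaconv = a, dyasf_p2 = b, lsdecd = d,
                        width_mult = 0.125)
    m <- build_model(cfg)
    outs <- ag_no_grad(model_forward(m, x))
    expect_length(outs, if (b) 4L else 3L)
    for (o in outs) {
      expect_true(all(is.finite(ag_value(o$cls))))
      expect_true(all(is.finite(ag_value(o$reg))))
    }
  }
})

test_that("cost ablations move in the documented directions", {
  p_base <- count_params(build_model(model_config("baseline", width_mult = 0.125)))
  p_head <- count_params(build_model(model_config("baseline", lsdecd = TRUE,
                                                  width_mult = 0.125)))
  expect_lt(p_head, p_base)  # the shared head is lighter
  f_base <- count_flops(build_model(model_config("baseline", width_mult = 0.125)),
                        input_size = 128)
  f_neck <- count_flops(build_model(model_config("baseline", dyasf_p2 = TRUE,
                                                 width_mult = 0.125)),
                        input_size = 128)
  expect_gt(f_neck, f_base)  # the P2 level adds computation
})

test_that("checkpoints restore bit-identical forward passes", {
  cfg <- model_config("bird", width_mult = 0.125, input_size = 64)
  m <- build_model(cfg, init_seed = 4)
  x <- array(runif(64 * 64 * 3), c(64, 64, 3, 1))
  y1 <- ag_no_grad(model_forward(m, x))
  ck <- tempfile(fileext = ".rds")
  save_checkpoint(m, ck)
  m2 <- load_checkpoint(ck)
  y2 <- ag_no_grad(model_forward(m2, x))
  for (l in seq_along(y1)) {
    expect_identical(ag_value(y1[[l]]$cls), ag_value(y2[[l]]$cls))
    expect_identical(ag_value(y1[[l]]$reg), ag_value(y2[[l]]$reg))
  }
})

test_that("switching the box loss changes only the box term at step zero", {
  set.seed(30)
  cfg1 <- model_config("baseline", width_mult = 0.125, input_size = 64,
                       loss = list(name = "ciou"))
  cfg2 <- model_config("baseline", width_mult = 0.125, input_size = 64,
                       loss = list(name = "inner_shape_iou", ratio = 1.2))
  m1 <- build_model(cfg1, init_seed = 9)
  m2 <- build_model(cfg2, init_seed = 9)
  s <- generate_scene(scene_spec(image_size = 64, seed = 3,
                                 objects_range = c(2, 4),
                                 scale_range = c(0.2, 0.5)))
  x <- array(s$image, c(64, 64, 3, 1))
  lab <- data.frame(class = s$boxes$class, xc = s$boxes$xc * 64,
                    yc = s$boxes$yc * 64, w = s$boxes$w * 64, h = s$boxes$h * 64)
  o1 <- model_forward(m1, x, train = TRUE)
  o2 <- model_forward(m2, x, train = TRUE)
  l1 <- aviscan:::detection_loss(o1, list(lab), m1)
  l2 <- aviscan:::detection_loss(o2, list(lab), m2)
  expect_identical(l1$cls, l2$cls)
  expect_identical(l1$dfl, l2$dfl)
  expect_false(isTRUE(all.equal(l1$box, l2$box)))
})

test_that("training is bit-deterministic for a fixed seed", {
  mk_batch <- function() {
    imgs <- list(); labs <- list()
    for (i in 1:2) {
      s <- generate_scene(scene_spec(image_size = 64, seed = 40 + i,
                                     objects_range = c(1, 2),
                                     scale_range = c(0.3, 0.5), occlusion = 0))
      imgs[[i]] <- array(s$image, c(64, 64, 3, 1))
      labs[[i]] <- data.frame(class = s$boxes$class, xc = s$boxes$xc * 64,
                              yc = s$boxes$yc * 64, w = s$boxes$w * 64,
                              h = s$boxes$h * 64)
    }
    list(images = imgs, labels = labs)
  }
  cfg <- model_config("bird", width_mult = 0.125, input_size = 64)
  x <- array(runif(64 * 64 * 3), c(64, 64, 3, 1))
  hist <- list(); outs <- list()
  for (rep in 1:2) {
    m <- build_model(cfg, init_seed = 7)
    r <- train_model(m, mk_batch(), epochs = 3, batch_size = 2, lr = 0.005,
                     seed = 3)
    hist[[rep]] <- r$history
    outs[[rep]] <- ag_no_grad(model_forward(m, x))
  }
  expect_identical(hist[[1]], hist[[2]])
  for (l in seq_along(outs[[1]])) {
    expect_identical(ag_value(outs[[1]][[l]]$cls), ag_value(outs[[2]][[l]]$cls))
    expect_identical(ag_value(outs[[1]][[l]]$reg), ag_value(outs[[2]][[l]]$reg))
  }
})

test_that("a few SGD steps reduce the loss and the model stays serialisable", {
  set.seed(31)
  cfg <- model_config("bird", width_mult = 0.125, input_size = 64)
  m <- build_model(cfg, init_seed = 6)
  imgs <- list(); labs <- list()
  for (i in 1:2) {
    s <- generate_scene(scene_spec(image_size = 64, seed = 20 + i,
                                   objects_range = c(1, 2),
                                   scale_range = c(0.3, 0.6), occlusion = 0))
    imgs[[i]] <- array(s$image, c(64, 64, 3, 1))
    labs[[i]] <- data.frame(class = s$boxes$class, xc = s$boxes$xc * 64,
                            yc = s$boxes$yc * 64, w = s$boxes$w * 64,
                            h = s$boxes$h * 64)
  }
  r <- train_model(m, list(images = imgs, labels = labs), epochs = 8,
                   batch_size = 2, lr = 0.01, seed = 2)
  h <- r$history
  expect_true(all(is.finite(h$total)))
  expect_lt(h$total[nrow(h)], h$total[1])
})
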