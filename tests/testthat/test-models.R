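toy_specs <- list(
  unet = architecture_spec("unet", initial_filters = 2, depth = 1),
  small_unet = architecture_spec("small_unet", initial_filters = 2,
                                 depth = 1),
  resunet = architecture_spec("resunet", initial_filters = 2, depth = 1),
  c_resunet = architecture_spec("c_resunet", initial_filters = 2, depth = 1))

test_that("architecture specs enforce the family flag invariants", {
  sp <- architecture_spec("c_resunet")
  expect_true(sp$use_colorspace_conv && sp$use_5x5_bottleneck)
  sp <- architecture_spec("resunet")
  expect_false(sp$use_colorspace_conv || sp$use_5x5_bottleneck)
  expect_error(architecture_spec("c_resunet", use_colorspace_conv = FALSE),
               "requires both")
  expect_error(architecture_spec("resunet", use_5x5_bottleneck = TRUE),
               "neither")
  expect_error(architecture_spec("unet", use_colorspace_conv = TRUE),
               "ResUnet-family")
})

test_that("parameter counting is exact on a minimal layer", {
  g <- cellcount:::nn_graph_new()
  cellcount:::nn_add(g, "in", "input", out_channels = 3L)
  cellcount:::nn_conv(g, "c", "in", 1L, k = 1L)   # 3 weights + 1 bias
  m <- structure(list(spec = architecture_spec("unet"), layers = g$layers,
                      bn_stats = list()),
                 class = "segmentation_model")
  expect_identical(count_parameters(m), 4)
})

test_that("the printed parameter ordering holds across families", {
  counts <- vapply(c("unet", "c_resunet", "resunet", "small_unet"),
                   function(f) count_parameters(
                     build_model(architecture_spec(f))), numeric(1))
  expect_gt(counts[["unet"]], counts[["c_resunet"]])
  expect_gt(counts[["c_resunet"]], counts[["resunet"]])
  # small Unet comparable to the ResUnet: within 2%
  expect_lt(abs(counts[["small_unet"]] - counts[["resunet"]]) /
              counts[["resunet"]], 0.02)
  # counts are a pure function of the spec
  expect_identical(counts[["resunet"]],
                   count_parameters(build_model(architecture_spec("resunet"),
                                                init_seed = 99)))
})

test_that("every family maps H x W x 3 to H x W probabilities", {
  img <- array(runif(8 * 8 * 3), dim = c(8, 8, 3))
  for (nm in names(toy_specs)) {
    m <- build_model(toy_specs[[nm]], init_seed = 5)
    hm <- predict_heatmap(m, img)
    expect_equal(dim(hm), c(8, 8))
    expect_true(all(hm >= 0 & hm <= 1))
  }
  # non-divisible sizes are reflect-padded transparently
  m <- build_model(toy_specs$c_resunet, init_seed = 5)
  hm <- predict_heatmap(m, array(runif(9 * 13 * 3), dim = c(9, 13, 3)))
  expect_equal(dim(hm), c(9, 13))
})

test_that("c_resunet differs from resunet only by its two extra blocks", {
  a <- build_model(architecture_spec("resunet"), init_seed = 1)
  b <- build_model(architecture_spec("c_resunet"), init_seed = 1)
  extra <- setdiff(names(b$layers), names(a$layers))
  expect_setequal(unique(sub("_(conv|bn|relu|merge|out|sc)[0-9]*$", "",
                             extra)),
                  c("colorspace", "bridge5x5"))
  expect_length(setdiff(names(a$layers), names(b$layers)), 0)
})

test_that("one optimization step reduces the loss for every family", {
  set.seed(31)
  x <- array(runif(16 * 16 * 3 * 2), dim = c(16, 16, 3, 2))
  t <- array(0, dim = c(16, 16, 1, 2))
  t[5:12, 5:12, 1, ] <- 1
  wm <- array(0, dim = dim(t))
  cw <- class_weights()
  for (nm in names(toy_specs)) {
    m <- build_model(architecture_spec(toy_specs[[nm]]$family,
                                       initial_filters = 2, depth = 2),
                     init_seed = 8)
    adam <- cellcount:::nn_adam_new(m)
    fw <- cellcount:::nn_forward(m, x, training = TRUE)
    lg <- cellcount:::wbce_with_grad(t, fw$out, wm, cw)
    gr <- cellcount:::nn_backward(m, fw$cache, "head", lg$glogit)
    st <- cellcount:::nn_adam_step(m, gr, adam, lr = 0.01)
    fw2 <- cellcount:::nn_forward(st$model, x, training = TRUE)
    lg2 <- cellcount:::wbce_with_grad(t, fw2$out, wm, cw)
    expect_lt(lg2$loss, lg$loss)
  }
})

test_that("checkpoints round-trip weights and running statistics", {
  m <- build_model(toy_specs$resunet, init_seed = 3)
  x <- array(runif(8 * 8 * 3), dim = c(8, 8, 3))
  p <- file.path(tempdir(), "ckpt.rds")
  save_checkpoint(m, p)
  m2 <- load_checkpoint(p)
  expect_equal(predict_heatmap(m2, x), predict_heatmap(m, x),
               tolerance = 1e-12)
  unlink(p)
})
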