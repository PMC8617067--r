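#' Describe one of the four segmentation architectures
#'
#' Creates a validated architecture specification for [build_model()].  Four
#' families are available:
#'
#' * `"unet"`: an encoder--decoder network with triple 3x3 convolution
#'   blocks, 2x2 max pooling, a four-convolution bottleneck at twice the
#'   deepest encoder width, and a transposed-convolution decoder with skip
#'   concatenations (64 initial filters, three pooling levels by default).
#' * `"small_unet"`: the same template scaled down to the residual family's
#'   ladder (16 initial filters by default).
#' * `"resunet"`: a compact residual U-Net: residual units (two 3x3
#'   convolutions with batch normalization and a projection shortcut when
#'   the shape changes), stride-2 downsampling, a two-unit bridge, and a
#'   nearest-neighbour upsampling decoder with two residual units per level
#'   (32 initial filters, two downsamplings by default).
#' * `"c_resunet"`: the cell ResUnet; the residual U-Net plus a learned
#'   1x1 "colorspace" convolution that collapses RGB to a single channel
#'   before the encoder, and an extra residual block with 5x5 filters at
#'   the end of the encoding path that widens the receptive field where
#'   clumped cells and large background structures must be resolved.
#'
#' The default filter ladders are frozen so that the trainable parameter
#' totals of the four builders are approximately 14M (unet), 876k
#' (small_unet), 887k (resunet) and 1.7M (c_resunet); see
#' [count_parameters()].
#'
#' @param family one of `"unet"`, `"small_unet"`, `"resunet"`,
#'   `"c_resunet"`.
#' @param initial_filters width of the first encoder level; defaults to the
#'   frozen per-family value (64, 16, 32, 32 respectively).
#' @param depth number of 2x downsamplings; defaults to 3 for the Unet
#'   family and 2 for the ResUnet family.
#' @param use_colorspace_conv logical; prepend the learned 1x1 RGB-to-gray
#'   convolution (default `TRUE` only for `c_resunet`).
#' @param use_5x5_bottleneck logical; append the 5x5 residual block at the
#'   end of the encoder (default `TRUE` only for `c_resunet`).
#' @param batch_norm logical; include batch normalization layers.
#' @return an object of class `architecture_spec`.
#' @export
#' @examples
#' spec <- architecture_spec("c_resunet")
#' spec$initial_filters
architecture_spec <- function(family = c("c_resunet", "resunet", "unet",
                                         "small_unet"),
                              initial_filters = NULL, depth = NULL,
                              use_colorspace_conv = NULL,
                              use_5x5_bottleneck = NULL,
                              batch_norm = TRUE) {
  family <- match.arg(family)
  res_family <- family %in% c("resunet", "c_resunet")
  if (is.null(initial_filters))
    initial_filters <- switch(family, unet = 64L, small_unet = 16L,
                              resunet = 32L, c_resunet = 32L)
  if (is.null(depth)) depth <- if (res_family) 2L else 3L
  if (is.null(use_colorspace_conv)) use_colorspace_conv <- family == "c_resunet"
  if (is.null(use_5x5_bottleneck)) use_5x5_bottleneck <- family == "c_resunet"
  stopifnot(initial_filters >= 1, depth >= 1)
  if (family == "c_resunet" && !(use_colorspace_conv && use_5x5_bottleneck))
    stop("c_resunet requires both the colorspace convolution and the 5x5 ",
         "bottleneck block")
  if (family == "resunet" && (use_colorspace_conv || use_5x5_bottleneck))
    stop("resunet carries neither the colorspace convolution nor the 5x5 ",
         "bottleneck block; use family = 'c_resunet'")
  if (!res_family && (use_colorspace_conv || use_5x5_bottleneck))
    stop("the colorspace convolution and 5x5 bottleneck are ResUnet-family ",
         "additions")
  structure(list(family = family,
                 initial_filters = as.integer(initial_filters),
                 depth = as.integer(depth),
                 use_colorspace_conv = use_colorspace_conv,
                 use_5x5_bottleneck = use_5x5_bottleneck,
                 batch_norm = batch_norm),
            class = "architecture_spec")
}

# conv (+ BN) + ReLU
nn_cbr <- function(g, name, input, co, k = 3L, bn = TRUE) {
  x <- nn_conv(g, paste0(name, "_conv"), input, co, k = k)
  if (bn) x <- nn_bn(g, paste0(name, "_bn"), x)
  nn_relu(g, paste0(name, "_relu"), x)
}

# residual unit: conv-BN-ReLU-conv-BN (+ projection shortcut on shape
# change) -> add -> ReLU
nn_resblock <- function(g, name, input, co, k = 3L, stride = 1L, bn = TRUE) {
  ci <- g$channels[[input]]
  x <- nn_conv(g, paste0(name, "_conv1"), input, co, k = k, stride = stride)
  if (bn) x <- nn_bn(g, paste0(name, "_bn1"), x)
  x <- nn_relu(g, paste0(name, "_relu1"), x)
  x <- nn_conv(g, paste0(name, "_conv2"), x, co, k = k)
  if (bn) x <- nn_bn(g, paste0(name, "_bn2"), x)
  sc <- if (ci != co || stride != 1L)
    nn_conv(g, paste0(name, "_sc"), input, co, k = 1L, stride = stride)
  else input
  x <- nn_add_op(g, paste0(name, "_merge"), c(x, sc))
  nn_relu(g, paste0(name, "_out"), x)
}

build_unet_graph <- function(f, depth, bn) {
  g <- nn_graph_new()
  x <- nn_add(g, "in", "input", out_channels = 3L)
  skips <- character(depth)
  for (i in seq_len(depth)) {
    w <- f * 2^(i - 1)
    for (j in 1:3) x <- nn_cbr(g, sprintf("enc%d_%d", i, j), x, w, bn = bn)
    skips[i] <- x
    x <- nn_maxpool(g, sprintf("pool%d", i), x)
  }
  wb <- f * 2^depth
  for (j in 1:4) x <- nn_cbr(g, sprintf("bott_%d", j), x, wb, bn = bn)
  for (i in rev(seq_len(depth))) {
    w <- f * 2^(i - 1)
    x <- nn_tconv(g, sprintf("up%d", i), x, w, bias = FALSE)
    x <- nn_concat(g, sprintf("cat%d", i), c(x, skips[i]))
    for (j in 1:3) x <- nn_cbr(g, sprintf("dec%d_%d", i, j), x, w, bn = bn)
  }
  x <- nn_conv(g, "head", x, 1L, k = 1L, gain = 1)
  nn_sigmoid(g, "out", x)
  g
}

build_resunet_graph <- function(f, depth, colorspace, bott5, bn) {
  g <- nn_graph_new()
  x <- nn_add(g, "in", "input", out_channels = 3L)
  if (colorspace) x <- nn_conv(g, "colorspace", x, 1L, k = 1L, gain = 1)
  x <- nn_resblock(g, "stem", x, f, bn = bn)
  skips <- character(depth)
  skips[1] <- x
  if (depth > 1) {
    for (i in seq_len(depth - 1)) {
      x <- nn_resblock(g, sprintf("enc%d", i), x, f * 2^i, stride = 2L,
                       bn = bn)
      skips[i + 1] <- x
    }
  }
  wb <- f * 2^depth
  x <- nn_resblock(g, "bridge1", x, wb, stride = 2L, bn = bn)
  x <- nn_resblock(g, "bridge2", x, wb, bn = bn)
  if (bott5) x <- nn_resblock(g, "bridge5x5", x, wb, k = 5L, bn = bn)
  for (i in rev(seq_len(depth))) {
    w <- f * 2^(i - 1)
    x <- nn_upsample(g, sprintf("up%d", i), x)
    x <- nn_concat(g, sprintf("cat%d", i), c(x, skips[i]))
    x <- nn_resblock(g, sprintf("dec%da", i), x, w, bn = bn)
    x <- nn_resblock(g, sprintf("dec%db", i), x, w, bn = bn)
  }
  x <- nn_conv(g, "head", x, 1L, k = 1L, gain = 1)
  nn_sigmoid(g, "out", x)
  g
}

#' Build a segmentation model from an architecture specification
#'
#' Instantiates the network graph and its weights (He-normal
#' initialization).  The resulting model maps an RGB raster of shape
#' `H x W x 3` (values in `[0, 1]`, spatial dims divisible by
#' `2^spec$depth`) to a per-pixel cell-probability heatmap of the same
#' spatial shape, bounded in `[0, 1]` by a sigmoid head.
#'
#' @param spec an [architecture_spec()].
#' @param init_seed integer seed for the weight initialization.
#' @return an object of class `segmentation_model`.
#' @export
#' @examples
#' m <- build_model(architecture_spec("resunet", initial_filters = 4,
#'                                    depth = 1))
#' count_parameters(m)
build_model <- function(spec, init_seed = 1L) {
  stopifnot(inherits(spec, "architecture_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(init_seed)
  g <- if (spec$family %in% c("unet", "small_unet"))
    build_unet_graph(spec$initial_filters, spec$depth, spec$batch_norm)
  else
    build_resunet_graph(spec$initial_filters, spec$depth,
                        spec$use_colorspace_conv, spec$use_5x5_bottleneck,
                        spec$batch_norm)
  bn_stats <- list()
  for (ly in g$layers)
    if (ly$op == "bn") {
      nc <- length(ly$params$gamma)
      bn_stats[[ly$name]] <- list(mean = numeric(nc), var = rep(1, nc))
    }
  structure(list(spec = spec, layers = g$layers, bn_stats = bn_stats),
            class = "segmentation_model")
}

#' Count trainable parameters of a model
#'
#' Counts every trainable scalar: convolution and transposed-convolution
#' kernels and biases, and batch-normalization scale/offset pairs (running
#' statistics are not trainable and are excluded).
#'
#' @param model a [build_model()] result.
#' @return integer count.
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "segmentation_model"))
  sum(vapply(model$layers,
             function(ly) sum(vapply(ly$params, length, numeric(1))),
             numeric(1)))
}

#' @export
print.segmentation_model <- function(x, ...) {
  cat(sprintf("<segmentation_model %s: %d layers, %s trainable parameters>\n",
              x$spec$family, length(x$layers),
              format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Predict a cell-probability heatmap for one image
#'
#' Runs the network in inference mode.  Images whose spatial dimensions are
#' not divisible by `2^depth` are reflect-padded to the next multiple and
#' the heatmap is cropped back, so any size is accepted.
#'
#' @param model a trained [build_model()] result.
#' @param image `H x W x 3` array in `[0, 1]` (a grayscale matrix is
#'   replicated across channels).
#' @return `H x W` matrix of cell probabilities in `[0, 1]`.
#' @export
predict_heatmap <- function(model, image) {
  if (is.matrix(image)) image <- array(rep(image, 3), dim = c(dim(image), 3))
  stopifnot(length(dim(image)) == 3, dim(image)[3] == 3)
  d <- dim(image)
  div <- 2^model$spec$depth
  Hp <- ceiling(d[1] / div) * div
  Wp <- ceiling(d[2] / div) * div
  if (Hp != d[1] || Wp != d[2]) {
    ri <- c(seq_len(d[1]), rev(seq_len(d[1])))[seq_len(Hp)]
    ci <- c(seq_len(d[2]), rev(seq_len(d[2])))[seq_len(Wp)]
    image <- image[ri, ci, , drop = FALSE]
  }
  out <- nn_forward(model, image, training = FALSE)$out
  out <- out[seq_len(d[1]), seq_len(d[2]), 1, 1]
  matrix(out, d[1], d[2])
}

#' Extract or restore model weights
#'
#' `get_weights()` returns all parameters plus batch-normalization running
#' statistics; `set_weights()` writes them back.  `save_checkpoint()` and
#' `load_checkpoint()` serialize a model to a single file.
#'
#' @param model a `segmentation_model`.
#' @return `get_weights()`: a named list; `set_weights()`: the model.
#' @export
get_weights <- function(model) {
  w <- list()
  for (key in nn_param_names(model)) w[[key]] <- nn_get_param(model, key)
  list(params = w, bn_stats = model$bn_stats)
}

#' @rdname get_weights
#' @param weights a `get_weights()` result.
#' @export
set_weights <- function(model, weights) {
  for (key in names(weights$params))
    model <- nn_set_param(model, key, weights$params[[key]])
  model$bn_stats <- weights$bn_stats
  model
}

#' @rdname get_weights
#' @param path file path for the checkpoint (`.rds`).
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(spec = unclass(model$spec), weights = get_weights(model)),
          path)
  invisible(path)
}

#' @rdname get_weights
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  spec <- do.call(architecture_spec, ck$spec[c("family", "initial_filters",
                                               "depth", "use_colorspace_conv",
                                               "use_5x5_bottleneck",
                                               "batch_norm")])
  set_weights(build_model(spec), ck$weights)
}
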