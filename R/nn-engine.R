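#' @useDynLib cellcount, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# ---------------------------------------------------------------------------
# Minimal computational-graph engine for the segmentation networks.
#
# A model is a list of layers in topological order.  Each layer is a list
# with fields: name, op, inputs (names of producer layers), cfg, params.
# Activations are dense arrays (H, W, C, N).  The engine implements exactly
# the operations the four architectures need: convolution ("same" padding,
# stride 1 or 2), 2x2 transposed convolution, 2x2 max pooling, nearest
# neighbour x2 upsampling, batch normalization, ReLU/sigmoid, channel
# concatenation and element-wise addition.
# ---------------------------------------------------------------------------

nn_graph_new <- function() {
  g <- new.env(parent = emptyenv())
  g$layers <- list()
  g$channels <- list()
  g
}

nn_add <- function(g, name, op, inputs = character(), cfg = list(),
                   params = list(), out_channels = NULL) {
  if (is.null(out_channels) && length(inputs))
    out_channels <- g$channels[[inputs[[1L]]]]
  g$layers[[name]] <- list(name = name, op = op, inputs = inputs,
                           cfg = cfg, params = params)
  g$channels[[name]] <- out_channels
  name
}

nn_he_init <- function(k, ci, co, gain = 2) {
  array(stats::rnorm(k * k * ci * co, sd = sqrt(gain / (k * k * ci))),
        dim = c(k, k, ci, co))
}

nn_conv <- function(g, name, input, co, k = 3L, stride = 1L, bias = TRUE,
                    gain = 2) {
  ci <- g$channels[[input]]
  params <- list(w = nn_he_init(k, ci, co, gain))
  if (bias) params$b <- numeric(co)
  nn_add(g, name, "conv", input,
         cfg = list(k = k, stride = stride, bias = bias),
         params = params, out_channels = co)
}

nn_tconv <- function(g, name, input, co, bias = TRUE) {
  ci <- g$channels[[input]]
  params <- list(w = array(stats::rnorm(4 * ci * co, sd = sqrt(2 / (4 * ci))),
                           dim = c(2, 2, ci, co)))
  if (bias) params$b <- numeric(co)
  nn_add(g, name, "tconv", input, cfg = list(bias = bias),
         params = params, out_channels = co)
}

nn_bn <- function(g, name, input) {
  c0 <- g$channels[[input]]
  nn_add(g, name, "bn", input,
         params = list(gamma = rep(1, c0), beta = numeric(c0)),
         cfg = list(eps = 1e-5, momentum = 0.9),
         out_channels = c0)
}

nn_relu <- function(g, name, input) nn_add(g, name, "relu", input)
nn_sigmoid <- function(g, name, input) nn_add(g, name, "sigmoid", input)
nn_maxpool <- function(g, name, input) nn_add(g, name, "maxpool", input)
nn_upsample <- function(g, name, input) nn_add(g, name, "upsample", input)

nn_concat <- function(g, name, inputs) {
  co <- sum(vapply(inputs, function(i) as.integer(g$channels[[i]]),
                   integer(1)))
  nn_add(g, name, "concat", inputs, out_channels = co)
}

nn_add_op <- function(g, name, inputs) nn_add(g, name, "add", inputs)

nn_as_batch <- function(x) {
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L, 1L)
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  x
}

# Forward pass ----------------------------------------------------------------

nn_forward <- function(model, x, training = FALSE, keep_cache = training) {
  x <- nn_as_batch(x)
  layers <- model$layers
  nms <- names(layers)
  cache <- new.env(parent = emptyenv())
  # last index at which each layer's output is still needed
  last_use <- structure(seq_along(layers), names = nms)
  for (i in seq_along(layers))
    for (inp in layers[[i]]$inputs) last_use[[inp]] <- i

  out <- NULL
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    ins <- lapply(ly$inputs, function(nm) cache[[nm]]$out)
    res <- switch(ly$op,
      input = list(out = x),
      conv = {
        xi <- ins[[1]]
        if (ly$cfg$stride > 1L && any(dim(xi)[1:2] %% ly$cfg$stride != 0))
          stop("spatial dimensions not divisible by the network stride; ",
               "pad the input to a multiple of 2^depth")
        b <- if (ly$cfg$bias) ly$params$b else numeric(0)
        list(out = .conv2d_fwd(xi, dim(xi), ly$params$w, dim(ly$params$w),
                               b, ly$cfg$stride))
      },
      tconv = {
        xi <- ins[[1]]
        b <- if (ly$cfg$bias) ly$params$b else numeric(0)
        list(out = .tconv2_fwd(xi, dim(xi), ly$params$w, dim(ly$params$w), b))
      },
      maxpool = {
        xi <- ins[[1]]
        if (any(dim(xi)[1:2] %% 2L != 0))
          stop("spatial dimensions not divisible by the network stride; ",
               "pad the input to a multiple of 2^depth")
        r <- .maxpool2_fwd(xi, dim(xi))
        list(out = r$y, idx = r$idx, xdim = dim(xi))
      },
      upsample = {
        xi <- ins[[1]]
        d <- dim(xi)
        list(out = xi[rep(seq_len(d[1]), each = 2),
                      rep(seq_len(d[2]), each = 2), , , drop = FALSE])
      },
      bn = {
        xi <- ins[[1]]
        st <- .bn_fwd(xi, dim(xi), ly$params$gamma, ly$params$beta,
                      ly$cfg$eps, training,
                      model$bn_stats[[ly$name]]$mean,
                      model$bn_stats[[ly$name]]$var)
        if (training) {
          mom <- ly$cfg$momentum
          s <- model$bn_stats[[ly$name]]
          model$bn_stats[[ly$name]] <- list(
            mean = mom * s$mean + (1 - mom) * st$mu,
            var = mom * s$var + (1 - mom) * st$v)
        }
        list(out = st$y, xhat = st$xhat, sdv = st$sdv)
      },
      relu = list(out = pmax(ins[[1]], 0)),
      sigmoid = list(out = 1 / (1 + exp(-ins[[1]]))),
      concat = {
        d1 <- dim(ins[[1]])
        cs <- vapply(ins, function(a) dim(a)[3], numeric(1))
        y <- array(0, dim = c(d1[1], d1[2], sum(cs), d1[4]))
        at <- 0L
        for (a in ins) {
          y[, , at + seq_len(dim(a)[3]), ] <- a
          at <- at + dim(a)[3]
        }
        list(out = y)
      },
      add = list(out = ins[[1]] + ins[[2]]),
      stop("unknown op: ", ly$op))
    cache[[ly$name]] <- res
    out <- res$out
    if (!keep_cache) {
      for (nm in nms[seq_len(i)])
        if (last_use[[nm]] <= i && nm != ly$name)
          if (!is.null(cache[[nm]])) cache[[nm]]$out <- NULL
    }
  }
  list(out = out, cache = cache, model = model)
}

# Backward pass ---------------------------------------------------------------
#
# `g_at` allows injecting the loss gradient at a layer upstream of the
# output (used to fuse the sigmoid with the cross-entropy for numerical
# stability); layers after `g_at` are skipped.

nn_backward <- function(model, cache, g_at, g) {
  layers <- model$layers
  nms <- names(layers)
  grads_out <- new.env(parent = emptyenv())
  grads_out[[g_at]] <- g
  pgrads <- list()
  start <- match(g_at, nms)
  for (i in seq(start, 1L)) {
    ly <- layers[[i]]
    gy <- grads_out[[ly$name]]
    if (is.null(gy)) next
    res <- cache[[ly$name]]
    ins <- ly$inputs
    push <- function(nm, val) {
      cur <- grads_out[[nm]]
      grads_out[[nm]] <- if (is.null(cur)) val else cur + val
    }
    switch(ly$op,
      input = NULL,
      conv = {
        xi <- cache[[ins[[1]]]]$out
        bw <- .conv2d_bwd(xi, dim(xi), ly$params$w, dim(ly$params$w),
                          gy, ly$cfg$stride, ly$cfg$bias)
        pg <- list(w = bw$gw)
        if (ly$cfg$bias) pg$b <- bw$gb
        pgrads[[ly$name]] <- pg
        push(ins[[1]], bw$gx)
      },
      tconv = {
        xi <- cache[[ins[[1]]]]$out
        bw <- .tconv2_bwd(xi, dim(xi), ly$params$w, dim(ly$params$w),
                          gy, ly$cfg$bias)
        pg <- list(w = bw$gw)
        if (ly$cfg$bias) pg$b <- bw$gb
        pgrads[[ly$name]] <- pg
        push(ins[[1]], bw$gx)
      },
      maxpool = push(ins[[1]], .maxpool2_bwd(gy, res$idx, res$xdim)),
      upsample = {
        d <- dim(gy)
        io <- seq(1L, d[1], by = 2L)
        jo <- seq(1L, d[2], by = 2L)
        gx <- gy[io, jo, , , drop = FALSE] +
          gy[io + 1L, jo, , , drop = FALSE] +
          gy[io, jo + 1L, , , drop = FALSE] +
          gy[io + 1L, jo + 1L, , , drop = FALSE]
        push(ins[[1]], gx)
      },
      bn = {
        bw <- .bn_bwd(gy, dim(gy), res$xhat, res$sdv, ly$params$gamma)
        pgrads[[ly$name]] <- list(gamma = bw$ggamma, beta = bw$gbeta)
        push(ins[[1]], bw$gx)
      },
      relu = push(ins[[1]], gy * (res$out > 0)),
      sigmoid = push(ins[[1]], gy * res$out * (1 - res$out)),
      concat = {
        at <- 0L
        for (nm in ins) {
          ca <- dim(cache[[nm]]$out)[3]
          push(nm, gy[, , at + seq_len(ca), , drop = FALSE])
          at <- at + ca
        }
      },
      add = {
        push(ins[[1]], gy)
        push(ins[[2]], gy)
      })
    grads_out[[ly$name]] <- NULL
  }
  pgrads
}

# Weight access ---------------------------------------------------------------

nn_param_names <- function(model) {
  out <- character(0)
  for (ly in model$layers)
    for (p in names(ly$params)) out <- c(out, paste(ly$name, p, sep = "."))
  out
}

nn_get_param <- function(model, key) {
  parts <- strsplit(key, ".", fixed = TRUE)[[1]]
  model$layers[[parts[1]]]$params[[parts[2]]]
}

nn_set_param <- function(model, key, value) {
  parts <- strsplit(key, ".", fixed = TRUE)[[1]]
  model$layers[[parts[1]]]$params[[parts[2]]] <- value
  model
}

# Adam ------------------------------------------------------------------------

nn_adam_new <- function(model) {
  st <- list(t = 0L, m = list(), v = list())
  for (key in nn_param_names(model)) {
    p <- nn_get_param(model, key)
    st$m[[key]] <- array(0, dim = dim(p) %||% length(p))
    st$v[[key]] <- st$m[[key]]
  }
  st
}

nn_adam_step <- function(model, grads, st, lr,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-7) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  for (lname in names(grads)) {
    for (pn in names(grads[[lname]])) {
      key <- paste(lname, pn, sep = ".")
      gr <- grads[[lname]][[pn]]
      st$m[[key]] <- beta1 * st$m[[key]] + (1 - beta1) * gr
      st$v[[key]] <- beta2 * st$v[[key]] + (1 - beta2) * gr * gr
      mhat <- st$m[[key]] / bc1
      vhat <- st$v[[key]] / bc2
      p <- nn_get_param(model, key) - lr * mhat / (sqrt(vhat) + eps)
      model <- nn_set_param(model, key, p)
    }
  }
  list(model = model, state = st)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
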