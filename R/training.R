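#' Training configuration
#'
#' Reproduces the optimization protocol used for all four architectures:
#' Adam with an initial learning rate of 0.006, a 30% learning-rate decay
#' whenever the validation loss fails to improve for four consecutive
#' epochs, early stopping after twenty stale epochs, and the weighted
#' binary cross-entropy loss with class weights 1 (cell) and 1.5
#' (background) on top of the border weight maps.
#'
#' @param initial_lr initial learning rate (default 0.006).
#' @param lr_decay_factor multiplicative decay per stale window (default
#'   0.7, i.e. a 30% decrease).
#' @param lr_patience epochs without improvement before a decay (default 4).
#' @param stop_patience epochs without improvement before stopping
#'   (default 20).
#' @param batch_size minibatch size (default 8).
#' @param max_epochs hard epoch cap.
#' @param seed integer seed for shuffling.
#' @param class_weights a [class_weights()].
#' @return an object of class `train_config`.
#' @export
train_config <- function(initial_lr = 0.006, lr_decay_factor = 0.7,
                         lr_patience = 4L, stop_patience = 20L,
                         batch_size = 8L, max_epochs = 100L, seed = 1L,
                         class_weights = cellcount::class_weights()) {
  stopifnot(initial_lr > 0, lr_decay_factor > 0, lr_decay_factor < 1,
            lr_patience >= 1, stop_patience >= 1, batch_size >= 1,
            max_epochs >= 1)
  structure(list(initial_lr = initial_lr,
                 lr_decay_factor = lr_decay_factor,
                 lr_patience = as.integer(lr_patience),
                 stop_patience = as.integer(stop_patience),
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 seed = as.integer(seed),
                 class_weights = class_weights),
            class = "train_config")
}

#' Plateau learning-rate schedule
#'
#' Given the validation losses of the completed epochs, returns the current
#' learning rate `initial_lr * lr_decay_factor^k`, where `k` counts the
#' completed no-improvement windows of `lr_patience` epochs.  "Improvement"
#' means strictly lower than the best value seen so far; the stale counter
#' resets on improvement and after each decay.
#'
#' @param history numeric vector of per-epoch validation losses.
#' @param cfg a [train_config()].
#' @return the learning rate for the next epoch.
#' @export
#' @examples
#' schedule_lr(c(1, 0.9, 0.8), train_config())       # 0.006
#' schedule_lr(rep(1, 5), train_config())            # 0.0042
schedule_lr <- function(history, cfg = train_config()) {
  stopifnot(length(history) >= 1)
  best <- Inf
  stale <- 0L
  k <- 0L
  for (loss in history) {
    if (loss < best) {
      best <- loss
      stale <- 0L
    } else {
      stale <- stale + 1L
      if (stale == cfg$lr_patience) {
        k <- k + 1L
        stale <- 0L
      }
    }
  }
  cfg$initial_lr * cfg$lr_decay_factor^k
}

# stack a list of samples (image, mask, wmap) into batch arrays
assemble_batch <- function(samples) {
  h <- dim(samples[[1]]$image)[1]
  w <- dim(samples[[1]]$image)[2]
  n <- length(samples)
  x <- array(0, dim = c(h, w, 3, n))
  t <- array(0, dim = c(h, w, 1, n))
  wm <- array(0, dim = c(h, w, 1, n))
  for (i in seq_len(n)) {
    s <- samples[[i]]
    img <- s$image
    if (is.matrix(img)) img <- array(rep(img, 3), dim = c(h, w, 3))
    x[, , , i] <- img
    t[, , 1, i] <- s$mask
    if (!is.null(s$wmap)) wm[, , 1, i] <- s$wmap
  }
  list(x = x, t = t, wm = wm)
}

eval_loss <- function(model, stream, cfg) {
  tot <- 0
  npix <- 0
  for (i in seq(1, length(stream), by = cfg$batch_size)) {
    idx <- i:min(i + cfg$batch_size - 1L, length(stream))
    b <- assemble_batch(stream[idx])
    p <- nn_forward(model, b$x, training = FALSE)$out
    l <- wbce_with_grad(b$t, p, b$wm, cfg$class_weights)$loss
    tot <- tot + l * length(b$t)
    npix <- npix + length(b$t)
  }
  tot / npix
}

#' Train a segmentation model
#'
#' Minimizes the weighted binary cross-entropy with Adam, monitoring the
#' validation loss for the plateau learning-rate schedule
#' ([schedule_lr()]) and for early stopping, and keeping the weights of the
#' best validation epoch.
#'
#' @param model a [build_model()] result.
#' @param train_stream,val_stream non-empty lists of samples; each sample
#'   is a list with `image` (`H x W x 3` in `[0, 1]`), `mask` (binary
#'   `H x W`) and optionally `wmap` (border weight map).
#' @param cfg a [train_config()].
#' @return list with `model` (weights of the best epoch), `history`
#'   (data frame: epoch, lr, train_loss, val_loss) and `best_epoch`.
#' @export
train_model <- function(model, train_stream, val_stream,
                        cfg = train_config()) {
  if (length(train_stream) == 0 || length(val_stream) == 0)
    stop("empty sample stream")
  adam <- nn_adam_new(model)
  history <- data.frame(epoch = integer(0), lr = numeric(0),
                        train_loss = numeric(0), val_loss = numeric(0))
  best_loss <- Inf
  best_epoch <- 0L
  best_weights <- NULL
  stale <- 0L
  for (epoch in seq_len(cfg$max_epochs)) {
    lr <- if (nrow(history) == 0) cfg$initial_lr
    else schedule_lr(history$val_loss, cfg)
    ord <- with_seed(cfg$seed + epoch, sample(length(train_stream)))
    ep_loss <- 0
    ep_n <- 0
    for (i in seq(1, length(ord), by = cfg$batch_size)) {
      idx <- ord[i:min(i + cfg$batch_size - 1L, length(ord))]
      b <- assemble_batch(train_stream[idx])
      fw <- nn_forward(model, b$x, training = TRUE)
      model <- fw$model  # batch-norm running statistics
      lg <- wbce_with_grad(b$t, fw$out, b$wm, cfg$class_weights)
      grads <- nn_backward(model, fw$cache, "head", lg$glogit)
      st <- nn_adam_step(model, grads, adam, lr)
      model <- st$model
      adam <- st$state
      ep_loss <- ep_loss + lg$loss * length(idx)
      ep_n <- ep_n + length(idx)
    }
    val_loss <- eval_loss(model, val_stream, cfg)
    history <- rbind(history,
                     data.frame(epoch = epoch, lr = lr,
                                train_loss = ep_loss / ep_n,
                                val_loss = val_loss))
    if (val_loss < best_loss) {
      best_loss <- val_loss
      best_epoch <- epoch
      best_weights <- get_weights(model)
      stale <- 0L
    } else {
      stale <- stale + 1L
      if (stale >= cfg$stop_patience) break
    }
  }
  if (!is.null(best_weights)) model <- set_weights(model, best_weights)
  list(model = model, history = history, best_epoch = best_epoch)
}
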