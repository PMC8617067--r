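#' Parameters of the border-penalty weight map
#'
#' The weight map penalizes segmentation errors on background pixels near
#' cell borders.  Each cell contributes a Gaussian decay
#' `g(d) = w0 * exp(-d^2 / (2 * sigma^2))` of its border distance `d`, and
#' contributions from different cells are compounded additively, so the map
#' is highest in the narrow background corridors between close-by cells.
#'
#' @param w0 peak amplitude of a single cell's contribution at its border
#'   (dimensionless, default 10).
#' @param sigma decay length in pixels (default 25, half the average cell
#'   diameter).
#' @param max_radius cutoff in pixels beyond which a cell contributes
#'   nothing (default `3 * sigma`, where the Gaussian tail is below 1.2%).
#' @return an object of class `weight_map_params`.
#' @export
weight_map_params <- function(w0 = 10, sigma = 25, max_radius = 3 * sigma) {
  stopifnot(w0 >= 0, sigma > 0, max_radius >= sigma)
  structure(list(w0 = w0, sigma = sigma, max_radius = max_radius),
            class = "weight_map_params")
}

#' Class weights of the segmentation loss
#'
#' @param cell weight of cell pixels (default 1.0).
#' @param background weight of background pixels (default 1.5).
#' @return an object of class `class_weights`.
#' @export
class_weights <- function(cell = 1, background = 1.5) {
  stopifnot(cell > 0, background > 0)
  structure(list(cell = cell, background = background),
            class = "class_weights")
}

check_binary_mask <- function(mask) {
  if (!all(mask %in% c(0, 1)))
    stop("mask must be binary (values 0/1)")
  invisible(mask)
}

#' Euclidean distance to one cell's border
#'
#' For every pixel, the Euclidean distance (in pixels) to the nearest pixel
#' of the connected component labelled `cell_id`; zero on that cell's own
#' pixels.
#'
#' @param mask binary matrix (1 = cell).
#' @param cell_id positive integer label of a connected component of `mask`
#'   (labels as assigned by [label_components()], 8-connectivity).
#' @return numeric matrix of distances.
#' @export
cell_border_distance <- function(mask, cell_id) {
  check_binary_mask(mask)
  labels <- label_components(mask)
  if (!(cell_id %in% labels))
    stop("cell_id ", cell_id, " does not label any component of the mask")
  cell <- labels == cell_id
  d <- EBImage::distmap(1 - cell, metric = "euclidean")
  matrix(as.numeric(d), nrow(mask), ncol(mask))
}

#' Build the additive border-penalty weight map of a mask
#'
#' For each background pixel `x`, sums `kernel(d_i(x))` over every cell `i`
#' whose border distance `d_i(x)` is within `max_radius`; cell pixels carry
#' weight zero (they are weighted through the class weights only).  Because
#' single-cell contributions add, the map takes higher values where several
#' cells crowd together than next to an isolated cell at the same distance.
#'
#' @param mask binary matrix (1 = cell).
#' @param params a [weight_map_params()].
#' @param kernel optional replacement decay function of the distance vector;
#'   defaults to the Gaussian `w0 * exp(-d^2 / (2 * sigma^2))`.
#' @return nonnegative numeric matrix, zero on cell pixels.
#' @export
#' @examples
#' mask <- matrix(0L, 32, 32)
#' mask[8:12, 8:12] <- 1L
#' wm <- build_weight_map(mask, weight_map_params(sigma = 5))
#' max(wm)
build_weight_map <- function(mask, params = weight_map_params(),
                             kernel = NULL) {
  check_binary_mask(mask)
  if (is.null(kernel))
    kernel <- function(d) params$w0 * exp(-d^2 / (2 * params$sigma^2))
  labels <- label_components(mask)
  n <- max(labels)
  wm <- matrix(0, nrow(mask), ncol(mask))
  if (n > 0) {
    pad <- ceiling(params$max_radius) + 1L
    for (id in seq_len(n)) {
      px <- which(labels == id, arr.ind = TRUE)
      r0 <- max(1L, min(px[, 1]) - pad)
      r1 <- min(nrow(mask), max(px[, 1]) + pad)
      c0 <- max(1L, min(px[, 2]) - pad)
      c1 <- min(ncol(mask), max(px[, 2]) + pad)
      sub <- labels[r0:r1, c0:c1, drop = FALSE] == id
      d <- matrix(as.numeric(EBImage::distmap(1 - sub, "euclidean")),
                  nrow(sub), ncol(sub))
      gg <- kernel(d)
      gg[d > params$max_radius] <- 0
      wm[r0:r1, c0:c1] <- wm[r0:r1, c0:c1] + gg
    }
    wm[mask == 1] <- 0
  }
  wm
}

#' Weighted binary cross-entropy loss
#'
#' Mean over pixels of `omega(x) * BCE(x)` where
#' `omega(x) = class_weight(x) * (1 + wmap(x))`.  With a zero weight map and
#' unit class weights this reduces to the plain binary cross-entropy; the
#' `(1 + wmap)` composition guarantees that limit.
#'
#' @param target binary mask (array or matrix).
#' @param prediction probabilities in `[0, 1]`, same shape as `target`
#'   (clipped internally to `[1e-7, 1 - 1e-7]`).
#' @param wmap border weight map, same shape (`NULL` for none).
#' @param cw a [class_weights()].
#' @return scalar loss (nonnegative, finite).
#' @export
weighted_bce <- function(target, prediction, wmap = NULL,
                         cw = class_weights()) {
  if (!all(dim(target) == dim(prediction)))
    stop("target and prediction shapes differ")
  if (!is.null(wmap) && !all(dim(wmap) == dim(target)))
    stop("weight map shape differs from target")
  check_binary_mask(target)
  stopifnot(min(prediction) >= 0, max(prediction) <= 1)
  eps <- 1e-7
  p <- pmin(pmax(prediction, eps), 1 - eps)
  omega <- ifelse(target == 1, cw$cell, cw$background)
  if (!is.null(wmap)) omega <- omega * (1 + wmap)
  mean(-omega * (target * log(p) + (1 - target) * log(1 - p)))
}

# loss + gradient wrt the (pre-clipping) sigmoid output, fused for the
# training loop; M normalizes over all pixels in the batch
wbce_with_grad <- function(target, prediction, wmap, cw) {
  eps <- 1e-7
  p <- pmin(pmax(prediction, eps), 1 - eps)
  omega <- ifelse(target == 1, cw$cell, cw$background)
  if (!is.null(wmap)) omega <- omega * (1 + wmap)
  loss <- mean(-omega * (target * log(p) + (1 - target) * log(1 - p)))
  # gradient wrt the pre-sigmoid logits (sigmoid fused analytically)
  glogit <- omega * (p - target) / length(p)
  list(loss = loss, glogit = glogit)
}
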