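#' Post-processing configuration
#'
#' Controls the conversion of a probability heatmap into counted cell
#' instances: binarization threshold, speck removal, hole filling, and the
#' watershed split of touching cells, whose marker spacing is driven by the
#' average cell diameter.
#'
#' @param threshold probability cutoff in (0, 1) (default 0.875, the
#'   knee-selected operating point of the cell ResUnet).
#' @param min_area components smaller than this area (px^2) are removed
#'   (default 100, about 1/20 of a 50 px diameter cell).
#' @param fill_holes fill interior holes of the detected cells.
#' @param avg_cell_diameter average cell diameter in px (default 50).
#' @return an object of class `postproc_config`.
#' @export
postproc_config <- function(threshold = 0.875, min_area = 100,
                            fill_holes = TRUE, avg_cell_diameter = 50) {
  stopifnot(threshold > 0, threshold < 1, min_area >= 0,
            avg_cell_diameter > 0)
  structure(list(threshold = threshold, min_area = min_area,
                 fill_holes = fill_holes,
                 avg_cell_diameter = avg_cell_diameter),
            class = "postproc_config")
}

#' Threshold a heatmap into a binary mask
#'
#' A pixel becomes a cell pixel iff its probability is greater than or
#' equal to the threshold (ties count as cells, fixed for determinism).
#'
#' @param heatmap matrix of probabilities in `[0, 1]`.
#' @param threshold cutoff in (0, 1).
#' @return binary integer matrix.
#' @export
binarize <- function(heatmap, threshold = 0.875) {
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must lie strictly inside (0, 1)")
  stopifnot(min(heatmap) >= 0, max(heatmap) <= 1)
  m <- matrix(0L, nrow(heatmap), ncol(heatmap))
  m[heatmap >= threshold] <- 1L
  m
}

#' Remove specks and fill holes in a binary mask
#'
#' Deletes connected components (8-connectivity) smaller than
#' `cfg$min_area` and, if `cfg$fill_holes`, fills interior holes of the
#' surviving components.
#'
#' @param mask binary matrix.
#' @param cfg a [postproc_config()].
#' @return binary integer matrix.
#' @export
clean_mask <- function(mask, cfg = postproc_config()) {
  check_binary_mask(mask)
  labels <- label_components(mask)
  n <- max(labels)
  if (n == 0) return(matrix(0L, nrow(mask), ncol(mask)))
  areas <- tabulate(labels[labels > 0], nbins = n)
  keep <- areas >= cfg$min_area
  out <- matrix(0L, nrow(mask), ncol(mask))
  sel <- labels > 0
  out[sel][keep[labels[sel]]] <- 1L
  if (cfg$fill_holes)
    out <- matrix(as.integer(EBImage::fillHull(out)), nrow(out), ncol(out))
  out
}

#' Split touching cells with a distance-transform watershed
#'
#' Computes the Euclidean distance transform of the mask, smooths it
#' lightly, and runs a watershed whose neighbourhood radius for marker
#' (local maximum) detection is half the average cell diameter, so maxima
#' closer than that merge into one marker.  The foreground pixel set is
#' preserved exactly; each foreground pixel receives exactly one label.
#'
#' @param mask cleaned binary matrix.
#' @param cfg a [postproc_config()].
#' @return integer label matrix (0 background, labels contiguous from 1).
#' @export
split_touching <- function(mask, cfg = postproc_config()) {
  check_binary_mask(mask)
  if (!any(mask == 1)) return(matrix(0L, nrow(mask), ncol(mask)))
  d <- EBImage::distmap(mask, metric = "euclidean")
  sm <- as.matrix(EBImage::gblur(d, sigma = max(1, cfg$avg_cell_diameter / 25)))
  sm[mask == 0] <- 0
  sel <- mask == 1
  sm[sel] <- pmax(sm[sel], 1e-6)
  ws <- EBImage::watershed(EBImage::as.Image(sm), tolerance = 1,
                           ext = max(1L, as.integer(round(
                             cfg$avg_cell_diameter / 2))))
  lab <- matrix(as.integer(ws), nrow(mask), ncol(mask))
  relabel_contiguous(lab)
}

relabel_contiguous <- function(lab) {
  u <- sort(unique(lab[lab > 0]))
  if (length(u) == 0 || identical(u, seq_along(u))) return(lab)
  map <- integer(max(u))
  map[u] <- seq_along(u)
  lab[lab > 0] <- map[lab[lab > 0]]
  lab
}

#' Label the connected components of a binary mask
#'
#' 8-connectivity (diagonally touching pixels belong to the same
#' component); labels are contiguous from 1.
#'
#' @param mask binary matrix.
#' @return integer label matrix.
#' @export
label_components <- function(mask) {
  check_binary_mask(mask)
  storage.mode(mask) <- "integer"
  .label8(mask)
}

#' Count instances in a labeled mask
#'
#' @param labeled integer label matrix (0 = background).
#' @return list with `count` (number of instances) and `instances`
#'   (data frame: `label`, centroid `row`/`col`, `area`).
#' @export
count_cells <- function(labeled) {
  n <- max(labeled)
  if (n == 0)
    return(list(count = 0L,
                instances = data.frame(label = integer(0), row = numeric(0),
                                       col = numeric(0), area = integer(0))))
  idx <- which(labeled > 0, arr.ind = TRUE)
  lab <- labeled[labeled > 0]
  inst <- data.frame(
    label = seq_len(n),
    row = as.numeric(tapply(idx[, 1], lab, mean)),
    col = as.numeric(tapply(idx[, 2], lab, mean)),
    area = as.integer(tabulate(lab, nbins = n)))
  list(count = as.integer(n), instances = inst)
}

#' Full heatmap-to-counts post-processing pipeline
#'
#' Binarize, clean, watershed-split and count, in that order.
#'
#' @param heatmap probability matrix in `[0, 1]`.
#' @param cfg a [postproc_config()].
#' @return list with `labels` (instance label matrix), `count` and
#'   `instances` (see [count_cells()]).
#' @export
postprocess_heatmap <- function(heatmap, cfg = postproc_config()) {
  m <- binarize(heatmap, cfg$threshold)
  m <- clean_mask(m, cfg)
  lab <- split_touching(m, cfg)
  c(list(labels = lab), count_cells(lab))
}
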