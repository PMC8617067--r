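#' Dataset split configuration
#'
#' @param n_test number of full-size images held out as the test set
#'   (default 70).
#' @param val_fraction fraction of the remaining images assigned to
#'   validation (default 0.3).
#' @param seed integer seed of the shuffle.
#' @return an object of class `split_config`.
#' @export
split_config <- function(n_test = 70L, val_fraction = 0.3, seed = 1L) {
  stopifnot(n_test >= 0, val_fraction > 0, val_fraction < 1)
  structure(list(n_test = as.integer(n_test), val_fraction = val_fraction,
                 seed = as.integer(seed)),
            class = "split_config")
}

#' Augmentation configuration
#'
#' Controls the augmentation pipeline: random rotation, elastic deformation
#' (random displacement fields smoothed with a Gaussian), multiplicative
#' brightness variation and additive Gaussian noise.  Geometric transforms
#' are applied identically to image, mask and weight map; photometric
#' transforms touch the image only.
#'
#' @param factor_manual augmentation factor for manually segmented images
#'   (default 10).
#' @param factor_auto augmentation factor for all other images (default 4).
#' @param factor_artifact augmentation factor for artifact crops in
#'   [oversample_artifacts()] (default 150).
#' @param rotation_range rotation angle interval in degrees.
#' @param noise_sd additive Gaussian noise, 8-bit units (applied on the
#'   `[0, 1]` scale as `noise_sd / 255`).
#' @param brightness_range multiplicative brightness interval.
#' @param elastic_alpha displacement amplitude (px) of the elastic
#'   deformation; 0 disables it.
#' @param elastic_sigma Gaussian smoothing sd (px) of the displacement
#'   fields.
#' @param manual_fraction fraction of synthetic images flagged as
#'   "manually segmented" in the manifest (drives the factor split).
#' @param seed integer seed.
#' @return an object of class `augment_config`.
#' @export
augment_config <- function(factor_manual = 10L, factor_auto = 4L,
                           factor_artifact = 150L,
                           rotation_range = c(-180, 180), noise_sd = 3,
                           brightness_range = c(0.9, 1.1),
                           elastic_alpha = 20, elastic_sigma = 6,
                           manual_fraction = 0.15, seed = 1L) {
  stopifnot(factor_manual >= 1, factor_auto >= 1, factor_artifact >= 1,
            length(rotation_range) == 2, noise_sd >= 0,
            length(brightness_range) == 2, elastic_alpha >= 0,
            elastic_sigma > 0, manual_fraction >= 0, manual_fraction <= 1)
  structure(list(factor_manual = as.integer(factor_manual),
                 factor_auto = as.integer(factor_auto),
                 factor_artifact = as.integer(factor_artifact),
                 rotation_range = rotation_range, noise_sd = noise_sd,
                 brightness_range = brightness_range,
                 elastic_alpha = elastic_alpha,
                 elastic_sigma = elastic_sigma,
                 manual_fraction = manual_fraction,
                 seed = as.integer(seed)),
            class = "augment_config")
}

#' Split image identifiers into train/validation/test sets
#'
#' Holds `n_test` identifiers apart as the test set, then splits the
#' remainder into validation (`floor(val_fraction * n_rest)`) and training
#' sets, all by a seeded shuffle.
#'
#' @param ids unique identifier vector.
#' @param cfg a [split_config()].
#' @return list with disjoint `train`, `val`, `test` covering `ids`.
#' @export
split_dataset <- function(ids, cfg = split_config()) {
  if (anyDuplicated(ids)) stop("ids must be unique")
  if (cfg$n_test >= length(ids))
    stop("n_test (", cfg$n_test, ") must be smaller than the dataset size (",
         length(ids), ")")
  perm <- with_seed(cfg$seed, sample(ids))
  test <- perm[seq_len(cfg$n_test)]
  rest <- perm[setdiff(seq_along(perm), seq_len(cfg$n_test))]
  n_val <- floor(cfg$val_fraction * length(rest))
  list(train = rest[setdiff(seq_along(rest), seq_len(n_val))],
       val = rest[seq_len(n_val)],
       test = test)
}

#' Tile an image into partially overlapping square crops
#'
#' Covers the image with a grid of `ceil(W/crop) x ceil(H/crop)` crops whose
#' start offsets are evenly spaced with integer rounding, the last row and
#' column flush with the border, so every pixel is covered by at least one
#' crop.  A 1600x1200 image with the default 512 px crops yields the 4x3 =
#' 12 partially overlapping tiles used for training.
#'
#' @param image matrix or `H x W x C` array.
#' @param crop_size square crop side in pixels (default 512).
#' @return list with `crops` (list of arrays) and `offsets` (data frame of
#'   1-based `row`, `col` top-left corners, row-major order).
#' @export
tile_image <- function(image, crop_size = 512L) {
  d <- dim(image)
  h <- d[1]
  w <- d[2]
  if (h < crop_size || w < crop_size)
    stop("image (", h, "x", w, ") is smaller than the crop size ", crop_size)
  starts <- function(n) {
    k <- ceiling(n / crop_size)
    if (k == 1) 0L
    else as.integer(round((seq_len(k) - 1) * (n - crop_size) / (k - 1)))
  }
  sr <- starts(h)
  sc <- starts(w)
  crops <- list()
  offs <- data.frame(row = integer(0), col = integer(0))
  for (r in sr) {
    for (c in sc) {
      crop <- if (length(d) == 2)
        image[r + seq_len(crop_size), c + seq_len(crop_size), drop = FALSE]
      else
        image[r + seq_len(crop_size), c + seq_len(crop_size), , drop = FALSE]
      crops[[length(crops) + 1L]] <- crop
      offs <- rbind(offs, data.frame(row = r + 1L, col = c + 1L))
    }
  }
  list(crops = crops, offsets = offs)
}

#' Reassemble per-crop heatmaps into a full-size heatmap
#'
#' Inverse of [tile_image()] for model outputs: overlapping predictions are
#' averaged.
#'
#' @param crops list of `crop x crop` matrices.
#' @param offsets the `offsets` data frame returned by [tile_image()].
#' @param height,width full image size.
#' @return `height x width` matrix.
#' @export
stitch_crops <- function(crops, offsets, height, width) {
  acc <- matrix(0, height, width)
  cnt <- matrix(0, height, width)
  for (i in seq_along(crops)) {
    cs <- dim(crops[[i]])
    rr <- offsets$row[i] + seq_len(cs[1]) - 1L
    cc <- offsets$col[i] + seq_len(cs[2]) - 1L
    acc[rr, cc] <- acc[rr, cc] + crops[[i]]
    cnt[rr, cc] <- cnt[rr, cc] + 1
  }
  acc / pmax(cnt, 1)
}

# sample one warp (rotation + elastic field) and apply it to image (bilinear)
# and mask/wmap (nearest); identity parameters reproduce the input exactly
warp_triple <- function(image, mask, wmap, angle_deg, dr, dc,
                        brightness, noise_sd) {
  h <- if (is.matrix(image)) nrow(image) else dim(image)[1]
  w <- if (is.matrix(image)) ncol(image) else dim(image)[2]
  identity_warp <- angle_deg == 0 && is.null(dr)
  if (!identity_warp) {
    th <- angle_deg * pi / 180
    cr <- (h + 1) / 2
    cc <- (w + 1) / 2
    gr <- matrix(seq_len(h), h, w)
    gc <- matrix(seq_len(w), h, w, byrow = TRUE)
    # inverse rotation about the crop center
    src_r <- cr + cos(th) * (gr - cr) - sin(th) * (gc - cc)
    src_c <- cc + sin(th) * (gr - cr) + cos(th) * (gc - cc)
    if (!is.null(dr)) {
      src_r <- src_r + dr
      src_c <- src_c + dc
    }
    warp_m <- function(m, method) {
      v <- if (method == "bilinear") bilinear_gather(m, src_r, src_c)
      else nearest_gather(m, src_r, src_c)
      matrix(v, h, w)
    }
  } else {
    warp_m <- function(m, method) m
  }
  img_out <- if (is.matrix(image)) warp_m(image, "bilinear")
  else {
    out <- image
    for (k in seq_len(dim(image)[3]))
      out[, , k] <- warp_m(image[, , k], "bilinear")
    out
  }
  img_out <- img_out * brightness
  if (noise_sd > 0)
    img_out <- img_out + stats::rnorm(length(img_out), 0, noise_sd / 255)
  img_out <- clampv(img_out, 0, 1)
  list(image = img_out,
       mask = if (!is.null(mask)) warp_m(mask, "nearest"),
       wmap = if (!is.null(wmap)) warp_m(wmap, "nearest"))
}

#' Augment a crop together with its mask and weight map
#'
#' Produces exactly `factor` augmented triples.  Rotation and elastic
#' deformation are applied identically to all three rasters (nearest
#' neighbour for mask and weight map, so masks stay binary); brightness and
#' noise perturb the image only.
#'
#' @param crop image matrix or `H x W x C` array in `[0, 1]`.
#' @param mask binary matrix of the same spatial shape.
#' @param wmap weight-map matrix of the same spatial shape.
#' @param factor number of augmented copies.
#' @param cfg an [augment_config()].
#' @param seed integer seed.
#' @return list of `factor` lists with elements `image`, `mask`, `wmap`.
#' @export
augment <- function(crop, mask, wmap, factor, cfg = augment_config(),
                    seed = 1L) {
  dc0 <- dim(crop)[1:2]
  if (!is.null(mask) && !all(dim(mask) == dc0))
    stop("mask shape differs from crop")
  if (!is.null(wmap) && !all(dim(wmap) == dc0))
    stop("weight map shape differs from crop")
  stopifnot(factor >= 1)
  with_seed(seed, {
    lapply(seq_len(factor), function(i) {
      angle <- stats::runif(1, cfg$rotation_range[1], cfg$rotation_range[2])
      dr <- dc <- NULL
      if (cfg$elastic_alpha > 0) {
        dr <- as.matrix(EBImage::gblur(
          matrix(stats::runif(prod(dc0), -1, 1), dc0[1], dc0[2]),
          sigma = cfg$elastic_sigma)) * cfg$elastic_alpha
        dc <- as.matrix(EBImage::gblur(
          matrix(stats::runif(prod(dc0), -1, 1), dc0[1], dc0[2]),
          sigma = cfg$elastic_sigma)) * cfg$elastic_alpha
      }
      brightness <- stats::runif(1, cfg$brightness_range[1],
                                 cfg$brightness_range[2])
      warp_triple(crop, mask, wmap, angle, dr, dc, brightness, cfg$noise_sd)
    })
  })
}

#' Oversample artifact crops
#'
#' Re-samples each crop containing confounding bright structures
#' `factor_artifact` times through the augmentation pipeline, attaching
#' all-background masks: artifacts are distractors, never cells, and the
#' oversampled copies teach the model to ignore them.
#'
#' @param artifact_crops non-empty list of image crops (matrices or
#'   `H x W x C` arrays in `[0, 1]`).
#' @param cfg an [augment_config()].
#' @return flat list of `length(artifact_crops) * factor_artifact` lists
#'   with elements `image`, `mask` (all zeros), `wmap` (all zeros).
#' @export
oversample_artifacts <- function(artifact_crops, cfg = augment_config()) {
  if (length(artifact_crops) == 0) stop("artifact_crops must be non-empty")
  out <- list()
  for (i in seq_along(artifact_crops)) {
    crop <- artifact_crops[[i]]
    zero <- matrix(0L, dim(crop)[1], dim(crop)[2])
    out <- c(out, augment(crop, zero, zero, cfg$factor_artifact, cfg,
                          seed = cfg$seed + i))
  }
  out
}
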