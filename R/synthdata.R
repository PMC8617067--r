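#' Specification of the synthetic fluorescence-image generator
#'
#' Describes the study conditions emulated by [generate_image()]: yellow-ish
#' elliptical cells of variable size and saturation (about 50 px mean
#' diameter) over a darker textured background, with counts ranging from
#' zero to several dozen per image, a fraction of cells clumping together,
#' and bright non-cell distractors (artifact strips/blobs and thin
#' filaments) that brighten the image but are never labelled in the mask.
#'
#' @param height,width image size in pixels (default 1200 x 1600).
#' @param n_cells_range inclusive integer interval for the cell count.
#' @param mean_diameter,diameter_sd cell diameter distribution in pixels.
#' @param intensity_range cell peak brightness interval in `[0, 255]`.
#' @param background_level_range background base level interval in
#'   `[0, 255]`.
#' @param background_texture_scale spatial scale (px) of the low-frequency
#'   background texture.
#' @param clump_fraction probability that a cell is placed adjacent to or
#'   overlapping an existing cell.
#' @param artifact_rate expected number of bright artifact distractors
#'   (strips/blobs) per image (Poisson).
#' @param filament_rate expected number of bright thin filaments per image
#'   (Poisson).
#' @param noise_sd additive Gaussian pixel noise, in 8-bit units.
#' @return an object of class `synthetic_spec`.
#' @export
#' @examples
#' spec <- synthetic_spec(height = 128, width = 128,
#'                        n_cells_range = c(3, 6), mean_diameter = 20)
#' out <- generate_image(spec, seed = 1)
#' nrow(out$cells)
synthetic_spec <- function(height = 1200, width = 1600,
                           n_cells_range = c(0L, 50L),
                           mean_diameter = 50, diameter_sd = 10,
                           intensity_range = c(120, 255),
                           background_level_range = c(15, 60),
                           background_texture_scale = 120,
                           clump_fraction = 0.3,
                           artifact_rate = 1, filament_rate = 1,
                           noise_sd = 4) {
  stopifnot(height > 0, width > 0,
            length(n_cells_range) == 2,
            n_cells_range[1] >= 0, n_cells_range[1] <= n_cells_range[2],
            mean_diameter > 0, diameter_sd >= 0,
            all(intensity_range >= 0), all(intensity_range <= 255),
            all(background_level_range >= 0),
            all(background_level_range <= 255),
            background_texture_scale > 0,
            clump_fraction >= 0, clump_fraction <= 1,
            artifact_rate >= 0, filament_rate >= 0, noise_sd >= 0)
  structure(list(height = as.integer(height), width = as.integer(width),
                 n_cells_range = as.integer(n_cells_range),
                 mean_diameter = mean_diameter, diameter_sd = diameter_sd,
                 intensity_range = intensity_range,
                 background_level_range = background_level_range,
                 background_texture_scale = background_texture_scale,
                 clump_fraction = clump_fraction,
                 artifact_rate = artifact_rate,
                 filament_rate = filament_rate,
                 noise_sd = noise_sd),
            class = "synthetic_spec")
}

# draw a soft-edged ellipse into chans (list of channel matrices) and its
# hard footprint into mask; returns list(chans, mask, area)
draw_ellipse <- function(chans, mask, row, col, a, b, theta, rgb255,
                         update_mask = TRUE) {
  h <- nrow(chans[[1]])
  w <- ncol(chans[[1]])
  rad <- ceiling(max(a, b)) + 1L
  rr <- max(1L, floor(row - rad)):min(h, ceiling(row + rad))
  cc <- max(1L, floor(col - rad)):min(w, ceiling(col + rad))
  dy <- outer(rr - row, rep(1, length(cc)))
  dx <- outer(rep(1, length(rr)), cc - col)
  u <- (cos(theta) * dy + sin(theta) * dx) / a
  v <- (-sin(theta) * dy + cos(theta) * dx) / b
  rn <- sqrt(u^2 + v^2)
  cov <- clampv((1 - rn) * min(a, b) + 0.5, 0, 1)
  inside <- rn <= 1
  for (k in 1:3)
    chans[[k]][rr, cc] <- pmax(chans[[k]][rr, cc], cov * rgb255[k])
  if (update_mask) mask[rr, cc][inside] <- 1L
  list(chans = chans, mask = mask, area = sum(inside))
}

place_cells <- function(spec, n) {
  h <- spec$height
  w <- spec$width
  md <- spec$mean_diameter
  pos <- matrix(numeric(0), 0, 2)
  clumped <- logical(0)
  for (i in seq_len(n)) {
    if (i > 1 && stats::runif(1) < spec$clump_fraction) {
      anchor <- pos[sample.int(i - 1L, 1L), ]
      d <- stats::runif(1, 0.5, 1) * md
      ang <- stats::runif(1, 0, 2 * pi)
      p <- c(anchor[1] + d * cos(ang), anchor[2] + d * sin(ang))
      p <- c(clampv(p[1], 2, h - 1), clampv(p[2], 2, w - 1))
      pos <- rbind(pos, p)
      clumped <- c(clumped, TRUE)
    } else {
      ok <- FALSE
      for (try in 1:100) {
        p <- c(stats::runif(1, md / 2, h - md / 2),
               stats::runif(1, md / 2, w - md / 2))
        if (nrow(pos) == 0 ||
            min(sqrt((pos[, 1] - p[1])^2 + (pos[, 2] - p[2])^2)) >=
              1.2 * md) {
          ok <- TRUE
          break
        }
      }
      if (!ok)
        stop("cell placement infeasible: could not place ", n,
             " cells of diameter ~", md, " on a ", h, "x", w,
             " image after bounded retries")
      pos <- rbind(pos, p)
      clumped <- c(clumped, FALSE)
    }
  }
  list(pos = pos, clumped = clumped)
}

draw_artifacts <- function(chans, spec) {
  n_art <- stats::rpois(1, spec$artifact_rate)
  h <- nrow(chans[[1]])
  w <- ncol(chans[[1]])
  for (k in seq_len(n_art)) {
    inten <- stats::runif(1, 160, 255)
    tint <- c(1, stats::runif(1, 0.7, 0.95), stats::runif(1, 0.1, 0.4))
    if (stats::runif(1) < 0.5) {
      # bright strip: a long, thin, rotated ellipse
      res <- draw_ellipse(chans, NULL,
                          stats::runif(1, 1, h), stats::runif(1, 1, w),
                          a = stats::runif(1, 0.08, 0.25) * min(h, w),
                          b = stats::runif(1, 3, 8),
                          theta = stats::runif(1, 0, pi),
                          rgb255 = inten * tint, update_mask = FALSE)
    } else {
      # large bright blob
      res <- draw_ellipse(chans, NULL,
                          stats::runif(1, 1, h), stats::runif(1, 1, w),
                          a = stats::runif(1, 0.6, 1.6) * spec$mean_diameter,
                          b = stats::runif(1, 0.6, 1.6) * spec$mean_diameter,
                          theta = stats::runif(1, 0, pi),
                          rgb255 = inten * tint, update_mask = FALSE)
    }
    chans <- res$chans
  }
  n_fil <- stats::rpois(1, spec$filament_rate)
  for (k in seq_len(n_fil)) {
    inten <- stats::runif(1, 150, 240)
    tint <- c(1, stats::runif(1, 0.75, 0.95), stats::runif(1, 0.1, 0.35))
    p <- c(stats::runif(1, 1, h), stats::runif(1, 1, w))
    ang <- stats::runif(1, 0, 2 * pi)
    for (s in 1:40) {
      ang <- ang + stats::rnorm(1, 0, 0.35)
      q <- p + 4 * c(cos(ang), sin(ang))
      # thin segment drawn as a short narrow ellipse
      res <- draw_ellipse(chans, NULL, (p[1] + q[1]) / 2, (p[2] + q[2]) / 2,
                          a = 3, b = 1.2,
                          theta = atan2(q[2] - p[2], q[1] - p[1]),
                          rgb255 = inten * tint, update_mask = FALSE)
      chans <- res$chans
      p <- q
      if (p[1] < 1 || p[1] > h || p[2] < 1 || p[2] > w) break
    }
  }
  chans
}

#' Generate one synthetic fluorescence image with ground truth
#'
#' Renders a seeded synthetic micrograph: textured dark background,
#' anti-aliased yellow-ish elliptical cells (recorded in the binary mask and
#' the cell table), plus unlabelled bright distractors.  Identical
#' `(spec, seed)` pairs give bit-identical outputs.
#'
#' @param spec a [synthetic_spec()].
#' @param seed integer seed driving all randomness of this image.
#' @return a list with `image` (`H x W x 3` array in `[0, 1]`, 8-bit
#'   quantized), `mask` (`H x W` integer matrix, 1 = cell pixel), and
#'   `cells` (data frame: `id`, `row`, `col`, `area`, `clumped`).
#' @export
generate_image <- function(spec, seed) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(seed, {
    h <- spec$height
    w <- spec$width
    n <- spec$n_cells_range[1] +
      sample.int(spec$n_cells_range[2] - spec$n_cells_range[1] + 1L, 1L) - 1L

    # background: global level plus low-frequency texture, warm color cast
    level <- stats::runif(1, spec$background_level_range[1],
                          spec$background_level_range[2])
    gh <- max(2L, ceiling(h / spec$background_texture_scale) + 1L)
    gw <- max(2L, ceiling(w / spec$background_texture_scale) + 1L)
    tex <- bilinear_resize(matrix(stats::rnorm(gh * gw, 0, 12), gh, gw), h, w)
    base <- clampv(level + tex, 0, 255)
    chans <- list(base, base * 0.9, base * 0.6)

    mask <- matrix(0L, h, w)
    cells <- data.frame(id = integer(0), row = numeric(0), col = numeric(0),
                        area = numeric(0), clumped = logical(0))
    if (n > 0) {
      pl <- place_cells(spec, n)
      for (i in seq_len(n)) {
        diam <- max(6, stats::rnorm(1, spec$mean_diameter, spec$diameter_sd))
        a <- diam / 2
        ecc <- stats::runif(1, 0, 0.8)
        b <- a * sqrt(1 - ecc^2)
        theta <- stats::runif(1, 0, pi)
        inten <- stats::runif(1, spec$intensity_range[1],
                              spec$intensity_range[2])
        tint <- c(1, stats::runif(1, 0.75, 0.95), stats::runif(1, 0.08, 0.35))
        res <- draw_ellipse(chans, mask, pl$pos[i, 1], pl$pos[i, 2],
                            a, b, theta, inten * tint)
        chans <- res$chans
        mask <- res$mask
        cells <- rbind(cells, data.frame(id = i, row = pl$pos[i, 1],
                                         col = pl$pos[i, 2], area = res$area,
                                         clumped = pl$clumped[i]))
      }
    }

    chans <- draw_artifacts(chans, spec)

    img <- array(0, dim = c(h, w, 3))
    for (k in 1:3) {
      ch <- chans[[k]] + stats::rnorm(h * w, 0, spec$noise_sd)
      img[, , k] <- round(clampv(ch, 0, 255)) / 255
    }
    list(image = img, mask = mask, cells = cells)
  })
}

#' Generate a synthetic dataset on disk
#'
#' Writes `n_images` seeded image/mask pairs (8-bit RGB PNG images,
#' single-channel 0/255 PNG masks) and a `manifest.csv` with columns
#' `image,mask,n_true`.  Re-running with the same arguments reproduces the
#' directory byte for byte.
#'
#' @param n_images number of images.
#' @param spec a [synthetic_spec()].
#' @param seed master seed; per-image seeds are derived from it.
#' @param out_dir output directory (created if missing).
#' @return the manifest data frame (paths relative to `out_dir`),
#'   invisibly also written to `out_dir/manifest.csv`.
#' @export
generate_dataset <- function(n_images, spec, seed, out_dir) {
  stopifnot(n_images >= 1)
  dir.create(file.path(out_dir, "images"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(out_dir, "masks"), recursive = TRUE,
             showWarnings = FALSE)
  if (!dir.exists(out_dir))
    stop("cannot create output directory: ", out_dir)
  seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, n_images))
  manifest <- data.frame(image = character(n_images),
                         mask = character(n_images),
                         n_true = integer(n_images))
  for (i in seq_len(n_images)) {
    out <- generate_image(spec, seeds[i])
    ip <- sprintf("images/img_%04d.png", i)
    mp <- sprintf("masks/mask_%04d.png", i)
    png::writePNG(out$image, file.path(out_dir, ip))
    png::writePNG(out$mask + 0, file.path(out_dir, mp))
    manifest$image[i] <- ip
    manifest$mask[i] <- mp
    manifest$n_true[i] <- nrow(out$cells)
  }
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  manifest
}
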