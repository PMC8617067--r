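test_that("split sizes follow the hold-out arithmetic", {
  ids283 <- sprintf("im%03d", 1:283)
  sp <- split_dataset(ids283, split_config(n_test = 70, val_fraction = 0.3,
                                           seed = 4))
  expect_length(sp$test, 70)
  expect_length(sp$val, floor(0.3 * 213))
  expect_length(c(sp$train, sp$val), 213)

  sp10 <- split_dataset(letters[1:10],
                        split_config(n_test = 2, val_fraction = 0.5,
                                     seed = 1))
  expect_equal(lengths(sp10[c("train", "val", "test")]),
               c(train = 4, val = 4, test = 2))
})

test_that("splits partition the ids and are reproducible under a seed", {
  ids <- sprintf("x%02d", 1:37)
  cfg <- split_config(n_test = 5, val_fraction = 0.25, seed = 9)
  sp <- split_dataset(ids, cfg)
  expect_length(intersect(sp$train, sp$val), 0)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_length(intersect(sp$val, sp$test), 0)
  expect_setequal(c(sp$train, sp$val, sp$test), ids)
  expect_identical(sp, split_dataset(ids, cfg))
  expect_error(split_dataset(letters[1:3],
                             split_config(n_test = 3, val_fraction = 0.5)),
               "smaller")
  expect_error(split_dataset(c("a", "a", "b"), cfg), "unique")
})

test_that("tiling yields the evenly spaced overlapping grid", {
  t12 <- tile_image(array(0, dim = c(1200, 1600, 3)), 512)
  expect_length(t12$crops, 12)
  expect_length(unique(t12$offsets$row), 3)   # 3 rows
  expect_length(unique(t12$offsets$col), 4)   # 4 columns
  # last row/column flush with the border
  expect_equal(max(t12$offsets$row) + 512 - 1, 1200)
  expect_equal(max(t12$offsets$col) + 512 - 1, 1600)

  t1 <- tile_image(matrix(0, 512, 512), 512)
  expect_length(t1$crops, 1)
  expect_equal(t1$offsets, data.frame(row = 1L, col = 1L))

  t2 <- tile_image(matrix(0, 1024, 512), 512)
  expect_length(t2$crops, 2)
  expect_equal(t2$offsets$row, c(1L, 513L))  # zero overlap

  expect_error(tile_image(matrix(0, 100, 600), 512), "smaller")
})

test_that("every pixel is covered by at least one crop", {
  for (dims in list(c(700, 1300), c(512, 513), c(1200, 1600))) {
    img <- matrix(0, dims[1], dims[2])
    tl <- tile_image(img, 512)
    cover <- matrix(0L, dims[1], dims[2])
    for (i in seq_along(tl$crops)) {
      rr <- tl$offsets$row[i] + 0:511
      cc <- tl$offsets$col[i] + 0:511
      cover[rr, cc] <- cover[rr, cc] + 1L
    }
    expect_true(all(cover >= 1))
  }
})

test_that("augmentation produces the requested factor and honours identity", {
  id_cfg <- augment_config(rotation_range = c(0, 0), noise_sd = 0,
                           brightness_range = c(1, 1), elastic_alpha = 0)
  crop <- array(runif(32 * 32 * 3), dim = c(32, 32, 3))
  mask <- matrix(rbinom(32 * 32, 1, 0.2), 32, 32)
  wmap <- matrix(runif(32 * 32), 32, 32)
  out <- augment(crop, mask, wmap, factor = 10, cfg = id_cfg, seed = 2)
  expect_length(out, 10)
  expect_identical(out[[1]]$image, crop)
  expect_identical(out[[7]]$mask, mask)
  expect_identical(out[[4]]$wmap, wmap)
  expect_error(augment(crop, matrix(0, 8, 8), wmap, 2, id_cfg),
               "mask shape")
})

test_that("rotation moves a cell centroid as the analytic rotation does", {
  for (angle in c(90, 180, 45)) {
    cfg <- augment_config(rotation_range = c(angle, angle), noise_sd = 0,
                          brightness_range = c(1, 1), elastic_alpha = 0)
    mask <- matrix(0L, 64, 64)
    mask[10:14, 30:34] <- 1L   # centroid (12, 32)
    out <- augment(array(0, dim = c(64, 64, 3)), mask, NULL, 1, cfg,
                   seed = 3)
    got <- colMeans(which(out[[1]]$mask == 1, arr.ind = TRUE))
    ctr <- c(32.5, 32.5)
    th <- -angle * pi / 180   # content rotates by the inverse mapping
    v <- c(12, 32) - ctr
    want <- ctr + c(cos(th) * v[1] - sin(th) * v[2],
                    sin(th) * v[1] + cos(th) * v[2])
    expect_lt(sqrt(sum((got - want)^2)), 1.0)
    expect_true(all(out[[1]]$mask %in% c(0L, 1L)))
  }
})

test_that("masks stay binary under elastic warping", {
  cfg <- augment_config(rotation_range = c(-180, 180), noise_sd = 2,
                        brightness_range = c(0.9, 1.1), elastic_alpha = 15,
                        elastic_sigma = 5)
  mask <- disc_mask(64, 64, rbind(c(20, 20), c(44, 40)), 8)
  out <- augment(array(runif(64 * 64 * 3), dim = c(64, 64, 3)), mask,
                 mask * 2.5, 5, cfg, seed = 8)
  for (o in out) {
    expect_true(all(o$mask %in% c(0, 1)))
    expect_true(all(o$image >= 0 & o$image <= 1))
  }
})

test_that("warping a delta mask lands where the warped grid says", {
  # geometric consistency: the mask warp and the coordinate warp commute
  cfg <- augment_config(rotation_range = c(30, 30), noise_sd = 0,
                        brightness_range = c(1, 1), elastic_alpha = 0)
  for (p0 in list(c(16, 40), c(50, 12))) {
    mask <- matrix(0L, 64, 64)
    mask[p0[1], p0[2]] <- 1L
    out <- augment(array(0, dim = c(64, 64, 3)), mask, NULL, 1, cfg,
                   seed = 1)
    hits <- which(out[[1]]$mask == 1, arr.ind = TRUE)
    expect_gte(nrow(hits), 1)
    ctr <- c(32.5, 32.5)
    th <- -30 * pi / 180
    v <- p0 - ctr
    want <- ctr + c(cos(th) * v[1] - sin(th) * v[2],
                    sin(th) * v[1] + cos(th) * v[2])
    expect_lt(min(sqrt((hits[, 1] - want[1])^2 + (hits[, 2] - want[2])^2)),
              1.0)
  }
})

test_that("artifact oversampling emits factor_artifact empty-mask copies", {
  cfg <- augment_config(factor_artifact = 12, elastic_alpha = 5,
                        elastic_sigma = 4)
  crops <- list(array(runif(32 * 32 * 3), dim = c(32, 32, 3)),
                array(runif(32 * 32 * 3), dim = c(32, 32, 3)))
  out <- oversample_artifacts(crops, cfg)
  expect_length(out, 24)
  expect_true(all(vapply(out, function(o) sum(o$mask), numeric(1)) == 0))
  expect_error(oversample_artifacts(list(), cfg), "non-empty")
})

test_that("stitching inverts tiling up to overlap averaging", {
  img <- matrix(runif(600 * 700), 600, 700)
  tl <- tile_image(img, 512)
  back <- stitch_crops(tl$crops, tl$offsets, 600, 700)
  expect_equal(back, img, tolerance = 1e-12)
})
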