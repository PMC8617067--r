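test_that("border distances follow the Euclidean metric", {
  mask <- matrix(0L, 9, 9)
  mask[4:6, 4:6] <- 1L
  d <- cell_border_distance(mask, 1)
  expect_equal(d[5, 7], 1)          # 4-neighbour of the right edge
  expect_equal(d[3, 3], sqrt(2))    # diagonal of the corner
  expect_equal(d[5, 5], 0)          # inside the cell
  expect_error(cell_border_distance(mask, 7), "does not label")
  expect_error(cell_border_distance(mask * 3, 1), "binary")
})

test_that("border distances match the exhaustive oracle", {
  set.seed(42)
  for (rep in 1:3) {
    mask <- matrix(0L, 32, 32)
    mask[disc_mask(32, 32, cbind(sample(8:24, 2), sample(8:24, 2)), 4) == 1] <- 1L
    labels <- label_components(mask)
    for (id in seq_len(max(labels))) {
      got <- cell_border_distance(mask, id)
      want <- oracle_distance(matrix(as.integer(labels == id), 32, 32))
      expect_equal(got, want, tolerance = 1e-6)
    }
  }
})

test_that("weight maps are zero without cells and on cell pixels", {
  expect_equal(build_weight_map(matrix(0L, 16, 16)), matrix(0, 16, 16))
  mask <- disc_mask(48, 48, rbind(c(24, 24)), 6)
  wm <- build_weight_map(mask, weight_map_params(sigma = 5, max_radius = 15))
  expect_true(all(wm[mask == 1] == 0))
  expect_true(all(wm >= 0) && all(is.finite(wm)))
})

test_that("single-cell maps decay monotonically away from the border", {
  mask <- disc_mask(64, 64, rbind(c(32, 32)), 8)
  p <- weight_map_params(w0 = 10, sigma = 6, max_radius = 18)
  wm <- build_weight_map(mask, p)
  ray <- wm[32, 41:60]    # leaving the border towards the right
  expect_true(all(diff(ray) <= 1e-12))
  # values equal the kernel evaluated on the oracle distances
  d <- oracle_distance(mask)
  want <- 10 * exp(-d^2 / (2 * 6^2))
  want[d > 18] <- 0
  want[mask == 1] <- 0
  expect_equal(wm, want, tolerance = 1e-6)
})

test_that("multi-cell maps are the sum of single-cell maps", {
  p <- weight_map_params(w0 = 10, sigma = 5, max_radius = 15)
  centers <- rbind(c(20, 20), c(20, 40), c(44, 30))
  mask <- disc_mask(64, 64, centers, 6)
  wm <- build_weight_map(mask, p)
  acc <- matrix(0, 64, 64)
  for (k in 1:3)
    acc <- acc + build_weight_map(disc_mask(64, 64, centers[k, , drop = FALSE],
                                            6), p)
  acc[mask == 1] <- 0
  expect_equal(wm, acc, tolerance = 1e-8)
})

test_that("crowded corridors outweigh isolated borders at equal distance", {
  sigma <- 6
  p <- weight_map_params(w0 = 10, sigma = sigma, max_radius = 3 * sigma)
  r <- 5
  gap <- 2 * sigma
  # two discs whose borders are 2*sigma apart; midpoint at distance sigma
  two <- disc_mask(64, 64, rbind(c(32, 20), c(32, 20 + 2 * r + gap)), r)
  wm2 <- build_weight_map(two, p)
  mid <- wm2[32, 20 + r + gap / 2]
  one <- disc_mask(64, 64, rbind(c(32, 20)), r)
  wm1 <- build_weight_map(one, p)
  single_at_sigma <- wm1[32, 20 + r + sigma]
  expect_gt(mid, single_at_sigma)
})

test_that("a custom kernel is honoured", {
  mask <- disc_mask(32, 32, rbind(c(16, 16)), 4)
  p <- weight_map_params(w0 = 3, sigma = 4, max_radius = 12)
  wm <- build_weight_map(mask, p, kernel = function(d) 3 * exp(-d / 4))
  d <- oracle_distance(mask)
  want <- 3 * exp(-d / 4)
  want[d > 12] <- 0
  want[mask == 1] <- 0
  expect_equal(wm, want, tolerance = 1e-6)
})

test_that("weighted BCE reduces to plain BCE and scales linearly", {
  set.seed(7)
  t <- matrix(rbinom(400, 1, 0.3), 20, 20)
  p <- matrix(runif(400, 0.01, 0.99), 20, 20)
  plain <- -mean(t * log(p) + (1 - t) * log(1 - p))
  expect_equal(weighted_bce(t, p, wmap = NULL, cw = class_weights(1, 1)),
               plain, tolerance = 1e-12)
  expect_equal(weighted_bce(t, p, wmap = matrix(0, 20, 20),
                            cw = class_weights(1, 1)),
               plain, tolerance = 1e-12)
  # homogeneity: doubling all weights doubles the loss
  l1 <- weighted_bce(t, p, cw = class_weights(1, 1.5))
  l2 <- weighted_bce(t, p, cw = class_weights(2, 3))
  expect_equal(l2, 2 * l1, tolerance = 1e-12)
  # perfect prediction: only the clipping epsilon remains
  expect_lt(weighted_bce(t, t), 1e-6)
  expect_error(weighted_bce(t, p[1:10, ]), "shapes differ")
})

test_that("errors on high-weight pixels cost more than on zero-weight ones", {
  t <- matrix(0L, 8, 8)
  wmap <- matrix(0, 8, 8)
  wmap[4, 4] <- 12
  base <- matrix(0.01, 8, 8)
  hi <- base
  hi[4, 4] <- 0.6          # error on the weighted pixel
  lo <- base
  lo[5, 5] <- 0.6          # same error on an unweighted pixel
  cw <- class_weights()
  expect_gt(weighted_bce(t, hi, wmap, cw) - weighted_bce(t, base, wmap, cw),
            weighted_bce(t, lo, wmap, cw) - weighted_bce(t, base, wmap, cw))
})
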