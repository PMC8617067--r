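test_that("matching handles perfect, empty and asymmetric cases", {
  pts <- cbind(c(10, 50, 90), c(10, 50, 90))
  m <- match_detections(pts, pts)
  expect_identical(c(m$TP, m$FP, m$FN), c(3L, 0L, 0L))
  expect_equal(m$pairs$distance, rep(0, 3))

  m0 <- match_detections(pts, NULL)
  expect_identical(c(m0$TP, m0$FP, m0$FN), c(0L, 0L, 3L))
  me <- match_detections(NULL, NULL)
  expect_identical(c(me$TP, me$FP, me$FN), c(0L, 0L, 0L))

  # one prediction between two targets pairs with the closer one
  m1 <- match_detections(rbind(c(0, 0), c(30, 0)), rbind(c(10, 0)))
  expect_identical(c(m1$TP, m1$FP, m1$FN), c(1L, 0L, 1L))
  expect_identical(m1$pairs$target, 1L)

  # the gate is strict: a pair exactly at max_match_dist does not count
  mg <- match_detections(rbind(c(0, 0)), rbind(c(50, 0)),
                         eval_config(max_match_dist = 50))
  expect_identical(c(mg$TP, mg$FP, mg$FN), c(0L, 1L, 1L))
})

test_that("matching conserves targets and predictions on random sets", {
  set.seed(5)
  for (trial in 1:50) {
    nt <- sample(0:10, 1)
    np <- sample(0:10, 1)
    tg <- cbind(runif(nt, 0, 300), runif(nt, 0, 300))
    pr <- cbind(runif(np, 0, 300), runif(np, 0, 300))
    m <- match_detections(tg, pr)
    expect_identical(m$TP + m$FN, nt)
    expect_identical(m$TP + m$FP, np)
    expect_true(all(m$pairs$distance < 50))
    expect_false(anyDuplicated(m$pairs$prediction) > 0)
  }
})

test_that("detection metrics evaluate the object-level formulas", {
  dm <- detection_metrics(list(TP = 8, FP = 2, FN = 2))
  expect_equal(dm$precision, 0.8)
  expect_equal(dm$recall, 0.8)
  expect_equal(dm$f1, 0.8)
  expect_equal(dm$accuracy, 8 / 12)

  perfect <- detection_metrics(list(TP = 5, FP = 0, FN = 0))
  expect_equal(unlist(perfect), c(accuracy = 1, precision = 1, recall = 1,
                                  f1 = 1))
  expect_error(detection_metrics(list(TP = 0, FP = 0, FN = 0)), "undefined")

  # the harmonic-mean form agrees with the counting form, and accuracy
  # never exceeds F1
  set.seed(8)
  for (trial in 1:50) {
    TP <- sample(0:20, 1)
    FP <- sample(0:20, 1)
    FN <- sample(0:20, 1)
    if (TP + FP + FN == 0) next
    dm <- detection_metrics(list(TP = TP, FP = FP, FN = FN))
    if (dm$precision + dm$recall > 0)
      expect_equal(dm$f1, 2 * dm$precision * dm$recall /
                     (dm$precision + dm$recall), tolerance = 1e-12)
    expect_lte(dm$accuracy, dm$f1 + 1e-12)
    expect_true(all(unlist(dm) >= 0 & unlist(dm) <= 1))
  }
})

test_that("counting metrics follow the AE/PE definitions", {
  cm0 <- counting_metrics(data.frame(n_true = c(10, 5), n_pred = c(10, 5)))
  expect_equal(unlist(cm0), c(mae = 0, medae = 0, mpe_percent = 0))

  cm <- counting_metrics(data.frame(n_true = c(10, 20), n_pred = c(12, 19)))
  expect_equal(cm$mae, 1.5)
  expect_equal(cm$medae, 1.5)
  expect_equal(cm$mpe_percent, mean(c(-0.2, 0.05)) * 100)

  # zero-truth images contribute to AE only
  cmz <- counting_metrics(data.frame(n_true = c(0, 10), n_pred = c(3, 10)))
  expect_equal(cmz$mae, 1.5)
  expect_equal(cmz$mpe_percent, 0)
  expect_error(counting_metrics(data.frame(n_true = 0, n_pred = 3)),
               "undefined")
})

test_that("threshold selection picks the knee of the post-peak segment", {
  # strictly increasing curve: no decreasing segment, argmax = last point
  inc <- optimize_threshold(c(0.1, 0.2, 0.3, 0.4), c(0.5, 0.6, 0.7, 0.8))
  expect_equal(inc$threshold, 0.8)
  expect_identical(inc$method, "argmax")

  # flat plateau then steep drop: knee at the flat-to-drop transition,
  # matching the independent knee oracle on the same points
  th <- seq(0.5, 0.775, by = 0.025)
  f1 <- c(0.82, 0.82, 0.82, 0.82, 0.82, 0.81, 0.79, 0.74, 0.65, 0.50,
          0.30, 0.10)
  sel <- optimize_threshold(f1, th)
  expect_identical(sel$method, "kneedle")
  peak <- which.max(f1)
  oracle_idx <- peak - 1 + oracle_kneedle_decreasing(th[peak:12], f1[peak:12])
  expect_equal(sel$threshold, th[oracle_idx])
  expect_gte(sel$threshold, th[peak])

  # conservatism across random plateau-then-drop curves
  set.seed(21)
  grid <- eval_config()$threshold_grid
  for (trial in 1:20) {
    peak_at <- sample(3:8, 1)
    plateau <- sample(3:6, 1)
    n <- length(grid)
    y <- c(seq(0.6, 0.8, length.out = peak_at),
           rep(0.8, plateau) - cumsum(runif(plateau, 0, 0.01)))
    drop <- n - length(y)
    y <- c(y, y[length(y)] - cumsum(runif(drop, 0.02, 0.08)))
    sel <- optimize_threshold(pmax(y, 0), grid)
    expect_gte(sel$threshold, grid[which.max(y)])
  }
})

test_that("summaries pool detections and counts across images", {
  per_image <- data.frame(n_true = c(4, 6), n_pred = c(4, 5),
                          TP = c(4, 4), FP = c(0, 1), FN = c(0, 2))
  s <- summarize_evaluation(per_image, threshold = 0.875)
  expect_equal(s$f1, 2 * 8 / (2 * 8 + 1 + 2))
  expect_equal(s$accuracy, 8 / 11)
  expect_equal(s$mae, 0.5)
  expect_equal(s$mpe_percent, mean(c(0, 1 / 6)) * 100)
  expect_identical(names(s), c("threshold", "f1", "accuracy", "precision",
                               "recall", "mae", "medae", "mpe_percent"))
})

test_that("mask centroids locate component centers", {
  mask <- disc_mask(64, 64, rbind(c(20, 20), c(45, 50)), 6)
  ct <- mask_centroids(mask)
  expect_identical(nrow(ct), 2L)
  ct <- ct[order(ct$row), ]
  expect_equal(ct$row, c(20, 45), tolerance = 0.1)
  expect_equal(ct$col, c(20, 50), tolerance = 0.1)
})
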