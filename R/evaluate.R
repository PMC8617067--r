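#' Evaluation configuration
#'
#' @param max_match_dist centroid distance gate in pixels; a target and a
#'   prediction can only match if strictly closer than this (default 50,
#'   the average cell diameter).
#' @param threshold_grid strictly increasing probability grid scanned by
#'   [optimize_threshold()] (default 0.500 to 0.975 in steps of 0.025).
#' @return an object of class `eval_config`.
#' @export
eval_config <- function(max_match_dist = 50,
                        threshold_grid = seq(0.5, 0.975, by = 0.025)) {
  stopifnot(max_match_dist > 0, all(diff(threshold_grid) > 0),
            all(threshold_grid > 0), all(threshold_grid < 1))
  structure(list(max_match_dist = max_match_dist,
                 threshold_grid = threshold_grid),
            class = "eval_config")
}

as_centroids <- function(x) {
  if (is.null(x) || (is.data.frame(x) && nrow(x) == 0))
    return(matrix(numeric(0), 0, 2))
  if (is.data.frame(x)) x <- cbind(x$row, x$col)
  if (is.null(dim(x))) x <- matrix(x, ncol = 2)
  stopifnot(ncol(x) == 2, all(is.finite(x)))
  x
}

#' Match predicted to target centroids
#'
#' Greedy one-to-one assignment in ascending distance order: each target is
#' uniquely associated with its closest available prediction, accepted as a
#' true positive when the centroid distance is strictly below
#' `max_match_dist`.  Unmatched targets are false negatives; unmatched
#' predictions false positives.  Ties are broken by target index, then
#' prediction index, for determinism.
#'
#' @param targets,predictions centroid sets: `n x 2` matrices of
#'   `(row, col)` or data frames with `row`/`col` columns; may be empty.
#' @param cfg an [eval_config()].
#' @return object of class `match_result`: list with `TP`, `FP`, `FN` and
#'   `pairs` (data frame: `target`, `prediction`, `distance`).
#' @export
match_detections <- function(targets, predictions, cfg = eval_config()) {
  tg <- as_centroids(targets)
  pr <- as_centroids(predictions)
  nt <- nrow(tg)
  np <- nrow(pr)
  pairs <- data.frame(target = integer(0), prediction = integer(0),
                      distance = numeric(0))
  if (nt > 0 && np > 0) {
    dmat <- sqrt(outer(tg[, 1], pr[, 1], "-")^2 +
                 outer(tg[, 2], pr[, 2], "-")^2)
    cand <- which(dmat < cfg$max_match_dist, arr.ind = TRUE)
    if (nrow(cand) > 0) {
      dd <- dmat[cand]
      ord <- order(dd, cand[, 1], cand[, 2])
      used_t <- logical(nt)
      used_p <- logical(np)
      for (i in ord) {
        ti <- cand[i, 1]
        pi <- cand[i, 2]
        if (!used_t[ti] && !used_p[pi]) {
          used_t[ti] <- TRUE
          used_p[pi] <- TRUE
          pairs <- rbind(pairs, data.frame(target = ti, prediction = pi,
                                           distance = dmat[ti, pi]))
        }
      }
    }
  }
  structure(list(TP = nrow(pairs), FP = np - nrow(pairs),
                 FN = nt - nrow(pairs), pairs = pairs),
            class = "match_result")
}

#' Detection metrics from a match result
#'
#' Object-level accuracy, precision, recall and F1.  There are no true
#' negatives at the object level (the background is not an object), so
#' accuracy is `TP / (TP + FP + FN)`; F1 equals `2 TP / (2 TP + FP + FN)`.
#' With an empty side, precision/recall follow the convention: 1 when both
#' sides are empty, else 0.
#'
#' @param m a [match_detections()] result (or any list with TP/FP/FN).
#' @return list with `accuracy`, `precision`, `recall`, `f1`, all in
#'   `[0, 1]`.
#' @export
detection_metrics <- function(m) {
  TP <- m$TP
  FP <- m$FP
  FN <- m$FN
  if (TP + FP + FN == 0)
    stop("detection metrics undefined: no targets and no predictions")
  prec <- if (TP + FP == 0) (if (TP + FN == 0) 1 else 0) else TP / (TP + FP)
  rec <- if (TP + FN == 0) (if (TP + FP == 0) 1 else 0) else TP / (TP + FN)
  list(accuracy = TP / (TP + FP + FN),
       precision = prec,
       recall = rec,
       f1 = 2 * TP / (2 * TP + FP + FN))
}

#' Counting metrics over a set of images
#'
#' Per-image absolute error `AE = |n_true - n_pred|` and percentage error
#' `PE = (n_true - n_pred) / n_true`; the summary metrics are the mean and
#' median of AE (MAE, MedAE) and the mean of PE in percent (MPE).  Images
#' with `n_true = 0` contribute to the absolute errors only.  Note the PE
#' sign convention: undercounting (`n_pred < n_true`) gives positive PE.
#'
#' @param counts data frame with columns `n_true` and `n_pred` (one row per
#'   image).
#' @return list with `mae`, `medae`, `mpe_percent`.
#' @export
counting_metrics <- function(counts) {
  stopifnot(nrow(counts) >= 1, all(counts$n_true >= 0),
            all(counts$n_pred >= 0))
  ae <- abs(counts$n_true - counts$n_pred)
  pos <- counts$n_true > 0
  if (!any(pos))
    stop("mean percentage error undefined: every image has n_true = 0")
  pe <- (counts$n_true[pos] - counts$n_pred[pos]) / counts$n_true[pos]
  list(mae = mean(ae), medae = stats::median(ae),
       mpe_percent = mean(pe) * 100)
}

#' Knee-point selection of the binarization threshold
#'
#' Scans the F1-vs-threshold curve computed on full-size validation images
#' and picks the knee of its post-peak decreasing segment (the point of
#' maximum distance above the chord joining the peak to the last grid
#' point, i.e. the Kneedle criterion for a concave decreasing curve).
#' Such curves are typically flat after their peak, so the knee sits at the
#' flat-to-drop transition: a more conservative cutoff than the argmax with
#' only a slight loss in F1.  When fewer than three points follow the peak,
#' or no concave knee exists, the argmax threshold is returned.
#'
#' @param f1 F1 scores on `thresholds`.
#' @param thresholds the probability grid (default from [eval_config()]).
#' @return list with `threshold`, `f1` at it, and `method`
#'   (`"kneedle"` or `"argmax"`).
#' @export
optimize_threshold <- function(f1, thresholds = eval_config()$threshold_grid) {
  stopifnot(length(f1) == length(thresholds), length(f1) >= 1)
  peak <- which.max(f1)
  seg <- peak:length(f1)
  if (length(seg) < 3)
    return(list(threshold = thresholds[peak], f1 = f1[peak],
                method = "argmax"))
  xs <- thresholds[seg]
  ys <- f1[seg]
  xn <- (xs - xs[1]) / (xs[length(xs)] - xs[1])
  yr <- max(ys) - min(ys)
  if (yr == 0)
    return(list(threshold = thresholds[peak], f1 = f1[peak],
                method = "argmax"))
  yn <- (ys - min(ys)) / yr
  # height above the descending chord from (0, yn[1]) to (1, yn[end])
  chord <- yn[1] + (yn[length(yn)] - yn[1]) * xn
  diffc <- yn - chord
  if (max(diffc) <= 0)
    return(list(threshold = thresholds[peak], f1 = f1[peak],
                method = "argmax"))
  k <- seg[which.max(diffc)]
  list(threshold = thresholds[k], f1 = f1[k], method = "kneedle")
}

#' Centroids of the connected components of a binary mask
#'
#' Utility to derive target centroids from a ground-truth mask.
#'
#' @param mask binary matrix.
#' @return data frame with `row`, `col`, `area` per component.
#' @export
mask_centroids <- function(mask) {
  check_binary_mask(mask)
  count_cells(label_components(mask))$instances[, c("row", "col", "area")]
}

#' Aggregate detection and counting performance over images
#'
#' Pools TP/FP/FN across images for the detection metrics and computes the
#' counting metrics from the per-image counts, mirroring the per-model rows
#' of the evaluation summary table.
#'
#' @param per_image data frame with columns `n_true`, `n_pred`, `TP`, `FP`,
#'   `FN` (one row per image).
#' @param threshold the binarization threshold the predictions used.
#' @return one-row data frame: `threshold`, `f1`, `accuracy`, `precision`,
#'   `recall`, `mae`, `medae`, `mpe_percent`.
#' @export
summarize_evaluation <- function(per_image, threshold = NA_real_) {
  dm <- detection_metrics(list(TP = sum(per_image$TP),
                               FP = sum(per_image$FP),
                               FN = sum(per_image$FN)))
  cm <- counting_metrics(per_image)
  data.frame(threshold = threshold, f1 = dm$f1, accuracy = dm$accuracy,
             precision = dm$precision, recall = dm$recall, mae = cm$mae,
             medae = cm$medae, mpe_percent = cm$mpe_percent)
}
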