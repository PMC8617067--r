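# Independent oracles used to check the package implementation.

# flood-fill connected-component count (8-connectivity), queue-based
oracle_component_count <- function(mask) {
  h <- nrow(mask)
  w <- ncol(mask)
  seen <- matrix(FALSE, h, w)
  n <- 0L
  for (j in seq_len(w)) {
    for (i in seq_len(h)) {
      if (mask[i, j] == 1 && !seen[i, j]) {
        n <- n + 1L
        queue <- list(c(i, j))
        seen[i, j] <- TRUE
        while (length(queue)) {
          p <- queue[[length(queue)]]
          queue[[length(queue)]] <- NULL
          for (di in -1:1) for (dj in -1:1) {
            ii <- p[1] + di
            jj <- p[2] + dj
            if (ii >= 1 && ii <= h && jj >= 1 && jj <= w &&
                mask[ii, jj] == 1 && !seen[ii, jj]) {
              seen[ii, jj] <- TRUE
              queue[[length(queue) + 1L]] <- c(ii, jj)
            }
          }
        }
      }
    }
  }
  n
}

# exhaustive per-pixel minimum distance to any pixel of one cell
oracle_distance <- function(cell_mask) {
  px <- which(cell_mask == 1, arr.ind = TRUE)
  d <- matrix(Inf, nrow(cell_mask), ncol(cell_mask))
  for (j in seq_len(ncol(cell_mask))) {
    for (i in seq_len(nrow(cell_mask))) {
      d[i, j] <- sqrt(min((px[, 1] - i)^2 + (px[, 2] - j)^2))
    }
  }
  d
}

# maximum-cardinality bipartite matching (Kuhn augmenting paths) on the
# distance-feasibility graph
oracle_max_matching <- function(adj) {
  nt <- nrow(adj)
  np <- ncol(adj)
  if (nt == 0 || np == 0) return(0L)
  matchp <- rep(0L, np)
  seen <- rep(FALSE, np)
  try_augment <- function(t) {
    for (p in which(adj[t, , drop = FALSE])) {
      if (!seen[p]) {
        seen[p] <<- TRUE
        if (matchp[p] == 0L || try_augment(matchp[p])) {
          matchp[p] <<- t
          return(TRUE)
        }
      }
    }
    FALSE
  }
  n <- 0L
  for (t in seq_len(nt)) {
    seen <- rep(FALSE, np)
    if (try_augment(t)) n <- n + 1L
  }
  n
}

# textbook knee point of a decreasing concave curve: normalize both axes,
# build the difference curve against the descending diagonal, take its
# maximum (independent of the package's chord construction)
oracle_kneedle_decreasing <- function(x, y) {
  xn <- (x - min(x)) / (max(x) - min(x))
  yn <- (y - min(y)) / (max(y) - min(y))
  # flip a decreasing curve into the increasing-concave orientation
  yd <- yn - (1 - xn)
  which.max(yd)
}

disc_mask <- function(h, w, centers, radius) {
  m <- matrix(0L, h, w)
  for (k in seq_len(nrow(centers))) {
    sel <- (row(m) - centers[k, 1])^2 + (col(m) - centers[k, 2])^2 <=
      radius^2
    m[sel] <- 1L
  }
  m
}

# study conditions of the desk-scale training check: small crops with a few
# well-separated bright cells and no distractors
easy_synth_spec <- function() {
  synthetic_spec(height = 128L, width = 128L, n_cells_range = c(2L, 5L),
                 mean_diameter = 20, diameter_sd = 3,
                 intensity_range = c(150, 255),
                 background_level_range = c(10, 40),
                 background_texture_scale = 40, clump_fraction = 0,
                 artifact_rate = 0, filament_rate = 0, noise_sd = 3)
}

easy_stream <- function(n, seed0, wm_params = weight_map_params(
                          sigma = 10, max_radius = 30)) {
  spec <- easy_synth_spec()
  lapply(seq_len(n), function(i) {
    o <- generate_image(spec, seed0 + i)
    list(image = o$image, mask = o$mask,
         wmap = build_weight_map(o$mask, wm_params))
  })
}
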