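# Shared raster helpers: resizing and coordinate-based resampling.

clampv <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# bilinear upscale/downscale of a matrix to out_h x out_w
bilinear_resize <- function(m, out_h, out_w) {
  h <- nrow(m)
  w <- ncol(m)
  r <- clampv((seq_len(out_h) - 0.5) / out_h * h + 0.5, 1, h)
  c <- clampv((seq_len(out_w) - 0.5) / out_w * w + 0.5, 1, w)
  r0 <- floor(r)
  c0 <- floor(c)
  fr <- r - r0
  fc <- c - c0
  r1 <- pmin(r0 + 1, h)
  c1 <- pmin(c0 + 1, w)
  m[r0, c0, drop = FALSE] * outer(1 - fr, 1 - fc) +
    m[r1, c0, drop = FALSE] * outer(fr, 1 - fc) +
    m[r0, c1, drop = FALSE] * outer(1 - fr, fc) +
    m[r1, c1, drop = FALSE] * outer(fr, fc)
}

# gather matrix values at fractional (rows, cols); out-of-range -> fill
bilinear_gather <- function(m, rows, cols, fill = 0) {
  h <- nrow(m)
  w <- ncol(m)
  rows <- as.vector(rows)
  cols <- as.vector(cols)
  inside <- rows >= 1 & rows <= h & cols >= 1 & cols <= w
  r <- clampv(rows, 1, h)
  c <- clampv(cols, 1, w)
  r0 <- floor(r)
  c0 <- floor(c)
  r1 <- pmin(r0 + 1, h)
  c1 <- pmin(c0 + 1, w)
  fr <- r - r0
  fc <- c - c0
  v <- m[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    m[cbind(r1, c0)] * fr * (1 - fc) +
    m[cbind(r0, c1)] * (1 - fr) * fc +
    m[cbind(r1, c1)] * fr * fc
  v[!inside] <- fill
  v
}

nearest_gather <- function(m, rows, cols, fill = 0) {
  h <- nrow(m)
  w <- ncol(m)
  rows <- as.vector(rows)
  cols <- as.vector(cols)
  r <- round(rows)
  c <- round(cols)
  inside <- r >= 1 & r <= h & c >= 1 & c <= w
  v <- m[cbind(clampv(r, 1, h), clampv(c, 1, w))]
  v[!inside] <- fill
  v
}

# run a function with a temporary RNG state, restoring the caller's
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv())
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, globalenv())
  })
  set.seed(seed)
  expr
}
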