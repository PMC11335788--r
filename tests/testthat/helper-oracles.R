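# Independent oracles used across the suite. These deliberately avoid the
# package's code paths: reference formulas and brute-force loops only.

# CIE 1976 L* of an sRGB triplet (0-255), returned on the 0-255 scale
oracle_lightness <- function(rgb) {
  lin <- function(u) ifelse(u <= 0.04045, u / 12.92, ((u + 0.055) / 1.055)^2.4)
  y <- sum(lin(rgb / 255) * c(0.2126729, 0.7151522, 0.0721750))
  f <- function(t) if (t > (6 / 29)^3) t^(1 / 3) else t / (3 * (6 / 29)^2) + 4 / 29
  (116 * f(y) - 16) * 255 / 100
}

# direct O(n^2) causal convolution truncated to length(x)
oracle_convolve <- function(x, kernel) {
  n <- length(x); m <- length(kernel)
  out <- numeric(n)
  for (i in seq_len(n)) {
    jmax <- min(i, m)
    out[i] <- sum(kernel[seq_len(jmax)] * x[i - seq_len(jmax) + 1])
  }
  out
}

# brute-force threshold-then-greedy event detection
oracle_detect <- function(x, dt, threshold, min_sep) {
  keep <- integer(0); last <- -Inf
  for (i in seq_along(x)) {
    if (abs(x[i]) >= threshold && (i - 1) * dt - last >= min_sep) {
      keep <- c(keep, i); last <- (i - 1) * dt
    }
  }
  keep
}

# per-rectangle mean by nested loops (equal blocks, last absorbs remainder)
oracle_region_means <- function(canvas, rows, cols) {
  h <- nrow(canvas); w <- ncol(canvas)
  bh <- h %/% rows; bw <- w %/% cols
  out <- numeric(rows * cols)
  for (i in seq_len(rows)) {
    for (j in seq_len(cols)) {
      r1 <- (i - 1) * bh + 1; r2 <- if (i == rows) h else i * bh
      c1 <- (j - 1) * bw + 1; c2 <- if (j == cols) w else j * bw
      acc <- 0; cnt <- 0
      for (r in r1:r2) for (cc in c1:c2) { acc <- acc + canvas[r, cc]; cnt <- cnt + 1 }
      out[(i - 1) * cols + j] <- acc / cnt
    }
  }
  out
}

# uniform gray RGB frame
gray_frame <- function(g, height = 48, width = 64)
  array(g, dim = c(height, width, 3))

# event traces with a single active region carrying the given change series
single_region_traces <- function(change, region = 1, dt = 0.04,
                                 grid = region_grid()) {
  n <- length(change)
  L <- matrix(0, n, grid$rows * grid$cols)
  L[, region] <- change
  event_traces((seq_len(n) - 1) * dt, L, grid = grid, fps = 1 / dt)
}
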