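# Independent oracles and fixture builders used across the suite.

# Naive set-shift binary morphology. Border convention matches classical
# definitions on the infinite plane: erosion pads with 1, dilation with 0.
naive_shift <- function(m, dy, dx, fill) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  ys <- max(1, 1 - dy):min(nr, nr - dy)
  xs <- max(1, 1 - dx):min(nc, nc - dx)
  out[ys + dy, xs + dx] <- m[ys, xs]
  out
}

naive_erode <- function(m, k) {
  r <- (k - 1) / 2
  out <- matrix(1L, nrow(m), ncol(m))
  for (dy in -r:r) for (dx in -r:r)
    out <- out & naive_shift(m, dy, dx, fill = 1L)
  out + 0L
}

naive_dilate <- function(m, k) {
  r <- (k - 1) / 2
  out <- matrix(0L, nrow(m), ncol(m))
  for (dy in -r:r) for (dx in -r:r)
    out <- out | naive_shift(m, dy, dx, fill = 0L)
  out + 0L
}

naive_open <- function(m, k) naive_dilate(naive_erode(m, k), k)
naive_close <- function(m, k) naive_erode(naive_dilate(m, k), k)

# Brute-force Otsu on the same 256-bin rescaling of an ExG field: try every
# threshold, compute between-class variance from first principles.
brute_otsu_mask <- function(field) {
  v <- pmin(pmax(field, -1), 2)
  bin <- pmin(255L, as.integer(floor((v + 1) / 3 * 256)))
  best_t <- -1; best_s <- -Inf
  for (t in 0:254) {
    lo <- bin[bin <= t]; hi <- bin[bin > t]
    if (!length(lo) || !length(hi)) s <- 0
    else {
      w0 <- length(lo) / length(bin); w1 <- 1 - w0
      s <- w0 * w1 * (mean(lo) - mean(hi))^2
    }
    if (s > best_s + 1e-12) { best_s <- s; best_t <- t }
  }
  out <- (bin > best_t) + 0L
  dim(out) <- dim(field)
  out
}

# Binary mask with vertical strips (full height) and optional uniform scatter.
strip_mask <- function(h = 80, w = 120, centers = c(20, 60, 100),
                       strip_w = 4, scatter_frac = 0, seed = 1) {
  m <- matrix(0L, h, w)
  labels <- matrix(0L, h, w)
  for (i in seq_along(centers)) {
    cols <- round(centers[i] - strip_w / 2 + 1):round(centers[i] + strip_w / 2)
    cols <- cols[cols >= 1 & cols <= w]
    m[, cols] <- 1L
    labels[, cols] <- i
  }
  if (scatter_frac > 0) {
    set.seed(seed)
    n <- round(scatter_frac * h * w)
    idx <- sample(which(m == 0L), n)
    m[idx] <- 1L
  }
  list(mask = m, labels = labels)
}

# Points (x, y) sampled on a near-vertical line with jitter plus uniform
# contamination inside a box; returns list(points, slope_true_deg).
contaminated_line_points <- function(n_in = 70, n_out = 30, x0 = 50,
                                     slope_a = 0, h = 80, w = 120, seed = 1) {
  set.seed(seed)
  y <- runif(n_in, 0, h - 1)
  x <- x0 + slope_a * y + runif(n_in, -0.5, 0.5)
  ox <- runif(n_out, 0, w - 1); oy <- runif(n_out, 0, h - 1)
  list(points = cbind(x = c(x, ox), y = c(y, oy)),
       slope_true_deg = (atan2(1, slope_a) * 180 / pi) %% 180)
}

# Two solid vertical strips joined by a sparse horizontal weed band.
bridged_mask <- function(h = 80, w = 120, c1 = 30, c2 = 90, strip_w = 6,
                         band_y = 30:50, fill = 0.3, seed = 1) {
  set.seed(seed)
  m <- matrix(0L, h, w)
  half <- strip_w / 2
  m[, (c1 - half + 1):(c1 + half)] <- 1L
  m[, (c2 - half + 1):(c2 + half)] <- 1L
  bridge_cols <- (c1 + half + 1):(c2 - half)
  bridge <- matrix(runif(length(band_y) * length(bridge_cols)) < fill,
                   length(band_y), length(bridge_cols))
  bridge_idx <- which(bridge, arr.ind = TRUE)
  m[cbind(band_y[bridge_idx[, 1]], bridge_cols[bridge_idx[, 2]])] <- 1L
  list(mask = m,
       bridge_pts = cbind(x = bridge_cols[bridge_idx[, 2]] - 1,
                          y = band_y[bridge_idx[, 1]] - 1))
}

# Canonical point-set equality for (x, y) matrices.
sort_pts <- function(p) p[order(p[, 1], p[, 2]), , drop = FALSE]
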