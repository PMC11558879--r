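# Planar geometry: ROI cropping, 4-point homography estimation, projective
# warping. Coordinate convention throughout the package: 0-based pixel
# indices, origin at the top-left corner, x rightward, y downward. A matrix
# element m[i, j] holds the pixel at (x = j - 1, y = i - 1).

#' Rectangular region of interest
#'
#' @param x0,y0 0-based pixel offsets of the ROI top-left corner in the full
#'   frame.
#' @param width,height ROI extent in pixels; both must be positive.
#' @return An object of class `roi_rect`.
#' @export
roi_rect <- function(x0, y0, width, height) {
  stopifnot(is.numeric(x0), is.numeric(y0), is.numeric(width), is.numeric(height))
  if (width <= 0 || height <= 0)
    stop("roi_rect: width and height must be positive")
  structure(list(x0 = as.numeric(x0), y0 = as.numeric(y0),
                 width = as.numeric(width), height = as.numeric(height)),
            class = "roi_rect")
}

#' @export
print.roi_rect <- function(x, ...) {
  cat(sprintf("<roi_rect %gx%g at (%g, %g)>\n", x$width, x$height, x$x0, x$y0))
  invisible(x)
}

image_dims <- function(image) {
  d <- dim(image)
  c(height = d[1], width = d[2])
}

#' Crop a region of interest out of an image
#'
#' Pixel values are copied unchanged; the ROI offset is recorded in the
#' `"roi_offset"` attribute so detections can later be projected back onto
#' the full frame.
#'
#' @param image Matrix (grayscale/mask) or h x w x 3 array (RGB).
#' @param roi A [roi_rect()].
#' @return Cropped raster of exactly `roi$width` x `roi$height` pixels.
#' @export
crop_roi <- function(image, roi) {
  stopifnot(inherits(roi, "roi_rect"))
  d <- image_dims(image)
  if (roi$x0 < 0) stop("crop_roi: ROI crosses the left image edge")
  if (roi$y0 < 0) stop("crop_roi: ROI crosses the top image edge")
  if (roi$x0 + roi$width > d[["width"]])
    stop("crop_roi: ROI crosses the right image edge")
  if (roi$y0 + roi$height > d[["height"]])
    stop("crop_roi: ROI crosses the bottom image edge")
  rows <- seq(roi$y0 + 1, roi$y0 + roi$height)
  cols <- seq(roi$x0 + 1, roi$x0 + roi$width)
  out <- if (length(dim(image)) == 3) image[rows, cols, , drop = FALSE]
         else image[rows, cols, drop = FALSE]
  attr(out, "roi_offset") <- c(x0 = roi$x0, y0 = roi$y0)
  out
}

#' Normalize a 3x3 matrix into a homography (h33 = 1)
#'
#' @param h A 3x3 numeric matrix, non-singular.
#' @param det_floor Smallest admissible |det| after normalization.
#' @return 3x3 matrix with `h[3, 3] == 1`.
#' @export
as_homography <- function(h, det_floor = 1e-12) {
  h <- as.matrix(h)
  stopifnot(all(dim(h) == c(3, 3)))
  if (abs(h[3, 3]) < .Machine$double.eps * 1e3)
    stop("as_homography: h33 is (near) zero, cannot normalize")
  h <- h / h[3, 3]
  if (abs(det(h)) < det_floor)
    stop("as_homography: matrix is singular (|det| below floor)")
  h
}

# Twice the signed triangle area of points p1, p2, p3 (rows of 2-col matrix).
.tri_area2 <- function(p1, p2, p3) {
  (p2[1] - p1[1]) * (p3[2] - p1[2]) - (p3[1] - p1[1]) * (p2[2] - p1[2])
}

.any_collinear <- function(pts, rel_tol = 1e-6) {
  span <- max(apply(pts, 2, function(v) diff(range(v))), .Machine$double.eps)
  combs <- utils::combn(nrow(pts), 3)
  for (k in seq_len(ncol(combs))) {
    i <- combs[, k]
    a2 <- abs(.tri_area2(pts[i[1], ], pts[i[2], ], pts[i[3], ])) / 2
    if (a2 < rel_tol * span^2) return(TRUE)
  }
  FALSE
}

#' Estimate a homography from exactly four point correspondences
#'
#' Fixing h33 = 1 leaves eight unknowns; four correspondences give eight
#' linear equations (two per pair), solved directly. If the 8x8 system is
#' ill-conditioned (condition number above `cond_max`) a least-squares
#' solve is used instead. No three source points and no three destination
#' points may be collinear.
#'
#' @param src,dst 4x2 matrices of (x, y) coordinates; row i of `src`
#'   corresponds to row i of `dst`.
#' @param collinear_tol Relative triangle-area tolerance used for the
#'   collinearity test (area below `collinear_tol * span^2` is degenerate).
#' @param cond_max Condition-number threshold for the least-squares fallback.
#' @return 3x3 homography matrix H with `H[3,3] == 1` mapping
#'   `src` to `dst` homogeneous coordinates.
#' @export
estimate_homography <- function(src, dst, collinear_tol = 1e-6, cond_max = 1e12) {
  src <- as.matrix(src); dst <- as.matrix(dst)
  if (!all(dim(src) == c(4, 2)) || !all(dim(dst) == c(4, 2)))
    stop("estimate_homography: src and dst must each be 4x2 matrices")
  if (!all(is.finite(src)) || !all(is.finite(dst)))
    stop("estimate_homography: coordinates must be finite")
  if (.any_collinear(src, collinear_tol))
    stop("estimate_homography: degenerate configuration, three source points are collinear")
  if (.any_collinear(dst, collinear_tol))
    stop("estimate_homography: degenerate configuration, three destination points are collinear")

  A <- matrix(0, 8, 8)
  b <- numeric(8)
  for (i in 1:4) {
    x <- src[i, 1]; y <- src[i, 2]
    xp <- dst[i, 1]; yp <- dst[i, 2]
    A[2 * i - 1, ] <- c(x, y, 1, 0, 0, 0, -xp * x, -xp * y)
    A[2 * i, ]     <- c(0, 0, 0, x, y, 1, -yp * x, -yp * y)
    b[2 * i - 1] <- xp
    b[2 * i]     <- yp
  }
  kappa <- kappa(A, exact = FALSE)
  if (!is.finite(kappa) || kappa > cond_max) {
    h <- tryCatch(qr.solve(A, b), error = function(e)
      stop("estimate_homography: rank-deficient system"))
  } else {
    h <- tryCatch(solve(A, b), error = function(e)
      stop("estimate_homography: rank-deficient system"))
  }
  as_homography(matrix(c(h, 1), 3, 3, byrow = TRUE))
}

#' Apply a homography to points
#'
#' Maps each (x, y) to ((h11 x + h12 y + h13) / w, (h21 x + h22 y + h23) / w)
#' with w = h31 x + h32 y + h33.
#'
#' @param H 3x3 homography matrix.
#' @param pts n x 2 matrix (or length-2 vector) of (x, y) coordinates.
#' @param tol Points whose homogeneous denominator |w| falls below `tol` map
#'   to infinity and raise an error.
#' @return n x 2 matrix of transformed coordinates.
#' @export
apply_homography <- function(H, pts, tol = 1e-9) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2)
  pts <- as.matrix(pts)
  stopifnot(ncol(pts) == 2, all(dim(H) == c(3, 3)))
  w <- H[3, 1] * pts[, 1] + H[3, 2] * pts[, 2] + H[3, 3]
  if (any(abs(w) < tol))
    stop("apply_homography: point maps to infinity (homogeneous denominator below tolerance)")
  cbind(x = (H[1, 1] * pts[, 1] + H[1, 2] * pts[, 2] + H[1, 3]) / w,
        y = (H[2, 1] * pts[, 1] + H[2, 2] * pts[, 2] + H[2, 3]) / w)
}

#' Invert a homography
#'
#' @param H 3x3 non-singular homography matrix.
#' @return The inverse, normalized so its (3,3) entry is 1.
#' @export
invert_homography <- function(H) {
  stopifnot(all(dim(H) == c(3, 3)))
  inv <- tryCatch(solve(H), error = function(e)
    stop("invert_homography: matrix is singular"))
  as_homography(inv)
}

# Bilinear sample of a single-channel matrix at (x, y) 0-based coordinates.
# Out-of-bounds samples return `fill`.
.bilinear_sample <- function(m, x, y, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0;   fy <- y - y0
  inb <- x0 >= 0 & y0 >= 0 & x0 <= nc - 1 & y0 <= nr - 1
  # clamp the +1 neighbours so edge pixels interpolate against themselves
  xi0 <- pmin(pmax(x0, 0), nc - 1); yi0 <- pmin(pmax(y0, 0), nr - 1)
  xi1 <- pmin(xi0 + 1, nc - 1);     yi1 <- pmin(yi0 + 1, nr - 1)
  idx <- function(yy, xx) yy + 1 + xx * nr   # column-major linear index
  v <- (1 - fx) * (1 - fy) * m[idx(yi0, xi0)] +
       fx       * (1 - fy) * m[idx(yi0, xi1)] +
       (1 - fx) * fy       * m[idx(yi1, xi0)] +
       fx       * fy       * m[idx(yi1, xi1)]
  v[!inb] <- fill
  v
}

#' Warp an image with a homography
#'
#' The output is sampled by inverse mapping: output pixel p receives the
#' bilinear interpolation of the input at H^-1 p. Pixels mapping outside the
#' source are set to `fill`.
#'
#' @param image Matrix or h x w x 3 array.
#' @param H 3x3 homography taking input coordinates to output coordinates.
#' @param out_size `c(width, height)` of the output raster; defaults to the
#'   input size.
#' @param fill Fill value (scalar, or length-3 for RGB input).
#' @return Warped raster of the requested size.
#' @export
warp_image <- function(image, H, out_size = NULL, fill = 0) {
  Hinv <- invert_homography(H)   # errors on singular H
  d <- image_dims(image)
  if (is.null(out_size)) out_size <- c(d[["width"]], d[["height"]])
  w <- out_size[1]; h <- out_size[2]
  grid <- cbind(x = rep(seq_len(w) - 1, each = h),
                y = rep(seq_len(h) - 1, times = w))
  srcp <- apply_homography(Hinv, grid)
  if (length(dim(image)) == 3) {
    nch <- dim(image)[3]
    fill <- rep_len(fill, nch)
    out <- array(0, c(h, w, nch))
    for (k in seq_len(nch))
      out[, , k] <- matrix(.bilinear_sample(image[, , k], srcp[, 1], srcp[, 2],
                                            fill[k]), h, w)
  } else {
    out <- matrix(.bilinear_sample(image, srcp[, 1], srcp[, 2], fill), h, w)
  }
  out
}

#' Warp a binary mask with a homography
#'
#' Bilinear warp followed by thresholding at 0.5, so the result stays binary.
#'
#' @inheritParams warp_image
#' @param mask Binary 0/1 matrix.
#' @return Binary 0/1 matrix of the requested size.
#' @export
warp_mask <- function(mask, H, out_size = NULL) {
  out <- warp_image(mask + 0, H, out_size, fill = 0)
  (out >= 0.5) + 0L
}
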