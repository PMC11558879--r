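# Vegetation segmentation: chromaticity normalization, Excess Green index,
# Otsu binarization, morphological cleanup.

#' Chromaticity normalization of an RGB image
#'
#' Each channel is first scaled by its maximum (Rn = R / Rmax etc.), then
#' divided by the per-pixel channel sum with a minute constant added to the
#' denominator to guard against division by zero. The resulting r, g, b
#' planes sum to (almost exactly) 1 at every pixel with nonzero intensity
#' and are illumination-robust: a shadow that scales all channels equally
#' leaves them unchanged.
#'
#' @param image h x w x 3 array with nonnegative values (any scale; 0-1 and
#'   0-255 both work).
#' @param epsilon Guard constant added to the per-pixel denominator.
#' @param fixed_max If `TRUE`, use the nominal full-scale value (255 for
#'   integer-scaled input, 1 otherwise) instead of per-image channel maxima.
#' @return List with matrices `r`, `g`, `b`, class `chromaticity`.
#' @export
normalize_channels <- function(image, epsilon = 1e-8, fixed_max = FALSE) {
  if (length(dim(image)) != 3 || dim(image)[3] != 3)
    stop("normalize_channels: input must have exactly 3 channels")
  if (min(image) < 0)
    stop("normalize_channels: negative pixel values")
  mx <- if (fixed_max) rep(if (max(image) > 1) 255 else 1, 3)
        else apply(image, 3, max)
  mx[mx <= 0] <- 1   # an all-zero channel normalizes to zero
  Rn <- image[, , 1] / mx[1]
  Gn <- image[, , 2] / mx[2]
  Bn <- image[, , 3] / mx[3]
  s <- Rn + Gn + Bn + epsilon
  structure(list(r = Rn / s, g = Gn / s, b = Bn / s), class = "chromaticity")
}

#' Excess Green vegetation index
#'
#' ExG = 2g - r - b on chromaticity planes. Under r + g + b = 1 this equals
#' 3g - 1, so values lie in \[-1, 2\]: 2 for pure green, 0 for gray, -1 for
#' a green-free pixel.
#'
#' @param planes A `chromaticity` object from [normalize_channels()].
#' @return Matrix of ExG values.
#' @export
excess_green <- function(planes) {
  stopifnot(inherits(planes, "chromaticity") ||
              all(c("r", "g", "b") %in% names(planes)))
  d <- dim(planes$r)
  if (!identical(d, dim(planes$g)) || !identical(d, dim(planes$b)))
    stop("excess_green: chromaticity planes have mismatched shapes")
  2 * planes$g - planes$r - planes$b
}

# Exhaustive Otsu scan over a 256-bin histogram of counts. Returns the
# 0-based bin index t maximizing between-class variance for the split
# {bins <= t} vs {bins > t}; ties broken by the lowest t.
.otsu_scan <- function(counts) {
  n <- sum(counts)
  bins <- seq_along(counts) - 1
  w0 <- cumsum(counts)
  sum0 <- cumsum(counts * bins)
  mu_t <- sum0[length(counts)] / n
  w0n <- w0 / n
  mu0 <- ifelse(w0 > 0, sum0 / w0, 0)
  w1n <- 1 - w0n
  mu1 <- ifelse(w1n > 0, (mu_t - w0n * mu0) / w1n, 0)
  sigma_b <- w0n * w1n * (mu0 - mu1)^2
  sigma_b <- sigma_b[-length(sigma_b)]   # threshold after the last bin splits nothing
  which.max(sigma_b) - 1                 # which.max takes the first (lowest) max
}

#' Binarize an Excess Green field with Otsu's method
#'
#' The field is linearly rescaled from \[-1, 2\] into 256 histogram bins and
#' the threshold maximizing between-class variance is found by exhaustive
#' scan (ties broken toward the lowest threshold). Pixels strictly above the
#' threshold become foreground.
#'
#' @param field Matrix of ExG values in \[-1, 2\].
#' @return Binary 0/1 integer matrix (1 = vegetation) with attributes
#'   `threshold` (on the ExG scale) and, for a constant input, a
#'   `constant_field` warning flag (the mask is then all zero).
#' @export
otsu_binarize <- function(field) {
  stopifnot(is.matrix(field))
  if (diff(range(field)) == 0) {
    warning("otsu_binarize: constant field, returning an all-zero mask")
    out <- matrix(0L, nrow(field), ncol(field))
    attr(out, "constant_field") <- TRUE
    return(out)
  }
  v <- pmin(pmax(field, -1), 2)
  bin <- pmin(255L, as.integer(floor((v + 1) / 3 * 256)))
  counts <- tabulate(bin + 1L, nbins = 256L)
  t_bin <- .otsu_scan(counts)
  out <- (bin > t_bin) + 0L
  dim(out) <- dim(field)
  attr(out, "threshold") <- -1 + 3 * (t_bin + 1) / 256   # upper edge of bin t
  out
}

#' Morphological cleanup of a binary mask
#'
#' Binary opening (removes small foreground specks) followed by closing
#' (fills small holes), both with square structuring elements. A kernel size
#' of 1 disables that stage.
#'
#' @param mask Binary 0/1 matrix.
#' @param open_kernel_px,close_kernel_px Odd side lengths (pixels) of the
#'   square structuring elements.
#' @return Cleaned binary 0/1 integer matrix.
#' @export
morph_clean <- function(mask, open_kernel_px = 3, close_kernel_px = 3) {
  for (k in c(open_kernel_px, close_kernel_px))
    if (k < 1 || k %% 2 == 0)
      stop("morph_clean: kernel sizes must be odd and >= 1")
  m <- mask + 0
  if (open_kernel_px > 1)
    m <- EBImage::opening(m, EBImage::makeBrush(open_kernel_px, shape = "box"))
  if (close_kernel_px > 1)
    m <- EBImage::closing(m, EBImage::makeBrush(close_kernel_px, shape = "box"))
  out <- (as.matrix(m) > 0.5) + 0L
  dim(out) <- dim(mask)
  out
}

#' Segment vegetation in one call
#'
#' Convenience chain: [normalize_channels()] -> [excess_green()] ->
#' [otsu_binarize()] -> [morph_clean()].
#'
#' @inheritParams normalize_channels
#' @inheritParams morph_clean
#' @return Binary 0/1 vegetation mask.
#' @export
segment_vegetation <- function(image, epsilon = 1e-8, fixed_max = FALSE,
                               open_kernel_px = 3, close_kernel_px = 3) {
  exg <- excess_green(normalize_channels(image, epsilon, fixed_max))
  mask <- suppressWarnings(otsu_binarize(exg))
  if (isTRUE(attr(mask, "constant_field"))) return(mask)
  morph_clean(mask, open_kernel_px, close_kernel_px)
}
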