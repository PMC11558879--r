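# Raster and table I/O plus simple overlay rendering.

#' Read an RGB image (PNG or TIFF)
#'
#' @param path Image file; `.png` or `.tif`/`.tiff`.
#' @return h x w x 3 numeric array in 0-1 (gray input is replicated to 3
#'   channels, an alpha channel is dropped).
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("read_image: the 'tiff' package is needed for TIFF input")
      tiff::readTIFF(path)
    },
    stop("read_image: unsupported image format '", ext, "'"))
  if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
  if (dim(img)[3] > 3) img <- img[, , 1:3, drop = FALSE]
  img
}

#' Write an RGB image or mask as PNG
#'
#' Binary masks are written with values 0 and 255.
#'
#' @param image h x w x 3 array in 0-1, or a binary 0/1 matrix.
#' @param path Output `.png` path.
#' @export
write_image <- function(image, path) {
  if (is.matrix(image)) image <- image + 0   # 0/1 mask -> 0/1 gray = 0/255 PNG
  png::writePNG(pmin(pmax(image, 0), 1), path)
  invisible(path)
}

#' Read / write line tables as CSV
#'
#' Schema: `image_id, frame, x_top, y_top, x_bottom, y_bottom, slope_deg,
#' inlier_count`. Ground-truth files may omit `frame`, `slope_deg` and
#' `inlier_count`.
#'
#' @param path CSV path.
#' @return `read_lines_csv` returns a line `data.frame`.
#' @export
read_lines_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("x_top", "y_top", "x_bottom", "y_bottom")
  if (!all(need %in% names(d)))
    stop("read_lines_csv: missing columns ", paste(setdiff(need, names(d)), collapse = ", "))
  row_lines(d$x_top, d$y_top, d$x_bottom, d$y_bottom,
            frame = if ("frame" %in% names(d)) d$frame else "camera",
            inlier_count = if ("inlier_count" %in% names(d)) d$inlier_count else NA_integer_,
            image_id = if ("image_id" %in% names(d)) d$image_id else NA_character_)
}

#' @rdname read_lines_csv
#' @param lines Line `data.frame`.
#' @export
write_lines_csv <- function(lines, path) {
  utils::write.csv(lines, path, row.names = FALSE)
  invisible(path)
}

#' Draw lines onto an RGB image
#'
#' Simple rasterization for overlay output: each segment is sampled at
#' half-pixel steps and painted with the given color and thickness.
#'
#' @param image h x w x 3 array in 0-1.
#' @param lines Line `data.frame` in the image's coordinate frame.
#' @param color Length-3 RGB in 0-1.
#' @param thickness Stroke half-width in pixels.
#' @return The annotated image array.
#' @export
draw_lines <- function(image, lines, color = c(1, 0, 0), thickness = 1) {
  h <- dim(image)[1]; w <- dim(image)[2]
  for (i in seq_len(nrow(lines))) {
    l <- lines[i, ]
    len <- sqrt((l$x_bottom - l$x_top)^2 + (l$y_bottom - l$y_top)^2)
    t <- seq(0, 1, length.out = max(2, ceiling(len * 2)))
    px <- round(l$x_top + t * (l$x_bottom - l$x_top))
    py <- round(l$y_top + t * (l$y_bottom - l$y_top))
    for (dx in -thickness:thickness) for (dy in -thickness:thickness) {
      xs <- px + dx; ys <- py + dy
      ok <- xs >= 0 & xs < w & ys >= 0 & ys < h
      for (k in 1:3) image[cbind(ys[ok] + 1, xs[ok] + 1, k)] <- color[k]
    }
  }
  image
}

#' List the frames of an image-directory "video"
#'
#' Video input is handled as a directory of numbered PNG/TIFF frames.
#'
#' @param dir Directory path.
#' @return Character vector of frame paths in lexical order.
#' @export
list_frames <- function(dir) {
  f <- list.files(dir, pattern = "\\.(png|tif|tiff)$", ignore.case = TRUE,
                  full.names = TRUE)
  sort(f)
}
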