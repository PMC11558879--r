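# Robust per-cluster line fitting (RANSAC), slope gating, and mapping of
# fitted lines back to the camera frame. Lines are carried as data frames
# with one row per line, ready for CSV export:
#   image_id, frame, x_top, y_top, x_bottom, y_bottom, slope_deg, inlier_count

.slope_deg_of <- function(dx, dy) (atan2(dy, dx) * 180 / pi) %% 180

#' Build a line table from endpoints
#'
#' @param x_top,y_top,x_bottom,y_bottom Endpoint coordinates (pixels). The
#'   "top" endpoint is the one with the smaller y.
#' @param frame Coordinate frame tag, `"rectified"` or `"camera"`.
#' @param inlier_count Supporting-point count (RANSAC consensus, votes, ...).
#' @param image_id Identifier of the source image.
#' @return `data.frame` with one row per line; slope_deg is the orientation
#'   in degrees from the +x axis, in \[0, 180).
#' @export
row_lines <- function(x_top, y_top, x_bottom, y_bottom,
                      frame = "rectified", inlier_count = NA_integer_,
                      image_id = NA_character_) {
  n <- length(x_top)
  if (n && any(x_top == x_bottom & y_top == y_bottom))
    stop("row_lines: degenerate line with identical endpoints")
  data.frame(image_id = rep_len(image_id, n),
             frame = rep_len(frame, n),
             x_top = as.numeric(x_top), y_top = as.numeric(y_top),
             x_bottom = as.numeric(x_bottom), y_bottom = as.numeric(y_bottom),
             slope_deg = .slope_deg_of(x_bottom - x_top, y_bottom - y_top),
             inlier_count = as.integer(rep_len(inlier_count, n)),
             stringsAsFactors = FALSE)
}

#' Empty line table
#' @return Zero-row line `data.frame` with the standard columns.
#' @export
empty_lines <- function() {
  row_lines(numeric(0), numeric(0), numeric(0), numeric(0))
}

# Run expr with a temporarily-seeded RNG, restoring the caller's stream.
.with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = .GlobalEnv)
    else assign(".Random.seed", old, envir = .GlobalEnv)
  })
  set.seed(seed)
  expr
}

# Least-squares fit x = a*y + b (y as regressor; safe for near-vertical
# rows). Returns c(a, b), or NULL when all y coincide.
.fit_x_on_y <- function(pts) {
  y <- pts[, 2]; x <- pts[, 1]
  vy <- stats::var(y)
  if (!is.finite(vy) || vy == 0) return(NULL)
  a <- stats::cov(y, x) / vy
  c(a = a, b = mean(x) - a * mean(y))
}

.line_from_ab <- function(ab, y_extent, frame, inlier_count, image_id = NA_character_) {
  ys <- sort(y_extent)
  row_lines(x_top = ab[1] * ys[1] + ab[2], y_top = ys[1],
            x_bottom = ab[1] * ys[2] + ab[2], y_bottom = ys[2],
            frame = frame, inlier_count = inlier_count, image_id = image_id)
}

#' Fit a line to a point cloud with RANSAC
#'
#' Repeatedly samples two distinct points, counts the points within
#' `residual_tol_px` perpendicular distance of the implied line, and keeps
#' the consensus-maximal model. The number of iterations adapts to the best
#' inlier ratio w found so far: ceil(log(1 - confidence) / log(1 - w^2)),
#' capped at `max_iters`. The winning inlier set is refit by least squares
#' parameterized x = a*y + b, which stays finite for the near-vertical lines
#' expected after rectification.
#'
#' @param points n x 2 matrix of (x, y) pixel coordinates, n >= 2.
#' @param residual_tol_px Inlier distance tolerance (perpendicular, pixels).
#' @param confidence Target probability that an all-inlier sample was drawn.
#' @param max_iters Iteration cap.
#' @param seed Optional integer; fixes the sampling RNG for determinism
#'   without disturbing the caller's RNG stream.
#' @param y_extent Length-2 y range for the reported endpoints; defaults to
#'   the data's y range. Use `c(0, roi_height - 1)` to span the ROI.
#' @return One-row line `data.frame` (frame `"rectified"`), with
#'   `inlier_count` the winning consensus size.
#' @export
ransac_line <- function(points, residual_tol_px = 2, confidence = 0.99,
                        max_iters = 500, seed = NULL, y_extent = NULL) {
  pts <- as.matrix(points)
  if (nrow(pts) < 2)
    stop("ransac_line: insufficient data, need at least 2 points")
  if (all(pts[, 1] == pts[1, 1]) && all(pts[, 2] == pts[1, 2]))
    stop("ransac_line: degenerate input, all points identical")
  stopifnot(confidence > 0, confidence < 1)
  n <- nrow(pts)
  if (is.null(y_extent)) y_extent <- range(pts[, 2])

  .with_local_seed(seed, {
    best_count <- 0L
    best_inliers <- NULL
    i <- 0L
    N <- max_iters
    while (i < N) {
      i <- i + 1L
      s <- sample.int(n, 2)
      p1 <- pts[s[1], ]; p2 <- pts[s[2], ]
      d <- p2 - p1
      len <- sqrt(sum(d^2))
      if (len == 0) next
      nv <- c(-d[2], d[1]) / len
      resid <- abs((pts[, 1] - p1[1]) * nv[1] + (pts[, 2] - p1[2]) * nv[2])
      inl <- resid <= residual_tol_px
      cnt <- sum(inl)
      if (cnt > best_count) {
        best_count <- cnt
        best_inliers <- inl
        w <- cnt / n
        if (w >= 1) {
          N <- i
        } else {
          N <- min(max_iters,
                   ceiling(log(1 - confidence) / log(1 - w^2)))
        }
      }
    }
    # local optimization: refit, re-select inliers against the refit line,
    # repeat until the inlier set stabilizes (centres the fit on the row)
    inl <- best_inliers
    ab <- .fit_x_on_y(pts[inl, , drop = FALSE])
    if (!is.null(ab)) {
      for (it in 1:10) {
        resid <- abs(pts[, 1] - (ab[1] * pts[, 2] + ab[2])) / sqrt(1 + ab[1]^2)
        inl_new <- resid <= residual_tol_px
        if (identical(inl_new, inl) || sum(inl_new) < 2) break
        ab_new <- .fit_x_on_y(pts[inl_new, , drop = FALSE])
        if (is.null(ab_new)) break
        inl <- inl_new
        ab <- ab_new
      }
      best_count <- max(best_count, sum(inl))
    }
    if (is.null(ab)) {
      # inliers share one y: report the horizontal segment through them
      sub <- pts[inl, , drop = FALSE]
      return(row_lines(x_top = min(sub[, 1]), y_top = sub[1, 2],
                       x_bottom = max(sub[, 1]), y_bottom = sub[1, 2],
                       inlier_count = best_count))
    }
    .line_from_ab(ab, y_extent, "rectified", best_count)
  })
}

#' Keep only lines whose slope lies inside a window
#'
#' After rectification crop rows run near-vertical, so fitted lines with
#' slopes far from 90 degrees are spurious (weed alignments, mask artefacts)
#' and are discarded. The interval is closed on both ends.
#'
#' @param lines Line `data.frame`.
#' @param lo_deg,hi_deg Window bounds in degrees, `0 <= lo < hi <= 180`.
#' @return The filtered line table.
#' @export
filter_lines_by_slope <- function(lines, lo_deg = 70, hi_deg = 110) {
  stopifnot(lo_deg >= 0, hi_deg <= 180, lo_deg < hi_deg)
  lines[lines$slope_deg >= lo_deg & lines$slope_deg <= hi_deg, , drop = FALSE]
}

#' Map fitted lines from the rectified frame back to the camera frame
#'
#' Endpoints are passed through the inverse rectification homography and
#' offset by the ROI origin; slopes are recomputed in the camera frame.
#'
#' @param lines Line `data.frame` in the rectified frame.
#' @param H_inv Inverse of the rectification homography.
#' @param roi The [roi_rect()] that was cropped before rectification.
#' @return Line table with `frame = "camera"`.
#' @export
backproject_lines <- function(lines, H_inv, roi) {
  stopifnot(inherits(roi, "roi_rect"))
  if (!nrow(lines)) {
    out <- lines
    out$frame <- character(0)
    return(out)
  }
  p0 <- apply_homography(H_inv, cbind(lines$x_top, lines$y_top))
  p1 <- apply_homography(H_inv, cbind(lines$x_bottom, lines$y_bottom))
  out <- row_lines(x_top = p0[, 1] + roi$x0, y_top = p0[, 2] + roi$y0,
                   x_bottom = p1[, 1] + roi$x0, y_bottom = p1[, 2] + roi$y0,
                   frame = "camera", inlier_count = lines$inlier_count,
                   image_id = lines$image_id)
  out
}
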