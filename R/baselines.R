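# Baseline detectors operating on the same binary mask / cluster set inputs
# and emitting the same line tables as the main detector, so all methods are
# plug-compatible with the evaluation module.

#' Hough-transform row detector
#'
#' Edges of the binary mask (morphological boundary: mask minus its
#' erosion) vote in a standard (rho, theta) line accumulator. Lines with at
#' least `vote_threshold` votes are kept, filtered to the slope window, and
#' greedily merged: among lines whose mid-height x positions differ by less
#' than `merge_dist_px`, only the highest-vote one survives.
#'
#' @param mask Binary 0/1 matrix.
#' @param vote_threshold Minimum accumulator votes for a candidate line;
#'   defaults to a quarter of the mask height.
#' @param slope_window `c(lo, hi)` degrees, applied as in
#'   [filter_lines_by_slope()].
#' @param merge_dist_px Proximity-merge distance at mid height, pixels.
#' @param theta_step_deg,rho_step_px Accumulator resolution.
#' @return Line `data.frame` (frame `"rectified"`), `inlier_count` = votes.
#' @export
hough_rows <- function(mask, vote_threshold = NULL, slope_window = c(70, 110),
                       merge_dist_px = 10, theta_step_deg = 1, rho_step_px = 1) {
  h <- nrow(mask); w <- ncol(mask)
  if (is.null(vote_threshold)) vote_threshold <- floor(h / 4)
  if (!any(mask > 0)) return(empty_lines())

  er <- EBImage::erode(mask + 0, EBImage::makeBrush(3, shape = "box"))
  edges <- which(mask > 0 & as.matrix(er) < 0.5)
  if (!length(edges)) edges <- which(mask > 0)   # thin structures erode away
  ex <- (edges - 1) %/% h
  ey <- (edges - 1) %% h

  theta_deg <- seq(0, 180 - theta_step_deg, by = theta_step_deg)
  theta <- theta_deg * pi / 180
  diag_len <- sqrt(h^2 + w^2)
  nrho <- 2 * ceiling(diag_len / rho_step_px) + 1
  rho0 <- ceiling(diag_len / rho_step_px) + 1   # bin index of rho = 0
  acc <- matrix(0L, nrho, length(theta))
  for (j in seq_along(theta)) {
    rho <- ex * cos(theta[j]) + ey * sin(theta[j])
    bins <- round(rho / rho_step_px) + rho0
    tab <- tabulate(bins, nbins = nrho)
    acc[, j] <- tab
  }
  cand <- which(acc >= vote_threshold, arr.ind = TRUE)
  if (!nrow(cand)) return(empty_lines())

  votes <- acc[cand]
  rho_v <- (cand[, 1] - rho0) * rho_step_px
  th_v <- theta[cand[, 2]]
  slope <- (theta_deg[cand[, 2]] + 90) %% 180
  keep <- slope >= slope_window[1] & slope <= slope_window[2]
  if (!any(keep)) return(empty_lines())
  votes <- votes[keep]; rho_v <- rho_v[keep]; th_v <- th_v[keep]

  # endpoints at the top and bottom mask edges: x = (rho - y sin t)/cos t
  # (cos t is bounded away from 0 inside a near-vertical slope window)
  x_at <- function(y) (rho_v - y * sin(th_v)) / cos(th_v)
  x_top <- x_at(0); x_bot <- x_at(h - 1)
  x_mid <- x_at((h - 1) / 2)

  ord <- order(-votes, x_mid)
  taken <- logical(length(votes))
  sel <- integer(0)
  for (i in ord) {
    if (taken[i]) next
    sel <- c(sel, i)
    taken[abs(x_mid - x_mid[i]) < merge_dist_px] <- TRUE
  }
  out <- row_lines(x_top[sel], 0, x_bot[sel], h - 1,
                   frame = "rectified", inlier_count = votes[sel])
  out[order(out$x_top), , drop = FALSE]
}

#' Sliding-window row detector
#'
#' A `window_px` x `window_px` window tiles the mask (stride equal to the
#' window size). Each tile holding at least `min_fg_px` foreground pixels
#' contributes the centroid of its white pixels. Centroids are chained
#' top-to-bottom by nearest-x linking (gate of one window width), and an
#' ordinary least-squares line x = a*y + b is fit through every chain with
#' at least two centroids. Least squares makes this detector sensitive to
#' weed mass near a row — its documented failure mode.
#'
#' @param mask Binary 0/1 matrix.
#' @param window_px Window side, pixels (must not exceed the mask size).
#' @param min_fg_px Minimum foreground count for a valid tile centroid.
#' @return Line `data.frame` (frame `"rectified"`), `inlier_count` = number
#'   of chained centroids.
#' @export
sliding_window_rows <- function(mask, window_px = 20, min_fg_px = 10) {
  h <- nrow(mask); w <- ncol(mask)
  if (window_px > h || window_px > w)
    stop("sliding_window_rows: window larger than the mask")
  ys <- seq(1, h - window_px + 1, by = window_px)
  xs <- seq(1, w - window_px + 1, by = window_px)

  chains <- list()   # each: list(xs, ys) of chained centroids
  for (yi in ys) {
    band <- list()
    for (xi in xs) {
      tile <- mask[yi:(yi + window_px - 1), xi:(xi + window_px - 1)]
      idx <- which(tile > 0)
      if (length(idx) >= min_fg_px) {
        cx <- mean((idx - 1) %/% window_px) + (xi - 1)
        cy <- mean((idx - 1) %% window_px) + (yi - 1)
        band[[length(band) + 1]] <- c(cx, cy)
      }
    }
    for (cen in band) {
      best <- 0; bestd <- Inf
      for (ci in seq_along(chains)) {
        last_x <- tail(chains[[ci]]$xs, 1)
        d <- abs(last_x - cen[1])
        if (d < bestd && d <= window_px) { best <- ci; bestd <- d }
      }
      if (best > 0) {
        chains[[best]]$xs <- c(chains[[best]]$xs, cen[1])
        chains[[best]]$ys <- c(chains[[best]]$ys, cen[2])
      } else {
        chains[[length(chains) + 1]] <- list(xs = cen[1], ys = cen[2])
      }
    }
  }
  fits <- lapply(chains, function(ch) {
    if (length(ch$xs) < 2) return(NULL)
    ab <- .fit_x_on_y(cbind(ch$xs, ch$ys))
    if (is.null(ab)) return(NULL)
    .line_from_ab(ab, c(0, h - 1), "rectified", length(ch$xs))
  })
  fits <- fits[!vapply(fits, is.null, TRUE)]
  if (!length(fits)) return(empty_lines())
  out <- do.call(rbind, fits)
  out[order(out$x_top), , drop = FALSE]
}

#' Per-cluster least-squares row detector
#'
#' Ordinary least squares x = a*y + b through each cluster's points. Shares
#' the cluster pipeline of the main detector but lacks RANSAC's outlier
#' rejection, so contaminating weed pixels bias the fit.
#'
#' @param cs A `cluster_set` (after repair/pruning).
#' @param y_extent Endpoint y range; defaults to `c(0, mask height - 1)`.
#' @return Line `data.frame` (frame `"rectified"`), `inlier_count` = cluster
#'   size. Singleton clusters are skipped with a warning.
#' @export
cluster_leastsq_rows <- function(cs, y_extent = NULL) {
  stopifnot(inherits(cs, "cluster_set"))
  if (is.null(y_extent)) y_extent <- c(0, cs$dim[1] - 1)
  fits <- lapply(cs$clusters, function(cl) {
    if (cl$size < 2) {
      warning("cluster_leastsq_rows: skipping singleton cluster ", cl$label)
      return(NULL)
    }
    ab <- .fit_x_on_y(cl$points)
    if (is.null(ab)) return(NULL)
    .line_from_ab(ab, y_extent, "rectified", cl$size)
  })
  fits <- fits[!vapply(fits, is.null, TRUE)]
  if (!length(fits)) return(empty_lines())
  do.call(rbind, fits)
}
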