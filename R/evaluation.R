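# Evaluation protocol: each row line (truth or detection) becomes an
# axis-aligned bounding box capturing its height and width; boxes are
# compared by intersection over union, matched one-to-one, and summarized
# as accuracy, precision and recall.

#' Bounding box of a row line
#'
#' Axis-aligned box of the two endpoints, expanded by `half_width_px` in x.
#' If the raw extent in either axis is below 1 px (a vertical or horizontal
#' line has zero width or height), that axis is also expanded by
#' `half_width_px` so the box keeps positive area.
#'
#' @param line One-row line `data.frame` (or list with `x_top`, `y_top`,
#'   `x_bottom`, `y_bottom`).
#' @param half_width_px Half the nominal row width, pixels; must be > 0.
#' @return Named numeric vector `c(x_min, y_min, x_max, y_max)`.
#' @export
line_bbox <- function(line, half_width_px) {
  stopifnot(half_width_px > 0)
  xr <- range(c(line$x_top, line$x_bottom))
  yr <- range(c(line$y_top, line$y_bottom))
  xr <- xr + c(-1, 1) * half_width_px
  if (diff(yr) < 1) yr <- yr + c(-1, 1) * half_width_px
  c(x_min = xr[1], y_min = yr[1], x_max = xr[2], y_max = yr[2])
}

#' Intersection over union of two boxes
#'
#' @param a,b Boxes as returned by [line_bbox()].
#' @return Overlap area divided by union area; 0 for disjoint boxes, 1 for
#'   identical ones.
#' @export
iou <- function(a, b) {
  iw <- min(a["x_max"], b["x_max"]) - max(a["x_min"], b["x_min"])
  ih <- min(a["y_max"], b["y_max"]) - max(a["y_min"], b["y_min"])
  if (iw <= 0 || ih <= 0) return(0)
  inter <- iw * ih
  area <- function(z) (z["x_max"] - z["x_min"]) * (z["y_max"] - z["y_min"])
  unname(inter / (area(a) + area(b) - inter))
}

#' Match detections to ground truth and count TP/FP/FN
#'
#' Both line sets are converted to boxes ([line_bbox()]) and matched
#' greedily one-to-one by descending pairwise IOU. A matched pair with IOU
#' at least `tp_iou_threshold` is a true positive; unmatched (or
#' under-threshold) detections are false positives and unmatched truths
#' false negatives.
#'
#' @param detected,truth Line `data.frame`s in the same coordinate frame.
#' @param half_width_px Box half width, pixels.
#' @param tp_iou_threshold Minimum IOU for a true positive.
#' @return List `detection_counts`: `tp`, `fp`, `fn`, `mean_iou_matched`
#'   (mean IOU over TP pairs; `NA` when there are none).
#' @export
match_and_score <- function(detected, truth, half_width_px,
                            tp_iou_threshold = 0.5) {
  nd <- nrow(detected); nt <- nrow(truth)
  counts <- list(tp = 0L, fp = nd, fn = nt, mean_iou_matched = NA_real_)
  class(counts) <- "detection_counts"
  if (nd == 0 || nt == 0) return(counts)
  dbox <- lapply(seq_len(nd), function(i) line_bbox(detected[i, ], half_width_px))
  tbox <- lapply(seq_len(nt), function(i) line_bbox(truth[i, ], half_width_px))
  m <- matrix(0, nd, nt)
  for (i in seq_len(nd)) for (j in seq_len(nt)) m[i, j] <- iou(dbox[[i]], tbox[[j]])

  matched_iou <- numeric(0)
  dfree <- rep(TRUE, nd); tfree <- rep(TRUE, nt)
  repeat {
    m_av <- m
    m_av[!dfree, ] <- -1; m_av[, !tfree] <- -1
    best <- max(m_av)
    if (best <= 0) break
    ij <- which(m_av == best, arr.ind = TRUE)[1, ]
    dfree[ij[1]] <- FALSE; tfree[ij[2]] <- FALSE
    matched_iou <- c(matched_iou, best)
  }
  tp <- sum(matched_iou >= tp_iou_threshold)
  counts$tp <- as.integer(tp)
  counts$fp <- as.integer(nd - tp)
  counts$fn <- as.integer(nt - tp)
  counts$mean_iou_matched <- if (tp > 0) mean(matched_iou[matched_iou >= tp_iou_threshold]) else NA_real_
  counts$matched_ious <- matched_iou
  counts
}

#' Accuracy, precision and recall from detection counts
#'
#' precision = tp / (tp + fp); recall = tp / (tp + fn);
#' accuracy = tp / (tp + fp + fn). With this accuracy definition both
#' precision and recall always dominate accuracy.
#'
#' @param c A `detection_counts` list (or any list with `tp`, `fp`, `fn`).
#' @return Named list with `accuracy`, `precision`, `recall`.
#' @export
prf <- function(c) {
  tp <- c$tp; fp <- c$fp; fn <- c$fn
  if (tp + fp + fn == 0)
    stop("prf: all counts are zero, metrics undefined")
  safe_div <- function(num, den) if (den == 0) 0 else num / den
  list(accuracy = tp / (tp + fp + fn),
       precision = safe_div(tp, tp + fp),
       recall = safe_div(tp, tp + fn))
}

#' Sum detection counts across frames
#' @param counts_list List of `detection_counts`.
#' @return A single aggregated `detection_counts`.
#' @export
sum_counts <- function(counts_list) {
  tot <- list(tp = sum(vapply(counts_list, `[[`, 0L, "tp")),
              fp = sum(vapply(counts_list, `[[`, 0L, "fp")),
              fn = sum(vapply(counts_list, `[[`, 0L, "fn")))
  ious <- unlist(lapply(counts_list, function(x)
    if (!is.null(x$matched_ious)) x$matched_ious else numeric(0)))
  tot$mean_iou_matched <- if (length(ious)) mean(ious) else NA_real_
  class(tot) <- "detection_counts"
  tot
}

#' Clip truth lines to an ROI's vertical span
#'
#' Detections only exist inside the ROI, so ground-truth lines spanning the
#' full frame are cut down to the ROI's y range (x interpolated linearly)
#' before scoring; lines that miss the ROI horizontally are dropped.
#'
#' @param lines Camera-frame line `data.frame`.
#' @param roi A [roi_rect()].
#' @return Clipped line table.
#' @export
clip_lines_to_roi <- function(lines, roi) {
  stopifnot(inherits(roi, "roi_rect"))
  if (!nrow(lines)) return(lines)
  y0 <- roi$y0; y1 <- roi$y0 + roi$height - 1
  x_at <- function(l, y) {
    if (l$y_bottom == l$y_top) return(l$x_top)
    l$x_top + (l$x_bottom - l$x_top) * (y - l$y_top) / (l$y_bottom - l$y_top)
  }
  keep <- list()
  for (i in seq_len(nrow(lines))) {
    l <- lines[i, ]
    xt <- x_at(l, y0); xb <- x_at(l, y1)
    xm <- (xt + xb) / 2
    if (xm < roi$x0 || xm >= roi$x0 + roi$width) next
    keep[[length(keep) + 1]] <-
      row_lines(xt, y0, xb, y1, frame = "camera",
                inlier_count = l$inlier_count, image_id = l$image_id)
  }
  if (!length(keep)) return(empty_lines())
  do.call(rbind, keep)
}
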