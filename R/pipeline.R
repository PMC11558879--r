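# End-to-end orchestration: configuration, the full detector chain
# (rectify -> segment -> cluster -> repair -> prune -> RANSAC -> slope gate
# -> backproject), baseline method dispatch, batch runs and reports.

#' Default detector configuration
#'
#' Nested list of every tunable parameter. `boundary_points` (the four
#' rectifying correspondences) must be supplied by the user or taken from a
#' synthetic scene's truth ([scene_config()]); the default maps the ROI
#' onto itself (identity rectification).
#'
#' @param roi A [roi_rect()]; default is the 120 x 80 ROI used throughout.
#' @return Config list.
#' @export
default_config <- function(roi = roi_rect(180, 140, 120, 80)) {
  corners <- rbind(c(0, 0), c(roi$width - 1, 0),
                   c(0, roi$height - 1), c(roi$width - 1, roi$height - 1))
  list(
    roi = roi,
    boundary_points = list(src = corners, dst = corners),
    rect_size = c(roi$width, roi$height),
    use_warp = TRUE,
    segmentation = list(epsilon = 1e-8, fixed_max = FALSE,
                        open_kernel = 3, close_kernel = 3),
    cluster = list(min_cluster_size = 50, eps = c(4, 20), min_pts = 12,
                   expected_rows = 3, crop_row_distance_px = 17,
                   max_repair_iters = 5, peel_fraction = 0.1),
    ransac = list(residual_tol_px = 3, confidence = 0.99,
                  max_iters = 500, seed = 1),
    slope_window = c(70, 110),
    sliding = list(window_px = 20, min_fg_px = 10),
    hough = list(vote_threshold = NULL, merge_dist_px = 10,
                 theta_step_deg = 1, rho_step_px = 1),
    eval = list(half_width_px = 6, tp_iou_threshold = 0.5)
  )
}

#' Configuration matched to a synthetic scene
#'
#' Builds a [default_config()] whose ROI and boundary points are the exact
#' correspondences the generator emitted, with the crop-row distance set to
#' 0.6 x the generated rectified row spacing and the evaluation box half
#' width to 0.15 x the camera-frame row spacing.
#'
#' @param scene Output of [generate_field()].
#' @param ... Named config entries overriding the derived defaults
#'   (merged recursively).
#' @return Config list.
#' @export
scene_config <- function(scene, ...) {
  tr <- scene$truth
  cfg <- default_config(tr$roi)
  cfg$boundary_points <- tr$correspondences
  if (!is.null(tr$rect_size)) cfg$rect_size <- tr$rect_size
  cfg$cluster$expected_rows <- tr$params_used$n_rows
  cfg$cluster$crop_row_distance_px <- 0.6 * tr$row_spacing_rect_px
  cfg$eval$half_width_px <- 0.15 * tr$row_spacing_camera_px
  dots <- list(...)
  if (length(dots)) cfg <- utils::modifyList(cfg, dots)
  cfg
}

#' Read / write a config file (YAML)
#'
#' @param path File path.
#' @return `read_config` returns a config list.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg <- utils::modifyList(default_config(), cfg)
  r <- cfg$roi
  if (!inherits(r, "roi_rect")) cfg$roi <- roi_rect(r$x0, r$y0, r$width, r$height)
  cfg$boundary_points$src <- matrix(unlist(cfg$boundary_points$src), ncol = 2, byrow = TRUE)
  cfg$boundary_points$dst <- matrix(unlist(cfg$boundary_points$dst), ncol = 2, byrow = TRUE)
  cfg
}

#' @rdname read_config
#' @param cfg Config list.
#' @export
write_config <- function(cfg, path) {
  cfg$roi <- unclass(cfg$roi)
  cfg$boundary_points <- lapply(cfg$boundary_points, function(m)
    lapply(seq_len(nrow(m)), function(i) as.numeric(m[i, ])))
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Detect crop rows in one image
#'
#' Runs the full chain: ROI crop, four-point rectification, Excess
#' Green / Otsu segmentation, morphological cleanup, density clustering
#' with iterative repair and adjacent-cluster pruning, robust line fitting,
#' slope gating, and back-projection onto the camera frame. Content never
#' raises: a frame with no vegetation yields zero lines plus diagnostics.
#'
#' @param image h x w x 3 RGB array (0-1 or 0-255).
#' @param config Config list (see [default_config()]).
#' @param method `"carolif"` (clustering + RANSAC, the main detector),
#'   `"cluster_ls"` (clustering + least squares), `"hough"`, or
#'   `"sliding"`.
#' @param image_id Identifier recorded in the output lines.
#' @return `row_detection` list: `lines_rectified`, `lines_camera`,
#'   `n_clusters_final`, `repair_converged`, the binary `mask`, the
#'   `cluster_set` (clustering methods), `H` and the homography inverse
#'   used for back-projection.
#' @export
detect <- function(image, config = default_config(),
                   method = c("carolif", "hough", "sliding", "cluster_ls"),
                   image_id = NA_character_) {
  method <- match.arg(method)
  cfg <- config
  roi_img <- crop_roi(image, cfg$roi)

  if (isTRUE(cfg$use_warp)) {
    H <- estimate_homography(cfg$boundary_points$src, cfg$boundary_points$dst)
  } else {
    H <- diag(3)
  }
  rect_size <- if (!is.null(cfg$rect_size)) cfg$rect_size
               else c(cfg$roi$width, cfg$roi$height)
  if (identical(H, diag(3))) {
    warped <- roi_img
    valid <- NULL
  } else {
    warped <- warp_image(roi_img, H, rect_size)
    # pixels sampling outside the ROI hold fill values, not field content;
    # exclude them from segmentation output
    ones <- matrix(1, nrow(roi_img), ncol(roi_img))
    valid <- warp_image(ones, H, rect_size) > 0.999
  }

  seg <- cfg$segmentation
  mask <- segment_vegetation(warped, seg$epsilon, seg$fixed_max,
                             seg$open_kernel, seg$close_kernel)
  if (!is.null(valid)) mask <- mask * (valid + 0L)
  h_rect <- nrow(mask)

  cs <- NULL
  lines <- empty_lines()
  if (any(mask > 0)) {
    if (method %in% c("carolif", "cluster_ls")) {
      cl <- cfg$cluster
      cs <- cluster_foreground(mask, cl$min_cluster_size, cl$eps, cl$min_pts)
      cs <- ensure_min_rows(cs, cl$expected_rows, cl$max_repair_iters,
                            cl$peel_fraction)
      cs <- prune_adjacent_clusters(cs, cl$crop_row_distance_px)
      if (method == "carolif") {
        fits <- lapply(cs$clusters, function(clu) {
          tryCatch(ransac_line(clu$points, cfg$ransac$residual_tol_px,
                               cfg$ransac$confidence, cfg$ransac$max_iters,
                               seed = cfg$ransac$seed + clu$label,
                               y_extent = c(0, h_rect - 1)),
                   error = function(e) NULL)
        })
        fits <- fits[!vapply(fits, is.null, TRUE)]
        if (length(fits)) lines <- do.call(rbind, fits)
      } else {
        lines <- suppressWarnings(cluster_leastsq_rows(cs, c(0, h_rect - 1)))
      }
    } else if (method == "hough") {
      hg <- cfg$hough
      lines <- hough_rows(mask, hg$vote_threshold, cfg$slope_window,
                          hg$merge_dist_px, hg$theta_step_deg, hg$rho_step_px)
    } else {
      lines <- sliding_window_rows(mask, cfg$sliding$window_px,
                                   cfg$sliding$min_fg_px)
    }
  }
  lines <- filter_lines_by_slope(lines, cfg$slope_window[1], cfg$slope_window[2])
  if (nrow(lines)) lines$image_id <- image_id
  H_inv <- invert_homography(H)
  lines_cam <- backproject_lines(lines, H_inv, cfg$roi)

  structure(list(image_id = image_id, method = method,
                 lines_rectified = lines, lines_camera = lines_cam,
                 n_clusters_final = if (is.null(cs)) nrow(lines)
                                    else length(cs$clusters),
                 repair_converged = if (is.null(cs)) TRUE else cs$repair_converged,
                 mask = mask, cluster_set = cs, H = H, H_inv = H_inv,
                 config = cfg),
            class = "row_detection")
}

#' @export
print.row_detection <- function(x, ...) {
  cat(sprintf("<row_detection %s: %d line(s), %d cluster(s)%s>\n",
              x$method, nrow(x$lines_camera), x$n_clusters_final,
              if (x$repair_converged) "" else ", repair not converged"))
  invisible(x)
}

#' Score one detection against a scene's ground truth
#'
#' Clips the camera-frame truth lines to the ROI and matches them against
#' the detected camera-frame lines by box IOU.
#'
#' @param det A `row_detection`.
#' @param truth Scene truth (from [generate_field()]) or a camera-frame
#'   truth line `data.frame`.
#' @param config Config providing `eval$half_width_px` and
#'   `eval$tp_iou_threshold` (defaults to the detection's own config).
#' @return `detection_counts`.
#' @export
evaluate_detection <- function(det, truth, config = det$config) {
  tl <- if (is.data.frame(truth)) truth else truth$truth_lines
  tl <- clip_lines_to_roi(tl, config$roi)
  match_and_score(det$lines_camera, tl,
                  config$eval$half_width_px, config$eval$tp_iou_threshold)
}

#' Run the detector over a batch of frames
#'
#' Frames are processed independently. When truths are supplied, per-frame
#' detection counts are computed and summed into an aggregate summary with
#' accuracy / precision / recall and the mean matched IOU.
#'
#' @param images List of RGB arrays (or a list of scenes from
#'   [generate_field()], in which case truths are taken from them).
#' @param config Config list, or `NULL` to derive one per scene via
#'   [scene_config()] (scene input only).
#' @param method Detector, as in [detect()].
#' @param truths Optional list of truth objects/line tables, one per frame.
#' @param ids Optional character vector of frame identifiers (defaults to
#'   `frame_0001`, `frame_0002`, ...).
#' @return List with `per_image` (one record per frame: id, lines, counts)
#'   and `summary` (aggregate counts + metrics; `NULL` without truths).
#' @export
run_batch <- function(images, config = NULL,
                      method = "carolif", truths = NULL, ids = NULL) {
  is_scene <- function(x) is.list(x) && !is.null(x$image) && !is.null(x$truth)
  per <- vector("list", length(images))
  counts <- list()
  for (i in seq_along(images)) {
    frame <- images[[i]]
    if (is_scene(frame)) {
      img <- frame$image
      tru <- frame$truth
      cfg <- if (is.null(config)) scene_config(frame) else config
    } else {
      img <- frame
      tru <- if (!is.null(truths)) truths[[i]] else NULL
      cfg <- if (is.null(config)) default_config() else config
    }
    id <- if (!is.null(ids)) ids[i] else sprintf("frame_%04d", i)
    det <- detect(img, cfg, method, image_id = id)
    rec <- list(image_id = id, lines = det$lines_camera,
                n_clusters = det$n_clusters_final,
                repair_converged = det$repair_converged)
    if (!is.null(tru)) {
      cnt <- evaluate_detection(det, tru, cfg)
      rec$counts <- cnt
      counts[[length(counts) + 1]] <- cnt
    }
    per[[i]] <- rec
  }
  summary <- NULL
  if (length(counts)) {
    tot <- sum_counts(counts)
    summary <- c(tot[c("tp", "fp", "fn")], prf(tot),
                 list(mean_iou = tot$mean_iou_matched))
  }
  list(per_image = per, summary = summary)
}

#' Write a batch report as JSON (with a CSV line table alongside)
#'
#' @param batch Output of [run_batch()].
#' @param json_path Output JSON path; a `.csv` twin of all detected lines
#'   is written next to it.
#' @return `json_path`, invisibly.
#' @export
write_report <- function(batch, json_path) {
  per <- lapply(batch$per_image, function(r) {
    out <- list(image_id = r$image_id, n_lines = nrow(r$lines),
                n_clusters = r$n_clusters,
                repair_converged = r$repair_converged)
    if (!is.null(r$counts))
      out <- c(out, r$counts[c("tp", "fp", "fn", "mean_iou_matched")])
    out
  })
  jsonlite::write_json(list(per_image = per, summary = batch$summary),
                       json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  lines <- do.call(rbind, lapply(batch$per_image, `[[`, "lines"))
  utils::write.csv(lines, sub("\\.json$", ".csv", json_path), row.names = FALSE)
  invisible(json_path)
}
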