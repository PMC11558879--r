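# Seeded synthetic crop-field generator. A top-view scene (parallel
# vertical rows of green crop blobs, Poisson-scattered weed blobs between
# rows, textured soil, optional shadow bands) is warped to a tilted camera
# view by a projective transformation, so rows converge toward the horizon
# exactly as a tractor-mounted camera sees them. Exact ground-truth row
# lines, vegetation/weed masks and the rectifying correspondences are
# emitted with every image.

.default_tilt_homography <- function(size, pinch = 0.5) {
  w <- size[1]; h <- size[2]
  src <- rbind(c(0, 0), c(w - 1, 0), c(0, h - 1), c(w - 1, h - 1))
  dst <- rbind(c(pinch * w / 2, 0), c(w - 1 - pinch * w / 2, 0),
               c(0, h - 1), c(w - 1, h - 1))
  estimate_homography(src, dst)
}

#' Parameters of a synthetic crop-field scene
#'
#' Defaults describe a 480 x 360 camera frame with three straight rows,
#' 40 px apart in the top view, of 3 px-radius crop blobs every 8 px along
#' the row, under a strong perspective tilt (top of the frame pinched to
#' half width) — geometry matching a forward-tilted vehicle camera over
#' young row crops, with all detection done in a central 120 x 80 ROI.
#'
#' @param n_rows Number of crop rows.
#' @param row_spacing_px Row spacing in the top view, pixels.
#' @param crop_blob_radius_px Nominal crop blob radius (each blob's radius
#'   is jittered by +-20%). Must satisfy `row_spacing_px > 2 * radius`.
#' @param crop_spacing_along_row_px Blob spacing along a row.
#' @param missing_crop_prob Per-blob probability of a missing plant.
#' @param weed_density Weed blobs per 1000 square pixels of top-view area.
#' @param weed_radius_range `c(lo, hi)` disk radius range for weed blobs
#'   (each weed is a union of 2-5 random disks, so opening only removes the
#'   smallest).
#' @param shadow_strength Multiplicative darkening of shadow bands, 0-1.
#' @param camera_tilt_homography 3x3 homography mapping top-view to camera
#'   coordinates; `NULL` selects the default tilt.
#' @param soil_texture_noise Gaussian speckle sd added to the soil color.
#' @param image_size `c(width, height)` of the camera frame.
#' @param seed Integer RNG seed; the whole scene is deterministic in it.
#' @return `scene_params` list.
#' @export
scene_params <- function(n_rows = 3, row_spacing_px = 40,
                         crop_blob_radius_px = 3,
                         crop_spacing_along_row_px = 8,
                         missing_crop_prob = 0, weed_density = 0,
                         weed_radius_range = c(1.5, 4),
                         shadow_strength = 0,
                         camera_tilt_homography = NULL,
                         soil_texture_noise = 0.03,
                         image_size = c(480, 360), seed = 1) {
  stopifnot(n_rows >= 1,
            missing_crop_prob >= 0, missing_crop_prob <= 1,
            shadow_strength >= 0, shadow_strength <= 1,
            weed_density >= 0)
  if (row_spacing_px <= 2 * crop_blob_radius_px)
    stop("scene_params: row spacing must exceed twice the crop blob radius")
  if ((n_rows - 1) * row_spacing_px >= image_size[1])
    stop("scene_params: infeasible geometry, rows wider than the image")
  if (is.null(camera_tilt_homography))
    camera_tilt_homography <- .default_tilt_homography(image_size)
  structure(list(n_rows = n_rows, row_spacing_px = row_spacing_px,
                 crop_blob_radius_px = crop_blob_radius_px,
                 crop_spacing_along_row_px = crop_spacing_along_row_px,
                 missing_crop_prob = missing_crop_prob,
                 weed_density = weed_density,
                 weed_radius_range = weed_radius_range,
                 shadow_strength = shadow_strength,
                 camera_tilt_homography = camera_tilt_homography,
                 soil_texture_noise = soil_texture_noise,
                 image_size = image_size, seed = as.integer(seed)),
            class = "scene_params")
}

#' Scene presets mirroring easy and challenging field conditions
#'
#' `"easy"`: well-spaced continuous rows, no weeds, no shadow, 5% missing
#' plants. `"challenging"`: 30% missing plants, shadow bands at strength
#' 0.5, and weed density calibrated so weed pixels are roughly 30% of the
#' vegetation pixels.
#'
#' @param name `"easy"` or `"challenging"`.
#' @param seed RNG seed stored in the parameters.
#' @return `scene_params`.
#' @export
make_preset <- function(name, seed = 1) {
  base <- scene_params(seed = seed)
  switch(name,
    easy = {
      base$missing_crop_prob <- 0.05
      base$weed_density <- 0
      base$shadow_strength <- 0
      base
    },
    challenging = {
      base$missing_crop_prob <- 0.3
      base$shadow_strength <- 0.5
      # aim weed area at ~30% of crop area: crop px per frame ~ n_rows *
      # (h / along-row spacing) * (1 - missing) * pi r^2; a weed blob
      # (union of 2-5 disks, radii U(1.5, 4)) covers ~45 px^2 on average
      A <- prod(base$image_size)
      crop_px <- base$n_rows * (base$image_size[2] / base$crop_spacing_along_row_px) *
        (1 - base$missing_crop_prob) * pi * base$crop_blob_radius_px^2
      base$weed_density <- 0.3 * crop_px / 45 / A * 1000
      base
    },
    stop("make_preset: unknown preset '", name, "'")
  )
}

# Paint filled disks onto a binary matrix; centers 0-based (x, y).
.paint_disks <- function(m, cx, cy, r) {
  nr <- nrow(m); nc <- ncol(m)
  for (i in seq_along(cx)) {
    x0 <- max(0, floor(cx[i] - r[i])); x1 <- min(nc - 1, ceiling(cx[i] + r[i]))
    y0 <- max(0, floor(cy[i] - r[i])); y1 <- min(nr - 1, ceiling(cy[i] + r[i]))
    if (x1 < x0 || y1 < y0) next
    xs <- x0:x1; ys <- y0:y1
    dd <- outer((ys - cy[i])^2, (xs - cx[i])^2, "+")
    sub <- m[ys + 1, xs + 1, drop = FALSE]
    sub[dd <= r[i]^2] <- 1L
    m[ys + 1, xs + 1] <- sub
  }
  m
}

#' Generate a synthetic crop-field image with exact ground truth
#'
#' @param params A [scene_params()] object.
#' @return List with `image` (h x w x 3 camera-frame RGB in 0-1) and
#'   `truth`, a list holding `truth_lines` (camera-frame line table, one
#'   per row), `vegetation_mask` and `weed_mask` (camera frame, weed mask a
#'   subset of vegetation), `correspondences` (`src`/`dst` 4x2 matrices
#'   rectifying the recommended ROI), `roi` (the recommended [roi_rect()]),
#'   `row_spacing_camera_px` (spacing at ROI mid height),
#'   `row_spacing_rect_px` (spacing in the rectified frame) and
#'   `params_used`.
#' @export
generate_field <- function(params) {
  stopifnot(inherits(params, "scene_params"))
  p <- params
  w <- p$image_size[1]; h <- p$image_size[2]
  .with_local_seed(p$seed, {
    # --- top-view scene ---
    cxs <- (w - 1) / 2 + (seq_len(p$n_rows) - (p$n_rows + 1) / 2) * p$row_spacing_px
    crop_mask <- matrix(0L, h, w)
    for (rx in cxs) {
      by <- seq(0, h - 1, by = p$crop_spacing_along_row_px)
      present <- stats::runif(length(by)) >= p$missing_crop_prob
      by <- by[present]
      if (!length(by)) next
      rr <- p$crop_blob_radius_px * stats::runif(length(by), 0.8, 1.2)
      bx <- rx + stats::rnorm(length(by), 0, 0.3)
      crop_mask <- .paint_disks(crop_mask, bx, by, rr)
    }
    weed_mask <- matrix(0L, h, w)
    n_weed <- stats::rpois(1, p$weed_density * w * h / 1000)
    if (diff(range(cxs)) <= 2 * (p$crop_blob_radius_px + 1))
      n_weed <- 0   # no inter-row band to put weeds in
    if (n_weed > 0) {
      placed <- 0
      while (placed < n_weed) {
        # weeds grow in the inter-row band, not on the row lines themselves
        wx <- stats::runif(1, min(cxs), max(cxs)); wy <- stats::runif(1, 0, h - 1)
        if (min(abs(wx - cxs)) < p$crop_blob_radius_px + 1) next  # inter-row only
        k <- sample(2:5, 1)
        dr <- stats::runif(k, p$weed_radius_range[1], p$weed_radius_range[2])
        dx <- wx + stats::rnorm(k, 0, 2); dy <- wy + stats::rnorm(k, 0, 2)
        weed_mask <- .paint_disks(weed_mask, dx, dy, dr)
        placed <- placed + 1
      }
    }
    veg_mask <- ((crop_mask + weed_mask) > 0) + 0L

    soil <- c(0.42, 0.33, 0.24); green <- c(0.18, 0.52, 0.16)
    top <- array(0, c(h, w, 3))
    for (k in 1:3) {
      plane <- matrix(soil[k] + stats::rnorm(h * w, 0, p$soil_texture_noise), h, w)
      plane[veg_mask > 0] <- green[k] +
        stats::rnorm(sum(veg_mask > 0), 0, p$soil_texture_noise)
      top[, , k] <- plane
    }
    if (p$shadow_strength > 0) {
      # two diagonal multiplicative shadow bands
      sx <- outer(seq_len(h) * 0.5, seq_len(w), "+")
      span <- range(sx)
      starts <- stats::runif(2, span[1], span[2] - 0.15 * diff(span))
      shade <- matrix(1, h, w)
      for (s0 in starts)
        shade[sx >= s0 & sx <= s0 + 0.15 * diff(span)] <- 1 - p$shadow_strength
      for (k in 1:3) top[, , k] <- top[, , k] * shade
    }
    top <- pmin(pmax(top, 0), 1)

    # --- camera view ---
    H <- p$camera_tilt_homography
    img <- warp_image(top, H, c(w, h), fill = soil)
    veg_cam <- warp_mask(veg_mask, H, c(w, h))
    weed_cam <- warp_mask(weed_mask, H, c(w, h))
    weed_cam <- weed_cam * veg_cam   # enforce weed subset of vegetation

    tl <- do.call(rbind, lapply(cxs, function(rx) {
      ends <- apply_homography(H, rbind(c(rx, 0), c(rx, h - 1)))
      row_lines(ends[1, 1], ends[1, 2], ends[2, 1], ends[2, 2],
                frame = "camera", inlier_count = NA_integer_)
    }))

    # --- recommended ROI and its rectifying correspondences ---
    roi <- roi_rect((w - 120) / 2, 140, 120, 80)
    corners_local <- rbind(c(0, 0), c(roi$width - 1, 0),
                           c(0, roi$height - 1), c(roi$width - 1, roi$height - 1))
    corners_cam <- sweep(corners_local, 2, c(roi$x0, roi$y0), "+")
    q <- apply_homography(invert_homography(H), corners_cam)
    # rectify onto the top-view plane at its native 1:1 scale (translated to
    # the origin): vertical rows stay vertical and nothing is downsampled
    dst <- cbind(q[, 1] - min(q[, 1]), q[, 2] - min(q[, 2]))
    corr <- list(src = corners_local, dst = dst)
    rect_size <- c(ceiling(diff(range(q[, 1]))) + 1,
                   ceiling(diff(range(q[, 2]))) + 1)

    sx_rect <- p$row_spacing_px
    y_mid <- roi$y0 + (roi$height - 1) / 2
    x_mid <- vapply(seq_len(nrow(tl)), function(i) {
      l <- tl[i, ]
      l$x_top + (l$x_bottom - l$x_top) * (y_mid - l$y_top) / (l$y_bottom - l$y_top)
    }, 0)
    sx_cam <- if (p$n_rows > 1) mean(diff(sort(x_mid))) else sx_rect

    list(image = img,
         truth = list(truth_lines = tl,
                      vegetation_mask = veg_cam,
                      weed_mask = weed_cam,
                      correspondences = corr,
                      n_weed_blobs = n_weed,
                      rect_size = rect_size,
                      roi = roi,
                      row_spacing_camera_px = sx_cam,
                      row_spacing_rect_px = sx_rect,
                      params_used = p))
  })
}
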