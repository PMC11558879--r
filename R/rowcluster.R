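# Grouping foreground pixels into candidate crop rows: density-based
# clustering plus the two geometric repair rules (iterative outlier peeling
# when too few rows are found; pruning of clusters closer than one crop-row
# spacing, which are taken to be weeds).

# --- raster DBSCAN ----------------------------------------------------------
# Foreground pixels live on the integer lattice, so the eps-neighbourhood
# graph can be evaluated with matrix shifts instead of a spatial index.

# eps may be c(eps_x, eps_y): an elliptical neighbourhood, elongated along
# y to follow the near-vertical rows of the rectified frame (plays the role
# of HDBSCAN's tolerance to the sparser along-row density).
.disc_offsets <- function(eps) {
  eps <- rep_len(eps, 2)
  rx <- floor(eps[1]); ry <- floor(eps[2])
  g <- expand.grid(dx = -rx:rx, dy = -ry:ry)
  g <- g[g$dx^2 / eps[1]^2 + g$dy^2 / eps[2]^2 <= 1 &
           !(g$dx == 0 & g$dy == 0), ]
  as.matrix(g)
}

.shift_mat <- function(m, dy, dx, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  ys <- max(1, 1 - dy):min(nr, nr - dy)
  xs <- max(1, 1 - dx):min(nc, nc - dx)
  if (length(ys) && length(xs))
    out[ys + dy, xs + dx] <- m[ys, xs]
  out
}

# Per-pixel neighbour count (self included) within the eps disc.
.density_counts <- function(mask, offsets) {
  counts <- mask + 0
  for (k in seq_len(nrow(offsets)))
    counts <- counts + .shift_mat(mask, offsets[k, "dy"], offsets[k, "dx"])
  counts
}

# DBSCAN on a binary raster. Returns a label matrix (0 = not foreground,
# -1 = outlier, 1..K = cluster) and the density matrix.
.dbscan_raster <- function(mask, eps, min_pts) {
  offsets <- .disc_offsets(eps)
  dens <- .density_counts(mask, offsets)
  fg <- mask > 0
  core <- fg & dens >= min_pts

  # connected components of core pixels under eps-adjacency: propagate the
  # minimum provisional label across disc offsets until stable
  lab <- matrix(Inf, nrow(mask), ncol(mask))
  lab[core] <- which(core)                      # column-major index as id
  if (any(core)) {
    repeat {
      new <- lab
      for (k in seq_len(nrow(offsets))) {
        sh <- .shift_mat(lab, offsets[k, "dy"], offsets[k, "dx"], fill = Inf)
        new <- pmin(new, sh)
      }
      new[!core] <- Inf
      if (identical(new, lab)) break
      lab <- new
    }
  }

  # border pixels: foreground, not core, adjacent (within eps) to a core pixel
  border_lab <- matrix(Inf, nrow(mask), ncol(mask))
  for (k in seq_len(nrow(offsets))) {
    sh <- .shift_mat(lab, offsets[k, "dy"], offsets[k, "dx"], fill = Inf)
    border_lab <- pmin(border_lab, sh)
  }
  final <- matrix(0, nrow(mask), ncol(mask))
  final[core] <- lab[core]
  bsel <- fg & !core & is.finite(border_lab)
  final[bsel] <- border_lab[bsel]
  final[fg & final == 0] <- -1

  # compact labels to 1..K
  ids <- sort(unique(final[final > 0]))
  if (length(ids))
    final[final > 0] <- match(final[final > 0], ids)
  list(labels = final, density = dens)
}

# --- cluster containers -----------------------------------------------------

.mk_cluster <- function(label, pts, strength) {
  list(label = label,
       points = pts,
       size = nrow(pts),
       height_px = if (nrow(pts)) diff(range(pts[, 2])) else 0,
       centroid_x = if (nrow(pts)) mean(pts[, 1]) else NA_real_,
       strength = strength)
}

.empty_pts <- function() matrix(numeric(0), 0, 2, dimnames = list(NULL, c("x", "y")))

.mk_cluster_set <- function(clusters, outliers, dim, params,
                            repair_iterations = 0L, repair_converged = TRUE) {
  structure(list(clusters = clusters,
                 outliers = outliers,
                 repair_iterations = as.integer(repair_iterations),
                 repair_converged = repair_converged,
                 dim = dim, params = params),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("<cluster_set: %d clusters (sizes %s), %d outliers, repair %d iter%s>\n",
              length(x$clusters),
              paste(vapply(x$clusters, `[[`, 0, "size"), collapse = ","),
              nrow(x$outliers), x$repair_iterations,
              if (x$repair_converged) "" else ", NOT converged"))
  invisible(x)
}

#' Total points held by a cluster set (clusters plus outliers)
#' @param cs A `cluster_set`.
#' @return Two-column matrix of (x, y) coordinates.
#' @export
cluster_set_points <- function(cs) {
  pts <- lapply(cs$clusters, `[[`, "points")
  do.call(rbind, c(pts, list(cs$outliers)))
}

#' Cluster foreground pixels into candidate crop rows
#'
#' Density-based clustering (DBSCAN on the pixel lattice): pixels with at
#' least `min_pts` foreground neighbours within an `eps`-radius disc are
#' core points; clusters are maximal sets of density-connected points;
#' sparse scattered pixels (weeds, noise) are returned as outliers.
#' Clusters smaller than `min_cluster_size` are dissolved into the outlier
#' set — this is the detector's main tuning parameter. Each retained point
#' carries a membership strength (its neighbourhood density), used by the
#' iterative repair of [ensure_min_rows()].
#'
#' @param mask Binary 0/1 matrix, 1 = vegetation.
#' @param min_cluster_size Minimum number of pixels for a cluster to count
#'   as a candidate crop row.
#' @param eps Neighbourhood radius in pixels; a length-2 vector
#'   `c(eps_x, eps_y)` gives an elliptical neighbourhood elongated along y,
#'   matching the vertical elongation of rectified crop rows (so gaps from
#'   missing plants along a row are bridged without reaching sideways
#'   toward the neighbouring row).
#' @param min_pts Core-point density requirement (neighbours within the
#'   `eps` neighbourhood, self included).
#' @return A `cluster_set`: list of clusters (each with `points`, `size`,
#'   `height_px`, `centroid_x`, per-point `strength`), an `outliers` matrix,
#'   and repair bookkeeping fields.
#' @export
cluster_foreground <- function(mask, min_cluster_size = 50, eps = c(4, 20),
                               min_pts = 12) {
  if (min_cluster_size < 2)
    stop("cluster_foreground: min_cluster_size must be >= 2")
  params <- list(min_cluster_size = min_cluster_size, eps = eps, min_pts = min_pts)
  fg_idx <- which(mask > 0)
  if (!length(fg_idx))
    return(.mk_cluster_set(list(), .empty_pts(), dim(mask), params))
  res <- .dbscan_raster(mask, eps, min_pts)
  lab <- res$labels; dens <- res$density

  coords_of <- function(idx) {
    cbind(x = (idx - 1) %/% nrow(mask), y = (idx - 1) %% nrow(mask))
  }
  clusters <- list()
  out_idx <- which(lab == -1)
  ids <- sort(unique(lab[lab > 0]))
  keep <- 0L
  for (id in ids) {
    idx <- which(lab == id)
    if (length(idx) < min_cluster_size) {
      out_idx <- c(out_idx, idx)
    } else {
      keep <- keep + 1L
      clusters[[keep]] <- .mk_cluster(keep, coords_of(idx), dens[idx])
    }
  }
  # order candidate rows left to right
  if (length(clusters) > 1) {
    ord <- order(vapply(clusters, `[[`, 0, "centroid_x"))
    clusters <- clusters[ord]
    for (i in seq_along(clusters)) clusters[[i]]$label <- i
  }
  .mk_cluster_set(clusters, coords_of(sort(out_idx)), dim(mask), params)
}

.points_to_mask <- function(pts, dim) {
  m <- matrix(0L, dim[1], dim[2])
  if (nrow(pts)) m[pts[, 2] + 1 + pts[, 1] * dim[1]] <- 1L
  m
}

#' Repair a cluster set that found fewer rows than expected
#'
#' When fewer than `expected_rows` clusters are present the rows are assumed
#' to have merged through weed bridges. Each repair iteration removes the
#' `peel_fraction` of current points with the lowest membership strength
#' (neighbourhood density — weed bridges are sparser than crop rows) and
#' re-clusters, up to `max_repair_iters` times. Peeled points are moved to
#' the outlier set, so clusters plus outliers always equal the original
#' foreground set. Non-convergence is reported via `repair_converged`,
#' never raised.
#'
#' @param cs A `cluster_set` from [cluster_foreground()].
#' @param expected_rows Number of crop rows expected inside the ROI.
#' @param max_repair_iters Iteration cap.
#' @param peel_fraction Fraction of points removed per iteration.
#' @return A `cluster_set` with `repair_iterations` and `repair_converged`
#'   filled in.
#' @export
ensure_min_rows <- function(cs, expected_rows = 3, max_repair_iters = 5,
                            peel_fraction = 0.1) {
  stopifnot(inherits(cs, "cluster_set"), expected_rows >= 1)
  all_pts <- cluster_set_points(cs)
  if (!nrow(all_pts)) {
    cs$repair_converged <- FALSE
    return(cs)
  }
  if (length(cs$clusters) >= expected_rows) {
    cs$repair_iterations <- 0L
    cs$repair_converged <- TRUE
    return(cs)
  }
  p <- cs$params
  peeled <- .empty_pts()
  active <- all_pts
  cur <- cs
  best <- cs                       # best-so-far: most clusters, least peeling
  best_peeled <- peeled
  iters <- 0L
  while (length(cur$clusters) < expected_rows && iters < max_repair_iters &&
         nrow(active) > p$min_cluster_size) {
    iters <- iters + 1L
    m <- .points_to_mask(active, cs$dim)
    dens <- .density_counts(m, .disc_offsets(p$eps))
    strength <- dens[active[, 2] + 1 + active[, 1] * cs$dim[1]]
    n_drop <- max(1L, floor(peel_fraction * nrow(active)))
    drop <- order(strength, seq_len(nrow(active)))[seq_len(n_drop)]   # deterministic ties
    peeled <- rbind(peeled, active[drop, , drop = FALSE])
    active <- active[-drop, , drop = FALSE]
    cur <- cluster_foreground(.points_to_mask(active, cs$dim),
                              p$min_cluster_size, p$eps, p$min_pts)
    if (length(cur$clusters) > length(best$clusters)) {
      best <- cur
      best_peeled <- peeled
    }
  }
  # peeling can only help while clusters are merged; if it fragmented the
  # scene instead, fall back to the best clustering seen
  best$outliers <- rbind(best$outliers, best_peeled)
  best$repair_iterations <- iters
  best$repair_converged <- length(best$clusters) >= expected_rows
  best$dim <- cs$dim
  best
}

#' Prune clusters closer together than one crop-row spacing
#'
#' Real crop rows keep a fixed spacing, so two clusters whose x-centroids
#' are closer than `crop_row_distance_px` cannot both be rows: the one
#' ranked lower by point count (height breaking ties) is taken to be a weed
#' patch and deleted, its points moving to the outlier set. Deletions run in
#' ascending rank order until no violating pair remains.
#'
#' @param cs A `cluster_set`.
#' @param crop_row_distance_px Minimum admissible centroid separation in
#'   pixels (typically a fraction of the known row spacing).
#' @return The pruned `cluster_set`; no pair of surviving centroids is
#'   closer than the threshold.
#' @export
prune_adjacent_clusters <- function(cs, crop_row_distance_px) {
  stopifnot(inherits(cs, "cluster_set"))
  if (crop_row_distance_px <= 0)
    stop("prune_adjacent_clusters: crop_row_distance_px must be positive")
  cl <- cs$clusters
  repeat {
    if (length(cl) < 2) break
    cx <- vapply(cl, `[[`, 0, "centroid_x")
    sz <- vapply(cl, `[[`, 0, "size")
    ht <- vapply(cl, `[[`, 0, "height_px")
    d <- abs(outer(cx, cx, "-"))
    viol <- d < crop_row_distance_px & upper.tri(d)
    if (!any(viol)) break
    in_pair <- unique(c(row(d)[viol], col(d)[viol]))
    rank_ord <- order(sz, ht)                   # ascending: weakest first
    victim <- rank_ord[rank_ord %in% in_pair][1]
    cs$outliers <- rbind(cs$outliers, cl[[victim]]$points)
    cl <- cl[-victim]
  }
  for (i in seq_along(cl)) cl[[i]]$label <- i
  cs$clusters <- cl
  cs
}
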