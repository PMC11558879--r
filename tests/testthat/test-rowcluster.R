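# Density clustering of foreground pixels and the two geometric repair rules.

test_that("too few foreground pixels yield no clusters, only outliers", {
  m <- matrix(0L, 80, 120)
  m[cbind(c(10, 40, 70), c(5, 60, 115))] <- 1L
  cs <- cluster_foreground(m, min_cluster_size = 50)
  expect_length(cs$clusters, 0)
  expect_equal(nrow(cs$outliers), 3)

  empty <- cluster_foreground(matrix(0L, 20, 20), 50)
  expect_length(empty$clusters, 0)
  expect_equal(nrow(empty$outliers), 0)
})

test_that("three dense strips with scatter cluster cleanly", {
  sm <- strip_mask(scatter_frac = 0.01, seed = 5)
  cs <- cluster_foreground(sm$mask, min_cluster_size = 50)
  expect_length(cs$clusters, 3)
  # >=95% label purity against the generating strip assignment
  for (cl in cs$clusters) {
    lab <- sm$labels[cbind(cl$points[, 2] + 1, cl$points[, 1] + 1)]
    dominant <- max(tabulate(lab + 1L))
    expect_gte(dominant / cl$size, 0.95)
  }
})

test_that("a single strip forms one cluster holding nearly all its pixels", {
  sm <- strip_mask(centers = 60)
  cs <- cluster_foreground(sm$mask, min_cluster_size = 50)
  expect_length(cs$clusters, 1)
  expect_gte(cs$clusters[[1]]$size / sum(sm$mask), 0.95)
})

test_that("clusters and outliers always partition the input foreground", {
  set.seed(31)
  for (i in 1:4) {
    m <- matrix(as.integer(runif(80 * 120) < runif(1, 0.02, 0.15)), 80, 120)
    cs <- cluster_foreground(m, min_cluster_size = 30)
    got <- sort_pts(cluster_set_points(cs))
    idx <- which(m > 0)
    want <- sort_pts(cbind(x = (idx - 1) %/% 80, y = (idx - 1) %% 80))
    expect_equal(got, want, ignore_attr = TRUE)
  }
})

test_that("repair leaves a satisfied cluster set untouched", {
  sm <- strip_mask()
  cs <- cluster_foreground(sm$mask, 50)
  out <- ensure_min_rows(cs, expected_rows = 3)
  expect_equal(out$repair_iterations, 0L)
  expect_true(out$repair_converged)
  expect_equal(length(out$clusters), 3)
})

test_that("iterative outlier peeling separates weed-bridged rows", {
  bm <- bridged_mask(seed = 6)
  cs0 <- cluster_foreground(bm$mask, min_cluster_size = 50)
  expect_lt(length(cs0$clusters), 2)   # the bridge merges the two strips
  cs <- ensure_min_rows(cs0, expected_rows = 2)
  expect_gte(length(cs$clusters), 2)
  # the two dominant clusters sit on the strips, not on the weed band
  cx <- sort(vapply(cs$clusters, `[[`, 0, "centroid_x"))
  expect_lt(abs(cx[1] - 30), 5)
  expect_lt(abs(cx[length(cx)] - 90), 5)
  # residual weed-band clusters are deleted by proximity pruning, after
  # which the bridge pixels sit mostly in the outlier set
  pruned <- prune_adjacent_clusters(cs, 36)   # 0.6 x the 60 px strip spacing
  cl_pts <- do.call(rbind, lapply(pruned$clusters, `[[`, "points"))
  keyed <- paste(cl_pts[, 1], cl_pts[, 2])
  in_clusters <- mean(paste(bm$bridge_pts[, 1], bm$bridge_pts[, 2]) %in% keyed)
  expect_lt(in_clusters, 0.5)
  # point conservation through repair and pruning
  expect_equal(nrow(cluster_set_points(pruned)), sum(bm$mask))
})

test_that("repair on an empty set reports non-convergence without error", {
  cs <- cluster_foreground(matrix(0L, 20, 20), 50)
  out <- ensure_min_rows(cs, expected_rows = 3)
  expect_false(out$repair_converged)
  expect_length(out$clusters, 0)
})

mk_cluster_set_at <- function(cx, sizes, heights, dim = c(80, 120)) {
  clusters <- lapply(seq_along(cx), function(i) {
    n <- sizes[i]
    ys <- seq(0, heights[i], length.out = n)
    croprows:::.mk_cluster(i, cbind(x = rep(cx[i], n), y = ys), rep(1, n))
  })
  croprows:::.mk_cluster_set(clusters, croprows:::.empty_pts(), dim,
                             list(min_cluster_size = 2, eps = c(4, 20),
                                  min_pts = 2))
}

test_that("proximity pruning deletes the smaller, shorter cluster", {
  cs <- mk_cluster_set_at(c(20, 60, 100), c(300, 300, 300), c(80, 80, 80))
  out <- prune_adjacent_clusters(cs, 30)
  expect_length(out$clusters, 3)   # spacing 40 > threshold: untouched

  cs2 <- mk_cluster_set_at(c(20, 28), c(300, 40), c(80, 20))
  out2 <- prune_adjacent_clusters(cs2, 30)
  expect_length(out2$clusters, 1)
  expect_equal(out2$clusters[[1]]$size, 300)   # the (40, 20) weed goes
  expect_equal(nrow(out2$outliers), 40)        # its points become outliers

  # equal sizes: height breaks the tie, the shorter cluster is deleted
  cs3 <- mk_cluster_set_at(c(20, 28), c(100, 100), c(80, 20))
  out3 <- prune_adjacent_clusters(cs3, 30)
  expect_length(out3$clusters, 1)
  expect_equal(out3$clusters[[1]]$height_px, 80)
})

test_that("after pruning no centroid pair is closer than the threshold", {
  set.seed(33)
  for (i in 1:5) {
    k <- sample(3:6, 1)
    cs <- mk_cluster_set_at(runif(k, 0, 119), sample(50:300, k),
                            sample(10:80, k))
    out <- prune_adjacent_clusters(cs, 25)
    cx <- vapply(out$clusters, `[[`, 0, "centroid_x")
    if (length(cx) > 1) expect_gte(min(dist(cx)), 25)
    # conservation: points moved to outliers, not lost
    tot <- sum(vapply(out$clusters, `[[`, 0, "size")) + nrow(out$outliers)
    expect_equal(tot, sum(vapply(cs$clusters, `[[`, 0, "size")))
  }
})
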