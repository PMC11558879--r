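# ROI cropping, homography estimation and projective warping.

test_that("crop_roi copies pixels and records the offset", {
  set.seed(1)
  img <- array(runif(100 * 100 * 3), c(100, 100, 3))
  out <- crop_roi(img, roi_rect(0, 0, 100, 100))
  expect_equal(out, img, ignore_attr = TRUE)

  img2 <- array(runif(100 * 200 * 3), c(100, 200, 3))   # 200 wide, 100 tall
  out2 <- crop_roi(img2, roi_rect(10, 20, 50, 30))
  expect_equal(dim(out2), c(30, 50, 3))
  expect_equal(out2[1, 1, ], img2[21, 11, ])   # pixel (0,0) == source (10,20)
  expect_equal(attr(out2, "roi_offset"), c(x0 = 10, y0 = 20))
})

test_that("crop_roi rejects out-of-bounds ROIs naming the edge", {
  img <- array(0, c(100, 200, 3))
  expect_error(crop_roi(img, roi_rect(180, 0, 50, 30)), "right")
  expect_error(crop_roi(img, roi_rect(0, 90, 50, 30)), "bottom")
  expect_error(crop_roi(img, roi_rect(-5, 0, 50, 30)), "left")
})

unit_square <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1))

test_that("four-correspondence estimation recovers known homographies", {
  expect_equal(estimate_homography(unit_square, unit_square), diag(3),
               tolerance = 1e-9)

  # forward-construct: pick H*, push 4 generic points through it, re-estimate
  H_true <- matrix(c(1.2, 0.1, 5,
                     0.05, 0.9, -3,
                     1e-3, 5e-4, 1), 3, 3, byrow = TRUE)
  src <- rbind(c(10, 10), c(100, 20), c(20, 90), c(110, 100))
  dst <- apply_homography(H_true, src)
  H_est <- estimate_homography(src, dst)
  expect_lt(max(abs(H_est - H_true)), 1e-6)
  # and the fit reproduces the correspondences to below 1e-6 px
  expect_lt(max(abs(apply_homography(H_est, src) - dst)), 1e-6)
})

test_that("estimation needs exactly four pairs and non-collinear points", {
  expect_error(estimate_homography(unit_square[1:3, ], unit_square[1:3, ]), "4x2")
  src_bad <- rbind(c(0, 0), c(1, 1), c(2, 2), c(5, 0))   # first three collinear
  expect_error(estimate_homography(src_bad, unit_square), "degenerate")
  expect_error(estimate_homography(unit_square, src_bad), "degenerate")
})

test_that("estimation is equivariant under a similarity of the destination", {
  src <- rbind(c(10, 10), c(100, 20), c(20, 90), c(110, 100))
  H_true <- matrix(c(1.1, 0.05, 2, 0.02, 0.95, -1, 5e-4, 1e-4, 1),
                   3, 3, byrow = TRUE)
  dst <- apply_homography(H_true, src)
  th <- 0.3
  S <- matrix(c(2 * cos(th), -2 * sin(th), 7,
                2 * sin(th),  2 * cos(th), -4,
                0, 0, 1), 3, 3, byrow = TRUE)
  H1 <- estimate_homography(src, apply_homography(S, dst))
  H2 <- as_homography(S %*% estimate_homography(src, dst))
  expect_lt(max(abs(H1 - H2)), 1e-6)
})

test_that("apply_homography evaluates the projective map", {
  expect_equal(apply_homography(diag(3), c(5, 7)), cbind(x = 5, y = 7))
  H_tr <- diag(3); H_tr[1, 3] <- 3; H_tr[2, 3] <- -2
  expect_equal(apply_homography(H_tr, c(10, 10)), cbind(x = 13, y = 8))
  H_p <- diag(3); H_p[3, 1] <- 0.001
  expect_equal(apply_homography(H_p, c(100, 50)),
               cbind(x = 100 / 1.1, y = 50 / 1.1))
  H_inf <- rbind(c(1, 0, 0), c(0, 1, 0), c(1, 0, -5))
  expect_error(apply_homography(H_inf, c(5, 3)), "infinity")
})

test_that("invert_homography inverts to machine precision", {
  expect_equal(invert_homography(diag(3)), diag(3))
  H_tr <- diag(3); H_tr[1, 3] <- 3
  expect_equal(invert_homography(H_tr)[1, 3], -3)
  set.seed(4)
  H <- matrix(c(1.3, 0.2, 8, -0.1, 1.1, 4, 2e-3, -1e-3, 1), 3, 3, byrow = TRUE)
  expect_lt(max(abs(as_homography(H %*% invert_homography(H)) - diag(3))), 1e-9)
  expect_error(invert_homography(matrix(1, 3, 3)), "singular")
})

test_that("warping: identity exact, integer translation exact, round trip close", {
  set.seed(2)
  xs <- seq(0, 3, length.out = 60); ys <- seq(0, 2, length.out = 50)
  smooth <- outer(sin(ys * 2), cos(xs * 3)) * 0.4 + 0.5
  expect_equal(warp_image(smooth, diag(3)), smooth)

  H_tr <- diag(3); H_tr[1, 3] <- 5; H_tr[2, 3] <- 3
  shifted <- warp_image(smooth, H_tr)
  expect_equal(shifted[4:50, 6:60], smooth[1:47, 1:55])
  expect_true(all(shifted[1:3, ] == 0))   # fill

  H <- matrix(c(1.05, 0.02, 2, -0.03, 0.98, 1, 4e-4, 2e-4, 1),
              3, 3, byrow = TRUE)
  round_trip <- warp_image(warp_image(smooth, H), invert_homography(H))
  interior <- round_trip[11:40, 11:50] - smooth[11:40, 11:50]
  expect_lt(max(abs(interior)), 2 / 255)

  expect_error(warp_image(smooth, matrix(1, 3, 3)), "singular")
})
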