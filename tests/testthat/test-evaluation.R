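# Bounding boxes, IOU, matching and summary metrics.

test_that("line boxes capture extent plus half-width padding", {
  b <- line_bbox(row_lines(50, 0, 50, 80), 6)
  expect_equal(unname(b), c(44, 0, 56, 80))
  b2 <- line_bbox(row_lines(40, 0, 60, 80), 5)
  expect_equal(unname(b2), c(35, 0, 65, 80))
  # a horizontal segment gets its degenerate y extent padded too
  b3 <- line_bbox(row_lines(10, 40, 90, 40), 5)
  expect_equal(unname(b3), c(5, 35, 95, 45))
})

test_that("IOU has its landmark values and symmetry", {
  a <- c(x_min = 0, y_min = 0, x_max = 10, y_max = 10)
  expect_equal(iou(a, a), 1)
  b <- c(x_min = 20, y_min = 0, x_max = 30, y_max = 10)
  expect_equal(iou(a, b), 0)
  c3 <- c(x_min = 0, y_min = 5, x_max = 10, y_max = 15)
  expect_equal(iou(a, c3), 1 / 3)   # 50 shared / 150 combined
  set.seed(51)
  rand_box <- function() {
    x0 <- runif(1, 0, 50); y0 <- runif(1, 0, 50)
    c(x_min = x0, y_min = y0,
      x_max = x0 + runif(1, 1, 30), y_max = y0 + runif(1, 1, 30))
  }
  for (i in 1:10) {
    r1 <- rand_box(); r2 <- rand_box()
    v <- iou(r1, r2)
    expect_equal(v, iou(r2, r1))
    expect_gte(v, 0); expect_lte(v, 1)
  }
})

truth3 <- function() row_lines(c(20, 60, 100), 0, c(20, 60, 100), 79)

test_that("matching counts TP, FP, FN as expected", {
  tr <- truth3()
  same <- match_and_score(tr, tr, half_width_px = 6)
  expect_equal(c(same$tp, same$fp, same$fn), c(3L, 0L, 0L))
  expect_equal(same$mean_iou_matched, 1)

  spurious <- rbind(tr, row_lines(200, 0, 200, 79))
  withext <- match_and_score(spurious, tr, half_width_px = 6)
  expect_equal(c(withext$tp, withext$fp, withext$fn), c(3L, 1L, 0L))

  none <- match_and_score(empty_lines(), tr, 6)
  expect_equal(c(none$tp, none$fp, none$fn), c(0L, 0L, 3L))
})

test_that("a uniform 3 px x-shift gives the closed-form IOU of 0.6", {
  tr <- truth3()
  det <- row_lines(tr$x_top + 3, 0, tr$x_bottom + 3, 79)
  got <- match_and_score(det, tr, half_width_px = 6, tp_iou_threshold = 0.5)
  expect_equal(got$tp, 3L)
  expect_equal(got$mean_iou_matched, (12 - 3) / (12 + 3))
})

test_that("matching is invariant to input ordering", {
  tr <- truth3()
  det <- row_lines(c(101, 21, 59), 0, c(99, 19, 61), 79)
  a <- match_and_score(det, tr, 6)
  b <- match_and_score(det[c(3, 1, 2), ], tr[c(2, 3, 1), ], 6)
  expect_equal(a$tp, b$tp)
  expect_equal(sort(a$matched_ious), sort(b$matched_ious))
})

test_that("precision/recall/accuracy identities hold", {
  m <- prf(list(tp = 9, fp = 1, fn = 2))
  expect_equal(m$precision, 0.9)
  expect_equal(m$recall, 9 / 11)
  expect_equal(m$accuracy, 0.75)

  perfect <- prf(list(tp = 5, fp = 0, fn = 0))
  expect_equal(unlist(perfect), c(accuracy = 1, precision = 1, recall = 1))

  blank <- prf(list(tp = 0, fp = 3, fn = 0))
  expect_equal(unlist(blank), c(accuracy = 0, precision = 0, recall = 0))

  expect_error(prf(list(tp = 0, fp = 0, fn = 0)), "undefined")

  set.seed(52)
  for (i in 1:10) {
    counts <- list(tp = sample(0:20, 1), fp = sample(0:10, 1), fn = sample(0:10, 1))
    if (counts$tp + counts$fp + counts$fn == 0) next
    m <- prf(counts)
    expect_gte(m$precision, m$accuracy)
    expect_gte(m$recall, m$accuracy)
  }
})

test_that("clipping truth lines to the ROI preserves x at the cut heights", {
  roi <- roi_rect(100, 50, 120, 80)
  full <- row_lines(c(150, 400), 0, c(170, 420), 199)   # second misses the ROI
  cl <- clip_lines_to_roi(full, roi)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$y_top, 50)
  expect_equal(cl$y_bottom, 129)
  expect_equal(cl$x_top, 150 + 20 * 50 / 199)
})
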