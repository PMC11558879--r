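# Chromaticity normalization, Excess Green, Otsu and morphology.

test_that("chromaticity planes follow max-then-sum normalization", {
  img <- array(0, c(2, 2, 3))
  img[1, 1, ] <- c(0, 255, 0)
  img[1, 2, ] <- c(100, 100, 100)
  img[2, 1, ] <- c(0, 0, 0)
  img[2, 2, ] <- c(255, 255, 255)
  pl <- normalize_channels(img)
  expect_equal(c(pl$r[1, 1], pl$g[1, 1], pl$b[1, 1]), c(0, 1, 0),
               tolerance = 1e-6)
  expect_equal(c(pl$r[1, 2], pl$g[1, 2], pl$b[1, 2]), rep(1 / 3, 3),
               tolerance = 1e-6)
  # black pixel: no division error, all-zero chromaticity
  expect_equal(c(pl$r[2, 1], pl$g[2, 1], pl$b[2, 1]), c(0, 0, 0))
  expect_error(normalize_channels(matrix(1, 4, 4)), "3 channels")
})

test_that("chromaticity sums to one at nonzero pixels", {
  set.seed(7)
  img <- array(runif(30 * 40 * 3, 0.02, 1), c(30, 40, 3))
  pl <- normalize_channels(img)
  expect_lt(max(abs(pl$r + pl$g + pl$b - 1)), 1e-6)
  expect_true(all(pl$r >= 0 & pl$r <= 1 & pl$g >= 0 & pl$g <= 1 &
                    pl$b >= 0 & pl$b <= 1))
})

test_that("Excess Green hits its landmark values", {
  mk <- function(r, g, b) structure(list(r = matrix(r), g = matrix(g),
                                         b = matrix(b)), class = "chromaticity")
  expect_equal(excess_green(mk(0, 1, 0))[1, 1], 2)
  expect_equal(excess_green(mk(1 / 3, 1 / 3, 1 / 3))[1, 1], 0)
  expect_equal(excess_green(mk(1, 0, 0))[1, 1], -1)
  expect_error(excess_green(mk(matrix(0, 2, 2), 1, 0)), "shape")
})

test_that("Excess Green is invariant to uniform channel scaling", {
  set.seed(8)
  img <- array(runif(20 * 20 * 3), c(20, 20, 3))
  e1 <- excess_green(normalize_channels(img))
  e2 <- excess_green(normalize_channels(img * 0.37))
  expect_equal(e1, e2, tolerance = 1e-9)
})

test_that("Otsu binarization separates a bimodal field and matches the scan oracle", {
  f <- matrix(c(rep(-1, 500), rep(2, 500)), 25, 40)
  m <- otsu_binarize(f)
  expect_identical(m == 1L, f == 2)

  set.seed(11)
  for (i in 1:4) {
    fld <- matrix(sample(seq(-1, 2, length.out = 40),
                         600, replace = TRUE, prob = runif(40)), 20, 30)
    expect_equal(otsu_binarize(fld), brute_otsu_mask(fld),
                 ignore_attr = TRUE, info = paste("random field", i))
  }
})

test_that("Otsu threshold agrees with EBImage's within one bin", {
  set.seed(12)
  fld <- matrix(rnorm(400, 0.3, 0.4), 20, 20)
  fld <- pmin(pmax(fld, -1), 2)
  th <- attr(otsu_binarize(fld), "threshold")
  th_eb <- EBImage::otsu((fld + 1) / 3, range = c(0, 1), levels = 256) * 3 - 1
  expect_lt(abs(th - th_eb), 3 / 256 + 1e-9)
})

test_that("constant field yields an all-zero mask with a warning, not a crash", {
  f <- matrix(0.5, 10, 10)
  expect_warning(m <- otsu_binarize(f), "constant")
  expect_true(all(m == 0L))
  expect_true(attr(m, "constant_field"))
})

test_that("morphological cleanup removes specks and fills holes", {
  m <- matrix(0L, 9, 9); m[5, 5] <- 1L
  expect_true(all(morph_clean(m, 3, 1) == 0L))       # isolated pixel opened away

  blob <- matrix(1L, 11, 11); blob[6, 6] <- 0L
  expect_equal(morph_clean(blob, 1, 3)[6, 6], 1L)    # hole closed

  expect_error(morph_clean(m, 4, 3), "odd")
})

test_that("morphology equals the naive set-shift oracle on random masks", {
  set.seed(13)
  for (i in 1:3) {
    m <- matrix(as.integer(runif(32 * 32) < 0.45), 32, 32)
    got <- morph_clean(m, 3, 3)
    want <- naive_close(naive_open(m, 3), 3)
    expect_identical(got, want, info = paste("mask", i))
  }
})

test_that("open/close cleanup is idempotent", {
  set.seed(14)
  m <- matrix(as.integer(runif(40 * 40) < 0.5), 40, 40)
  once <- morph_clean(m, 3, 3)
  expect_identical(morph_clean(once, 3, 3), once)
})

test_that("segmentation recovers the generator's vegetation truth on clean scenes", {
  p <- scene_params(seed = 21, soil_texture_noise = 0)
  sc <- generate_field(p)
  mask <- segment_vegetation(sc$image)
  agree <- mean(mask == sc$truth$vegetation_mask)
  expect_gte(agree, 0.99)
})
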