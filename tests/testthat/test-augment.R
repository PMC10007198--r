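test_that("gamma transform follows s = c r^gamma", {
  set.seed(41)
  img <- matrix(runif(36), 6, 6)
  expect_equal(gamma_transform(img, gamma_params(c = 1, gamma = 1)), img)
  expect_equal(gamma_transform(matrix(0.25), gamma_params(gamma = 0.7))[1, 1],
               0.25^0.7)
  expect_equal(gamma_transform(matrix(1), gamma_params(gamma = 3.3))[1, 1], 1)
  expect_error(gamma_params(gamma = 0), "positive")
  expect_error(gamma_params(c = -1), "positive")
  expect_error(gamma_transform(matrix(1.5)), "\\[0, 1\\]")
})

test_that("gamma < 1 brightens monotonically, pixel-wise", {
  set.seed(42)
  for (i in 1:5) {
    img <- array(runif(27, 0.01, 0.99), dim = c(3, 3, 3))
    out <- gamma_transform(img, gamma_params(gamma = 0.7))
    expect_true(all(out >= img))
    dark <- gamma_transform(img, gamma_params(gamma = 1.5))
    expect_true(all(dark <= img))
    # monotone in r: ordering of pixels is preserved
    o <- order(img)
    expect_true(all(diff(out[o]) >= 0))
  }
})

test_that("gamma composition multiplies exponents (c = 1)", {
  set.seed(43)
  img <- matrix(runif(25), 5, 5)
  g1 <- 0.7; g2 <- 1.8
  a <- gamma_transform(gamma_transform(img, gamma_params(gamma = g2)),
                       gamma_params(gamma = g1))
  b <- gamma_transform(img, gamma_params(gamma = g1 * g2))
  expect_equal(a, b, tolerance = 1e-9)
})

test_that("hsv jitter is seeded, bounded and an identity at zero gains", {
  set.seed(44)
  img <- array(runif(48, 0.2, 0.8), dim = c(4, 4, 3))
  expect_equal(hsv_jitter(img, jitter_params(0, 0, 0), seed = 5), img,
               tolerance = 1e-12)
  j1 <- hsv_jitter(img, seed = 9)
  j2 <- hsv_jitter(img, seed = 9)
  expect_identical(j1, j2)
  expect_false(identical(j1, hsv_jitter(img, seed = 10)))
  expect_true(all(j1 >= 0 & j1 <= 1))
  expect_equal(dim(j1), dim(img))
})

test_that("value-only jitter scales V by a constant factor before clipping", {
  set.seed(45)
  img <- array(runif(75, 0.1, 0.6), dim = c(5, 5, 3))
  out <- hsv_jitter(img, jitter_params(0, 0, 0.464), seed = 3)
  v_in <- rgb_to_hsv(img)[, , 3]
  v_out <- rgb_to_hsv(out)[, , 3]
  unclipped <- v_out < 1 - 1e-9
  ratio <- (v_out / v_in)[unclipped & v_in > 0]
  expect_lt(diff(range(ratio)), 1e-9)
})

test_that("mosaic geometry matches the forced-centre construction", {
  imgs <- lapply(1:4, function(i) array(i / 5, dim = c(640, 640, 3)))
  empty <- data.frame(x_min = numeric(0), y_min = numeric(0),
                      x_max = numeric(0), y_max = numeric(0))
  full <- data.frame(x_min = 0, y_min = 0, x_max = 640, y_max = 640)
  # label-free inputs give a box-free canvas
  m0 <- mosaic(imgs, rep(list(empty), 4), out_size = 640, seed = 1)
  expect_equal(nrow(m0$boxes), 0)
  expect_equal(dim(m0$image), c(640, 640, 3))
  # centre forced to the middle: four quadrant boxes of area (S/2)^2
  m1 <- mosaic(imgs, rep(list(full), 4), out_size = 640,
               center = c(320, 320))
  expect_equal(nrow(m1$boxes), 4)
  areas <- (m1$boxes$x_max - m1$boxes$x_min) *
    (m1$boxes$y_max - m1$boxes$y_min)
  expect_equal(areas, rep(320^2, 4))
  # each quadrant holds its source image's constant value
  expect_equal(m1$image[1, 1, 1], 1 / 5)
  expect_equal(m1$image[1, 640, 1], 2 / 5)
  expect_equal(m1$image[640, 1, 1], 3 / 5)
  expect_equal(m1$image[640, 640, 1], 4 / 5)
  # a box fully outside its quadrant crop is dropped
  off <- data.frame(x_min = 0, y_min = 0, x_max = 100, y_max = 100)
  m2 <- mosaic(imgs, list(off, empty, empty, empty), out_size = 640,
               center = c(320, 320))
  # tile 1 shows only the bottom-right 320x320 of image 1; the box at
  # (0,0,100,100) lies in the cropped-away part
  expect_equal(nrow(m2$boxes), 0)
})

test_that("mosaic boxes stay inside the canvas and respect the area cutoff", {
  set.seed(46)
  for (rep in 1:5) {
    imgs <- lapply(1:4, function(i) array(runif(1), dim = c(300, 300, 3)))
    labs <- lapply(1:4, function(i) {
      n <- sample(0:4, 1)
      if (n == 0) return(data.frame(x_min = numeric(0), y_min = numeric(0),
                                    x_max = numeric(0), y_max = numeric(0)))
      x0 <- runif(n, 0, 250); y0 <- runif(n, 0, 250)
      data.frame(x_min = x0, y_min = y0,
                 x_max = x0 + runif(n, 5, 50), y_max = y0 + runif(n, 5, 50))
    })
    m <- mosaic(imgs, labs, out_size = 400, seed = rep)
    if (nrow(m$boxes) > 0) {
      expect_true(all(m$boxes$x_min >= 0 & m$boxes$y_min >= 0))
      expect_true(all(m$boxes$x_max <= 400 & m$boxes$y_max <= 400))
      expect_true(all(m$boxes$x_max > m$boxes$x_min))
    }
    expect_true(all(m$image >= 0 & m$image <= 1))
  }
})
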