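test_that("cyan extraction follows the naive CMYK formula", {
  px <- function(r, g, b) {
    img <- array(c(r, g, b), c(1, 1, 3))
    extract_cyan(img)[1, 1]
  }
  expect_equal(px(255, 255, 255), 0)   # white: zero cyan
  expect_equal(px(0, 0, 0), 0)         # pure black, K = 1 convention
  expect_equal(px(0, 128, 255), 255)   # K = 0, C = 1
  expect_equal(px(60, 80, 180), round(255 * (180 - 60) / 180))
})

test_that("rolling-ball background subtraction has the opening properties", {
  const <- matrix(77, 40, 40)
  expect_true(all(subtract_background(const, 10) == 0))

  spike <- matrix(0, 64, 64); spike[32, 32] <- 255
  out <- subtract_background(spike, 20)
  expect_gte(out[32, 32], 200)  # a 20-px ball cannot fit a 1-px spike

  # intensity-offset invariance of the subtraction
  set.seed(11)
  img <- matrix(runif(40 * 40, 0, 150), 40, 40)
  expect_equal(subtract_background(img, 8),
               subtract_background(img + 60, 8), tolerance = 1e-10)

  expect_error(subtract_background(matrix(0, 10, 10), 10), "dimension")
})

test_that("contrast enhancement clips by cumulative histogram then stretches", {
  full <- matrix(c(0, 255, 128, 64), 2, 2)
  expect_equal(enhance_contrast(full, 0), full)  # already full range

  set.seed(2)
  v <- round(seq(50, 200, length.out = 1000))
  img <- matrix(v, 40, 25)
  out <- enhance_contrast(img, 0)
  expect_equal(min(out), 0)
  expect_equal(max(out), 255)
  expect_equal(out, (img - 50) * (255 / 150), tolerance = 1e-10)

  # a single outlier is saturated away at 0.2 % total saturation
  v2 <- c(255, round(runif(999, 50, 100)))
  img2 <- matrix(v2, 40, 25)
  out2 <- enhance_contrast(img2, 0.2)
  lo <- min(v2[-1]); hi <- max(v2[-1])
  expect_equal(out2, matrix(pmin(pmax((v2 - lo) * 255 / (hi - lo), 0), 255),
                            40, 25), tolerance = 1e-10)

  expect_warning(enhance_contrast(matrix(5, 4, 4)), "constant")
})

test_that("unsharp mask sharpens edges and is inert on flats", {
  const <- matrix(42, 20, 20)
  expect_equal(unsharp_mask(const), const, tolerance = 1e-9)

  img <- matrix(runif(400, 0, 255), 20, 20)
  expect_equal(unsharp_mask(img, 2, 1e-6), img, tolerance = 1e-3)

  step <- matrix(rep(c(0, 255), each = 8 * 16), 16, 16)
  out <- unsharp_mask(step, 2, 0.6)
  expect_true(all(out >= 0 & out <= 255))      # overshoot clamped
  expect_equal(out[1, 9], 255)                 # bright side saturates
  expect_equal(out[1, 8], 0)                   # dark side saturates
})

test_that("median filter and despeckle remove isolated pixels", {
  salt <- matrix(0, 9, 9); salt[5, 5] <- 255
  expect_true(all(median_filter(salt, 1) == 0))

  const <- matrix(7, 5, 5)
  expect_equal(median_filter(const, 1), const)

  m <- matrix(1:9, 3, 3)
  expect_equal(median_filter(m, 1)[2, 2], 5)

  speck <- matrix(FALSE, 9, 9); speck[5, 5] <- TRUE
  expect_true(!any(despeckle(speck)))
})

test_that("moments threshold preserves the histogram moments", {
  bimodal <- matrix(rep(c(0, 255), each = 200), 20, 20)
  t <- threshold_moments(bimodal)
  expect_true(t >= 0 && t < 255)
  expect_equal(mean(bimodal > t), 0.5)  # foreground is the 255 class

  img <- matrix(c(rep(100, 900), rep(200, 100)), 50, 20)
  t2 <- threshold_moments(img)
  expect_equal(mean(img > t2), 0.1)  # moment-preserving fraction

  set.seed(5)
  rnd <- matrix(sample(0:255, 400, TRUE), 20, 20)
  expect_equal(as.integer(threshold_moments(rnd)),
               as.integer(threshold_moments(rnd[, ncol(rnd):1])))

  expect_error(threshold_moments(matrix(9, 4, 4)), "degenerate")
})

test_that("moments threshold equals the exhaustive-search oracle", {
  set.seed(101)
  for (i in 1:30) {
    n <- 600
    # random bimodal-ish 8-bit histograms
    mu <- sort(sample(10:245, 2))
    v <- c(pmin(pmax(round(rnorm(n * 0.6, mu[1], sample(5:40, 1))), 0), 255),
           pmin(pmax(round(rnorm(n * 0.4, mu[2], sample(5:40, 1))), 0), 255))
    img <- matrix(v, 40)
    expect_equal(as.integer(threshold_moments(img)),
                 brute_moments_threshold(img))
  }
})

test_that("filters are shift-equivariant away from the borders", {
  set.seed(21)
  img <- matrix(runif(60 * 60, 0, 255), 60, 60)
  shifted <- img
  shifted[6:60, 4:60] <- img[1:55, 1:57]
  interior <- function(m) m[16:50, 14:50]
  for (f in list(function(x) median_filter(x, 2),
                 function(x) unsharp_mask(x, 2, 0.6))) {
    a <- f(img); b <- f(shifted)
    expect_equal(interior(b), a[11:45, 11:47], tolerance = 1e-9)
  }
})

test_that("the full binarization chain recovers rendered fiber masks", {
  fib <- fiber_network(192, target_fraction = 0.3, seed = 7)
  img <- render_trichrome(fib)
  mask <- binarize_ecm(img)
  expect_gte(jaccard(mask, fib), 0.9)

  # deterministic
  expect_identical(mask, binarize_ecm(img))

  # additive Gaussian noise sigma = 10 still recovers most of the mask
  noisy <- render_trichrome(fib, noise_sd = 10, seed = 3)
  expect_gte(jaccard(binarize_ecm(noisy), fib), 0.75)
})

test_that("a tissue-free image yields a flagged empty pattern", {
  white <- array(255, c(40, 40, 3))
  expect_warning(p <- binarize_ecm(white), "degenerate")
  expect_false(any(p))
  expect_true(isTRUE(attr(p, "degenerate")))
})
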