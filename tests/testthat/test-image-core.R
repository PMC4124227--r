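test_that("rgb_to_gray averages channels without truncation", {
  ch <- function(v) matrix(v, 2, 2)
  g <- rgb_to_gray(list(R = ch(255), G = ch(255), B = ch(255)))
  expect_equal(unclass(g), ch(255), ignore_attr = TRUE)
  g0 <- rgb_to_gray(list(R = ch(0), G = ch(0), B = ch(0)))
  expect_equal(unclass(g0), ch(0), ignore_attr = TRUE)
  g2 <- rgb_to_gray(list(R = ch(30), G = ch(60), B = ch(90)))
  expect_equal(unclass(g2), ch(60), ignore_attr = TRUE)
  # real-valued mean, no premature integer rounding
  g3 <- rgb_to_gray(list(R = ch(1), G = ch(1), B = ch(0)))
  expect_equal(g3[1, 1], 2 / 3)
  expect_error(rgb_to_gray(list(R = ch(1), G = ch(1), B = matrix(1, 3, 2))),
               "dimensions")
})

test_that("make_gaussian_mask follows the literal formula and normalizes", {
  expect_equal(unclass(make_gaussian_mask(1, 2)), matrix(1), ignore_attr = TRUE)
  # literal prefactor 1/(2 N pi sigma^2) at the center, N = D^2
  m <- make_gaussian_mask(3, 1, normalize = FALSE)
  expect_equal(m[2, 2], 1 / (2 * 9 * pi), tolerance = 1e-12)
  expect_equal(m[1, 1], exp(-1) / (2 * 9 * pi), tolerance = 1e-12)
  # unnormalized mask does not sum to 1 (the formula's quirk)
  expect_false(isTRUE(all.equal(sum(m), 1)))
  m5 <- make_gaussian_mask(5, 2)
  expect_equal(sum(m5), 1, tolerance = 1e-12)
  # symmetry under i<->-i, j<->-j, i<->j
  expect_equal(unclass(m5), unclass(m5)[5:1, ], ignore_attr = TRUE)
  expect_equal(unclass(m5), t(unclass(m5)), ignore_attr = TRUE)
  expect_error(make_gaussian_mask(4, 1), "odd")
  expect_error(make_gaussian_mask(3, 0), "positive")
})

test_that("gaussian_filter preserves constants, impulses, and dimensions", {
  img <- gray_image(matrix(77, 12, 15))
  out <- gaussian_filter(img)
  expect_equal(dim(out), dim(img))
  expect_equal(unclass(out), matrix(77, 12, 15), ignore_attr = TRUE,
               tolerance = 1e-12)
  # impulse response equals the kernel
  imp <- matrix(0, 11, 11); imp[6, 6] <- 100
  m <- make_gaussian_mask(3, 1)
  out <- gaussian_filter(gray_image(imp), m)
  expect_equal(out[5:7, 5:7], unclass(m) * 100, ignore_attr = TRUE,
               tolerance = 1e-12)
  # D = 1 mask is the identity
  expect_equal(unclass(gaussian_filter(img, make_gaussian_mask(1, 1))),
               unclass(img), ignore_attr = TRUE)
  expect_error(gaussian_filter(gray_image(matrix(1, 3, 3)),
                               make_gaussian_mask(5, 1)), "larger")
})

test_that("gaussian_filter matches the nested-loop oracle on random images", {
  set.seed(101)
  for (rep in 1:5) {
    img <- matrix(runif(16 * 16, 0, 255), 16, 16)
    mask <- make_gaussian_mask(5, runif(1, 0.5, 2))
    expect_equal(unclass(gaussian_filter(gray_image(img), mask)),
                 oracle_convolve(img, unclass(mask)),
                 ignore_attr = TRUE, tolerance = 1e-9)
  }
})

test_that("filtering commutes with transposition for symmetric masks", {
  set.seed(7)
  img <- matrix(runif(90, 0, 255), 9, 10)
  m <- make_gaussian_mask(5, 1.3)
  expect_equal(t(unclass(gaussian_filter(gray_image(img), m))),
               unclass(gaussian_filter(gray_image(t(img)), m)),
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("normalized filtering preserves interior means", {
  set.seed(8)
  img <- matrix(runif(400, 50, 200), 20, 20)
  out <- gaussian_filter(gray_image(img))
  # interior away from replicated borders; smoothing redistributes but
  # conserves mass up to boundary leakage
  expect_equal(mean(out[5:16, 5:16]), mean(img[3:18, 3:18]),
               tolerance = 0.02)
})
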