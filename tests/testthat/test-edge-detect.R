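test_that("Sobel masks are exactly the canonical pair", {
  m <- sobel_masks()
  expect_equal(m$Mx, matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3,
                            byrow = TRUE))
  expect_equal(m$My, matrix(c(1, 2, 1, 0, 0, 0, -1, -2, -1), 3, 3,
                            byrow = TRUE))
  expect_equal(sum(m$Mx), 0)
  expect_equal(sum(m$My), 0)
})

test_that("sobel_gradients on constants, steps, and transposes", {
  g0 <- sobel_gradients(gray_image(matrix(42, 8, 8)))
  expect_true(all(g0$S == 0))
  # vertical step: left half 0, right half 255
  img <- cbind(matrix(0, 10, 5), matrix(255, 10, 5))
  g <- sobel_gradients(gray_image(img))
  # hand convolution of Mx across the step: 4 * 255 on the two step cols
  expect_true(all(g$Sx[3:8, 5:6] == 4 * 255))
  expect_true(all(g$Sy[3:8, 5:6] == 0))
  expect_true(all(g$S == abs(g$Sx) + abs(g$Sy)))
  expect_true(all(g$theta_q %in% c(0, 45, 90, 135, 180, -45, -90, -135)))
  # transposition swaps the roles of Sx and Sy up to sign
  set.seed(11)
  r <- matrix(runif(100, 0, 255), 10, 10)
  ga <- sobel_gradients(gray_image(r))
  gb <- sobel_gradients(gray_image(t(r)))
  expect_equal(abs(t(ga$Sx)), abs(gb$Sy), tolerance = 1e-12)
  expect_equal(abs(t(ga$Sy)), abs(gb$Sx), tolerance = 1e-12)
  expect_error(sobel_gradients(gray_image(matrix(1, 2, 5))), "3x3")
})

test_that("non_max_suppress keeps ridge lines and drops plateaus", {
  # ideal one-pixel-wide bright vertical line
  img <- matrix(0, 11, 11); img[, 6] <- 255
  g <- sobel_gradients(gray_image(img))
  e <- non_max_suppress(g, threshold = 10)
  expect_true(all(e[3:9, c(5, 7)]))     # maxima flank the line
  expect_false(any(e[3:9, c(4, 8)]))
  # constant image: no edges at any positive threshold
  gc <- sobel_gradients(gray_image(matrix(9, 9, 9)))
  expect_equal(sum(non_max_suppress(gc, 0.5)), 0L)
  # blurred step (sigmoid over ~3 px, inflection on column 6): exactly
  # one edge column survives; a perfectly linear ramp would tie and be
  # suppressed entirely by the strict comparison
  ramp <- matrix(rep(255 * pnorm(1:10, mean = 6, sd = 1), each = 10),
                 10, 10)
  gr <- sobel_gradients(gray_image(ramp))
  er <- non_max_suppress(gr, threshold = 10)
  cols <- colSums(er[3:8, ])
  expect_equal(which(cols > 0), 6L, ignore_attr = TRUE)
  # edge pixels are a subset of above-threshold gradients
  set.seed(5)
  noisy <- matrix(runif(400, 0, 255), 20, 20)
  gn <- sobel_gradients(gaussian_filter(gray_image(noisy)))
  en <- non_max_suppress(gn, threshold = 200)
  expect_true(all(gn$S[unclass(en)] > 200))
})

test_that("otsu_threshold separates a bimodal gradient population", {
  set.seed(21)
  v <- c(abs(rnorm(900, 0, 5)), rnorm(100, 120, 10))
  th <- otsu_threshold(v)
  expect_gt(th, max(abs(v[1:900])) * 0.5)   # above the bulk of the noise
  expect_lt(th, 110)                        # below the signal mode
})

test_that("thin_edges produces stable one-pixel-wide subsets", {
  # already-thin ring is a fixed point
  ring <- matrix(FALSE, 21, 21)
  for (t in seq(0, 2 * pi, length.out = 200)) {
    ring[11 + round(7 * sin(t)), 11 + round(7 * cos(t))] <- TRUE
  }
  thin1 <- thin_edges(edge_image(ring))
  # idempotence
  expect_equal(unclass(thin_edges(thin1)), unclass(thin1))
  # 2-px thick annulus collapses to a connected 1-px ring
  xs <- 0:24
  d <- sqrt(outer((xs - 12)^2, (xs - 12)^2, `+`))
  fat <- edge_image(d >= 7.2 & d <= 9.2)
  thin2 <- thin_edges(fat)
  expect_true(all(unclass(thin2)[!unclass(fat)] == FALSE))  # subset
  expect_lt(sum(thin2), sum(fat))
  # no fully-set 2x2 block (one-pixel-wide contract)
  m <- unclass(thin2)
  blocks <- m[-25, -25] & m[-1, -25] & m[-25, -1] & m[-1, -1]
  expect_equal(sum(blocks), 0L)
  # ring stays a single connected component (flood fill over 8-neighbors)
  comp <- function(mask) {
    lab <- matrix(0L, nrow(mask), ncol(mask)); cur <- 0L
    for (s in which(mask)) {
      if (lab[s] > 0L) next
      cur <- cur + 1L; stack <- s
      while (length(stack)) {
        p <- stack[[1]]; stack <- stack[-1]
        if (lab[p] > 0L) next
        lab[p] <- cur
        y <- (p - 1L) %% nrow(mask) + 1L; x <- (p - 1L) %/% nrow(mask) + 1L
        for (dy in -1:1) for (dx in -1:1) {
          yy <- y + dy; xx <- x + dx
          if (yy >= 1 && yy <= nrow(mask) && xx >= 1 && xx <= ncol(mask) &&
              mask[yy, xx] && lab[yy, xx] == 0L)
            stack <- c(stack, (xx - 1L) * nrow(mask) + yy)
        }
      }
    }
    cur
  }
  expect_equal(comp(m), 1L)
  # empty image passes through
  expect_equal(sum(thin_edges(edge_image(matrix(FALSE, 5, 5)))), 0L)
})

test_that("detected edges of a rendered disc lie on the true radius", {
  # dark disc of radius 20 on bright background, no noise
  n <- 61; xs <- 0:(n - 1)
  d <- sqrt(outer((xs - 30)^2, (xs - 30)^2, `+`))
  img <- gray_image(matrix(200, n, n) - 140 * pmin(pmax(20.5 - d, 0), 1))
  e <- thin_edges(non_max_suppress(sobel_gradients(gaussian_filter(img))))
  px <- which(unclass(e), arr.ind = TRUE)
  r <- sqrt((px[, 1] - 31)^2 + (px[, 2] - 31)^2)
  expect_gte(mean(abs(r - 20) <= 1.5), 0.95)
})
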