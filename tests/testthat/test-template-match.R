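test_that("make_circle_template builds the tri-valued patterns", {
  tw <- make_circle_template(5, "white_only")
  expect_equal(dim(tw), c(15, 15))                 # D_T = 2 r + 5
  nw <- sum(tw == 1, na.rm = TRUE)
  expect_gte(nw, 28); expect_lte(nw, 32)           # rasterized perimeter
  expect_equal(sum(!is.na(tw)), nw)                # everything else excluded
  tg <- make_circle_template(5, "gray_boundary", g = 0.5)
  expect_equal(sum(tg == 1, na.rm = TRUE), nw)
  expect_gt(sum(tg == 0.5, na.rm = TRUE), 0)
  # gray rings hug the white circle: radii within [r-1.5, r+1.5]
  off <- seq_len(15) - 8
  d <- sqrt(outer(off^2, off^2, `+`))
  expect_true(all(abs(d[!is.na(tg) & tg == 0.5] - 5) <= 1.5))
  # symmetric under 90-degree rotation
  rot90 <- function(m) t(m)[, nrow(m):1]
  expect_equal(unclass(tg), rot90(unclass(tg)), ignore_attr = TRUE)
  expect_error(make_circle_template(1), ">= 2")
})

test_that("match_template scores perfect, empty, and border cases", {
  tm <- make_circle_template(4, "white_only")
  D <- nrow(tm)
  E <- matrix(FALSE, 31, 31)
  # plant the template's own white ring centered at (15, 15) 0-based
  ring <- which(!is.na(unclass(tm)) & unclass(tm) == 1, arr.ind = TRUE)
  k <- (D - 1) / 2
  E[cbind(15 + 1 + ring[, 1] - k - 1, 15 + 1 + ring[, 2] - k - 1)] <- TRUE
  C <- match_template(edge_image(E), tm)
  expect_equal(C[16, 16], 1)                       # perfect match saturates
  expect_true(all(unclass(C) >= 0 & unclass(C) <= 1))
  expect_equal(max(unclass(match_template(
    edge_image(matrix(FALSE, 31, 31)), tm))), 0)   # empty image
  expect_true(all(C[1:k, ] == 0))                  # border overhang scores 0
  expect_error(match_template(edge_image(matrix(FALSE, 5, 5)), tm), "larger")
})

test_that("match_template equals the nested-loop oracle on random inputs", {
  set.seed(33)
  for (rep in 1:5) {
    E <- edge_image(matrix(runif(32 * 32) < 0.15, 32, 32))
    tm <- make_circle_template(4, sample(c("white_only", "gray_boundary"), 1))
    expect_equal(unclass(match_template(E, tm)),
                 oracle_match(unclass(E), unclass(tm)),
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("match map is translation-equivariant in the interior", {
  set.seed(12)
  E <- matrix(runif(40 * 40) < 0.1, 40, 40)
  tm <- make_circle_template(4)
  C1 <- unclass(match_template(edge_image(E), tm))
  shifted <- matrix(FALSE, 40, 40)
  shifted[4:40, 3:40] <- E[1:37, 1:38]             # shift by (dy=3, dx=2)
  C2 <- unclass(match_template(edge_image(shifted), tm))
  expect_equal(C2[18:30, 18:30], C1[15:27, 16:28], tolerance = 1e-12)
})

test_that("gray-boundary template beats white-only on a displaced ring", {
  # ring displaced 1 px from the probe position
  tw <- make_circle_template(5, "white_only")
  tg <- make_circle_template(5, "gray_boundary")
  E <- matrix(FALSE, 25, 25)
  ring <- which(!is.na(unclass(tw)), arr.ind = TRUE)
  k <- (nrow(tw) - 1) / 2
  ctr <- c(12, 12)                                 # 0-based ring center
  # 1-px round-off displacement in each axis (an axis-aligned shift
  # slides half the ring along itself, leaving the two scores tied)
  E[cbind(ctr[2] + 1 + 1 + ring[, 1] - k - 1,
          ctr[1] + 1 + 1 + ring[, 2] - k - 1)] <- TRUE
  Cw <- match_template(edge_image(E), tw)
  Cg <- match_template(edge_image(E), tg)
  at <- function(C) C[ctr[2] + 1, ctr[1] + 1]
  expect_gt(at(Cg), at(Cw))
})

test_that("find_circle_triad recovers planted rings and enforces the floor", {
  tm <- make_circle_template(5, "white_only")
  ring <- which(!is.na(unclass(tm)), arr.ind = TRUE)
  k <- (nrow(tm) - 1) / 2
  plant <- function(E, ctr) {
    E[cbind(ctr[2] + 1 + ring[, 1] - k - 1,
            ctr[1] + 1 + ring[, 2] - k - 1)] <- TRUE
    E
  }
  E <- matrix(FALSE, 61, 61)
  truth <- list(c(15, 15), c(45, 13), c(17, 46))
  for (ctr in truth) E <- plant(E, ctr)
  tg <- make_circle_template(5)
  triad <- find_circle_triad(match_template(edge_image(E), tg),
                             refine = FALSE)
  expect_equal(triad$c1, c(15, 15))
  expect_equal(triad$c2, c(45, 13))
  expect_equal(triad$c3, c(17, 46))
  # two rings only: detection failure with the documented condition class
  E2 <- plant(plant(matrix(FALSE, 61, 61), c(15, 15)), c(45, 13))
  expect_error(find_circle_triad(match_template(edge_image(E2), tg)),
               class = "markalign_detection_failure")
})

test_that("triad recovery survives speckle noise", {
  tm <- make_circle_template(5, "white_only")
  ring <- which(!is.na(unclass(tm)), arr.ind = TRUE)
  k <- (nrow(tm) - 1) / 2
  tg <- make_circle_template(5)
  set.seed(99)
  bad <- 0
  for (rep in 1:25) {
    E <- matrix(runif(71 * 71) < 0.05, 71, 71)     # 5% speckle
    truth <- list(c(18, 18), c(52, 16), c(20, 50))
    for (ctr in truth) {
      E[cbind(ctr[2] + 1 + ring[, 1] - k - 1,
              ctr[1] + 1 + ring[, 2] - k - 1)] <- TRUE
    }
    triad <- find_circle_triad(match_template(edge_image(E), tg),
                               refine = FALSE)
    got <- list(triad$c1, triad$c2, triad$c3)
    for (i in 1:3) if (dist2(got[[i]], truth[[i]]) > 1) bad <- bad + 1
  }
  expect_lte(bad, 2)
})
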