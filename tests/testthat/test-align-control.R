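geom_t <- device_geometry()

# a stage planted a given pixel offset away from chamber (0,0)'s mark
offset_stage <- function(off_px, ...) {
  stage_state(position = mark_position(geom_t, c(0, 0)) -
                off_px * geom_t$pixel_width, ...)
}

test_that("realign_chamber converges in one iteration without noise", {
  set.seed(2)
  st <- offset_stage(c(40, -25), sigma_move_um = 0, rel_sigma = 0,
                     pitch_bias = 0)
  res <- realign_chamber(st, geom_t, c(0, 0),
                         alignment_config(capture_noise_sd = 0))
  expect_equal(res$record$status, "aligned")
  expect_equal(res$record$iterations, 1L)
  expect_lte(res$record$E, 3)
  expect_equal(res$record$E_pre, sqrt(40^2 + 25^2), tolerance = 1)
})

test_that("realign_chamber needs no correction when already on target", {
  set.seed(2)
  st <- offset_stage(c(0.5, -0.5), sigma_move_um = 0, rel_sigma = 0,
                     pitch_bias = 0)
  res <- realign_chamber(st, geom_t, c(0, 0),
                         alignment_config(capture_noise_sd = 0))
  expect_equal(res$record$iterations, 0L)
  expect_identical(res$state$believed, st$believed)
})

test_that("realign_chamber converges under default stage noise", {
  set.seed(31)
  n_ok3 <- 0
  for (i in 1:20) {
    off <- runif(2, 40, 100) * sample(c(-1, 1), 2, TRUE)
    res <- realign_chamber(offset_stage(off), geom_t, c(0, 0),
                           alignment_config())
    if (res$record$status == "aligned" && res$record$iterations <= 3)
      n_ok3 <- n_ok3 + 1
  }
  expect_gte(n_ok3, 19)
})

test_that("realignment reports detection failure when the mark is lost", {
  set.seed(2)
  st <- offset_stage(c(400, 0))        # far outside the camera frame
  res <- realign_chamber(st, geom_t, c(0, 0), alignment_config())
  expect_equal(res$record$status, "detection_failure")
})

test_that("update_chamber_distance is the additive replacement", {
  expect_equal(update_chamber_distance(c(1000, 0), c(1000, 0), c(8, -3)),
               c(1008, -3))
  expect_equal(update_chamber_distance(c(990, 5), c(1000, 0), c(0, 0)),
               c(1000, 0))
})

test_that("distance update lowers pre-alignment error under pitch bias", {
  rep <- run_experiment(cases = c(3, 4), n_repeats = 24, seed = 6,
                        geom = geom_t, measure = "truth")
  s <- rep$summary
  expect_lt(s$mean_E[s$case == 4], s$mean_E[s$case == 3])
})

test_that("image_chamber_center round-trips the mark-to-center shift", {
  set.seed(8)
  st <- offset_stage(c(0, 0), sigma_move_um = 0, rel_sigma = 0,
                     pitch_bias = 0)
  out <- image_chamber_center(st, geom_t,
                              alignment_config(capture_noise_sd = 0))
  expect_equal(out$state$believed, st$believed)     # exactly opposite shifts
  expect_equal(out$state$true, st$true)
  expect_equal(dim(out$image), c(geom_t$frame_px, geom_t$frame_px))
})

test_that("run_experiment orders the four cases like the characterization", {
  rep <- run_experiment(cases = 1:4, n_repeats = 24, seed = 13,
                        geom = geom_t, measure = "truth")
  s <- rep$summary
  expect_equal(s$case, 1:4)
  expect_true(all(s$n == 24))
  m <- function(k) s$mean_E[s$case == k]
  expect_gt(m(1), m(3))                  # never aligning is worst
  expect_gt(m(3), m(2))                  # post-alignment error is smallest
  expect_gt(m(4), m(2))
  expect_equal(s$mean_um, s$mean_E * 0.94, tolerance = 1e-12)
})

test_that("run_scans keeps aligned error within tolerance (pipeline)", {
  rec <- run_scans(1, with_alignment = TRUE, seed = 17, geom = geom_t,
                   config = alignment_config())
  expect_true(all(rec$E <= 3))
  expect_true(all(rec$status == "aligned"))
  expect_equal(nrow(rec), 32)
})
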