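# Closed-loop realignment: detect the mark, convert the pixel
# displacement to a stage move, repeat until the position error drops
# below tolerance; plus the multi-scan experiment drivers that reproduce
# the drift-accumulation and error-distribution characterizations.

#' Alignment-loop parameters
#'
#' @param tolerance stop criterion on the position error E, pixels
#'   (default 3, i.e. ~3 um at 0.94 um/px).
#' @param max_iterations maximum corrective moves per chamber.
#' @param update_distances refine the believed chamber-to-chamber
#'   distances from the residual measured at each arrival.
#' @param detect a [detect_config()].
#' @param capture_noise_sd intensity noise of captured views.
#' @param alpha device rotation seen by the camera, degrees.
#' @param well render the microwell disc in chamber views.
#' @return An `alignment_config` list.
#' @export
alignment_config <- function(tolerance = 3, max_iterations = 5L,
                             update_distances = TRUE,
                             detect = detect_config(),
                             capture_noise_sd = 5, alpha = 0, well = TRUE) {
  stopifnot(tolerance > 0, max_iterations >= 1)
  structure(list(tolerance = tolerance,
                 max_iterations = as.integer(max_iterations),
                 update_distances = update_distances, detect = detect,
                 capture_noise_sd = capture_noise_sd, alpha = alpha,
                 well = well),
            class = "alignment_config")
}

# Capture + detect at the current stage position; returns the pixel
# displacement of the mark reference from the image center (the position
# error vector) or a condition on failure.
measure_displacement <- function(state, geom, chamber, config) {
  view <- capture_view(state, geom, chamber, alpha = config$alpha,
                       noise_sd = config$capture_noise_sd,
                       well = config$well)
  pose <- detect_mark(view$image, config$detect)
  center <- rep((geom$frame_px - 1) / 2, 2L)
  list(disp_px = pose$ref - center, theta = pose$theta)
}

#' Realign the stage onto a chamber's mark
#'
#' Captures the chamber view, runs the detection pipeline, and computes
#' the position error E (pixel distance of the mark reference from the
#' image center).  While E exceeds the tolerance, commands the stage by
#' the measured displacement (converted to micrometers) and re-measures,
#' up to `max_iterations` corrective moves.  Detection failure aborts
#' with a diagnosable record (`status = "detection_failure"`);
#' non-convergence is a flagged record (`status = "not_converged"`), not
#' an exception, so long-running scans survive sporadic failures.
#'
#' @param state a [stage_state()].
#' @param geom a [device_geometry()].
#' @param chamber (row, col), 0-based.
#' @param config an [alignment_config()].
#' @return list with `state` (updated stage) and `record`: chamber,
#'   `E_pre` / `E` (first and final error, px), `E_um`, `theta`,
#'   `iterations` (corrective moves), `status`, `disp_pre_um` (the first
#'   measured residual, for distance updating).
#' @export
realign_chamber <- function(state, geom, chamber, config = alignment_config()) {
  pw <- geom$pixel_width
  E_pre <- NA_real_; disp_pre <- c(NA_real_, NA_real_)
  theta <- NA_real_; iterations <- 0L
  status <- "aligned"; E <- NA_real_
  repeat {
    m <- tryCatch(measure_displacement(state, geom, chamber, config),
                  markalign_detection_failure = function(e) e,
                  markalign_render_error = function(e) e)
    if (inherits(m, "condition")) {
      status <- "detection_failure"
      break
    }
    E <- sqrt(sum(m$disp_px^2))
    theta <- m$theta
    if (iterations == 0L) { E_pre <- E; disp_pre <- m$disp_px * pw }
    if (E <= config$tolerance) { status <- "aligned"; break }
    if (iterations >= config$max_iterations) {
      status <- "not_converged"; break
    }
    state <- move_stage(state, m$disp_px * pw)
    iterations <- iterations + 1L
  }
  record <- list(row = chamber[1], col = chamber[2],
                 E_pre = E_pre, E = E, E_um = E * pw, theta = theta,
                 iterations = iterations, status = status,
                 disp_pre_um = disp_pre)
  list(state = state, record = record)
}

#' Update a believed chamber-to-chamber distance
#'
#' Direct replacement: the new pitch estimate for a transition is the
#' commanded move plus the residual measured on arrival, which cancels
#' systematic pitch errors on subsequent moves.
#'
#' @param believed_pitch current (x, y) pitch estimate, um (unused by the
#'   replacement rule but kept for the contract).
#' @param commanded_move commanded (x, y) move, um.
#' @param residual measured (x, y) arrival residual, um.
#' @return New (x, y) pitch estimate.
#' @export
update_chamber_distance <- function(believed_pitch, commanded_move, residual) {
  as.numeric(commanded_move) + as.numeric(residual)
}

#' Image a chamber center via the mark-to-center shift
#'
#' After alignment on the mark, shifts the view by the configured
#' mark-to-chamber-center offset (1.2 mm in both axes by default),
#' captures the chamber interior, and shifts back by the exactly opposite
#' vector.  No realignment happens inside the round trip: the single
#' short move is assumed misalignment-free.
#'
#' @param state a [stage_state()].
#' @param geom a [device_geometry()].
#' @param config an [alignment_config()].
#' @return list with `state` (after the round trip) and `image`.
#' @export
image_chamber_center <- function(state, geom, config = alignment_config()) {
  shift <- geom$mark_to_chamber
  state <- move_stage(state, shift)
  n <- geom$frame_px
  xs <- 0:(n - 1)
  c0 <- (n - 1) / 2
  d <- sqrt(outer((xs - c0)^2, (xs - c0)^2, `+`))
  img <- matrix(200, n, n) + (150 - 200) * pmin(pmax(45 + 0.5 - d, 0), 1)
  if (config$capture_noise_sd > 0)
    img <- img + matrix(stats::rnorm(n * n, 0, config$capture_noise_sd), n, n)
  state <- move_stage(state, -shift)
  list(state = state, image = gray_image(pmin(pmax(img, 0), 255)))
}

# True position error (px) straight from simulator ground truth.
truth_error_px <- function(state, geom, chamber) {
  sqrt(sum((mark_position(geom, chamber) - state$true)^2)) / geom$pixel_width
}

#' Run serpentine imaging scans over the whole chamber grid
#'
#' Performs `n_scans` serpentine passes over all chambers, measuring the
#' position error E on arrival at each chamber and (optionally)
#' realigning before recording.  Chamber-to-chamber moves use the
#' controller's believed pitch estimates, which are refined from arrival
#' residuals when `config$update_distances` is on.  A per-scan drift is
#' applied to the hidden true position in per-move increments.
#'
#' @param n_scans number of serpentine passes.
#' @param with_alignment realign at every chamber before recording.
#' @param seed RNG seed for the whole experiment.
#' @param geom a [device_geometry()].
#' @param stage a [stage_state()]; default starts aligned on chamber
#'   (0, 0).
#' @param config an [alignment_config()].
#' @param measure `"pipeline"` measures E with the full image pipeline
#'   (falling back to ground truth when the mark drifts out of frame,
#'   flagged `detected = FALSE`); `"truth"` reads E from the simulator
#'   directly (fast, used for unaligned drift accounting).
#' @return data.frame with one row per chamber visit: `scan`, `row`,
#'   `col`, `E_pre`, `E` (final, = `E_pre` when not aligning), `E_um`,
#'   `iterations`, `status`, `detected`.
#' @export
run_scans <- function(n_scans = 5L, with_alignment = TRUE, seed = 1L,
                      geom = device_geometry(), stage = NULL,
                      config = alignment_config(),
                      measure = c("pipeline", "truth")) {
  measure <- match.arg(measure)
  set.seed(seed)
  if (is.null(stage)) stage <- stage_state(position = mark_position(geom, c(0, 0)))
  pw <- geom$pixel_width
  pitch_est <- c(geom$pitch_x, geom$pitch_y)   # believed pitch magnitudes
  n_ch <- geom$rows * geom$cols
  prev <- NULL
  out <- vector("list", n_scans * n_ch)
  k <- 0L
  for (s in seq_len(n_scans)) {
    path <- serpentine_path(geom, s)
    for (i in seq_len(nrow(path))) {
      ch <- path[i, ]
      if (!is.null(prev) && any(ch != prev)) {
        dgrid <- c(ch[["col"]] - prev[["col"]], ch[["row"]] - prev[["row"]])
        commanded <- dgrid * pitch_est
        stage <- move_stage(stage, commanded)
      } else {
        commanded <- c(0, 0)
      }
      stage <- apply_drift(stage, fraction = 1 / n_ch)
      detected <- TRUE
      if (with_alignment && measure == "pipeline") {
        res <- realign_chamber(stage, geom, ch, config)
        stage <- res$state
        rec <- res$record
        if (rec$status == "detection_failure") {
          rec$E_pre <- truth_error_px(stage, geom, ch)
          rec$E <- rec$E_pre
          detected <- FALSE
        }
      } else {
        E_pre <- truth_error_px(stage, geom, ch)
        disp_pre <- mark_position(geom, ch) - stage$true
        rec <- list(E_pre = E_pre, E = E_pre, theta = 0,
                    iterations = 0L, status = "unaligned",
                    disp_pre_um = disp_pre)
        if (with_alignment) {
          # truth-based correction: move by the exact residual
          stage <- move_stage(stage, disp_pre)
          rec$E <- truth_error_px(stage, geom, ch)
          rec$iterations <- 1L
          rec$status <- "aligned"
        }
      }
      if (with_alignment && config$update_distances && any(commanded != 0) &&
          !anyNA(rec$disp_pre_um)) {
        newp <- update_chamber_distance(pitch_est * sign(dgrid), commanded,
                                        rec$disp_pre_um)
        upd <- dgrid != 0
        pitch_est[upd] <- abs(newp[upd])
      }
      k <- k + 1L
      out[[k]] <- data.frame(scan = s, row = ch[["row"]], col = ch[["col"]],
                             E_pre = rec$E_pre, E = rec$E,
                             E_um = rec$E * pw,
                             iterations = rec$iterations,
                             status = rec$status, detected = detected)
      prev <- ch
    }
  }
  do.call(rbind, out)
}

#' Characterize alignment-error distributions over four conditions
#'
#' Reproduces the four-case error characterization: (1) E accumulating
#' with no alignment ever, (2) E immediately after realignment (with
#' distance update), (3) E on arrival at a chamber before correcting,
#' without distance updates, (4) same but with distance updates.  Cases
#' 2 and 4 come from the same aligned run.
#'
#' @param cases subset of 1:4.
#' @param n_repeats measurements per case.
#' @param seed RNG seed.
#' @param geom a [device_geometry()].
#' @param config an [alignment_config()].
#' @param measure see [run_scans()].
#' @return An `experiment_report`: list with `samples` (per-case E
#'   vectors, pixels) and `summary` (data.frame: case, n, mean/sd in px
#'   and um).
#' @export
run_experiment <- function(cases = 1:4, n_repeats = 80L, seed = 1L,
                           geom = device_geometry(),
                           config = alignment_config(),
                           measure = c("pipeline", "truth")) {
  measure <- match.arg(measure)
  stopifnot(all(cases %in% 1:4))
  n_ch <- geom$rows * geom$cols
  n_scans <- ceiling((n_repeats + 1) / n_ch)
  samples <- list()
  take <- function(x) utils::head(x[-1], n_repeats)  # drop the no-move start
  if (1 %in% cases) {
    rec <- run_scans(n_scans, with_alignment = FALSE, seed = seed,
                     geom = geom, config = config, measure = "truth")
    samples[["1"]] <- take(rec$E)
  }
  if (any(c(2, 4) %in% cases)) {
    cfg <- config; cfg$update_distances <- TRUE
    rec <- run_scans(n_scans, with_alignment = TRUE, seed = seed + 1L,
                     geom = geom, config = cfg, measure = measure)
    if (2 %in% cases) samples[["2"]] <- take(rec$E)
    if (4 %in% cases) samples[["4"]] <- take(rec$E_pre)
  }
  if (3 %in% cases) {
    cfg <- config; cfg$update_distances <- FALSE
    rec <- run_scans(n_scans, with_alignment = TRUE, seed = seed + 2L,
                     geom = geom, config = cfg, measure = measure)
    samples[["3"]] <- take(rec$E_pre)
  }
  samples <- samples[order(as.integer(names(samples)))]
  pw <- geom$pixel_width
  summ <- do.call(rbind, lapply(names(samples), function(nm) {
    x <- samples[[nm]]
    data.frame(case = as.integer(nm), n = length(x),
               mean_E = mean(x), sd_E = stats::sd(x),
               mean_um = mean(x) * pw, sd_um = stats::sd(x) * pw)
  }))
  structure(list(samples = samples, summary = summ),
            class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("<experiment_report>\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
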