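# Virtual motorized xy stage and device geometry.  The simulator
# reproduces the phenomenology of a real stage carrying a multichamber
# PDMS device: per-move positioning noise, a systematic pitch bias
# (mis-calibrated chamber-to-chamber distances), and slow directional
# drift (tubing pull, thermal relaxation) accumulating across scans.

#' Device geometry of the multichamber chip
#'
#' Defaults describe a 4 x 8 chamber array (32 chambers) with an
#' alignment mark fabricated at a fixed offset from each chamber center
#' (1.2 mm in both axes) and a camera pixel width of 0.94 um.  The mark
#' itself is three equal circles forming a right-angle triangle; its
#' pixel-scale geometry (`mark_radius_px`, `mark_spacing_px`) is shared
#' by the renderer and the matching template.
#'
#' @param rows,cols chamber grid.
#' @param pitch_x,pitch_y true chamber-to-chamber distances, um.
#' @param mark_to_chamber (x, y) mark-to-chamber-center offset, um.
#' @param pixel_width camera scale, um per pixel.
#' @param mark_radius_px,mark_spacing_px mark circle outer radius and
#'   center-to-center leg length, pixels.
#' @param frame_px camera frame side, pixels.
#' @return A `device_geometry` list.
#' @export
device_geometry <- function(rows = 4L, cols = 8L,
                            pitch_x = 3000, pitch_y = 3000,
                            mark_to_chamber = c(1200, 1200),
                            pixel_width = 0.94,
                            mark_radius_px = 8, mark_spacing_px = 40,
                            frame_px = 301L) {
  stopifnot(rows >= 1, cols >= 1, pitch_x > 0, pitch_y > 0, pixel_width > 0)
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 pitch_x = pitch_x, pitch_y = pitch_y,
                 mark_to_chamber = mark_to_chamber,
                 pixel_width = pixel_width,
                 mark_radius_px = mark_radius_px,
                 mark_spacing_px = mark_spacing_px,
                 frame_px = as.integer(frame_px)),
            class = "device_geometry")
}

#' True device position of a chamber's alignment mark
#'
#' @param geom a [device_geometry()].
#' @param chamber integer (row, col), 0-based.
#' @return (x, y) in um.
#' @export
mark_position <- function(geom, chamber) {
  row <- chamber[1]; col <- chamber[2]
  if (row < 0 || row >= geom$rows || col < 0 || col >= geom$cols)
    stop("chamber out of range", call. = FALSE)
  c(col * geom$pitch_x, row * geom$pitch_y)
}

#' Create a virtual stage
#'
#' The stage tracks a `believed` position (what the controller thinks)
#' and a hidden `true` position; they diverge only through the modeled
#' noise terms.  Each commanded move lands at
#' `displacement * (1 + pitch_bias) + eps`, with `eps` Gaussian per axis
#' with standard deviation `sqrt(sigma_move_um^2 +
#' (rel_sigma * displacement_axis)^2)` - an absolute repeatability floor
#' plus a distance-proportional term.  Because bias and proportional
#' noise scale with the commanded distance, a millimeter-scale
#' chamber-to-chamber move errs by several micrometers while a short
#' corrective move of tens of micrometers lands almost exactly - which is
#' why one realignment iteration usually suffices.  `drift_um` is a
#' deterministic per-scan creep applied by [run_scans()].
#'
#' @param position initial (x, y), um (believed = true at start).
#' @param sigma_move_um absolute per-axis noise floor, um.
#' @param rel_sigma distance-proportional per-axis noise fraction
#'   (default 0.05%).
#' @param pitch_bias systematic fractional scale error of moves (default
#'   0.2%).  With the defaults, a 3 mm chamber-pitch move errs by about
#'   6 um systematically plus ~2 um stochastically - ~7 px at
#'   0.94 um/px - dominated by the mis-calibrated preset distance, which
#'   is why updating the believed distances helps.
#' @param drift_um per-scan drift vector (x, y), um.
#' @return A `stage_state` environment-free list.
#' @export
stage_state <- function(position = c(0, 0), sigma_move_um = 0.3,
                        rel_sigma = 5e-4, pitch_bias = 0.002,
                        drift_um = c(25, 18)) {
  structure(list(true = as.numeric(position),
                 believed = as.numeric(position),
                 sigma_move_um = sigma_move_um, rel_sigma = rel_sigma,
                 pitch_bias = pitch_bias, drift_um = as.numeric(drift_um)),
            class = "stage_state")
}

#' @export
print.stage_state <- function(x, ...) {
  cat(sprintf(
    "<stage_state believed=(%.1f, %.1f) um, hidden error=(%.2f, %.2f) um>\n",
    x$believed[1], x$believed[2],
    x$true[1] - x$believed[1], x$true[2] - x$believed[2]))
  invisible(x)
}

#' Command a stage move
#'
#' Believed position advances by the displacement exactly; the true
#' position picks up the bias and noise terms.  Uses the current RNG
#' stream (seed experiments with `set.seed()` or the `seed` arguments of
#' the experiment drivers).
#'
#' @param state a [stage_state()].
#' @param displacement (x, y) commanded move, um.
#' @return Updated `stage_state`.
#' @export
move_stage <- function(state, displacement) {
  d <- as.numeric(displacement)
  if (length(d) != 2L || any(!is.finite(d)))
    stop("`displacement` must be a finite length-2 vector", call. = FALSE)
  sd_axis <- sqrt(state$sigma_move_um^2 + (state$rel_sigma * d)^2)
  eps <- stats::rnorm(2L, 0, sd_axis)
  state$believed <- state$believed + d
  state$true <- state$true + d * (1 + state$pitch_bias) + eps
  state
}

# Apply one scan's worth of drift to the hidden true position.
apply_drift <- function(state, fraction = 1) {
  state$true <- state$true + state$drift_um * fraction
  state
}

#' Serpentine chamber visiting order
#'
#' Odd-numbered scans traverse the grid boustrophedon (row 0 left to
#' right, row 1 right to left, ...); even-numbered scans retrace the same
#' path in reverse, so consecutive scans start where the previous one
#' ended.
#'
#' @param geom a [device_geometry()].
#' @param scan_index 1-based scan number.
#' @return integer matrix with columns `row`, `col` (0-based), one row
#'   per chamber in visiting order.
#' @export
serpentine_path <- function(geom, scan_index = 1L) {
  rows <- geom$rows; cols <- geom$cols
  path <- do.call(rbind, lapply(seq_len(rows) - 1L, function(r) {
    cs <- if (r %% 2L == 0L) seq_len(cols) - 1L else rev(seq_len(cols) - 1L)
    cbind(row = r, col = cs)
  }))
  if (scan_index %% 2L == 0L) path <- path[rev(seq_len(nrow(path))), ,
                                           drop = FALSE]
  path
}

#' Capture the camera view at a chamber's mark
#'
#' Renders the synthetic chamber view as seen with the stage at its
#' current true position: the mark appears displaced from the image
#' center by `(mark position - true stage position) / pixel_width`
#' pixels.  When the stage is perfectly on target the mark reference sits
#' exactly at the image center.
#'
#' @param state a [stage_state()].
#' @param geom a [device_geometry()].
#' @param chamber (row, col), 0-based.
#' @param alpha device rotation passed to the renderer, degrees.
#' @param noise_sd intensity noise sigma.
#' @param seed renderer seed.
#' @param well show the dark microwell disc.
#' @return list with `image` and `truth` as in [render_mark_image()].
#' @export
capture_view <- function(state, geom, chamber, alpha = 0, noise_sd = 5,
                         seed = NULL, well = TRUE) {
  p_mark <- mark_position(geom, chamber)
  off_px <- (p_mark - state$true) / geom$pixel_width
  spec <- render_spec(size = geom$frame_px, offset = off_px, alpha = alpha,
                      radius = geom$mark_radius_px,
                      spacing = geom$mark_spacing_px,
                      well_radius = if (well) 45 else 0,
                      noise_sd = noise_sd, seed = seed)
  render_mark_image(spec)
}
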