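# Synthetic chamber-view renderer: three dark annuli (the alignment-mark
# circles) at a known sub-pixel pose on a bright background, optionally a
# dark microwell disc and a background gradient, plus additive Gaussian
# intensity noise.  Ground truth is returned alongside every image so the
# whole detection pipeline is testable without a microscope.

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG
# stream; seed = NULL leaves the stream alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Specify a synthetic chamber-view rendering
#'
#' The stated world of the simulator: a bright-field view of the PDMS
#' relief alignment mark.  The mark is three equal annuli (outer radius
#' `radius`, radial thickness `ring_width`) whose centers form a
#' right-angle triangle with leg length `spacing`; the corner circle is
#' the reference.  The mark is darker than the background (polarity
#' configurable via `ring_intensity`).  `offset` displaces the reference
#' from the image center (sub-pixel values meaningful), `alpha` rotates
#' the triad about the reference.
#'
#' @param size image side in pixels (square).
#' @param background background intensity (0-255 scale).
#' @param gradient linear background slope, intensity units per pixel,
#'   length-2 (x, y).
#' @param offset (x, y) displacement of the mark reference from the image
#'   center, pixels.
#' @param alpha mark rotation, degrees (y-down convention of
#'   [estimate_pose()]).
#' @param radius outer radius of each mark circle, pixels.  The circle
#'   template used for detection should share this radius.
#' @param ring_width radial annulus thickness, pixels.
#' @param spacing leg length between circle centers, pixels.
#' @param ring_intensity intensity inside the annuli.
#' @param well_radius radius of the dark microwell disc (0 disables).
#' @param well_offset (x, y) position of the well center relative to the
#'   mark reference, pixels.
#' @param well_intensity intensity of the well disc interior.
#' @param noise_sd additive Gaussian intensity noise sigma.
#' @param seed RNG seed for the noise (NULL: use current stream).
#' @return A `render_spec` list.
#' @export
render_spec <- function(size = 301L, background = 200, gradient = c(0, 0),
                        offset = c(0, 0), alpha = 0,
                        radius = 8, ring_width = 3, spacing = 40,
                        ring_intensity = 60,
                        well_radius = 0, well_offset = c(90, 90),
                        well_intensity = 150,
                        noise_sd = 0, seed = NULL) {
  spec <- list(size = as.integer(size), background = background,
               gradient = gradient, offset = offset, alpha = alpha,
               radius = radius, ring_width = ring_width, spacing = spacing,
               ring_intensity = ring_intensity, well_radius = well_radius,
               well_offset = well_offset, well_intensity = well_intensity,
               noise_sd = noise_sd, seed = seed)
  if (spec$noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  if (spec$radius < 2 || spec$spacing <= 0)
    stop("invalid mark geometry", call. = FALSE)
  class(spec) <- "render_spec"
  spec
}

# Ground-truth circle centers (0-based pixel coords) for a spec.
triad_centers <- function(spec) {
  c0 <- (spec$size - 1) / 2
  ref <- c(c0 + spec$offset[1], c0 + spec$offset[2])
  a <- spec$alpha * pi / 180
  R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)  # y-down rotation
  legs <- cbind(c(spec$spacing, 0), c(0, spec$spacing))
  rot <- R %*% legs
  rbind(c1 = ref, c2 = ref + rot[, 1], c3 = ref + rot[, 2])
}

# Anti-aliased coverage of the annulus set, computed by 4x4 supersampling
# restricted to the triad bounding box.  Returns a full-size matrix of
# coverage fractions in [0, 1].
annuli_coverage <- function(spec, centers, ss = 4L) {
  n <- spec$size
  r_out <- spec$radius
  r_in <- spec$radius - spec$ring_width
  pad <- r_out + 2
  x0 <- max(0, floor(min(centers[, 1]) - pad))
  x1 <- min(n - 1, ceiling(max(centers[, 1]) + pad))
  y0 <- max(0, floor(min(centers[, 2]) - pad))
  y1 <- min(n - 1, ceiling(max(centers[, 2]) + pad))
  sub <- (seq_len(ss) - 0.5) / ss - 0.5
  xs <- as.vector(outer(sub, x0:x1, `+`))   # supersample x coords
  ys <- as.vector(outer(sub, y0:y1, `+`))
  inside <- matrix(0L, length(ys), length(xs))
  for (k in 1:3) {
    d2 <- outer((ys - centers[k, 2])^2, (xs - centers[k, 1])^2, `+`)
    inside <- inside | (d2 <= r_out^2 & d2 >= r_in^2)
  }
  # block-average ss x ss subsamples back to pixel resolution
  m <- matrix(as.numeric(inside), nrow(inside), ncol(inside))
  m <- rowsum(m, rep(seq_len(nrow(m) / ss), each = ss))
  cov <- t(rowsum(t(m), rep(seq_len(ncol(m) / ss), each = ss))) / ss^2
  full <- matrix(0, n, n)
  full[(y0 + 1):(y1 + 1), (x0 + 1):(x1 + 1)] <- cov
  full
}

#' Render a synthetic alignment-mark image
#'
#' Draws the three dark annuli at the rotated triad positions with 4x
#' supersampled anti-aliasing, optionally the dark chamber microwell disc
#' and a linear background gradient, then adds Gaussian intensity noise
#' and clamps to [0, 255].  Deterministic under `spec$seed`.
#'
#' @param spec a [render_spec()].
#' @return list with `image` (a [gray_image()]) and `truth` (a
#'   `mark_pose` holding the exact continuous-valued reference,
#'   orientation, and circle centers).
#' @export
render_mark_image <- function(spec) {
  stopifnot(inherits(spec, "render_spec"))
  n <- spec$size
  centers <- triad_centers(spec)
  pad <- spec$radius + 1
  if (min(centers) < pad || max(centers) > n - 1 - pad)
    stop(structure(class = c("markalign_render_error", "error", "condition"),
                   list(message = "mark not fully inside the frame",
                        call = NULL)))
  xs <- 0:(n - 1)
  img <- matrix(spec$background, n, n)
  if (any(spec$gradient != 0)) {
    img <- img + outer(xs * spec$gradient[2], xs * spec$gradient[1], `+`)
  }
  if (spec$well_radius > 0) {
    wc <- centers[1, ] + spec$well_offset
    d2 <- outer((xs - wc[2])^2, (xs - wc[1])^2, `+`)
    wcov <- pmin(pmax(spec$well_radius + 0.5 - sqrt(d2), 0), 1)
    img <- img + (spec$well_intensity - spec$background) * wcov
  }
  cov <- annuli_coverage(spec, centers)
  img <- img + (spec$ring_intensity - spec$background) * cov
  if (spec$noise_sd > 0) {
    img <- with_seed(spec$seed,
                     img + matrix(stats::rnorm(n * n, 0, spec$noise_sd), n, n))
  }
  img <- pmin(pmax(img, 0), 255)
  truth <- structure(
    list(ref = unname(centers[1, ]), theta = spec$alpha,
         triad = structure(list(c1 = unname(centers[1, ]),
                                c2 = unname(centers[2, ]),
                                c3 = unname(centers[3, ]),
                                scores = rep(NA_real_, 3)),
                           class = "circle_triad")),
    class = "mark_pose")
  list(image = gray_image(img), truth = truth)
}

#' Specify a liquid-replacement frame sequence
#'
#' Emulates dye/water exchange in a chamber: the mean intensity of the
#' chamber region relaxes exponentially from `I_start` to `I_end` with
#' time constant `tau` (first-order mixing), `I(t) = I_end +
#' (I_start - I_end) exp(-t / tau)`, sampled every `dt` seconds.
#'
#' @param tau time constant, seconds (> 0).
#' @param n_frames number of frames.
#' @param dt frame interval, seconds.
#' @param direction `"injection"` (dye in, chamber darkens) or
#'   `"extraction"` (mirror image).
#' @param I_start,I_end chamber plateau intensities.
#' @param size frame side, pixels.
#' @param chamber_radius chamber disc radius, pixels.
#' @param background surround intensity.
#' @param noise_sd per-pixel Gaussian noise sigma.
#' @param seed RNG seed.
#' @return A `mixing_spec` list.
#' @export
mixing_spec <- function(tau = 3, n_frames = 80L, dt = 0.25,
                        direction = c("injection", "extraction"),
                        I_start = 220, I_end = 60, size = 64L,
                        chamber_radius = 24, background = 235,
                        noise_sd = 0, seed = NULL) {
  direction <- match.arg(direction)
  if (tau <= 0) stop("`tau` must be > 0", call. = FALSE)
  if (n_frames < 2L) stop("need at least 2 frames", call. = FALSE)
  structure(list(tau = tau, n_frames = as.integer(n_frames), dt = dt,
                 direction = direction, I_start = I_start, I_end = I_end,
                 size = as.integer(size), chamber_radius = chamber_radius,
                 background = background, noise_sd = noise_sd, seed = seed),
            class = "mixing_spec")
}

#' Render a liquid-replacement frame sequence
#'
#' @param spec a [mixing_spec()].
#' @return list with `frames` (list of [gray_image()]), `times` (seconds),
#'   `roi` (chamber disc: `center` 0-based (x, y), `radius`).
#' @export
render_mixing_frames <- function(spec) {
  stopifnot(inherits(spec, "mixing_spec"))
  n <- spec$size
  t_s <- (seq_len(spec$n_frames) - 1L) * spec$dt
  a <- spec$I_start; b <- spec$I_end
  if (spec$direction == "extraction") { tmp <- a; a <- b; b <- tmp }
  levels <- b + (a - b) * exp(-t_s / spec$tau)
  c0 <- (n - 1) / 2
  xs <- 0:(n - 1)
  disc <- outer((xs - c0)^2, (xs - c0)^2, `+`) <= spec$chamber_radius^2
  frames <- with_seed(spec$seed, lapply(levels, function(lv) {
    img <- matrix(spec$background, n, n)
    img[disc] <- lv
    if (spec$noise_sd > 0)
      img <- img + matrix(stats::rnorm(n * n, 0, spec$noise_sd), n, n)
    gray_image(pmin(pmax(img, 0), 255))
  }))
  list(frames = frames, times = t_s,
       roi = list(center = c(c0, c0), radius = spec$chamber_radius))
}
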