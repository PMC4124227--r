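# Normalized chamber-intensity tracing over a frame sequence, used to
# characterize how long a liquid injection needs to run for a target
# replacement fraction.

#' Extract the normalized chamber intensity trace
#'
#' Computes the mean intensity over the chamber region of interest for
#' every frame and normalizes it between the start and end plateaus,
#' `n(t) = (I(t) - I_start) / (I_end - I_start)`, with each plateau
#' estimated as the mean over the first / last 5% of frames (at least
#' one frame).  The normalized trace runs 0 -> 1 for injection and is the
#' mirror image for extraction; it is invariant to affine intensity
#' rescaling of the frames.
#'
#' @param frames list of [gray_image()] frames (or a
#'   [render_mixing_frames()] result, in which case `roi` and `times`
#'   default from it).
#' @param roi list with `center` (0-based (x, y)) and `radius`, the
#'   chamber disc.
#' @param times frame times in seconds (default: frame index).
#' @return An `intensity_trace`: data.frame-backed list with `times`,
#'   `raw`, `normalized`.
#' @export
chamber_trace <- function(frames, roi = NULL, times = NULL) {
  if (is.list(frames) && !is.null(frames$frames)) {
    if (is.null(roi)) roi <- frames$roi
    if (is.null(times)) times <- frames$times
    frames <- frames$frames
  }
  if (length(frames) < 2L) stop("need at least 2 frames", call. = FALSE)
  if (is.null(roi)) stop("`roi` required", call. = FALSE)
  if (is.null(times)) times <- seq_along(frames) - 1
  f1 <- frames[[1]]
  xs <- 0:(ncol(f1) - 1); ys <- 0:(nrow(f1) - 1)
  mask <- outer((ys - roi$center[2])^2, (xs - roi$center[1])^2, `+`) <=
    roi$radius^2
  if (!any(mask)) stop("ROI outside frame", call. = FALSE)
  raw <- vapply(frames, function(f) mean(f[mask]), numeric(1))
  nf <- length(raw)
  npl <- max(1L, floor(0.05 * nf))
  I0 <- mean(raw[seq_len(npl)])
  I1 <- mean(raw[(nf - npl + 1L):nf])
  if (abs(I1 - I0) < 1e-9 * max(1, abs(I0), abs(I1)))
    stop(structure(class = c("markalign_degenerate_trace",
                             "error", "condition"),
                   list(message = "start and end plateaus coincide",
                        call = NULL)))
  structure(list(times = times, raw = raw,
                 normalized = (raw - I0) / (I1 - I0)),
            class = "intensity_trace")
}

#' @export
print.intensity_trace <- function(x, ...) {
  cat(sprintf("<intensity_trace %d frames, t = [%.3g, %.3g] s>\n",
              length(x$raw), min(x$times), max(x$times)))
  invisible(x)
}

#' Fit the mixing time constant of a trace
#'
#' Log-linear least squares on `log(1 - n(t))` over the informative part
#' of the trace (normalized values within `[lo, hi]`), returning the
#' first-order time constant tau such that `n(t) = 1 - exp(-t / tau)`.
#'
#' @param trace an [chamber_trace()] result.
#' @param lo,hi normalized range used for the fit.
#' @return tau in the units of `trace$times`.
#' @export
fit_time_constant <- function(trace, lo = 0.05, hi = 0.95) {
  n <- trace$normalized
  sel <- n >= lo & n <= hi & n < 1
  if (sum(sel) < 3L) stop("too few points in the fit window", call. = FALSE)
  fit <- stats::lm(log(1 - n[sel]) ~ trace$times[sel])
  -1 / unname(stats::coef(fit)[2])
}

#' Time to reach a target replacement fraction
#'
#' Linear interpolation of the first crossing of the normalized trace
#' through `frac` (default 0.9).
#'
#' @param trace an [chamber_trace()] result.
#' @param frac target normalized change.
#' @return time in the units of `trace$times` (NA if never reached).
#' @export
replacement_time <- function(trace, frac = 0.9) {
  n <- trace$normalized; t_s <- trace$times
  i <- which(n >= frac)[1]
  if (is.na(i)) return(NA_real_)
  if (i == 1L) return(t_s[1])
  t0 <- t_s[i - 1L]; t1 <- t_s[i]
  n0 <- n[i - 1L]; n1 <- n[i]
  t0 + (frac - n0) / (n1 - n0) * (t1 - t0)
}

#' Write a trace as CSV
#' @param trace an [chamber_trace()] result.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(data.frame(t_s = trace$times, raw = trace$raw,
                              normalized = trace$normalized),
                   path, row.names = FALSE)
  invisible(path)
}
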