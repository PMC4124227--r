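# Role assignment for the circle triad, mark reference position and
# orientation, and the chamber position error E.

#' Assign roles to three detected circle centers
#'
#' The mark's circles form a right-angle triangle; in image coordinates
#' (y down) the corner circle sits upper-left (`c1`, the reference), one
#' leg runs right (`c2`), one down (`c3`).  Rule: `c1` minimizes `x + y`;
#' of the remaining two, `c2` has the larger `x - y`, `c3` the smaller.
#' Valid for mark rotations within about +/-30 degrees.  Collinear or
#' rule-ambiguous configurations raise a role-assignment error
#' (condition class `markalign_role_error`).
#'
#' @param centers 3x2 numeric matrix of (x, y) pixel coordinates.
#' @param scores optional numeric(3) match scores carried along.
#' @return A `circle_triad`: list with `c1`, `c2`, `c3` (numeric (x, y))
#'   and `scores`.
#' @export
assign_roles <- function(centers, scores = rep(NA_real_, 3)) {
  centers <- as.matrix(centers)
  if (!all(dim(centers) == c(3L, 2L)))
    stop("`centers` must be a 3x2 matrix", call. = FALSE)
  if (anyNA(centers)) stop("`centers` contains NA", call. = FALSE)
  role_err <- function(msg) {
    stop(structure(class = c("markalign_role_error", "error", "condition"),
                   list(message = msg, call = NULL)))
  }
  # distinctness / collinearity: perpendicular distance of one point from
  # the line through the other two below 2 px is degenerate
  v1 <- centers[2, ] - centers[1, ]
  v2 <- centers[3, ] - centers[1, ]
  cross <- v1[1] * v2[2] - v1[2] * v2[1]
  base <- max(sqrt(sum(v1^2)), sqrt(sum(v2^2)),
              sqrt(sum((centers[3, ] - centers[2, ])^2)))
  if (base < .Machine$double.eps || abs(cross) / base < 2)
    role_err("circle centers are collinear or coincident")
  s <- centers[, 1] + centers[, 2]
  if (sum(s == min(s)) > 1L) role_err("ambiguous upper-left circle")
  i1 <- which.min(s)
  rest <- setdiff(1:3, i1)
  dgn <- centers[rest, 1] - centers[rest, 2]
  if (dgn[1] == dgn[2]) role_err("ambiguous right/lower roles")
  i2 <- rest[which.max(dgn)]
  i3 <- rest[which.min(dgn)]
  ord <- c(i1, i2, i3)
  structure(list(c1 = centers[i1, ], c2 = centers[i2, ], c3 = centers[i3, ],
                 scores = scores[ord]),
            class = "circle_triad")
}

#' @export
print.circle_triad <- function(x, ...) {
  cat(sprintf(
    "<circle_triad c1=(%.2f, %.2f) c2=(%.2f, %.2f) c3=(%.2f, %.2f)>\n",
    x$c1[1], x$c1[2], x$c2[1], x$c2[2], x$c3[1], x$c3[2]))
  invisible(x)
}

#' Estimate the mark pose from a circle triad
#'
#' The reference position is the upper-left circle center `(x_c1, y_c1)`.
#' The orientation averages the angles of the two legs,
#' `theta_m = (atan2(y_c2 - y_c1, x_c2 - x_c1)
#'            + atan2(y_c3 - y_c1, x_c3 - x_c1) - 90) / 2` degrees,
#' with angles measured in y-down image coordinates so that an unrotated
#' mark (c2 due right, c3 due below) reads exactly 0 and a mark rotated
#' by alpha reads alpha.
#'
#' @param triad a `circle_triad` from [assign_roles()] /
#'   [find_circle_triad()].
#' @return A `mark_pose`: list with `ref` (x, y), `theta` (degrees),
#'   `triad`.
#' @export
estimate_pose <- function(triad) {
  if (!inherits(triad, "circle_triad"))
    stop("`triad` must be a circle_triad", call. = FALSE)
  a2 <- atan2(triad$c2[2] - triad$c1[2], triad$c2[1] - triad$c1[1]) * 180 / pi
  a3 <- atan2(triad$c3[2] - triad$c1[2], triad$c3[1] - triad$c1[1]) * 180 / pi
  theta <- (a2 + (a3 - 90)) / 2
  structure(list(ref = unname(triad$c1), theta = theta, triad = triad),
            class = "mark_pose")
}

#' @export
print.mark_pose <- function(x, ...) {
  cat(sprintf("<mark_pose ref=(%.2f, %.2f), theta=%.2f deg>\n",
              x$ref[1], x$ref[2], x$theta))
  invisible(x)
}

#' Chamber position error
#'
#' The position error E is the Euclidean pixel distance between the
#' detected mark reference position and its target position; `E_um`
#' converts it to micrometers using the camera pixel width.
#'
#' @param detected a `mark_pose` or numeric (x, y) point in pixels.
#' @param target numeric (x, y) target point in pixels.
#' @param pixel_width micrometers per pixel (default 0.94).
#' @return An `alignment_error`: list with `E` (pixels) and `E_um`.
#' @export
position_error <- function(detected, target, pixel_width = 0.94) {
  p <- if (inherits(detected, "mark_pose")) detected$ref else as.numeric(detected)
  q <- if (inherits(target, "mark_pose")) target$ref else as.numeric(target)
  E <- sqrt(sum((p - q)^2))
  structure(list(E = E, E_um = E * pixel_width), class = "alignment_error")
}

#' @export
print.alignment_error <- function(x, ...) {
  cat(sprintf("<alignment_error E = %.2f px (%.2f um)>\n", x$E, x$E_um))
  invisible(x)
}

#' Serialize a pose record to JSON
#'
#' @param pose a `mark_pose`.
#' @param chamber_id optional chamber label.
#' @param error optional `alignment_error`.
#' @param path optional file; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly if written to file).
#' @export
pose_to_json <- function(pose, chamber_id = NA, error = NULL, path = NULL) {
  rec <- list(chamber_id = chamber_id,
              x_ref = pose$ref[1], y_ref = pose$ref[2],
              theta_deg = pose$theta,
              E_px = if (is.null(error)) NA else error$E,
              E_um = if (is.null(error)) NA else error$E_um,
              scores = pose$triad$scores)
  js <- jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA, na = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
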