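# Tri-valued circle templates and the normalized edge-template match map
# whose three strongest well-separated peaks localize the mark's circles.

# Midpoint-style one-pixel-wide circle rasterization: for every x in
# [-r, r] mark (x, round(+-sqrt(r^2 - x^2))) and the transpose, giving
# the thin 8-connected digital circle (the same topology the thinned
# edge detector emits).  Returns a logical mask of side `D` centered at
# 1-based pixel `c0`.
circle_raster <- function(r, D, c0) {
  mask <- matrix(FALSE, D, D)
  if (r < 1L) { mask[c0, c0] <- TRUE; return(mask) }
  x <- -r:r
  y <- round(sqrt(r^2 - x^2))
  px <- rbind(cbind(x, y), cbind(x, -y), cbind(y, x), cbind(-y, x))
  mask[cbind(px[, 2] + c0, px[, 1] + c0)] <- TRUE
  mask
}

#' Build a circle template
#'
#' Templates are square, size `D_T = 2 r_t + 5`, and tri-valued: *white*
#' pixels (weight 1) form the one-pixel-wide rasterized circle of radius
#' `r_t`; in the `gray_boundary` variant the immediately inner and outer
#' rings (radii `r_t - 1` and `r_t + 1`) carry partial weight `g` so edge
#' pixels displaced by rasterization round-off still contribute; *black*
#' pixels are excluded and carry no weight at all (`NA` internally).
#'
#' @param r_t circle radius in pixels (>= 2).
#' @param variant `"gray_boundary"` (default, the robust one) or
#'   `"white_only"`.
#' @param g gray weight in (0, 1], default 0.5.
#' @return A `template_image`: numeric matrix with `NA` = excluded,
#'   attributes `r_t`, `variant`, `g`.
#' @export
make_circle_template <- function(r_t, variant = c("gray_boundary", "white_only"),
                                 g = 0.5) {
  variant <- match.arg(variant)
  if (length(r_t) != 1L || is.na(r_t) || r_t < 2)
    stop("`r_t` must be >= 2", call. = FALSE)
  if (g <= 0 || g > 1) stop("`g` must be in (0, 1]", call. = FALSE)
  r_t <- as.integer(r_t)
  D_T <- 2L * r_t + 5L
  c0 <- r_t + 3L                       # center pixel (1-based)
  tmpl <- matrix(NA_real_, D_T, D_T)
  if (variant == "gray_boundary") {
    tmpl[circle_raster(r_t - 1L, D_T, c0)] <- g
    tmpl[circle_raster(r_t + 1L, D_T, c0)] <- g
  }
  tmpl[circle_raster(r_t, D_T, c0)] <- 1
  structure(tmpl, class = c("template_image", class(matrix())),
            r_t = r_t, variant = variant, g = g)
}

#' @export
print.template_image <- function(x, ...) {
  cat(sprintf("<template_image %dx%d, r_t = %d, %s, %d weighted px>\n",
              ncol(x), nrow(x), attr(x, "r_t"), attr(x, "variant"),
              sum(!is.na(x))))
  invisible(x)
}

#' Match a circle template against an edge image
#'
#' For each position (x, y) the score is the weight-normalized sum of edge
#' pixels under the non-excluded template pixels with the template
#' centered there:
#' `C(x,y) = sum_ij S_E(x+i, y+j) I_T(i,j) / sum_ij I_T(i,j)` over
#' non-excluded (i, j).  Scores lie in [0, 1].  Positions where the
#' template would overhang the image border score 0 (no partial-overlap
#' renormalization); marks that close to the border count as detection
#' failures.
#'
#' @param edges an [edge_image()].
#' @param tmpl a [make_circle_template()] result.
#' @return A `match_map`: numeric matrix of scores, same size as `edges`,
#'   carrying the template's `r_t` as an attribute.
#' @export
match_template <- function(edges, tmpl) {
  h <- nrow(edges); w <- ncol(edges)
  D_T <- nrow(tmpl)
  if (D_T > h || D_T > w) stop("template larger than image", call. = FALSE)
  k <- (D_T - 1L) %/% 2L               # D_T is odd by construction
  wsum <- sum(tmpl, na.rm = TRUE)
  # sparse accumulation: every edge pixel at (xe, ye) contributes weight
  # w(i,j) to C(xe - i, ye - j) for each non-excluded template offset
  eidx <- which(unclass(edges))
  ye <- (eidx - 1L) %% h               # 0-based
  xe <- (eidx - 1L) %/% h
  num <- numeric(h * w)
  for (wt in unique(tmpl[!is.na(tmpl)])) {
    tix <- which(!is.na(tmpl) & tmpl == wt, arr.ind = TRUE)
    di <- tix[, 2] - k - 1L            # template x offsets i
    dj <- tix[, 1] - k - 1L            # template y offsets j
    x0 <- rep(xe, times = length(di)) - rep(di, each = length(xe))
    y0 <- rep(ye, times = length(dj)) - rep(dj, each = length(ye))
    ok <- x0 >= 0L & x0 < w & y0 >= 0L & y0 < h
    if (any(ok))
      num <- num + wt * tabulate(x0[ok] * h + y0[ok] + 1L, nbins = h * w)
  }
  C <- matrix(num, h, w) / wsum
  # zero out border band where the template overhangs
  if (k > 0L) {
    C[c(seq_len(k), (h - k + 1L):h), ] <- 0
    C[, c(seq_len(k), (w - k + 1L):w)] <- 0
  }
  structure(C, class = c("match_map", class(matrix())),
            r_t = attr(tmpl, "r_t"))
}

#' @export
print.match_map <- function(x, ...) {
  cat(sprintf("<match_map %d x %d, max C = %.3f>\n",
              ncol(x), nrow(x), max(x)))
  invisible(x)
}

# Deterministic argmax: largest value, ties broken by smallest y then x.
# Returns 0-based (x, y).
peak_position <- function(C) {
  m <- max(C)
  cand <- which(C == m, arr.ind = TRUE)
  cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
  c(x = unname(cand[1, 2]) - 1L, y = unname(cand[1, 1]) - 1L, score = m)
}

# Center-of-mass refinement of a peak over its 3x3 C-map neighborhood.
# The window minimum is subtracted (removing the local pedestal that
# biases the centroid toward the window center) and the remaining mass
# cubed to sharpen the peak before the centroid; returns real-valued
# 0-based (x, y).
refine_peak <- function(C, x, y) {
  h <- nrow(C); w <- ncol(C)
  ys <- max(1L, y):min(h, y + 2L)      # rows y..y+2 are 0-based y-1..y+1
  xs <- max(1L, x):min(w, x + 2L)
  block <- C[ys, xs, drop = FALSE]
  block <- (block - min(block))^3
  s <- sum(block)
  if (s <= 0) return(c(x, y))
  cx <- sum(sweep(block, 2, xs - 1L, `*`)) / s
  cy <- sum(block * (ys - 1L)) / s
  c(cx, cy)
}

#' Locate the three circle centers in a match map
#'
#' Takes the global maximum of the map, suppresses an exclusion disc
#' around it, and repeats twice more.  Ties are broken deterministically
#' (smallest y, then x).  Peaks below `floor_score` do not count; finding
#' fewer than three is a detection failure (condition class
#' `markalign_detection_failure`), signalling the realignment caller to
#' abort or re-image.  Peak positions are refined to sub-pixel precision
#' by a center-of-mass over the 3x3 score neighborhood unless
#' `refine = FALSE`.
#'
#' @param C a [match_template()] map.
#' @param exclusion_radius suppression radius in pixels; default
#'   `2 * r_t` from the map's template attribute.
#' @param floor_score minimum acceptable peak score (default 0.2).
#' @param refine sub-pixel center-of-mass refinement (default TRUE).
#' @return A `circle_triad` (see [assign_roles()]): role-assigned centers
#'   `c1` (upper-left), `c2` (right), `c3` (lower) plus their scores.
#' @export
find_circle_triad <- function(C, exclusion_radius = NULL, floor_score = 0.2,
                              refine = TRUE) {
  if (is.null(exclusion_radius)) {
    r_t <- attr(C, "r_t")
    if (is.null(r_t)) stop("`exclusion_radius` required", call. = FALSE)
    exclusion_radius <- 2 * r_t
  }
  W <- unclass(C)
  h <- nrow(W); w <- ncol(W)
  centers <- matrix(NA_real_, 3L, 2L)
  scores <- numeric(3L)
  for (n in 1:3) {
    pk <- peak_position(W)
    if (pk[["score"]] < floor_score) {
      stop(structure(class = c("markalign_detection_failure",
                               "error", "condition"),
                     list(message = sprintf(
                       "only %d of 3 circle peaks above floor score %.2f",
                       n - 1L, floor_score), call = NULL)))
    }
    x0 <- pk[["x"]]; y0 <- pk[["y"]]
    centers[n, ] <- if (refine) refine_peak(W, x0, y0) else c(x0, y0)
    scores[n] <- pk[["score"]]
    ys <- max(0L, y0 - exclusion_radius):min(h - 1L, y0 + exclusion_radius)
    xs <- max(0L, x0 - exclusion_radius):min(w - 1L, x0 + exclusion_radius)
    disc <- outer((ys - y0)^2, (xs - x0)^2, `+`) <= exclusion_radius^2
    W[ys + 1L, xs + 1L][disc] <- -Inf
  }
  assign_roles(centers, scores = scores)
}
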