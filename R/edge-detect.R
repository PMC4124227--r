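# Sobel gradient extraction, non-maximum suppression along the quantized
# gradient direction ("prethinning"), and two-subiteration thinning down
# to one-pixel-wide edges.

#' Sobel operator masks
#'
#' The fixed 3x3 horizontal and vertical gradient masks.  Rows index the
#' vertical offset j, columns the horizontal offset i.
#' @return list with `Mx` and `My` integer matrices.
#' @export
sobel_masks <- function() {
  list(
    Mx = matrix(c(-1, 0, 1,
                  -2, 0, 2,
                  -1, 0, 1), 3, 3, byrow = TRUE),
    My = matrix(c( 1,  2,  1,
                   0,  0,  0,
                  -1, -2, -1), 3, 3, byrow = TRUE)
  )
}

#' Compute the Sobel gradient field
#'
#' Convolves the image with the two Sobel masks (replicated borders) and
#' derives the total-gradient magnitude using the `|Sx| + |Sy|`
#' approximation, the gradient angle `theta` via the two-argument
#' arctangent (degrees), and `theta_q`, the angle rounded to the nearest
#' multiple of 45 degrees.
#'
#' @param img a [gray_image()] at least 3x3.
#' @return A `gradient_field`: list with matrices `Sx`, `Sy`, `S`,
#'   `theta`, `theta_q`.
#' @export
sobel_gradients <- function(img) {
  if (nrow(img) < 3L || ncol(img) < 3L)
    stop("image must be at least 3x3", call. = FALSE)
  m <- sobel_masks()
  Sx <- correlate_replicate(img, m$Mx)
  Sy <- correlate_replicate(img, m$My)
  S <- abs(Sx) + abs(Sy)
  theta <- atan2(Sy, Sx) * 180 / pi
  theta_q <- round(theta / 45) * 45
  theta_q[theta_q == -180] <- 180
  structure(list(Sx = Sx, Sy = Sy, S = S, theta = theta, theta_q = theta_q),
            class = "gradient_field")
}

#' @export
print.gradient_field <- function(x, ...) {
  cat(sprintf("<gradient_field %d x %d px, max |S| = %.4g>\n",
              ncol(x$S), nrow(x$S), max(x$S)))
  invisible(x)
}

#' Otsu threshold of a gradient-magnitude map
#'
#' Standard between-class-variance maximization on a 256-bin histogram of
#' the values; used as the default gate rejecting weak texture gradients
#' before non-maximum suppression.
#'
#' @param S numeric matrix or vector of non-negative magnitudes.
#' @param nbins histogram bins.
#' @return Scalar threshold on the scale of `S`.
#' @export
otsu_threshold <- function(S, nbins = 256L) {
  v <- as.numeric(S)
  rng <- range(v)
  if (diff(rng) < .Machine$double.eps) return(rng[2])
  br <- seq(rng[1], rng[2], length.out = nbins + 1L)
  h <- tabulate(findInterval(v, br, rightmost.closed = TRUE), nbins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mids <- (br[-1] + br[-length(br)]) / 2
  mu <- cumsum(p * mids)
  mu_t <- mu[nbins]
  denom <- omega * (1 - omega)
  sigma_b <- (mu_t * omega - mu)^2 / ifelse(denom > 0, denom, NA)
  k <- which.max(sigma_b)
  mids[k]
}

# Shift a matrix by (dy, dx), filling vacated cells with `fill`.
shift_mat <- function(m, dy, dx, fill = 0) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(fill, h, w)
  ys <- max(1L, 1L - dy):min(h, h - dy)
  xs <- max(1L, 1L - dx):min(w, w - dx)
  if (length(ys) > 0L && length(xs) > 0L)
    out[ys, xs] <- m[ys + dy, xs + dx, drop = FALSE]
  out
}

#' Non-maximum suppression ("prethinning")
#'
#' A pixel is kept as an edge point iff its gradient magnitude exceeds the
#' threshold and is strictly greater than the magnitudes of both
#' neighbors along the quantized gradient direction; ties suppress the
#' pixel, which prevents double-width edges on plateaus.
#'
#' @param grad a [sobel_gradients()] result.
#' @param threshold `"otsu"` (default) for an automatic global gate on the
#'   magnitude histogram, or a non-negative number.
#' @return An `edge_image`: logical matrix, `TRUE` = edge.
#' @export
non_max_suppress <- function(grad, threshold = "otsu") {
  S <- grad$S
  if (identical(threshold, "otsu")) {
    threshold <- if (max(S) < 1e-9) Inf else otsu_threshold(S)
  }
  if (!is.numeric(threshold) || threshold < 0)
    stop("`threshold` must be \"otsu\" or a non-negative number",
         call. = FALSE)
  tq <- grad$theta_q
  # quantized directions collapse to four comparison axes (dy, dx)
  axes <- list(`0`   = c(0L, 1L),  `45`  = c(1L, 1L),
               `90`  = c(1L, 0L),  `135` = c(1L, -1L))
  edge <- matrix(FALSE, nrow(S), ncol(S))
  axis_of <- tq %% 180             # 0,45,90,135 per pixel (-45 -> 135)
  for (a in names(axes)) {
    d <- axes[[a]]
    sel <- axis_of == as.numeric(a)
    if (!any(sel)) next
    nb1 <- shift_mat(S, d[1], d[2], fill = -Inf)
    nb2 <- shift_mat(S, -d[1], -d[2], fill = -Inf)
    edge[sel] <- S[sel] > threshold & S[sel] > nb1[sel] & S[sel] > nb2[sel]
  }
  edge_image(edge)
}

#' Construct an edge image
#' @param mat logical matrix (`TRUE` = edge pixel).
#' @return An `edge_image` object.
#' @export
edge_image <- function(mat) {
  if (!is.matrix(mat) || !is.logical(mat))
    stop("`mat` must be a logical matrix", call. = FALSE)
  structure(mat, class = c("edge_image", class(matrix())))
}

#' @export
print.edge_image <- function(x, ...) {
  cat(sprintf("<edge_image %d x %d px, %d edge pixels>\n",
              ncol(x), nrow(x), sum(x)))
  invisible(x)
}

# 8-neighborhood in the Zhang-Suen order P2..P9 (N, NE, E, SE, S, SW, W,
# NW) as shifted copies of a logical matrix.
zs_neighbors <- function(P) {
  list(shift_mat(P, -1L, 0L), shift_mat(P, -1L, 1L),
       shift_mat(P, 0L, 1L),  shift_mat(P, 1L, 1L),
       shift_mat(P, 1L, 0L),  shift_mat(P, 1L, -1L),
       shift_mat(P, 0L, -1L), shift_mat(P, -1L, -1L))
}

zs_pass <- function(P, second) {
  nb <- zs_neighbors(P)
  B <- Reduce(`+`, nb)
  ring <- c(nb, nb[1])
  A <- matrix(0L, nrow(P), ncol(P))
  for (k in 1:8) A <- A + (!ring[[k]] & ring[[k + 1]])
  if (!second) {
    c3 <- !(nb[[1]] & nb[[3]] & nb[[5]])   # P2 P4 P6
    c4 <- !(nb[[3]] & nb[[5]] & nb[[7]])   # P4 P6 P8
  } else {
    c3 <- !(nb[[1]] & nb[[3]] & nb[[7]])   # P2 P4 P8
    c4 <- !(nb[[1]] & nb[[5]] & nb[[7]])   # P2 P6 P8
  }
  del <- P & B >= 2 & B <= 6 & A == 1L & c3 & c4
  P & !del
}

#' Thin edges to one-pixel width
#'
#' Zhang-Suen two-subiteration thinning, iterated until stable.  The
#' result is a subset of the input edge set and (apart from degenerate
#' solid blocks the suppressor never emits) contains no fully-set 2x2
#' neighborhood.  Idempotent.
#'
#' @param prethinned an [edge_image()].
#' @param max_iter safety cap on full iterations.
#' @return A thinned `edge_image`.
#' @export
thin_edges <- function(prethinned, max_iter = 100L) {
  full <- unclass(prethinned)
  if (!is.logical(full)) stop("`prethinned` must be logical", call. = FALSE)
  if (!any(full)) return(edge_image(full))
  # iterate only over the bounding box of set pixels (1 px margin);
  # everything outside is empty and cannot change
  idx <- which(full, arr.ind = TRUE)
  ys <- max(1L, min(idx[, 1]) - 1L):min(nrow(full), max(idx[, 1]) + 1L)
  xs <- max(1L, min(idx[, 2]) - 1L):min(ncol(full), max(idx[, 2]) + 1L)
  P <- full[ys, xs, drop = FALSE]
  for (it in seq_len(max_iter)) {
    Q <- zs_pass(P, second = FALSE)
    Q <- zs_pass(Q, second = TRUE)
    if (identical(Q, P)) break
    P <- Q
  }
  full[ys, xs] <- P
  edge_image(full)
}
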