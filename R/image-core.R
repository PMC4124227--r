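#' @keywords internal
"_PACKAGE"

# Images are numeric matrices indexed [row, col] = [y + 1, x + 1]:
# x runs horizontally (columns), y vertically downward (rows), 0-based in
# all user-facing coordinates.  Intensities live on the 0..255 scale and
# stay real-valued through the pipeline; quantization to 8 bit happens
# only on file write.

#' Construct a grayscale image
#'
#' A `gray_image` is a numeric matrix of intensities on the 0--255 scale
#' with `nrow = height` and `ncol = width`.  Pixel coordinates are 0-based
#' with the origin at the top-left corner and y increasing downward, the
#' usual raster convention.
#'
#' @param mat numeric matrix of intensities.
#' @return A `gray_image` object.
#' @export
gray_image <- function(mat) {
  if (!is.matrix(mat) || !is.numeric(mat))
    stop("`mat` must be a numeric matrix", call. = FALSE)
  if (nrow(mat) < 1L || ncol(mat) < 1L)
    stop("image dimensions must be positive", call. = FALSE)
  if (anyNA(mat)) stop("image contains NA intensities", call. = FALSE)
  structure(mat, class = c("gray_image", class(matrix())))
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image %d x %d px, intensity [%.4g, %.4g]>\n",
              ncol(x), nrow(x), min(x), max(x)))
  invisible(x)
}

img_width <- function(img) ncol(img)
img_height <- function(img) nrow(img)

#' Convert an RGB image to grayscale
#'
#' Pixel brightness is the plain channel mean (R + G + B) / 3, kept
#' real-valued (no integer truncation).
#'
#' @param img either a `height x width x 3` numeric array or a list with
#'   elements `R`, `G`, `B` (matrices of identical dimensions).
#' @return A [gray_image()].
#' @export
rgb_to_gray <- function(img) {
  if (is.list(img) && all(c("R", "G", "B") %in% names(img))) {
    r <- img$R; g <- img$G; b <- img$B
    if (!identical(dim(r), dim(g)) || !identical(dim(r), dim(b)))
      stop("R, G, B channels must share identical dimensions", call. = FALSE)
  } else if (is.array(img) && length(dim(img)) == 3L && dim(img)[3] == 3L) {
    r <- img[, , 1]; g <- img[, , 2]; b <- img[, , 3]
  } else {
    stop("`img` must be an RGB array or a list(R, G, B)", call. = FALSE)
  }
  gray_image((r + g + b) / 3)
}

#' Build a 2-D Gaussian smoothing mask
#'
#' Weights follow `G(i,j) = 1/(2 N pi sigma^2) * exp(-(i^2+j^2)/(2 sigma^2))`
#' on the square support `i, j in [-(D-1)/2, (D-1)/2]`, with `N = D^2`.
#' That prefactor does not make the weights sum to one, so a literal mask
#' darkens images; by default the mask is therefore renormalized to unit
#' sum (`normalize = TRUE`).  The literal form stays available behind the
#' flag for fidelity checks.
#'
#' @param D odd mask size in pixels.
#' @param sigma Gaussian standard deviation in pixels.
#' @param normalize rescale weights to sum to exactly 1 (default).
#' @return A `gaussian_mask`: a `D x D` matrix with attributes `D`,
#'   `sigma`, `normalized`.
#' @export
make_gaussian_mask <- function(D = 5L, sigma = 1.0, normalize = TRUE) {
  if (length(D) != 1L || is.na(D) || D < 1L || D %% 2L == 0L)
    stop("`D` must be a positive odd integer", call. = FALSE)
  if (length(sigma) != 1L || is.na(sigma) || sigma <= 0)
    stop("`sigma` must be positive", call. = FALSE)
  D <- as.integer(D)
  half <- (D - 1L) %/% 2L
  idx <- seq(-half, half)
  r2 <- outer(idx^2, idx^2, `+`)
  N <- D^2
  w <- exp(-r2 / (2 * sigma^2)) / (2 * N * pi * sigma^2)
  if (normalize) w <- w / sum(w)
  structure(w, class = c("gaussian_mask", class(matrix())),
            D = D, sigma = sigma, normalized = normalize)
}

# Replicate-pad a matrix by k rows/columns on every side.
pad_replicate <- function(mat, k) {
  if (k == 0L) return(mat)
  ri <- c(rep(1L, k), seq_len(nrow(mat)), rep(nrow(mat), k))
  ci <- c(rep(1L, k), seq_len(ncol(mat)), rep(ncol(mat), k))
  mat[ri, ci, drop = FALSE]
}

# Correlation of `img` with an arbitrary (2k+1)^2 kernel using shifted
# sums over a replicate-padded copy; out(x,y) = sum_ij w(i,j) img(x+i,y+j).
correlate_replicate <- function(img, kern) {
  k <- (nrow(kern) - 1L) %/% 2L
  h <- nrow(img); w <- ncol(img)
  pad <- pad_replicate(unclass(img), k)
  out <- matrix(0, h, w)
  for (j in seq_len(ncol(kern))) {
    dy <- j - k - 1L            # kernel row offset j maps to image y + j
    for (i in seq_len(nrow(kern))) {
      wt <- kern[j, i]
      if (wt == 0) next
      dx <- i - k - 1L
      out <- out + wt * pad[(1L + k + dy):(h + k + dy),
                            (1L + k + dx):(w + k + dx), drop = FALSE]
    }
  }
  out
}

#' Gaussian lowpass filtering
#'
#' Convolves the image with a Gaussian mask,
#' `I_G(x,y) = sum_i sum_j G(i,j) I_O(x+i, y+j)`, with border pixels
#' handled by edge replication so no dark frame is introduced.  Output
#' dimensions equal input dimensions.
#'
#' @param img a [gray_image()] (or plain numeric matrix).
#' @param mask a [make_gaussian_mask()] result (default `D = 5`,
#'   `sigma = 1`).
#' @return The filtered [gray_image()].
#' @export
gaussian_filter <- function(img, mask = make_gaussian_mask()) {
  if (!is.matrix(img)) stop("`img` must be a matrix", call. = FALSE)
  D <- nrow(mask)
  if (D > min(dim(img)))
    stop("mask larger than image", call. = FALSE)
  gray_image(correlate_replicate(img, unclass(mask)))
}
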