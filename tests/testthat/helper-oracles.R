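# Independent brute-force oracles: literal nested-loop transcriptions of
# the convolution and template-match definitions, kept deliberately
# separate from the package's vectorized implementations.

# out(x, y) = sum_ij G(i, j) I(x+i, y+j), replicated borders.
oracle_convolve <- function(img, kern) {
  h <- nrow(img); w <- ncol(img)
  k <- (nrow(kern) - 1) / 2
  clampi <- function(v, lo, hi) pmin(pmax(v, lo), hi)
  out <- matrix(0, h, w)
  for (y in 1:h) for (x in 1:w) {
    s <- 0
    for (j in -k:k) for (i in -k:k) {
      s <- s + kern[j + k + 1, i + k + 1] *
        img[clampi(y + j, 1, h), clampi(x + i, 1, w)]
    }
    out[y, x] <- s
  }
  out
}

# C(x, y) = sum_ij S_E(x+i, y+j) I_T(i, j) / sum_ij I_T(i, j) over
# non-excluded template pixels, template centered; border overhang -> 0.
oracle_match <- function(edges, tmpl) {
  E <- matrix(as.numeric(edges), nrow(edges), ncol(edges))
  h <- nrow(E); w <- ncol(E)
  D <- nrow(tmpl); k <- (D - 1) / 2
  den <- sum(tmpl, na.rm = TRUE)
  C <- matrix(0, h, w)
  for (y in 1:h) for (x in 1:w) {
    if (y - k < 1 || y + k > h || x - k < 1 || x + k > w) next
    s <- 0
    for (j in 1:D) for (i in 1:D) {
      wt <- tmpl[j, i]
      if (!is.na(wt)) s <- s + wt * E[y + j - k - 1, x + i - k - 1]
    }
    C[y, x] <- s / den
  }
  C
}

# Rotate points (x, y) about a pivot by alpha degrees in y-down image
# coordinates (positive alpha turns the +x leg toward +y).
rotate_points <- function(pts, alpha, pivot = c(0, 0)) {
  a <- alpha * pi / 180
  R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
  t(R %*% (t(pts) - pivot) + pivot)
}

# Euclidean distance between two (x, y) points.
dist2 <- function(p, q) sqrt(sum((p - q)^2))

# A quick standard render + full-pipeline detection used across tests.
detect_on_spec <- function(..., config = detect_config()) {
  r <- render_mark_image(render_spec(...))
  list(pose = detect_mark(r$image, config), truth = r$truth)
}
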