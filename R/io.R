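# Image file I/O.  PNG (8/16-bit gray and RGB) via the png package;
# ASCII PGM/PBM as a dependency-free plain-text interchange format used
# for fixtures.  Intensities are real-valued in memory; quantization
# happens only here.

#' Read a grayscale image
#'
#' PNG (gray or RGB, 8- or 16-bit; RGB is collapsed with
#' [rgb_to_gray()], 16-bit is rescaled to the 0-255 scale) or ASCII PGM
#' (`P2`).
#'
#' @param path file path; format from the extension (`.png`, `.pgm`).
#' @return A [gray_image()].
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    a <- png::readPNG(path)           # values in [0, 1]
    if (length(dim(a)) == 3L) {
      if (dim(a)[3] >= 3L) return(rgb_to_gray(a[, , 1:3] * 255))
      a <- a[, , 1]
    }
    return(gray_image(a * 255))
  }
  if (ext == "pgm") return(read_pgm(path))
  stop("unsupported image format: ", ext, call. = FALSE)
}

#' Write a grayscale or edge image
#'
#' 8-bit PNG or ASCII PGM; edge images are written as 0/255.
#' Intensities are clamped to [0, 255] and quantized on write (16-bit
#' PNG is supported on read only).
#'
#' @param img a [gray_image()] or [edge_image()].
#' @param path output path (`.png` or `.pgm`).
#' @return the path, invisibly.
#' @export
write_image <- function(img, path) {
  if (is.logical(img)) img <- matrix(as.numeric(img) * 255,
                                     nrow(img), ncol(img))
  img <- pmin(pmax(unclass(img), 0), 255)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(img / 255, path)
    return(invisible(path))
  }
  if (ext == "pgm") return(write_pgm(img, path))
  stop("unsupported image format: ", ext, call. = FALSE)
}

#' Read an ASCII PGM (P2) image
#' @param path file path.
#' @return A [gray_image()] on the 0-255 scale.
#' @export
read_pgm <- function(path) {
  txt <- readLines(path, warn = FALSE)
  txt <- sub("#.*$", "", txt)
  tok <- scan(text = paste(txt, collapse = " "), what = character(),
              quiet = TRUE)
  if (tok[1] != "P2") stop("not an ASCII PGM (P2) file", call. = FALSE)
  w <- as.integer(tok[2]); h <- as.integer(tok[3])
  maxv <- as.numeric(tok[4])
  v <- as.numeric(tok[-(1:4)])
  if (length(v) != w * h) stop("truncated PGM payload", call. = FALSE)
  gray_image(matrix(v, nrow = h, ncol = w, byrow = TRUE) * (255 / maxv))
}

#' Write an ASCII PGM (P2) image
#' @param img matrix of intensities on the 0-255 scale.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_pgm <- function(img, path) {
  q <- round(pmin(pmax(unclass(img), 0), 255))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(q), nrow(q)), "255"), con)
  utils::write.table(q, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a match map as plain-text CSV for debugging
#' @param C a [match_template()] map.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_match_map <- function(C, path) {
  utils::write.table(unclass(C), path, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
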