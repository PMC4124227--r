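# One-call detection pipeline: Gaussian lowpass -> Sobel gradients ->
# non-maximum suppression -> thinning -> gray-boundary template matching
# -> triad peaks -> pose.

#' Detection-pipeline parameters
#'
#' @param gaussian_size,gaussian_sigma,gaussian_normalize smoothing mask
#'   (see [make_gaussian_mask()]).
#' @param edge_threshold `"otsu"` or a number (see [non_max_suppress()]).
#' @param template_radius circle radius of the matching template; must
#'   equal the mark's outer circle radius in pixels.
#' @param template_variant,template_gray see [make_circle_template()].
#' @param exclusion_radius peak suppression radius (default
#'   `2 * template_radius`).
#' @param floor_score minimum peak score (see [find_circle_triad()]).
#' @param refine sub-pixel peak refinement flag.
#' @return A `detect_config` list.
#' @export
detect_config <- function(gaussian_size = 5L, gaussian_sigma = 1.0,
                          gaussian_normalize = TRUE,
                          edge_threshold = "otsu",
                          template_radius = 8L,
                          template_variant = "gray_boundary",
                          template_gray = 0.5,
                          exclusion_radius = NULL,
                          floor_score = 0.2,
                          refine = TRUE) {
  structure(list(gaussian_size = gaussian_size,
                 gaussian_sigma = gaussian_sigma,
                 gaussian_normalize = gaussian_normalize,
                 edge_threshold = edge_threshold,
                 template_radius = template_radius,
                 template_variant = template_variant,
                 template_gray = template_gray,
                 exclusion_radius = exclusion_radius,
                 floor_score = floor_score,
                 refine = refine),
            class = "detect_config")
}

#' Detect an alignment mark in a grayscale image
#'
#' Runs the full pipeline and returns the mark pose.  With
#' `intermediates = TRUE` the filtered image, gradient field, prethinned
#' and thinned edge images, and match map are attached for debugging or
#' stage-by-stage export.
#'
#' @param img a [gray_image()] (RGB input: convert with
#'   [rgb_to_gray()] first).
#' @param config a [detect_config()].
#' @param intermediates keep intermediate pipeline stages.
#' @return A `mark_pose`; with intermediates, attribute `stages`.
#' @export
detect_mark <- function(img, config = detect_config(), intermediates = FALSE) {
  mask <- make_gaussian_mask(config$gaussian_size, config$gaussian_sigma,
                             config$gaussian_normalize)
  smoothed <- gaussian_filter(img, mask)
  grad <- sobel_gradients(smoothed)
  prethinned <- non_max_suppress(grad, config$edge_threshold)
  edges <- thin_edges(prethinned)
  tmpl <- make_circle_template(config$template_radius,
                               config$template_variant, config$template_gray)
  C <- match_template(edges, tmpl)
  triad <- find_circle_triad(C, exclusion_radius = config$exclusion_radius,
                             floor_score = config$floor_score,
                             refine = config$refine)
  pose <- estimate_pose(triad)
  if (intermediates) {
    attr(pose, "stages") <- list(smoothed = smoothed, gradients = grad,
                                 prethinned = prethinned, edges = edges,
                                 match_map = C)
  }
  pose
}
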