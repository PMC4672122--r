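# Denoising, edge-preserving enhancement, local-Otsu binarization and
# isolated point-set removal.

#' 2D median filter
#'
#' Each output pixel is the median of its `window x window`
#' neighbourhood; borders are replicate-padded.
#'
#' @param image Numeric matrix in `[0, 1]`.
#' @param window Odd window side, >= 3.
#' @return Filtered matrix of the same shape.
#' @export
median_filter <- function(image, window = 3L) {
  assert_image(image)
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L)
    stop("window must be odd and >= 3")
  cpp_median_filter(image, window)
}

#' Edge-preserving anisotropic diffusion
#'
#' Perona-Malik diffusion with exponential conductance
#' `g(d) = exp(-(d/kappa)^2)` under an explicit 4-neighbour scheme with
#' zero-flux borders. Used to enhance the dendrite against the
#' background while keeping its edges in place; the scheme obeys a
#' maximum principle, so the intensity range never expands.
#'
#' @param image Numeric matrix.
#' @param iterations Number of diffusion steps (>= 0).
#' @param kappa Contrast scale separating edges (preserved) from noise
#'   (smoothed), in intensity units.
#' @param dt Time step; must satisfy `dt <= 0.25` for stability.
#' @return Smoothed matrix.
#' @export
pde_enhance <- function(image, iterations = 10L, kappa = 0.1, dt = 0.2) {
  assert_image(image)
  if (iterations < 0) stop("iterations must be >= 0")
  if (dt <= 0 || dt > 0.25)
    stop("dt outside the stability bound (0, 0.25]")
  if (iterations == 0L) return(image)
  cpp_pm_diffuse(image, as.integer(iterations), kappa, dt)
}

#' Local Otsu binarization
#'
#' The image is partitioned into `window x window` tiles and each tile
#' is thresholded at the value maximizing the between-class variance of
#' its intensities (exact search over the observed values; pixels `>=`
#' threshold become foreground). Degenerate tiles map to background so
#' that empty regions produce no spurious foreground: tiles of constant
#' intensity, and tiles whose two Otsu classes differ by less than
#' `min_contrast` in mean intensity (such tiles contain only background
#' noise, which Otsu would otherwise split in half).
#'
#' @param image Numeric matrix.
#' @param window Tile side in pixels; must be >= 8 and should exceed the
#'   dendrite width.
#' @param min_contrast Minimum between-class mean separation for a tile
#'   to contain foreground, in intensity units.
#' @return Integer 0/1 matrix of the same shape.
#' @export
local_otsu_binarize <- function(image, window = 32L, min_contrast = 0.1) {
  assert_image(image)
  if (window < 8) stop("window must be >= 8 pixels")
  cpp_local_otsu(image, as.integer(window), min_contrast)
}

#' Remove small isolated point-sets from a binary mask
#'
#' A positive pixel is kept only when its 3x3 neighbourhood contains
#' more than `n` positive pixels; otherwise it is forced to 0. By
#' default the centre pixel is not counted (the count is over the 8
#' neighbours); `include_center = TRUE` counts all 9 pixels, which
#' shifts the effective threshold by one.
#'
#' @param mask Binary 0/1 matrix.
#' @param n Neighbour-count threshold, `0 <= n <= 8`.
#' @param include_center Count the centre pixel itself.
#' @return Integer 0/1 matrix; output is always a subset of the input.
#' @export
remove_isolated_points <- function(mask, n = 2L, include_center = FALSE) {
  assert_mask(mask)
  if (n < 0 || n > 8) stop("n must be in [0, 8]")
  cpp_remove_isolated(as_int_mask(mask), as.integer(n), include_center)
}

#' Standard preprocessing chain
#'
#' Median filter followed by anisotropic diffusion.
#'
#' @param image Numeric matrix in `[0, 1]`.
#' @param median_window Median filter window (odd).
#' @param iterations,kappa,dt Diffusion parameters, see [pde_enhance()].
#' @return Preprocessed image.
#' @export
preprocess_image <- function(image, median_window = 3L, iterations = 10L,
                             kappa = 0.1, dt = 0.2) {
  pde_enhance(median_filter(image, median_window), iterations, kappa, dt)
}

#' Foreground mask of a preprocessed image
#'
#' Local Otsu binarization followed by isolated point-set removal.
#'
#' @param image Numeric matrix.
#' @param otsu_window Tile side for [local_otsu_binarize()].
#' @param isolated_n Threshold for [remove_isolated_points()].
#' @return Integer 0/1 matrix.
#' @export
foreground_mask <- function(image, otsu_window = 32L, isolated_n = 2L) {
  remove_isolated_points(local_otsu_binarize(image, otsu_window), isolated_n)
}
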