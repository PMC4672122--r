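#' Read a grayscale image from a TIFF or PNG file
#'
#' Intensities are rescaled to `[0, 1]` (8- and 16-bit files are divided
#' by their full-scale value by the underlying readers). Multi-channel
#' images are averaged to a single gray channel.
#'
#' @param path Path to a `.tif`/`.tiff` or `.png` file.
#' @return A numeric matrix with values in `[0, 1]` (rows = image rows).
#' @export
read_gray_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    tif = ,
    tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop("unsupported image format: .", ext)
  )
  if (length(dim(img)) == 3L) img <- apply(img, c(1, 2), mean)
  clip01(img)
}

#' Write a grayscale image to a TIFF or PNG file
#'
#' @param image Numeric matrix; values are clipped to `[0, 1]`.
#' @param path Output path; format chosen from the extension.
#' @param bits Bit depth (8 or 16).
#' @return The path, invisibly.
#' @export
write_gray_image <- function(image, path, bits = 16L) {
  assert_image(image)
  img <- clip01(image)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    tif = ,
    tiff = tiff::writeTIFF(img, path, bits.per.sample = as.integer(bits)),
    png = png::writePNG(img, path),
    stop("unsupported image format: .", ext)
  )
  invisible(path)
}

#' Read a multi-page TIFF as a 3D stack
#'
#' @param path Path to a multi-page TIFF.
#' @return A 3D array (rows x cols x slices).
#' @export
read_image_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) apply(p, c(1, 2), mean) else p
  })
  array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
}

#' Write a 3D stack as a multi-page TIFF
#'
#' @param stack A 3D array (rows x cols x slices) or list of matrices.
#' @param path Output path.
#' @param bits Bit depth (8 or 16).
#' @return The path, invisibly.
#' @export
write_image_stack <- function(stack, path, bits = 16L) {
  if (is.array(stack) && length(dim(stack)) == 3L)
    stack <- lapply(seq_len(dim(stack)[3]), function(z) stack[, , z])
  stack <- lapply(stack, clip01)
  tiff::writeTIFF(stack, path, bits.per.sample = as.integer(bits))
  invisible(path)
}
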