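# Internal helpers shared across modules.

# Run code under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

assert_image <- function(image, arg = "image") {
  if (!is.matrix(image) || !is.numeric(image))
    stop(sprintf("`%s` must be a numeric matrix", arg), call. = FALSE)
  if (any(!is.finite(image)))
    stop(sprintf("`%s` contains non-finite values", arg), call. = FALSE)
  invisible(image)
}

assert_mask <- function(mask, arg = "mask") {
  if (!is.matrix(mask)) stop(sprintf("`%s` must be a matrix", arg), call. = FALSE)
  v <- unique(as.vector(mask))
  if (!all(v %in% c(0, 1)))
    stop(sprintf("`%s` must be binary (0/1)", arg), call. = FALSE)
  invisible(mask)
}

as_int_mask <- function(mask) {
  storage.mode(mask) <- "integer"
  mask
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

# 1D normalized Gaussian taps with support +/- ceiling(4 sigma)
gauss_taps <- function(sigma) {
  r <- max(1L, as.integer(ceiling(4 * sigma)))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

gaussian_blur <- function(image, sigma) {
  if (sigma <= 0) return(image)
  k <- gauss_taps(sigma)
  cpp_sep_convolve(image, k, k)
}
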