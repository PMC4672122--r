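# Wavelet gradient, modulus maxima, conditional symmetric pairing and
# backbone assembly.

test_that("smoothing kernel has unit mass and obeys the 1/s^2 scaling law", {
  for (s in c(1, 2, 4, 8))
    expect_equal(sum(smoothing_kernel(s)), 1)
  k2 <- smoothing_kernel(2, normalize = FALSE)
  k4 <- smoothing_kernel(4, normalize = FALSE)
  # doubling s doubles the support (half-width doubles exactly)
  expect_equal(nrow(k4) - 1, 2 * (nrow(k2) - 1))
  # and quarters the values on the shared grid (compare centres)
  c2 <- (nrow(k2) + 1) / 2; c4 <- (nrow(k4) + 1) / 2
  expect_equal(k4[c4, c4] / k2[c2, c2], 1 / 4, tolerance = 1e-12)
  # pointwise: k_s(x, y) = (1/s^2) theta(x/s, y/s) for the base theta
  s <- 2; sigma0 <- 0.35
  k <- smoothing_kernel(s, sigma0, normalize = FALSE)
  r <- (nrow(k) - 1) / 2
  theta <- function(u, v) exp(-(u^2 + v^2) / (2 * sigma0^2)) / (2 * pi * sigma0^2)
  for (x in c(-r, 0, 1, r)) for (y in c(-r, 0, r))
    expect_equal(k[y + r + 1, x + r + 1], theta(y / s, x / s) / s^2)
})

test_that("piecewise basis: support, antisymmetric assembly, frozen values", {
  expect_identical(phi_plus(c(1, 1.5, 10)), c(0, 0, 0))
  xs <- seq(-0.95, 0.95, by = 0.05)
  expect_equal(phi_wavelet(xs), -phi_wavelet(-xs))
  # phi-(x) = -phi+(-x) by construction
  phi_minus <- function(x) -phi_plus(-x)
  expect_equal(phi_wavelet(xs), phi_plus(xs) + phi_minus(xs))
  # frozen direct-evaluation values of the implemented branch reading
  expect_equal(phi_plus(0.5), -0.03955004116350418, tolerance = 1e-12)
  expect_equal(phi_plus(0.1), 0.8679373150865536, tolerance = 1e-12)
  expect_equal(phi_plus(0.9), -0.1292823666943032, tolerance = 1e-12)
})

test_that("wavelet gradient: zero on constants, slope s on a ramp", {
  cfg <- wavelet_config()
  cst <- matrix(0.6, 16, 16)
  fld <- wavelet_gradient(cst, cfg, 3)
  expect_true(all(fld$wx == 0) && all(fld$wy == 0))
  ramp <- matrix(rep(1:20, each = 20) / 20, 20, 20)  # f = x / 20
  for (s in c(2, 4)) {
    fld <- wavelet_gradient(ramp, cfg, s)
    core <- fld$wx[8:13, 8:13]
    expect_equal(core, matrix(s / 20, 6, 6), tolerance = 1e-6)
    expect_equal(max(abs(fld$wy[8:13, 8:13])), 0, tolerance = 1e-10)
  }
})

test_that("wavelet gradient of a blob equals direct convolution", {
  set.seed(61)
  g <- seq(-7.5, 7.5)
  img <- exp(-outer(g^2, g^2, `+`) / 18) + matrix(rnorm(256, 0, 0.01), 16, 16)
  cfg <- wavelet_config(sigma0 = 0.35)
  s <- 4
  fld <- wavelet_gradient(img, cfg, s)
  taps <- exp(-((-6:6)^2) / (2 * (0.35 * s)^2))
  taps <- taps / sum(taps)
  sm <- oracle_convolve2(img, outer(taps, taps))
  h <- nrow(img); w <- ncol(img)
  wx <- s * (sm[, clampi(2:(w + 1), 1, w)] - sm[, clampi(0:(w - 1), 1, w)]) / 2
  wy <- s * (sm[clampi(2:(h + 1), 1, h), ] - sm[clampi(0:(h - 1), 1, h), ]) / 2
  expect_equal(fld$wx, wx, tolerance = 1e-12)
  expect_equal(fld$wy, wy, tolerance = 1e-12)
  expect_equal(fld$modulus, sqrt(wx^2 + wy^2), tolerance = 1e-12)
})

test_that("modulus maxima trace a vertical step edge", {
  fld0 <- wavelet_gradient(matrix(0.5, 12, 12), wavelet_config(), 3)
  expect_identical(nrow(modulus_maxima(fld0, 0.05)), 0L)
  img <- strip_image(24, 24, 13, 12, fore = 0.9, back = 0.1)
  fld <- wavelet_gradient(img, wavelet_config(), 3)
  pts <- modulus_maxima(fld, 0.1)
  inner <- pts[pts[, 1] > 3 & pts[, 1] < 22, , drop = FALSE]
  expect_gt(nrow(inner), 0)
  # all detected contour columns sit at the edge (between cols 12-13)
  expect_true(all(abs(inner[, 2] - 12.5) <= 1))
  # definition check: each point's modulus >= direction-interpolated
  # neighbours (verified on the lattice neighbours along x here)
  for (k in seq_len(nrow(inner))) {
    i <- inner[k, 1]; j <- inner[k, 2]
    expect_gte(fld$modulus[i, j], fld$modulus[i, clampi(j - 1, 1, 24)] - 1e-12)
    expect_gte(fld$modulus[i, j], fld$modulus[i, clampi(j + 1, 1, 24)] - 1e-12)
  }
})

test_that("symmetric pairing bridges a strip and rejects unpaired edges", {
  cfg <- wavelet_config()
  # half-plane step: a single edge has no counterpart
  img <- matrix(0.1, 24, 24); img[, 13:24] <- 0.9
  fld <- wavelet_gradient(img, cfg, 5)
  pts <- modulus_maxima(fld, cfg$mm_threshold)
  mask <- matrix(1L, 24, 24)
  pr <- pair_symmetric_points(pts, fld, mask, 5, cfg)
  expect_identical(nrow(pr), 0L)
  # strip of width 7 at s = 7: pairs bridge the strip, midpoints on the
  # centre column
  img <- strip_image(32, 32, 11, 7)
  mask <- (img > 0.4) + 0L
  fld <- wavelet_gradient(img, cfg, 7)
  pts <- modulus_maxima(fld, cfg$mm_threshold)
  pr <- pair_symmetric_points(pts, fld, mask, 7, cfg)
  expect_gt(nrow(pr), 10)
  expect_true(all(abs(pr$mid_col - 14) <= 1))
  expect_true(all(abs(pr$separation - 7) <= max(1, 0.2 * 7)))
})

test_that("pairs never join strips separated by a wide background gap", {
  cfg <- wavelet_config()
  img <- matrix(0.1, 32, 40)
  img[, 5:8] <- 0.9    # strip 1, width 4
  img[, 25:28] <- 0.9  # strip 2; gap of 16 >> s + tol
  mask <- (img > 0.4) + 0L
  for (s in c(3, 5)) {
    fld <- wavelet_gradient(img, cfg, s)
    pts <- modulus_maxima(fld, cfg$mm_threshold)
    pr <- pair_symmetric_points(pts, fld, mask, s, cfg)
    if (nrow(pr)) {
      same1 <- pr$p_col <= 16 & pr$q_col <= 16
      same2 <- pr$p_col > 16 & pr$q_col > 16
      expect_true(all(same1 | same2))
    }
  }
})

test_that("backbone of a straight strip is a single centred 1-px path", {
  expect_identical(extract_backbone(NULL, c(10, 10)), list())
  img <- strip_image(40, 32, 13, 7)
  mask <- (img > 0.4) + 0L
  bb <- dendrite_backbone(img, mask, wavelet_config())
  expect_identical(length(bb$paths), 1L)
  p <- bb$paths[[1]]
  # mean distance to the true centreline (col 16) below 1 px
  expect_lt(mean(abs(p$points[, 2] - 16)), 1)
  # 8-connected one-pixel-wide chain: consecutive Chebyshev steps of 1
  steps <- pmax(abs(diff(p$points[, 1])), abs(diff(p$points[, 2])))
  expect_true(all(steps == 1))
  # width recovery: separation ~= strip width
  expect_true(all(abs(p$width - 7) <= 1.2))
})

test_that("backbone recovers an S-curved dendrite against ground truth", {
  spec <- scene_spec(image_height = 160, image_width = 160,
                     width_profile = c(6, 6),
                     noise = list(gaussian_sigma = 0, poisson_scale = 0),
                     seed = 5)
  out <- make_dendrite_image(spec)
  mask <- out$truth$foreground_mask
  bb <- dendrite_backbone(out$image, mask, wavelet_config())
  pts <- do.call(rbind, lapply(bb$paths, `[[`, "points"))
  gt <- out$truth$backbone_points
  # arc-length coverage: fraction of ground-truth points within 1 px
  dmin <- vapply(seq_len(nrow(gt)), function(k)
    min(sqrt((pts[, 1] - gt[k, 1])^2 + (pts[, 2] - gt[k, 2])^2)), 0)
  expect_gte(mean(dmin <= 1), 0.95)
  # extracted points stay close to the truth and inside the mask
  dext <- vapply(seq_len(nrow(pts)), function(k)
    min(sqrt((gt[, 1] - pts[k, 1])^2 + (gt[, 2] - pts[k, 2])^2)), 0)
  expect_lt(mean(dext), 1)
  expect_true(all(mask[pts] == 1L))
})

test_that("geometry is equivariant to shifts and invariant to gray offsets", {
  img <- matrix(0.1, 40, 40)
  img[, 12:18] <- 0.8
  cfg <- wavelet_config()
  fld <- wavelet_gradient(img, cfg, 7)
  pts <- modulus_maxima(fld, cfg$mm_threshold)
  # gray shift: adding a constant leaves contour positions unchanged
  fld2 <- wavelet_gradient(img + 0.1, cfg, 7)
  expect_identical(modulus_maxima(fld2, cfg$mm_threshold), pts)
  # spatial shift: translating the strip by 6 columns shifts contours
  img3 <- matrix(0.1, 40, 40)
  img3[, 18:24] <- 0.8
  fld3 <- wavelet_gradient(img3, cfg, 7)
  pts3 <- modulus_maxima(fld3, cfg$mm_threshold)
  core <- pts[pts[, 1] > 7 & pts[, 1] < 34, , drop = FALSE]
  core3 <- pts3[pts3[, 1] > 7 & pts3[, 1] < 34, , drop = FALSE]
  core[, 2] <- core[, 2] + 6L
  expect_identical(core3[order(core3[, 1], core3[, 2]), ],
                   core[order(core[, 1], core[, 2]), ])
})

test_that("per-point width is recovered within 1 px on known strips", {
  for (w in c(4, 6, 9, 12)) {
    img <- strip_image(40, 40, 15, w)
    mask <- (img > 0.4) + 0L
    bb <- dendrite_backbone(img, mask, wavelet_config())
    expect_gt(length(bb$paths), 0)
    wd <- unlist(lapply(bb$paths, `[[`, "width"))
    expect_true(all(abs(wd - w) <= 1.01),
                label = sprintf("width %d recovered", w))
  }
})
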