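# Median filtering, anisotropic diffusion, local Otsu, isolated-point
# removal.

test_that("median filter matches a brute-force sort-and-pick oracle", {
  expect_error(median_filter(matrix(0, 4, 4), 4), "odd")
  cst <- matrix(0.4, 6, 6)
  expect_equal(median_filter(cst, 3), cst)
  imp <- matrix(0, 7, 7); imp[4, 4] <- 1
  expect_equal(median_filter(imp, 3), matrix(0, 7, 7))
  set.seed(21)
  for (rep in 1:5) {
    img <- matrix(runif(25), 5, 5)
    expect_equal(median_filter(img, 3), oracle_median_filter(img, 3))
  }
  img <- matrix(runif(81), 9, 9)
  expect_equal(median_filter(img, 5), oracle_median_filter(img, 5))
})

test_that("diffusion is identity at 0 iterations and inert on constants", {
  img <- matrix(runif(64), 8, 8)
  expect_identical(pde_enhance(img, 0), img)
  cst <- matrix(0.3, 8, 8)
  expect_equal(pde_enhance(cst, 25), cst)
  expect_error(pde_enhance(img, 5, dt = 0.5), "stability")
})

test_that("diffusion matches direct iteration, keeps edges, smooths flats", {
  set.seed(31)
  img <- strip_image(24, 24, 13, 12, fore = 0.9, back = 0.1) +
    matrix(rnorm(576, 0, 0.03), 24, 24)
  out <- pde_enhance(img, 5, kappa = 0.1, dt = 0.2)
  expect_equal(out, oracle_pm_diffuse(img, 5, 0.1, 0.2))
  # max principle: range does not expand
  expect_gte(min(out), min(img))
  expect_lte(max(out), max(img))
  # half-height crossing of the row-mean profile stays within 1 px
  prof <- colMeans(out)
  half <- (max(prof) + min(prof)) / 2
  expect_lte(abs(min(which(prof > half)) - 13), 1)
  # flat-region variance is reduced
  expect_lt(var(as.vector(out[, 1:8])), var(as.vector(img[, 1:8])))
})

test_that("local Otsu separates a bimodal image and ignores flat windows", {
  img <- matrix(0.2, 16, 16)
  img[5:12, 3:14] <- 0.8
  mask <- local_otsu_binarize(img, 8)
  expect_identical(mask == 1L, unname(img == 0.8))
  expect_true(all(local_otsu_binarize(matrix(0.5, 16, 16), 8) == 0L))
  expect_error(local_otsu_binarize(img, 4), ">= 8")
})

test_that("local Otsu thresholds maximize between-class variance exactly", {
  set.seed(41)
  img <- matrix(c(rnorm(32, 0.25, 0.05), rnorm(32, 0.75, 0.05)), 8, 8)
  mask <- local_otsu_binarize(img, 8)
  thr <- oracle_otsu_threshold(as.vector(img))
  expect_identical(mask == 1L, unname(img >= thr))
})

test_that("local Otsu is invariant to a constant intensity offset", {
  set.seed(43)
  img <- matrix(runif(32 * 32, 0, 0.6), 32, 32)
  img[8:20, 8:24] <- img[8:20, 8:24] + 0.3
  expect_identical(local_otsu_binarize(img, 16),
                   local_otsu_binarize(img + 0.17, 16))
})

test_that("isolated point removal counts 3x3 neighbours correctly", {
  m <- matrix(0L, 9, 9); m[5, 5] <- 1L
  expect_true(all(remove_isolated_points(m, 1) == 0L))
  blk <- matrix(0L, 9, 9); blk[3:7, 3:7] <- 1L
  out <- remove_isolated_points(blk, 4)
  # corners have 3 positive neighbours -> removed; edges (5) and
  # interior (8) survive
  expect_identical(out[3, 3], 0L)
  expect_identical(out[3, 7], 0L)
  expect_identical(out[3, 5], 1L)
  expect_identical(out[5, 5], 1L)
  set.seed(51)
  rnd <- matrix(rbinom(100, 1, 0.5), 10, 10)
  expect_identical(remove_isolated_points(rnd, 2),
                   oracle_remove_isolated(rnd, 2))
  expect_identical(remove_isolated_points(rnd, 2, include_center = TRUE),
                   oracle_remove_isolated(rnd, 2, include_center = TRUE))
})

test_that("isolated point removal is anti-extensive and monotone in n", {
  set.seed(52)
  for (rep in 1:5) {
    m <- matrix(rbinom(144, 1, 0.4), 12, 12)
    prev <- remove_isolated_points(m, 0)
    expect_true(all(prev <= m))
    for (n in 1:4) {
      cur <- remove_isolated_points(m, n)
      expect_true(all(cur <= prev))  # larger n keeps fewer pixels
      prev <- cur
    }
  }
})
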