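# Boundary search perpendicular to the backbone, discrete-line gap
# filling.

strip_backbone <- function(img, mask = NULL) {
  if (is.null(mask)) mask <- (img > 0.4) + 0L
  bb <- dendrite_backbone(img, mask, wavelet_config())
  bb$paths[[1]]
}

test_that("tangent direction follows the stroke and rotates with it", {
  imgV <- strip_image(40, 40, 15, 7)          # vertical strip
  fldV <- wavelet_gradient(imgV, wavelet_config(), 7)
  # gradient at the left edge points +x; tangent = gradient + pi/2
  ang <- local_line_direction(fldV, c(20, 15))
  expect_equal(abs(cos(ang)), 0, tolerance = 1e-6)  # tangent vertical
  imgH <- t(imgV)                              # horizontal strip
  fldH <- wavelet_gradient(imgH, wavelet_config(), 7)
  angH <- local_line_direction(fldH, c(15, 20))
  expect_equal(abs(sin(angH)), 0, tolerance = 1e-6) # tangent horizontal
  # zero gradient falls back
  fld0 <- wavelet_gradient(matrix(0.5, 10, 10), wavelet_config(), 3)
  expect_identical(local_line_direction(fld0, c(5, 5), fallback = 0.3), 0.3)
})

test_that("boundary of a sharp strip sits exactly on the edge columns", {
  img <- matrix(0, 40, 41)
  img[, 18:24] <- 1                            # width 7, centre col 21
  path <- strip_backbone(img, (img > 0.5) + 0L)
  expect_true(all(path$points[, 2] == 21))
  bnd <- search_boundary(img, path, boundary_config("global", alpha = 0.5))
  expect_gt(nrow(bnd$side1), 0)
  expect_gt(nrow(bnd$side2), 0)
  cols <- sort(unique(c(bnd$side1[, 2], bnd$side2[, 2])))
  expect_true(all(cols %in% c(18, 24)))        # 3 px from the centre
  # sidedness: the two chains lie on opposite sides of the backbone
  s1 <- unique(sign(bnd$side1[, 2] - 21))
  s2 <- unique(sign(bnd$side2[, 2] - 21))
  expect_identical(length(s1), 1L)
  expect_identical(s1, -s2)
})

test_that("degenerate alpha flags every point; flat image finds no edge", {
  img <- strip_image(30, 30, 12, 6)
  path <- strip_backbone(img)
  bnd <- search_boundary(img, path, boundary_config("global", alpha = 2))
  expect_identical(nrow(bnd$side1) + nrow(bnd$side2), 0L)
  expect_identical(length(bnd$flagged), nrow(path$points))
  # uniform bright frame: marching exhausts max_search with no edge
  flat <- matrix(0.9, 30, 30)
  bnd2 <- search_boundary(flat, path, boundary_config("global", alpha = 0.5,
                                                      max_search = 10))
  expect_identical(nrow(bnd2$side1) + nrow(bnd2$side2), 0L)
  expect_identical(length(bnd2$flagged), 0L)
})

test_that("raising alpha never moves the boundary outward", {
  img <- strip_image(36, 36, 14, 8)
  img <- gaussian_blur(img, 1.2)               # graded edges
  path <- strip_backbone(img, (img > 0.45) + 0L)
  prev_w <- Inf
  for (alpha in c(0.3, 0.45, 0.6, 0.75)) {
    bnd <- search_boundary(img, path, boundary_config("global", alpha))
    if (nrow(bnd$side1) == 0) break
    wdt <- abs(stats::median(bnd$side1[, 2]) - stats::median(bnd$side2[, 2]))
    expect_lte(wdt, prev_w)
    prev_w <- wdt
  }
})

test_that("discrete line linking matches the midpoint-algorithm oracle", {
  expect_error(link_missing_points(c(2, 2), c(2, 2)), "distinct")
  expect_identical(nrow(link_missing_points(c(1, 1), c(1, 2))), 0L)
  expect_identical(nrow(link_missing_points(c(1, 1), c(2, 2))), 0L)
  expect_identical(link_missing_points(c(1, 1), c(1, 4)),
                   rbind(c(1L, 2L), c(1L, 3L)))
  set.seed(81)
  for (rep in 1:100) {
    p1 <- c(sample(30, 1), sample(30, 1))
    p2 <- c(sample(30, 1), sample(30, 1))
    if (all(p1 == p2)) next
    ref <- oracle_digital_line(p1, p2)
    ref <- ref[-c(1, nrow(ref)), , drop = FALSE]   # interior only
    got <- link_missing_points(p1, p2)
    expect_identical(unname(got), unname(ref))
    # 8-connectivity of the full chain
    chain <- rbind(p1, got, p2)
    steps <- pmax(abs(diff(chain[, 1])), abs(diff(chain[, 2])))
    expect_true(all(steps == 1))
  }
})

test_that("fill_boundary restores connectivity and is idempotent", {
  side <- cbind(rep(5L, 4), c(1L, 2L, 3L, 4L))
  bnd <- structure(list(side1 = side, side2 = side[0, ],
                        index1 = 1:4, index2 = integer(0),
                        flagged = integer(0), closed = FALSE),
                   class = "boundary_point_set")
  expect_identical(fill_boundary(bnd)$side1, side)   # already connected
  gap <- side[c(1, 4), ]
  bnd$side1 <- gap; bnd$index1 <- c(1L, 4L)
  filled <- fill_boundary(bnd)
  expect_identical(filled$side1, side)
  steps <- pmax(abs(diff(filled$side1[, 1])), abs(diff(filled$side1[, 2])))
  expect_true(all(steps == 1))
})

test_that("boundary tracks the true mask edge on a noiseless dendrite", {
  spec <- scene_spec(image_height = 128, image_width = 128,
                     width_profile = c(7, 7),
                     noise = list(gaussian_sigma = 0, poisson_scale = 0),
                     seed = 6)
  out <- make_dendrite_image(spec)
  mask <- out$truth$foreground_mask
  bb <- dendrite_backbone(out$image, mask, wavelet_config())
  lens <- vapply(bb$paths, function(p) nrow(p$points), 0L)
  path <- bb$paths[[which.max(lens)]]
  bnd <- fill_boundary(search_boundary(
    out$image, path,
    boundary_config("global", alpha = (0.75 + 0.08) / 2)))
  # ground-truth edge: mask pixels adjacent to background
  inner <- cpp_binary_erode(mask, se_square(3L), 0L)
  edge <- which(mask == 1L & inner == 0L, arr.ind = TRUE)
  pts <- rbind(bnd$side1, bnd$side2)
  d <- vapply(seq_len(nrow(pts)), function(k)
    min(sqrt((edge[, 1] - pts[k, 1])^2 + (edge[, 2] - pts[k, 2])^2)), 0)
  expect_lt(mean(d), 1)
  expect_lt(max(d), 2.1)
})
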