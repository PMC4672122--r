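# Synthetic scene and spine-library generator.

test_that("a spine-free, noise-free scene renders exactly its tube", {
  spec <- scene_spec(image_height = 64, image_width = 96,
                     width_profile = c(5, 5),
                     noise = list(gaussian_sigma = 0, poisson_scale = 0),
                     blur_sigma = 0, seed = 3)
  out <- make_dendrite_image(spec)
  expect_equal(length(out$truth$spine_records), 0L)
  fg <- out$image > (spec$foreground_level + spec$background_level) / 2
  expect_identical(unname(fg + 0L), unname(out$truth$foreground_mask + 0L))
  expect_identical(out$truth$foreground_mask, out$truth$boundary_mask)
})

test_that("scene generation is deterministic in the seed", {
  spec <- demo_scene_spec(2, 2, 1, size = 128L, seed = 11)
  a <- make_dendrite_image(spec)
  b <- make_dendrite_image(spec)
  expect_identical(a, b)
  spec2 <- demo_scene_spec(2, 2, 1, size = 128L, seed = 12)
  expect_false(identical(make_dendrite_image(spec2)$image, a$image))
})

test_that("one spine per class yields exactly three labelled records", {
  specs <- list(spine_spec("mushroom", base_point = 0.25),
                spine_spec("stubby", base_point = 0.5, side = -1),
                spine_spec("thin", base_point = 0.75))
  sc <- scene_spec(image_height = 128, image_width = 128,
                   spine_specs = specs, width_profile = c(6, 6), seed = 2)
  out <- make_dendrite_image(sc)
  rec <- out$truth$spine_records
  expect_length(rec, 3L)
  expect_setequal(vapply(rec, `[[`, "", "class_label"),
                  c("mushroom", "stubby", "thin"))
  # spine pixels are disjoint from the trunk
  trunk <- out$truth$boundary_mask
  for (r in rec) {
    expect_gt(r$area, 0)
    expect_true(all(trunk[r$pixels] == 0L))
  }
  # backbone points lie inside the trunk mask
  expect_true(all(trunk[out$truth$backbone_points] == 1L))
})

test_that("off-canvas spine placement is rejected with a clear error", {
  sp <- spine_spec("mushroom", base_point = 0)
  sc <- scene_spec(image_height = 24, image_width = 24,
                   dendrite_control_points = cbind(c(2, 2), c(2, 22)),
                   width_profile = c(4, 4), spine_specs = list(sp), seed = 1)
  expect_error(make_dendrite_image(sc), "off the .* canvas")
})

test_that("spine library has the requested size, labels and determinism", {
  lib <- make_spine_library(4, seed = 9)
  expect_length(lib$images, 12L)
  expect_equal(as.vector(table(lib$labels)), c(4L, 4L, 4L))
  expect_true(all(vapply(lib$images, function(m) all(dim(m) == c(20, 20)),
                         TRUE)))
  expect_identical(lib, make_spine_library(4, seed = 9))
})

test_that("without jitter each class reduces to its canonical template", {
  lib <- make_spine_library(2, seed = 1, jitter = FALSE, noise = FALSE)
  for (cl in levels(lib$labels)) {
    idx <- which(lib$labels == cl)
    expect_identical(lib$images[[idx[1]]], lib$images[[idx[2]]])
  }
})

test_that("noiseless library subimages agree with a geometric class oracle", {
  lib <- make_spine_library(25, seed = 4, jitter = TRUE, noise = FALSE,
                            presentation = "isolated")
  pred <- vapply(lib$images, oracle_spine_class, "")
  expect_equal(pred, as.character(lib$labels))
})

test_that("spine spec invariants are enforced", {
  expect_error(spine_spec("mushroom", neck_length = 0), "neck_length")
  expect_error(spine_spec("mushroom", neck_width = 8, head_radius = 3),
               "head diameter")
  expect_error(spine_spec("stubby", neck_length = 2), "stubby")
  expect_error(spine_spec("thin", neck_length = 30), "envelope|20x20")
  expect_error(scene_spec(width_profile = c(1, 5)), "width_profile")
  expect_error(scene_spec(foreground_level = 0.1, background_level = 0.5),
               "foreground")
})

test_that("maximum intensity projection matches the brute-force maximum", {
  expect_error(max_intensity_projection(list()), "empty")
  one <- matrix(runif(16), 4, 4)
  expect_identical(max_intensity_projection(list(one)), one)
  zero <- matrix(0, 4, 4)
  expect_identical(max_intensity_projection(list(zero, one)), one)
  set.seed(8)
  st <- array(runif(3 * 4 * 4), dim = c(4, 4, 3))
  mip <- max_intensity_projection(st)
  for (i in 1:4) for (j in 1:4)
    expect_identical(mip[i, j], max(st[i, j, ]))
  # idempotence: projecting a projection changes nothing
  expect_identical(max_intensity_projection(array(mip, c(4, 4, 1))), mip)
})

test_that("images and stacks round-trip through TIFF and PNG", {
  img <- matrix(round(runif(64), 3), 8, 8)
  tf <- tempfile(fileext = ".tif")
  write_gray_image(img, tf)
  expect_equal(read_gray_image(tf), img, tolerance = 1e-4)
  pf <- tempfile(fileext = ".png")
  write_gray_image(img, pf)
  expect_equal(read_gray_image(pf), img, tolerance = 1 / 255)
  st <- array(round(runif(128), 3), dim = c(8, 8, 2))
  sf <- tempfile(fileext = ".tif")
  write_image_stack(st, sf)
  expect_equal(read_image_stack(sf), st, tolerance = 1e-4)
})
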