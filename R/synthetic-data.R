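# Seeded generator of confocal-like dendrite scenes and labeled spine
# subimage libraries. The generator replaces a non-distributable imaging
# data set: it renders bright curvilinear dendrites of varying width on
# a dark noisy background, with attached or detached protrusions of the
# three canonical spine morphologies, and reports full ground truth
# (backbone, foreground mask, per-spine pixel sets and geometry).

#' Default geometry parameter ranges per spine class
#'
#' Ranges are in pixels and were chosen so that every rendered spine
#' fits inside a 20x20 pixel box (thin spines inside roughly 5x20),
#' mushroom spines have a clear head on a thinner neck, stubby spines
#' are a head directly on the dendrite without a neck, and thin spines
#' are long, narrow and essentially headless.
#'
#' @param class One of `"mushroom"`, `"stubby"`, `"thin"`.
#' @return A list of `c(min, max)` ranges: `neck_length`, `neck_width`,
#'   `head_radius`.
#' @export
spine_geometry_defaults <- function(class) {
  switch(match.arg(class, c("mushroom", "stubby", "thin")),
    mushroom = list(neck_length = c(4, 7), neck_width = c(1.6, 2.4),
                    head_radius = c(3, 4.5)),
    stubby   = list(neck_length = c(0, 0), neck_width = c(0, 0),
                    head_radius = c(2.5, 3.8)),
    thin     = list(neck_length = c(10, 15), neck_width = c(1.0, 1.8),
                    head_radius = c(0.5, 0.9))  # capped at neck_width
  )
}

#' Specify a single spine
#'
#' @param class Spine morphology: `"mushroom"`, `"stubby"` or `"thin"`.
#' @param attachment `"attached"` (contiguous with the dendrite) or
#'   `"detached"` (separated by a small gap).
#' @param base_point Arc-length position of the spine base on the
#'   dendrite backbone, as a fraction in `[0, 1]`.
#' @param orientation Absolute direction of the spine axis in radians
#'   (image convention: angle of (row, col) displacement). `NA` means
#'   perpendicular to the dendrite, on the side given by `side`.
#' @param side +1 or -1; which side of the backbone the spine grows
#'   from when `orientation` is `NA`.
#' @param neck_length,neck_width,head_radius Geometry in pixels; `NULL`
#'   takes the midpoint of [spine_geometry_defaults()].
#' @param gap Gap in pixels between dendrite boundary and spine base for
#'   detached spines.
#' @return A `spine_spec` list.
#' @export
spine_spec <- function(class, attachment = c("attached", "detached"),
                       base_point = 0.5, orientation = NA, side = 1L,
                       neck_length = NULL, neck_width = NULL,
                       head_radius = NULL, gap = 3) {
  class <- match.arg(class, c("mushroom", "stubby", "thin"))
  attachment <- match.arg(attachment)
  def <- spine_geometry_defaults(class)
  if (is.null(neck_length)) neck_length <- mean(def$neck_length)
  if (is.null(neck_width)) neck_width <- mean(def$neck_width)
  if (is.null(head_radius)) head_radius <- mean(def$head_radius)
  if (class == "thin") head_radius <- min(head_radius, neck_width)
  sp <- list(class = class, attachment = attachment,
             base_point = base_point, orientation = orientation,
             side = as.integer(sign(side)), neck_length = neck_length,
             neck_width = neck_width, head_radius = head_radius, gap = gap)
  validate_spine_spec(sp)
  class(sp) <- "spine_spec"
  sp
}

validate_spine_spec <- function(sp) {
  if (sp$base_point < 0 || sp$base_point > 1)
    stop("base_point must be a fraction in [0, 1]")
  total <- sp$neck_length + 2 * sp$head_radius
  if (sp$class == "mushroom") {
    if (sp$neck_length <= 0) stop("mushroom spines need neck_length > 0")
    if (sp$neck_width >= 2 * sp$head_radius)
      stop("mushroom spines need neck_width < head diameter")
  } else if (sp$class == "stubby") {
    if (sp$neck_length != 0) stop("stubby spines have neck_length = 0")
  } else {
    if (sp$head_radius > sp$neck_width)
      stop("thin spines need head_radius <= neck_width")
    if (total <= 4 * sp$head_radius)
      stop("thin spines need total length > 2x head diameter")
    if (2 * max(sp$neck_width, sp$head_radius) > 5)
      stop("thin spines must fit a ~5x20 envelope")
  }
  if (total > 20 || 2 * sp$head_radius > 20)
    stop("spine does not fit the 20x20 pixel envelope")
  invisible(sp)
}

# draw a randomized spec of the given class using the current RNG
random_spine_spec <- function(class, attachment = "attached",
                              base_point = 0.5, side = 1L,
                              orientation = NA) {
  def <- spine_geometry_defaults(class)
  runif1 <- function(r) runif(1, r[1], r[2])
  nl <- runif1(def$neck_length)
  nw <- runif1(def$neck_width)
  hr <- runif1(def$head_radius)
  if (class == "thin") hr <- min(hr * nw, nw)  # fraction of the neck width
  spine_spec(class, attachment, base_point, orientation, side,
             neck_length = nl, neck_width = nw, head_radius = hr)
}

#' Specify a synthetic dendrite scene
#'
#' @param image_height,image_width Canvas size in pixels.
#' @param dendrite_control_points Matrix of (row, col) control points of
#'   the dendrite centerline; `NULL` draws a gentle S-curve across the
#'   canvas (seeded).
#' @param width_profile Either a `c(min, max)` range (widths drawn per
#'   control point and splined along the curve) or one width per control
#'   point. All widths must be >= 2 pixels.
#' @param spine_specs List of [spine_spec()] objects.
#' @param foreground_level,background_level Normalized intensities in
#'   `[0, 1]`; foreground must exceed background.
#' @param noise List with `gaussian_sigma` (additive read-out noise) and
#'   `poisson_scale` (photon count at intensity 1; 0 disables shot
#'   noise), a surrogate for photomultiplier-tube noise.
#' @param blur_sigma Gaussian blur approximating the optical PSF.
#' @param seed Integer seed; the same spec and seed give bit-identical
#'   output.
#' @return A `scene_spec` list.
#' @export
scene_spec <- function(image_height = 256, image_width = 256,
                       dendrite_control_points = NULL,
                       width_profile = c(4, 12), spine_specs = list(),
                       foreground_level = 0.75, background_level = 0.08,
                       noise = list(gaussian_sigma = 0.02,
                                    poisson_scale = 400),
                       blur_sigma = 0.7, seed = 1L) {
  if (foreground_level <= background_level)
    stop("foreground_level must exceed background_level")
  if (any(width_profile < 2)) stop("width_profile values must be >= 2")
  if (is.null(noise$gaussian_sigma)) noise$gaussian_sigma <- 0
  if (is.null(noise$poisson_scale)) noise$poisson_scale <- 0
  sp <- list(image_height = as.integer(image_height),
             image_width = as.integer(image_width),
             dendrite_control_points = dendrite_control_points,
             width_profile = width_profile, spine_specs = spine_specs,
             foreground_level = foreground_level,
             background_level = background_level, noise = noise,
             blur_sigma = blur_sigma, seed = as.integer(seed))
  class(sp) <- "scene_spec"
  sp
}

# ---- low-level rasterization -------------------------------------------

# stamp pixels within radius r of (cy, cx) into logical matrix m
stamp_disk <- function(m, cy, cx, r) {
  h <- nrow(m); w <- ncol(m)
  i0 <- max(1L, floor(cy - r)); i1 <- min(h, ceiling(cy + r))
  j0 <- max(1L, floor(cx - r)); j1 <- min(w, ceiling(cx + r))
  if (i0 > i1 || j0 > j1) return(m)
  ii <- i0:i1; jj <- j0:j1
  d2 <- outer((ii - cy)^2, (jj - cx)^2, `+`)
  m[ii, jj] <- m[ii, jj] | (d2 <= r^2)
  m
}

# stamp a capsule: all pixels within halfwidth of the segment p0-p1
stamp_capsule <- function(m, p0, p1, halfwidth) {
  h <- nrow(m); w <- ncol(m)
  r <- halfwidth
  i0 <- max(1L, floor(min(p0[1], p1[1]) - r))
  i1 <- min(h, ceiling(max(p0[1], p1[1]) + r))
  j0 <- max(1L, floor(min(p0[2], p1[2]) - r))
  j1 <- min(w, ceiling(max(p0[2], p1[2]) + r))
  if (i0 > i1 || j0 > j1) return(m)
  ii <- i0:i1; jj <- j0:j1
  py <- matrix(ii, length(ii), length(jj))
  px <- matrix(jj, length(ii), length(jj), byrow = TRUE)
  vy <- p1[1] - p0[1]; vx <- p1[2] - p0[2]
  L2 <- vy^2 + vx^2
  t <- if (L2 == 0) 0 else pmin(pmax(((py - p0[1]) * vy + (px - p0[2]) * vx) / L2, 0), 1)
  d2 <- (py - (p0[1] + t * vy))^2 + (px - (p0[2] + t * vx))^2
  m[ii, jj] <- m[ii, jj] | (d2 <= r^2)
  m
}

# render one spine into a fresh logical mask; base = (row, col) of the
# point where the spine meets the dendrite boundary, u = unit axis
# direction pointing away from the dendrite. Errors when the shape
# leaves the canvas.
render_spine_mask <- function(h, w, base, u, sp) {
  m <- matrix(FALSE, h, w)
  if (sp$class == "stubby") {
    c0 <- base + u * sp$head_radius * 0.75
    extreme <- rbind(c0 + sp$head_radius, c0 - sp$head_radius)
    check_on_canvas(extreme, h, w, sp$class)
    m <- stamp_disk(m, c0[1], c0[2], sp$head_radius)
  } else {
    p1 <- base + u * sp$neck_length
    hc <- p1 + u * sp$head_radius * 0.7
    extreme <- rbind(base, p1, hc + sp$head_radius, hc - sp$head_radius)
    check_on_canvas(extreme, h, w, sp$class)
    m <- stamp_capsule(m, base, p1, sp$neck_width / 2)
    if (sp$head_radius > 0) m <- stamp_disk(m, hc[1], hc[2], sp$head_radius)
  }
  m
}

check_on_canvas <- function(points, h, w, what) {
  if (any(points[, 1] < 1) || any(points[, 1] > h) ||
      any(points[, 2] < 1) || any(points[, 2] > w))
    stop(sprintf("%s spine placement falls off the %dx%d canvas", what, h, w))
}

# smooth centerline samples through control points, parametrized by
# cumulative chord length; returns positions, unit tangents and widths
sample_centerline <- function(ctrl, width_profile, n_per_px = 2.5) {
  d <- sqrt(diff(ctrl[, 1])^2 + diff(ctrl[, 2])^2)
  tt <- c(0, cumsum(d))
  L <- tt[length(tt)]
  fy <- splinefun(tt, ctrl[, 1], method = "natural")
  fx <- splinefun(tt, ctrl[, 2], method = "natural")
  s <- seq(0, L, length.out = max(50L, ceiling(n_per_px * L)))
  pos <- cbind(fy(s), fx(s))
  tan <- cbind(fy(s, deriv = 1), fx(s, deriv = 1))
  tan <- tan / pmax(sqrt(rowSums(tan^2)), 1e-9)
  if (length(width_profile) == 2L) {
    wk <- runif(nrow(ctrl), width_profile[1], width_profile[2])
  } else wk <- rep_len(width_profile, nrow(ctrl))
  fw <- splinefun(tt, wk, method = "natural")
  wd <- pmin(pmax(fw(s), min(wk)), max(wk))
  list(pos = pos, tangent = tan, width = wd, arc = s)
}

default_control_points <- function(h, w) {
  nx <- 5
  x <- seq(0.08 * w, 0.92 * w, length.out = nx)
  y <- h / 2 + 0.18 * h * sin(seq(0, pi * 1.5, length.out = nx)) +
    rnorm(nx, 0, 0.02 * h)
  cbind(y, x)
}

# ---- main generators ----------------------------------------------------

#' Render a synthetic dendrite scene with ground truth
#'
#' Renders a smooth curvilinear dendrite at the specified widths, adds
#' the requested spines, blurs with a Gaussian PSF surrogate and applies
#' Poisson + Gaussian noise. All randomness is governed by `spec$seed`;
#' the caller's RNG state is untouched.
#'
#' @param spec A [scene_spec()].
#' @return A list with `image` (numeric matrix in `[0, 1]`) and `truth`,
#'   a ground-truth list holding `backbone_points` (ordered (row, col)
#'   matrix), `backbone_width` (per backbone point), `boundary_mask`
#'   (binary dendrite trunk mask), `foreground_mask` (trunk plus
#'   spines), and `spine_records` (one list per spine: `class_label`,
#'   `attachment`, `pixels`, `center`, `area`, `max_width`, `length`).
#' @export
make_dendrite_image <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  with_seed(spec$seed, {
    h <- spec$image_height; w <- spec$image_width
    ctrl <- spec$dendrite_control_points
    if (is.null(ctrl)) ctrl <- default_control_points(h, w)
    cl <- sample_centerline(ctrl, spec$width_profile)
    trunk <- matrix(FALSE, h, w)
    for (k in seq_len(nrow(cl$pos)))
      trunk <- stamp_disk(trunk, cl$pos[k, 1], cl$pos[k, 2], cl$width[k] / 2)

    spine_masks <- list()
    for (sp in spec$spine_specs) {
      k <- 1L + round(sp$base_point * (nrow(cl$pos) - 1L))
      tg <- cl$tangent[k, ]
      normal <- c(-tg[2], tg[1]) * sp$side
      u <- if (is.na(sp$orientation)) normal
           else c(sin(sp$orientation), cos(sp$orientation))
      off <- if (sp$attachment == "attached") cl$width[k] / 2 - 1
             else cl$width[k] / 2 + sp$gap
      base <- cl$pos[k, ] + u * off
      spine_masks[[length(spine_masks) + 1L]] <-
        list(spec = sp, mask = render_spine_mask(h, w, base, u, sp))
    }

    fg <- trunk
    for (sm in spine_masks) fg <- fg | sm$mask
    img <- spec$background_level +
      (spec$foreground_level - spec$background_level) * fg
    img <- gaussian_blur(img, spec$blur_sigma)
    if (spec$noise$poisson_scale > 0)
      img <- matrix(rpois(length(img), img * spec$noise$poisson_scale) /
                      spec$noise$poisson_scale, h, w)
    if (spec$noise$gaussian_sigma > 0)
      img <- img + matrix(rnorm(length(img), 0, spec$noise$gaussian_sigma), h, w)
    img <- clip01(img)

    bb <- round(cl$pos)
    keep <- c(TRUE, rowSums(abs(diff(bb))) > 0)
    inside <- bb[, 1] >= 1 & bb[, 1] <= h & bb[, 2] >= 1 & bb[, 2] <= w
    keep <- keep & inside
    trunk_int <- as_int_mask(trunk + 0L)
    records <- lapply(spine_masks, function(sm) {
      px_mask <- sm$mask & !trunk       # spine pixels exclude the trunk
      pixels <- which(px_mask, arr.ind = TRUE)
      dimnames(pixels) <- NULL
      geom <- pixel_set_geometry(px_mask, pixels, trunk_int)
      list(class_label = sm$spec$class, attachment = sm$spec$attachment,
           pixels = pixels, center = geom$center, area = geom$area,
           max_width = geom$max_width, length = geom$length)
    })
    truth <- list(backbone_points = bb[keep, , drop = FALSE],
                  backbone_width = cl$width[keep],
                  boundary_mask = trunk_int,
                  foreground_mask = as_int_mask(fg + 0L),
                  spine_records = records)
    list(image = img, truth = truth)
  })
}

# geometry of a pixel set: area, centroid, extent perpendicular to the
# principal axis, and geodesic length from the trunk-nearest pixel
pixel_set_geometry <- function(px_mask, pixels, trunk) {
  n <- nrow(pixels)
  if (n == 0L)
    return(list(area = 0L, center = c(NA_real_, NA_real_),
                max_width = NA_real_, length = NA_real_))
  center <- colMeans(pixels)
  if (n == 1L) return(list(area = 1L, center = center, max_width = 1,
                           length = 0))
  cc <- sweep(pixels, 2, center)
  ev <- eigen(crossprod(cc) / n, symmetric = TRUE)$vectors
  minor <- cc %*% ev[, 2]
  max_width <- diff(range(minor)) + 1
  tpx <- which(trunk == 1L, arr.ind = TRUE)
  anchor <- if (nrow(tpx)) {
    d <- outer(pixels[, 1], tpx[, 1], `-`)^2 + outer(pixels[, 2], tpx[, 2], `-`)^2
    pixels[which(d == min(d), arr.ind = TRUE)[1, 1], ]
  } else pixels[which.max(pixels %*% ev[, 1]), ]
  gd <- cpp_geodesic(as_int_mask(px_mask + 0L), anchor[1], anchor[2])
  len <- suppressWarnings(max(gd[pixels], na.rm = TRUE))
  list(area = n, center = center, max_width = max_width,
       length = if (is.finite(len)) len else NA_real_)
}

#' Generate a labeled library of spine subimages
#'
#' Draws `n_per_class` subimages per morphology class with randomized
#' orientation, geometry jitter within [spine_geometry_defaults()],
#' intensity jitter, Gaussian blur and photon noise. Each subimage is
#' centred on the spine centroid. Three presentations are available:
#' `"isolated"` (default) renders the bare spine as a clean
#' golden-standard exemplar; `"masked"` renders a dendrite segment
#' carrying the spine, degrades it, and then cuts out the spine region
#' (the protrusion beyond the dendrite boundary, what an expert would
#' mark) against a flat background -- the presentation the detection
#' pipeline reproduces for segmented spine candidates; `"tile"` returns
#' the raw dendrite + spine tile. With `jitter = FALSE` and `noise =
#' FALSE` each class yields its canonical template.
#'
#' @param n_per_class Number of subimages per class (>= 1).
#' @param subimage_size Side of the square subimage in pixels.
#' @param seed Integer seed; same seed reproduces labels and pixels.
#' @param jitter Randomize geometry, orientation and intensity.
#' @param noise Apply Poisson + Gaussian noise.
#' @param presentation `"isolated"` (default; bare spine, no
#'   dendrite), `"masked"` (expert-marked protrusion region against
#'   flat background) or `"tile"` (raw dendrite + spine tile).
#' @return A list with `images` (list of matrices), `labels` (factor
#'   with levels mushroom/stubby/thin) and `specs` (the spine specs).
#' @export
make_spine_library <- function(n_per_class, subimage_size = 20L, seed = 1L,
                               jitter = TRUE, noise = TRUE,
                               presentation = c("isolated", "masked",
                                                "tile")) {
  if (n_per_class < 1) stop("n_per_class must be >= 1")
  presentation <- match.arg(presentation)
  classes <- c("mushroom", "stubby", "thin")
  sz <- as.integer(subimage_size)
  big <- 2L * sz + 8L  # render on a margin canvas, crop at the centroid
  off3 <- se_square(3L)
  with_seed(seed, {
    images <- vector("list", 3L * n_per_class)
    specs <- vector("list", 3L * n_per_class)
    labels <- factor(rep(classes, each = n_per_class), levels = classes)
    idx <- 0L
    for (cls in classes) {
      for (s in seq_len(n_per_class)) {
        idx <- idx + 1L
        sp <- if (jitter) random_spine_spec(cls)
              else spine_spec(cls)
        ang <- if (jitter) runif(1, 0, 2 * pi) else 0
        u <- c(sin(ang), cos(ang))
        wd <- if (jitter) runif(1, 5, 10) else 7
        dctr <- c(big / 2, big / 2)
        base <- dctr + u * (wd / 2 - 1)
        spine <- render_spine_mask(big, big, base, u, sp)
        tang <- c(-u[2], u[1])
        # dendrite segment with a gentle random bend, as in real arcs
        curv <- if (jitter) sample(c(-1, 1), 1) / runif(1, 60, 400) else 0
        tube_mask <- function(halfwidth) {
          m <- matrix(FALSE, big, big)
          for (t in seq(-big / 2, big / 2, by = 2)) {
            ctr_t <- dctr + tang * t + u * (curv * t^2 / 2)
            m <- stamp_disk(m, ctr_t[1], ctr_t[2], halfwidth)
          }
          m
        }
        tube <- tube_mask(wd / 2)
        shape <- if (presentation == "isolated") spine else spine | tube
        fore <- if (jitter) runif(1, 0.55, 0.9) else 0.75
        back <- 0.05
        img <- back + (fore - back) * shape
        img <- gaussian_blur(img, if (jitter) runif(1, 0.5, 0.9) else 0.7)
        if (noise) {
          img <- matrix(rpois(length(img), img * 400) / 400, big, big)
          img <- img + matrix(rnorm(length(img), 0, 0.02), big, big)
        }
        img <- clip01(img)
        # expert-marked spine region: protrusion beyond the (slightly
        # widened) dendrite boundary
        prot <- spine & !tube_mask(wd / 2 + 1)
        px <- which(if (presentation == "isolated") spine else prot,
                    arr.ind = TRUE)
        if (nrow(px) == 0L) px <- which(spine, arr.ind = TRUE)
        cen <- round(colMeans(px))
        if (presentation == "masked") {
          keepm <- matrix(0L, big, big)
          keepm[px] <- 1L
          keepm <- cpp_binary_dilate(keepm, off3)
          img <- ifelse(keepm == 1L, img, back)
        }
        i0 <- min(max(1L, cen[1] - (sz - 1L) %/% 2L), big - sz + 1L)
        j0 <- min(max(1L, cen[2] - (sz - 1L) %/% 2L), big - sz + 1L)
        images[[idx]] <- img[i0:(i0 + sz - 1L), j0:(j0 + sz - 1L)]
        specs[[idx]] <- sp
      }
    }
    list(images = images, labels = labels, specs = specs)
  })
}

#' Maximum intensity projection of a 3D stack
#'
#' @param stack A 3D array (rows x cols x slices) or a list of matrices.
#' @return A matrix: the per-pixel maximum over slices.
#' @export
max_intensity_projection <- function(stack) {
  if (is.list(stack)) {
    if (!length(stack)) stop("empty stack")
    return(Reduce(pmax, stack))
  }
  if (!is.array(stack) || length(dim(stack)) != 3L)
    stop("stack must be a 3D array or a list of matrices")
  if (dim(stack)[3] == 0L) stop("empty stack")
  apply(stack, c(1, 2), max)
}

#' Scene spec for a 20-spine demonstration dendrite
#'
#' A long S-curved dendrite carrying 8 mushroom, 8 stubby and 4 thin
#' spines (by default) at evenly spaced arc positions on alternating
#' sides; used for end-to-end detection experiments.
#'
#' @param n_mushroom,n_stubby,n_thin Spine counts per class.
#' @param size Canvas side in pixels.
#' @param seed Scene seed.
#' @param noise Noise model passed to [scene_spec()].
#' @return A [scene_spec()].
#' @export
demo_scene_spec <- function(n_mushroom = 8, n_stubby = 8, n_thin = 4,
                            size = 640L, seed = 7L,
                            noise = list(gaussian_sigma = 0.02,
                                         poisson_scale = 400)) {
  n <- n_mushroom + n_stubby + n_thin
  classes <- rep(c("mushroom", "stubby", "thin"),
                 c(n_mushroom, n_stubby, n_thin))
  specs <- with_seed(seed + 1L, {
    classes <- sample(classes)
    pos <- seq(0.05, 0.95, length.out = n)
    lapply(seq_len(n), function(i)
      random_spine_spec(classes[i], base_point = pos[i],
                        side = if (i %% 2) 1L else -1L))
  })
  scene_spec(image_height = size, image_width = size, spine_specs = specs,
             width_profile = c(5, 10), noise = noise, seed = seed)
}
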