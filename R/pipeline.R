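# End-to-end detection: sliding-window detection planes from the
# trained RMSNN, geometric separation of spines from the dendrite
# trunk, and per-spine characterization.

#' Sliding-window detection planes
#'
#' Scores every stride-spaced window of the image with the trained
#' RMSNN, producing one detection plane per class, then extracts
#' candidate detections as score local maxima above threshold after
#' non-maximum suppression within one window size.
#'
#' @param image Preprocessed numeric matrix (at least as large as the
#'   model window).
#' @param model Trained `rmsnn_model`.
#' @param stride Window stride in pixels.
#' @param score_threshold Minimum class score for a candidate.
#' @param nms_radius Suppression radius in pixels (default: the window
#'   side).
#' @param min_contrast Minimum intensity range inside a window for it
#'   to become a candidate; windows without structure (blank
#'   background) carry no shape information for the Hit-Miss features
#'   and are never reported, whatever their raw score.
#' @return List with `planes` (one score matrix per class; cell (i, j)
#'   scores the window with top-left `((i-1)*stride+1, (j-1)*stride+1)`),
#'   `candidates` (data.frame: window center, class, score) and
#'   `stride`/`window`.
#' @export
scan_detect <- function(image, model, stride = 2L,
                        score_threshold = 0.5, nms_radius = NULL,
                        min_contrast = 0.1) {
  assert_image(image)
  win <- model$input_size
  if (nrow(image) < win[1] || ncol(image) < win[2])
    stop(sprintf("image (%dx%d) is smaller than the %dx%d model window",
                 nrow(image), ncol(image), win[1], win[2]))
  if (is.null(nms_radius)) nms_radius <- max(win)
  planes <- cpp_scan_detect(image, model, as.integer(stride))
  names(planes) <- model$classes
  best <- planes[[1]]
  best_cl <- matrix(1L, nrow(best), ncol(best))
  for (k in seq_along(planes)[-1]) {
    upd <- planes[[k]] > best
    best[upd] <- planes[[k]][upd]
    best_cl[upd] <- k
  }
  cand_idx <- which(best > score_threshold, arr.ind = TRUE)
  if (nrow(cand_idx) && min_contrast > 0) {
    has_structure <- vapply(seq_len(nrow(cand_idx)), function(k) {
      i0 <- (cand_idx[k, 1] - 1L) * stride + 1L
      j0 <- (cand_idx[k, 2] - 1L) * stride + 1L
      patch <- image[i0:(i0 + win[1] - 1L), j0:(j0 + win[2] - 1L)]
      diff(range(patch)) >= min_contrast
    }, TRUE)
    cand_idx <- cand_idx[has_structure, , drop = FALSE]
  }
  cand <- data.frame(
    row = (cand_idx[, 1] - 1L) * stride + 1L + (win[1] - 1L) %/% 2L,
    col = (cand_idx[, 2] - 1L) * stride + 1L + (win[2] - 1L) %/% 2L,
    class = model$classes[best_cl[cand_idx]],
    score = best[cand_idx], stringsAsFactors = FALSE)
  cand <- cand[order(-cand$score), , drop = FALSE]
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    if (!any(keep)) { keep[k] <- TRUE; next }
    d2 <- (cand$row[keep] - cand$row[k])^2 + (cand$col[keep] - cand$col[k])^2
    if (all(d2 >= nms_radius^2)) keep[k] <- TRUE
  }
  cand <- cand[keep, , drop = FALSE]
  rownames(cand) <- NULL
  list(planes = planes, candidates = cand, stride = stride, window = win)
}

# distance from a pixel to the nearest background pixel of the mask
# (windowed search; the dendrite half-width bounds it in practice)
dist_to_background <- function(mask, pt, max_r = 20L) {
  h <- nrow(mask); w <- ncol(mask)
  if (!mask[pt[1], pt[2]]) return(0)
  for (r in 1:max_r) {
    ii <- max(1, pt[1] - r):min(h, pt[1] + r)
    jj <- max(1, pt[2] - r):min(w, pt[2] + r)
    sub <- mask[ii, jj, drop = FALSE]
    if (any(sub == 0L)) {
      bg <- which(sub == 0L, arr.ind = TRUE)
      return(sqrt(min((ii[bg[, 1]] - pt[1])^2 + (jj[bg[, 2]] - pt[2])^2)))
    }
    if (length(ii) == h && length(jj) == w) break
  }
  max_r
}

# Trunk mask between the boundary chains, realized as the union of the
# inscribed disks of the backbone: at every backbone point the trunk
# radius is the distance to the nearest background pixel. A one-sided
# protrusion (an attached spine) barely moves that radius, whereas
# width estimates read across the protrusion would absorb the whole
# spine into the trunk. The backbone is extrapolated along its end
# tangents so the rounded tube ends (which yield no symmetric pairs)
# are still claimed.
trunk_mask <- function(mask, paths, boundaries) {
  h <- nrow(mask); w <- ncol(mask)
  trunk <- matrix(FALSE, h, w)
  runsmooth <- function(x, np, k = 15L) {
    if (np < 3) return(x)
    as.numeric(stats::runmed(x, k = min(k, np - (1 - np %% 2))))
  }
  for (pi in seq_along(paths)) {
    p <- paths[[pi]]
    np <- nrow(p$points)
    radii <- vapply(seq_len(np), function(k)
      dist_to_background(mask, p$points[k, ]), 0)
    # the inscribed radius is still slightly inflated where a spine
    # merges with the trunk; a running median over a window wider than
    # a spine footprint keeps the regular radius
    rrob <- pmin(radii, runsmooth(radii, np, 21L))
    for (k in seq_len(np))
      trunk <- stamp_disk(trunk, p$points[k, 1], p$points[k, 2], rrob[k])
    # extrapolate beyond both path ends while still inside the mask
    if (np >= 2) {
      for (endk in c(1L, np)) {
        tg <- p$tangent[endk]
        dir <- c(sin(tg), cos(tg)) * (if (endk == 1L) -1 else 1)
        for (t in seq_len(25L)) {
          pos <- round(p$points[endk, ] + t * dir)
          if (pos[1] < 1 || pos[1] > h || pos[2] < 1 || pos[2] > w) break
          if (!mask[pos[1], pos[2]]) break
          trunk <- stamp_disk(trunk, pos[1], pos[2],
                              dist_to_background(mask, pos) + 0.5)
        }
      }
    }
  }
  storage.mode(trunk) <- "integer"
  trunk <- cpp_binary_dilate(trunk, se_square(3L))
  trunk * as_int_mask(mask)
}

#' Separate spine pixel sets from the dendrite trunk
#'
#' The trunk region is reconstructed between the two boundary chains;
#' spine candidates are the remaining foreground components, flagged
#' `attached` when contiguous with the trunk and `detached` when within
#' `detach_dist` pixels of it (farther components are dropped with a
#' reason). Detection candidates are matched to the nearest component.
#'
#' @param mask Binary foreground mask.
#' @param paths Backbone paths ([extract_backbone()]).
#' @param boundaries Boundary point sets ([dendrite_boundary()]).
#' @param candidates Optional candidate table from [scan_detect()].
#' @param min_area Minimum component area in pixels.
#' @param detach_dist Maximum trunk distance for a detached spine.
#' @param match_dist Maximum candidate-to-component centre distance.
#' @return List with `components` (each: `pixels`, `center`,
#'   `attachment`, `candidate` index or NA), `trunk` (mask) and
#'   `dropped` (components rejected, with reasons).
#' @export
segment_spines <- function(mask, paths, boundaries, candidates = NULL,
                           min_area = 4L, detach_dist = 5,
                           match_dist = 15) {
  assert_mask(mask)
  trunk <- trunk_mask(mask, paths, boundaries)
  rest <- as_int_mask(mask) * (1L - trunk)
  # label on the dilated remainder so that a protrusion split by a
  # one-pixel threshold dropout (a faint thin neck) stays one spine
  labs_d <- cpp_label_components(cpp_binary_dilate(rest, se_square(3L)))
  labs <- labs_d * rest
  comps <- list()
  dropped <- list()
  tpx <- which(trunk == 1L, arr.ind = TRUE)
  for (lb in seq_len(max(labs, 0L))) {
    pixels <- which(labs == lb, arr.ind = TRUE)
    dimnames(pixels) <- NULL
    if (nrow(pixels) == 0L) next
    if (nrow(pixels) < min_area) {
      dropped[[length(dropped) + 1L]] <-
        list(pixels = pixels, reason = "below min_area")
      next
    }
    dmin <- if (nrow(tpx)) min_dist_to_set(pixels, tpx) else Inf
    attachment <- if (dmin <= sqrt(2)) "attached"
                  else if (dmin <= detach_dist) "detached" else NA
    if (is.na(attachment)) {
      dropped[[length(dropped) + 1L]] <-
        list(pixels = pixels, reason = "too far from dendrite")
      next
    }
    # one-pixel-wide shallow components running along the trunk are
    # boundary slivers (residual mask edge), not spines: every spine
    # class is >= 2 px wide after thresholding or protrudes deeply
    if (nrow(pixels) >= 3L && nrow(tpx)) {
      cc <- sweep(pixels, 2, colMeans(pixels))
      ev <- eigen(crossprod(cc) / nrow(cc), symmetric = TRUE)$vectors
      minor <- diff(range(cc %*% ev[, 2])) + 1
      depth <- max(vapply(seq_len(nrow(pixels)), function(k)
        min_dist_to_set(pixels[k, , drop = FALSE], tpx), 0))
      if (minor < 1.5 && depth < 3) {
        dropped[[length(dropped) + 1L]] <-
          list(pixels = pixels, reason = "boundary sliver")
        next
      }
    }
    comps[[length(comps) + 1L]] <-
      list(pixels = pixels, center = colMeans(pixels),
           attachment = attachment, candidate = NA_integer_)
  }
  if (!is.null(candidates) && nrow(candidates) && length(comps)) {
    ctr <- t(vapply(comps, `[[`, numeric(2), "center"))
    for (k in seq_len(nrow(candidates))) {
      d2 <- (ctr[, 1] - candidates$row[k])^2 + (ctr[, 2] - candidates$col[k])^2
      j <- which.min(d2)
      if (d2[j] <= match_dist^2 && is.na(comps[[j]]$candidate))
        comps[[j]]$candidate <- k
    }
  }
  list(components = comps, trunk = trunk, dropped = dropped)
}

min_dist_to_set <- function(pixels, set) {
  # windowed search keeps this cheap for small components
  r0 <- range(pixels[, 1]); c0 <- range(pixels[, 2])
  near <- set[, 1] >= r0[1] - 8 & set[, 1] <= r0[2] + 8 &
          set[, 2] >= c0[1] - 8 & set[, 2] <= c0[2] + 8
  sub <- set[near, , drop = FALSE]
  if (!nrow(sub)) return(Inf)
  sqrt(min(outer(pixels[, 1], sub[, 1], `-`)^2 +
             outer(pixels[, 2], sub[, 2], `-`)^2))
}

#' Geometric attributes of a spine pixel set
#'
#' Area is the pixel count; perimeter the number of contour pixels
#' (component pixels 8-adjacent to the outside); `max_width` the extent
#' perpendicular to the principal axis; `length` the geodesic distance
#' (8-connected, diagonal steps sqrt(2)) from the attachment point to
#' the farthest pixel; `center` the centroid.
#'
#' @param pixels Integer (row, col) matrix of spine pixels (nonempty).
#' @param dim Image dimensions `c(rows, cols)`.
#' @param attachment_point Integer (row, col) starting point of the
#'   spine (typically the pixel nearest the dendrite boundary); `NULL`
#'   uses the pixel at the lowest principal-axis projection.
#' @return List: `area`, `perimeter`, `max_width`, `length`, `center`.
#' @export
characterize_spine <- function(pixels, dim, attachment_point = NULL) {
  if (is.null(pixels) || nrow(pixels) == 0L) stop("empty spine pixel set")
  n <- nrow(pixels)
  center <- colMeans(pixels)
  m <- matrix(0L, dim[1], dim[2])
  m[pixels] <- 1L
  inner <- cpp_binary_erode(m, se_square(3L), 0L)
  perimeter <- sum(m) - sum(inner * m)
  if (n == 1L)
    return(list(area = 1L, perimeter = 1L, max_width = 1, length = 0,
                center = center))
  cc <- sweep(pixels, 2, center)
  ev <- eigen(crossprod(cc) / n, symmetric = TRUE)$vectors
  max_width <- diff(range(cc %*% ev[, 2])) + 1
  if (is.null(attachment_point)) {
    proj <- cc %*% ev[, 1]
    attachment_point <- pixels[which.min(proj), ]
  }
  gd <- cpp_geodesic(m, attachment_point[1], attachment_point[2])
  len <- suppressWarnings(max(gd[pixels], na.rm = TRUE))
  list(area = n, perimeter = perimeter, max_width = max_width,
       length = if (is.finite(len)) len else NA_real_, center = center)
}

# classify the window centred on a point; the window is clipped to the
# frame by sliding it inside.
classify_window <- function(image, model, center) {
  win <- model$input_size
  h <- nrow(image); w <- ncol(image)
  i0 <- min(max(1L, round(center[1]) - (win[1] - 1L) %/% 2L), h - win[1] + 1L)
  j0 <- min(max(1L, round(center[2]) - (win[2] - 1L) %/% 2L), w - win[2] + 1L)
  patch <- image[i0:(i0 + win[1] - 1L), j0:(j0 + win[2] - 1L)]
  sc <- cpp_msnn_predict(list(patch), model)[1, ]
  names(sc) <- model$classes
  sc
}

# classify a segmented component from a masked patch: image values on
# the component (dilated by one pixel), flat background elsewhere --
# the same isolated-spine presentation the training library uses, so
# the classifier is not confounded by the adjacent dendrite trunk.
classify_component <- function(image, model, pixels, background) {
  win <- model$input_size
  h <- nrow(image); w <- ncol(image)
  m <- matrix(0L, h, w)
  m[pixels] <- 1L
  md <- cpp_binary_dilate(m, se_square(3L))
  center <- round(colMeans(pixels))
  i0 <- min(max(1L, center[1] - (win[1] - 1L) %/% 2L), h - win[1] + 1L)
  j0 <- min(max(1L, center[2] - (win[2] - 1L) %/% 2L), w - win[2] + 1L)
  ii <- i0:(i0 + win[1] - 1L); jj <- j0:(j0 + win[2] - 1L)
  patch <- matrix(background, win[1], win[2])
  sel <- md[ii, jj] == 1L
  patch[sel] <- image[ii, jj][sel]
  sc <- cpp_msnn_predict(list(patch), model)[1, ]
  names(sc) <- model$classes
  sc
}

#' Run the full spine-detection pipeline
#'
#' Preprocesses the image, extracts the backbone and boundary, scans
#' the image with the trained RMSNN, separates spine components from
#' the dendrite trunk and characterizes each spine. A component's class
#' is the argmax of the classifier scores at the window centred on its
#' centroid (the detection-plane value at its matched candidate when
#' the candidate coincides with that window).
#'
#' @param image Numeric matrix in `[0, 1]` or a path readable by
#'   [read_gray_image()].
#' @param model Trained `rmsnn_model` or a path to a JSON model file.
#' @param median_window,otsu_window,isolated_n Preprocessing
#'   parameters.
#' @param wavelet A [wavelet_config()].
#' @param boundary A [boundary_config()].
#' @param stride,score_threshold Scan parameters ([scan_detect()]).
#' @param min_area,detach_dist Segmentation parameters
#'   ([segment_spines()]).
#' @param seg_alpha_frac Fraction of the median backbone intensity used
#'   as the pixel-membership threshold when separating spine pixels.
#'   Deliberately below the boundary fraction: thin spine necks are
#'   narrower than the optical resolution and render dimmer than the
#'   trunk, so trunk-level thresholds would erase them.
#' @return List with `records` (data.frame: one row per spine),
#'   `candidates`, `planes`, `paths`, `boundaries`, `mask`, `trunk` and
#'   the preprocessed `image`.
#' @export
run_pipeline <- function(image, model, median_window = 3L,
                         otsu_window = 32L, isolated_n = 2L,
                         wavelet = wavelet_config(),
                         boundary = boundary_config(), stride = 2L,
                         score_threshold = 0.5, min_area = 4L,
                         detach_dist = 5, seg_alpha_frac = 0.35) {
  if (is.character(image)) image <- read_gray_image(image)
  if (is.character(model)) model <- load_rmsnn(model)
  pre <- preprocess_image(image, median_window)
  mask <- foreground_mask(pre, otsu_window, isolated_n)
  bb <- dendrite_backbone(pre, mask, wavelet)
  if (!length(bb$paths)) stop("pipeline stage `backbone`: no backbone found")
  bnd <- dendrite_boundary(pre, bb$paths, boundary)
  det <- scan_detect(pre, model, stride, score_threshold)
  # segmentation mask at the line-membership threshold alpha: faint
  # protrusions (thin spines) sit below the tile-Otsu threshold that
  # the bright dendrite sets, but well above alpha. The median filter
  # erases sub-resolution necks, so membership is evaluated on the
  # diffusion-enhanced image alone.
  pre_seg <- pde_enhance(image)
  bbpts <- do.call(rbind, lapply(bb$paths, `[[`, "points"))
  alpha_seg <- seg_alpha_frac * stats::median(pre_seg[bbpts])
  mask_seg <- remove_isolated_points((pre_seg >= alpha_seg) + 0L, isolated_n)
  seg <- segment_spines(mask_seg, bb$paths, bnd, det$candidates,
                        min_area, detach_dist)
  tpx <- which(seg$trunk == 1L, arr.ind = TRUE)
  # masked patches from the raw image: the training library renders
  # isolated spines in the raw (blur + noise) domain
  bg_est <- stats::median(image[pre_seg < alpha_seg])
  rows <- lapply(seg$components, function(cp) {
    anchor <- if (nrow(tpx)) {
      d2 <- outer(cp$pixels[, 1], tpx[, 1], `-`)^2 +
        outer(cp$pixels[, 2], tpx[, 2], `-`)^2
      cp$pixels[which(d2 == min(d2), arr.ind = TRUE)[1, 1], ]
    } else NULL
    geo <- characterize_spine(cp$pixels, dim(image), anchor)
    sc <- classify_component(image, model, cp$pixels, bg_est)
    data.frame(class = model$classes[which.max(sc)],
               score = max(sc), center_row = geo$center[1],
               center_col = geo$center[2], area = geo$area,
               perimeter = geo$perimeter, max_width = geo$max_width,
               length = geo$length, attachment = cp$attachment,
               candidate = cp$candidate, stringsAsFactors = FALSE)
  })
  records <- if (length(rows)) do.call(rbind, rows)
             else data.frame(class = character(0), score = numeric(0),
                             center_row = numeric(0), center_col = numeric(0),
                             area = integer(0), perimeter = numeric(0),
                             max_width = numeric(0), length = numeric(0),
                             attachment = character(0),
                             candidate = integer(0))
  rownames(records) <- NULL
  list(records = records, candidates = det$candidates, planes = det$planes,
       paths = bb$paths, boundaries = bnd, mask = mask,
       mask_seg = mask_seg, trunk = seg$trunk, dropped = seg$dropped,
       image = pre)
}

#' Write spine records to CSV or JSON
#'
#' @param records Records data.frame from [run_pipeline()].
#' @param path Output path (`.csv` or `.json`).
#' @return The path, invisibly.
#' @export
write_spine_records <- function(records, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") write.csv(records, path, row.names = FALSE)
  else if (ext == "json")
    jsonlite::write_json(records, path, digits = NA, dataframe = "rows")
  else stop("unsupported records format: .", ext)
  invisible(path)
}

#' Render a detection overlay
#'
#' Gray image with the backbone in purple, the boundary in red and the
#' periphery of every detected spine in blue.
#'
#' @param result Output of [run_pipeline()].
#' @param path Optional PNG path; `NULL` returns the RGB array only.
#' @return H x W x 3 RGB array, invisibly when written.
#' @export
detection_overlay <- function(result, path = NULL) {
  img <- clip01(result$image)
  rgb <- array(rep(img, 3), dim = c(dim(img), 3))
  put <- function(rgb, pts, col) {
    pts <- pts[pts[, 1] >= 1 & pts[, 1] <= dim(rgb)[1] &
                 pts[, 2] >= 1 & pts[, 2] <= dim(rgb)[2], , drop = FALSE]
    for (ch in 1:3) rgb[cbind(pts, ch)] <- col[ch]
    rgb
  }
  for (p in result$paths) rgb <- put(rgb, p$points, c(0.7, 0, 0.9))
  for (b in result$boundaries) {
    rgb <- put(rgb, b$side1, c(1, 0, 0))
    rgb <- put(rgb, b$side2, c(1, 0, 0))
  }
  for (cp in segment_components(result)) {
    m <- matrix(0L, dim(img)[1], dim(img)[2])
    m[cp] <- 1L
    inner <- cpp_binary_erode(m, se_square(3L), 0L)
    rgb <- put(rgb, which(m == 1L & inner == 0L, arr.ind = TRUE), c(0.2, 0.4, 1))
  }
  if (!is.null(path)) {
    png::writePNG(rgb, path)
    return(invisible(rgb))
  }
  rgb
}

segment_components <- function(result) {
  # pixel sets of retained spines; recomputed from the stored trunk
  m <- if (!is.null(result$mask_seg)) result$mask_seg else result$mask
  rest <- as_int_mask(m) * (1L - result$trunk)
  labs <- cpp_label_components(rest)
  out <- list()
  for (k in seq_len(nrow(result$records))) {
    ctr <- round(c(result$records$center_row[k], result$records$center_col[k]))
    lb <- labs[ctr[1], ctr[2]]
    if (lb == 0) {
      # centroid may fall outside a concave component; probe nearby
      win <- labs[max(1, ctr[1] - 2):min(nrow(labs), ctr[1] + 2),
                  max(1, ctr[2] - 2):min(ncol(labs), ctr[2] + 2)]
      lb <- max(win)
    }
    if (lb > 0) {
      px <- which(labs == lb, arr.ind = TRUE)
      dimnames(px) <- NULL
      out[[length(out) + 1L]] <- px
    }
  }
  out
}
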