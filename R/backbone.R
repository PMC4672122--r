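# Backbone extraction: multiscale wavelet gradient, modulus-maxima
# contour detection, conditional symmetric pairing and centerline
# assembly.
#
# The wavelet gradient at scale s is W_{x,s}f = s d/dx (f * theta_s),
# W_{y,s}f = s d/dy (f * theta_s) with theta_s(x,y) =
# (1/s^2) theta(x/s, y/s) a unit-mass low-pass kernel. Contour points
# are local maxima of the gradient modulus along the gradient
# direction; two contour points on opposite sides of a stroke whose
# separation matches the scale form a conditional symmetric pair, and
# the midpoints of all stable pairs trace the centerline.

#' Configuration for backbone extraction
#'
#' @param scales Wavelet scales (pixels), ascending; the scale sweep
#'   should bracket the expected dendrite widths.
#' @param kernel Smoothing family: `"gaussian_derivative"` (default;
#'   unit-mass Gaussian `theta`) or `"piecewise_phi"` (piecewise
#'   rational-log basis, best-effort reading; see [phi_plus()]).
#' @param pair_tolerance Allowed deviation of pair separation from the
#'   scale, in pixels; `NULL` means `max(1, 0.2 * s)`.
#' @param angle_tolerance Deviation from exactly opposite gradients
#'   still accepted when pairing (radians).
#' @param sigma0 Width of the base kernel `theta` in scale units; the
#'   effective smoothing at scale `s` is `sigma0 * s` pixels.
#' @param mm_threshold Modulus floor below which no contour point is
#'   reported.
#' @param min_path_length Minimum number of points for a standalone
#'   backbone path; shorter isolated paths (e.g. the centreline of a
#'   detached spine) are not dendrites and are discarded.
#' @param spur_length Minimum backbone branch length in pixels; shorter
#'   dead-end branches are pruned. The default slightly below the 20-px
#'   spine envelope removes the short centreline stubs that large
#'   (mushroom) spines grow, keeping the backbone on the dendrite
#'   proper.
#' @return A `wavelet_config` list.
#' @export
wavelet_config <- function(scales = c(3, 5, 7, 9, 11, 13),
                           kernel = c("gaussian_derivative", "piecewise_phi"),
                           pair_tolerance = NULL, angle_tolerance = pi / 4,
                           sigma0 = 0.35, mm_threshold = 0.1,
                           spur_length = 22, min_path_length = 20) {
  kernel <- match.arg(kernel)
  if (any(scales <= 0) || is.unsorted(scales))
    stop("scales must be positive and ascending")
  structure(list(scales = scales, kernel = kernel,
                 pair_tolerance = pair_tolerance,
                 angle_tolerance = angle_tolerance, sigma0 = sigma0,
                 mm_threshold = mm_threshold, spur_length = spur_length,
                 min_path_length = min_path_length),
            class = "wavelet_config")
}

#' Low-pass smoothing kernel at a given scale
#'
#' Samples `theta_s(x, y) = (1/s^2) theta(x/s, y/s)` on the integer
#' grid, where `theta` is an isotropic Gaussian of width `sigma0` (in
#' scale units). Doubling `s` doubles the support and quarters the raw
#' values; with `normalize = TRUE` (default) the sampled kernel is
#' rescaled to exact unit mass.
#'
#' @param s Scale in pixels (>= 1).
#' @param sigma0 Base kernel width in scale units.
#' @param normalize Rescale to exact unit sum.
#' @return A square numeric matrix (odd side).
#' @export
smoothing_kernel <- function(s, sigma0 = 0.35, normalize = TRUE) {
  if (s < 1) stop("s must be >= 1")
  r <- max(1L, as.integer(ceiling(ceiling(4 * sigma0) * s)))
  g <- -r:r
  theta <- function(u, v) exp(-(u^2 + v^2) / (2 * sigma0^2)) / (2 * pi * sigma0^2)
  k <- outer(g, g, function(y, x) theta(y / s, x / s)) / s^2
  if (normalize) k <- k / sum(k)
  k
}

#' Positive half of the piecewise symmetric wavelet basis
#'
#' Evaluates the positive branch `phi+` of the piecewise rational-log
#' basis on `[0, 1)` (zero for `x >= 1` and `x < 0`). The full odd
#' wavelet is assembled as `phi(x) = phi+(x) + phi-(x)` with
#' `phi-(x) = -phi+(-x)`; see [phi_wavelet()]. The printed form of this
#' basis is typographically ambiguous in its source; the branch
#' expressions implemented here are one consistent reading (logs are
#' guarded by absolute values), and the Gaussian-derivative kernel is
#' the default family for actual backbone extraction.
#'
#' @param x Numeric vector.
#' @return `phi+(x)`, vectorized.
#' @export
phi_plus <- function(x) {
  c0 <- sqrt(2) / (4 * pi)
  out <- numeric(length(x))
  sq <- function(v) sqrt(pmax(v, 0))
  b1 <- which(x >= 0 & x < 1 / 4)
  if (length(b1)) {
    z <- x[b1]
    out[b1] <- c0 * (z * log(abs((1 - 8 * z^2 + 2 * sq(1 - 16 * z^2)) /
                                   (1 + sq(1 - z^2)))) +
                       9 * z - 8 * z^2 + 3 * sq(9 - 16 * z^2) -
                       12 * z * sq(1 - 16 * z^2) - 3 * sq(9 - 16 * z^2) +
                       8 * sq(1 - z^2))
  }
  b2 <- which(x >= 1 / 4 & x < 3 / 4)
  if (length(b2)) {
    z <- x[b2]
    out[b2] <- c0 * (z * log(abs((8 * z * (1 + sq(1 - z^2))) /
                                   (9 + 3 * sq(9 - 16 * z^2) - 12 * z))) +
                       3 * sq(9 - 16 * z^2) - 8 * sq(1 - z^2))
  }
  b3 <- which(x >= 3 / 4 & x < 1)
  if (length(b3)) {
    z <- x[b3]
    out[b3] <- c0 * (z * log((1 + sq(1 - z^2)) / z) - 4 * z * sq(1 - z^2))
  }
  out
}

#' Assembled odd wavelet from the piecewise basis
#'
#' `phi(x) = phi+(x) - phi+(-x)`.
#'
#' @param x Numeric vector.
#' @return `phi(x)`, vectorized.
#' @export
phi_wavelet <- function(x) phi_plus(x) - phi_plus(-x)

# central differences with replicate borders; dim = 1 rows (y), 2 cols (x)
central_diff <- function(m, dim) {
  h <- nrow(m); w <- ncol(m)
  if (dim == 1L) {
    up <- m[c(1, seq_len(h - 1)), , drop = FALSE]
    dn <- m[c(seq_len(h - 1) + 1, h), , drop = FALSE]
  } else {
    up <- m[, c(1, seq_len(w - 1)), drop = FALSE]
    dn <- m[, c(seq_len(w - 1) + 1, w), drop = FALSE]
  }
  (dn - up) / 2
}

#' Wavelet gradient field at one scale
#'
#' @param image Numeric matrix (preprocessed).
#' @param config A [wavelet_config()].
#' @param scale Scale `s` in pixels.
#' @return A `gradient_field` list: `wx`, `wy` (wavelet gradient
#'   components, `s` times the derivative of the smoothed image),
#'   `modulus`, `angle` (`atan2(wy, wx)`, 0 where the modulus is 0),
#'   and `scale`.
#' @export
wavelet_gradient <- function(image, config = wavelet_config(), scale) {
  assert_image(image)
  s <- scale
  if (config$kernel == "gaussian_derivative") {
    g <- gauss_taps(config$sigma0 * s)
    sm <- cpp_sep_convolve(image, g, g)
    wx <- s * central_diff(sm, 2L)
    wy <- s * central_diff(sm, 1L)
  } else {
    r <- max(1L, as.integer(ceiling(s)))
    taps <- phi_wavelet((-r:r) / s)
    norm <- sum((-r:r) * taps)
    taps <- if (norm != 0) taps * (s / norm) else taps
    g <- gauss_taps(config$sigma0 * s)
    wx <- cpp_sep_convolve(image, g, taps)
    wy <- cpp_sep_convolve(image, taps, g)
  }
  modulus <- sqrt(wx^2 + wy^2)
  angle <- atan2(wy, wx)
  angle[modulus == 0] <- 0
  structure(list(wx = wx, wy = wy, modulus = modulus, angle = angle,
                 scale = s), class = "gradient_field")
}

#' Modulus-maxima contour points
#'
#' Pixels whose gradient modulus exceeds `threshold` and is a local
#' maximum along the gradient direction (compared against the modulus
#' bilinearly interpolated one pixel to either side).
#'
#' @param field A `gradient_field` from [wavelet_gradient()].
#' @param threshold Modulus floor; `NULL` uses the config default 0.1.
#' @return Integer matrix of (row, col) contour points.
#' @export
modulus_maxima <- function(field, threshold = 0.1) {
  pts <- cpp_modulus_maxima(field$wx, field$wy, field$modulus, threshold)
  colnames(pts) <- c("row", "col")
  pts
}

#' Conditionally symmetric pairs of contour points
#'
#' For each contour point, marches along its gradient direction (into
#' the bright stroke) and accepts the first counterpart contour point
#' with approximately opposite gradient whose separation matches the
#' scale within tolerance. Points without a counterpart are unstable
#' symmetry and discarded, as are pairs whose midpoint falls outside
#' the foreground mask.
#'
#' @param contours Integer (row, col) matrix from [modulus_maxima()].
#' @param field The matching `gradient_field`.
#' @param mask Binary foreground mask.
#' @param scale Scale `s` the contours were detected at.
#' @param config A [wavelet_config()].
#' @return A data.frame with pair endpoints, midpoint, separation and
#'   scale; one row per deduplicated pair.
#' @export
pair_symmetric_points <- function(contours, field, mask, scale,
                                  config = wavelet_config()) {
  tol <- config$pair_tolerance
  if (is.null(tol)) tol <- max(1, 0.2 * scale)
  res <- cpp_pair_points(contours, field$wx, field$wy, as_int_mask(mask),
                         scale, tol, config$angle_tolerance,
                         scale + tol + 1)
  df <- data.frame(p_row = res$p_row, p_col = res$p_col, q_row = res$q_row,
                   q_col = res$q_col, separation = res$separation,
                   width = res$width)
  if (nrow(df)) {
    key <- ifelse(df$p_row < df$q_row |
                    (df$p_row == df$q_row & df$p_col <= df$q_col),
                  paste(df$p_row, df$p_col, df$q_row, df$q_col),
                  paste(df$q_row, df$q_col, df$p_row, df$p_col))
    df <- df[!duplicated(key), , drop = FALSE]
    df$mid_row <- (df$p_row + df$q_row) / 2
    df$mid_col <- (df$p_col + df$q_col) / 2
  } else {
    df$mid_row <- numeric(0); df$mid_col <- numeric(0)
  }
  df$scale <- rep(scale, nrow(df))
  rownames(df) <- NULL
  df
}

#' Assemble backbone paths from symmetric pairs
#'
#' Pair midpoints (all scales pooled; at each midpoint pixel the pair
#' whose separation best matches its scale wins) are rasterized,
#' bridged across 1-pixel gaps, thinned to a one-pixel-wide skeleton,
#' split at junctions and pruned of short spurs. Each path carries a
#' per-point local width (the separation of the nearest pair) and
#' tangent direction.
#'
#' @param pairs A data.frame of pairs as returned by
#'   [pair_symmetric_points()] (possibly row-bound over scales).
#' @param dim Image dimensions `c(rows, cols)`.
#' @param config A [wavelet_config()].
#' @param mask Optional foreground mask; when given, path ends are
#'   extended along the stroke (re-centred on the local mask chord) to
#'   recover the tube end caps, which produce no symmetric pairs.
#' @return A list of backbone paths, each a list with `points`
#'   (ordered (row, col) matrix), `width`, `tangent` (radians) and
#'   `junction` (logical; endpoint touches a junction).
#' @export
extract_backbone <- function(pairs, dim, config = wavelet_config(),
                             mask = NULL) {
  if (is.null(pairs) || nrow(pairs) == 0L) return(list())
  paths <- build_backbone_paths(pairs, dim, config, mask)
  if (!length(paths)) return(paths)
  # refinement pass: pairs much wider than the regular-region width
  # read across dendrite + attached spine and drag the centreline into
  # the protrusion. The regular width is estimated per backbone point
  # from the first pass (running median over a window wider than a
  # spine footprint) and every pair is checked against the regular
  # width of its nearest backbone point.
  allpts <- do.call(rbind, lapply(paths, `[[`, "points"))
  allw <- unlist(lapply(paths, function(p) {
    wf <- p$width
    med <- stats::median(wf, na.rm = TRUE)
    wf[is.na(wf)] <- med
    np <- length(wf)
    if (np >= 3) as.numeric(stats::runmed(wf, min(21L, np - (1 - np %% 2))))
    else wf
  }))
  wreg_global <- stats::median(allw, na.rm = TRUE)
  if (is.na(wreg_global)) return(paths)
  wcol <- if (!is.null(pairs$width)) pairs$width else pairs$separation
  keep <- vapply(seq_len(nrow(pairs)), function(k) {
    d2 <- (allpts[, 1] - pairs$mid_row[k])^2 +
      (allpts[, 2] - pairs$mid_col[k])^2
    j <- which.min(d2)
    wloc <- if (d2[j] <= 36) allw[j] else wreg_global
    wcol[k] <= wloc + max(2, 0.3 * wloc)
  }, TRUE)
  if (any(!keep) && sum(keep) > 0)
    paths <- build_backbone_paths(pairs[keep, , drop = FALSE], dim, config,
                                  mask)
  paths
}

build_backbone_paths <- function(pairs, dim, config, mask = NULL) {
  if (is.null(pairs) || nrow(pairs) == 0L) return(list())
  mr <- round(pairs$mid_row); mc <- round(pairs$mid_col)
  fit <- abs(pairs$separation - pairs$scale)
  ord <- order(mr, mc, fit)
  first <- !duplicated(paste(mr[ord], mc[ord]))
  sel <- ord[first]
  h <- dim[1]; w <- dim[2]
  mid_raster <- matrix(0L, h, w)
  mid_raster[cbind(mr[sel], mc[sel])] <- 1L
  width_map <- matrix(NA_real_, h, w)
  wsel <- if (!is.null(pairs$width)) pairs$width[sel] else pairs$separation[sel]
  width_map[cbind(mr[sel], mc[sel])] <- wsel
  # bridge gaps and close pinholes between per-scale midpoint chains
  # (a hole would survive thinning as a loop and fragment the paths)
  bridged <- cpp_binary_erode(cpp_binary_dilate(mid_raster, se_square(5L)),
                              se_square(3L), 0L)
  skel <- cpp_thin(bridged)
  paths <- trace_skeleton(skel, config$spur_length)
  # a path is a dendrite only if the whole connected skeleton it
  # belongs to is long enough (a detached spine's skeleton is short
  # even when junctions split it into several pieces)
  minp <- if (is.null(config$min_path_length)) 0 else config$min_path_length
  if (minp > 0 && length(paths)) {
    labs <- cpp_label_components(skel)
    sizes <- tabulate(labs[labs > 0])
    paths <- Filter(function(p) {
      lb <- labs[p$points[1, 1], p$points[1, 2]]
      lb > 0 && sizes[lb] >= minp
    }, paths)
  }
  # short fragments beside a resolved dendrite path are centreline
  # stubs of large protrusions (spur pruning cannot reach a stub that
  # hangs between two junctions of a head loop): drop them
  if (length(paths) > 1) {
    nlen <- vapply(paths, function(p) nrow(p$points), 0L)
    long <- which(nlen >= config$spur_length)
    if (length(long) && length(long) < length(paths)) {
      longpts <- do.call(rbind, lapply(paths[long], `[[`, "points"))
      keep <- vapply(seq_along(paths), function(i) {
        if (i %in% long) return(TRUE)
        pts <- paths[[i]]$points
        dmin <- min(vapply(seq_len(nrow(pts)), function(k)
          min((longpts[, 1] - pts[k, 1])^2 + (longpts[, 2] - pts[k, 2])^2),
          0))
        sqrt(dmin) > 30
      }, TRUE)
      paths <- paths[keep]
    }
  }
  lapply(paths, function(p) {
    pts <- truncate_sharp_ends(p$points, config$spur_length)
    if (!is.null(mask)) {
      pts <- extend_path_ends(pts, mask)
      # two passes: the second uses tangents of the already-recentred
      # chain, which removes the residual bias on diagonal stretches
      pts <- recentre_path(pts, mask)
      pts <- recentre_path(pts, mask)
    }
    wd <- apply(pts, 1, function(pt) nearest_width(width_map, pt))
    tg <- path_tangent(pts)
    list(points = pts, width = wd, tangent = tg,
         junction = p$junction)
  })
}

# Re-centre each path point on the midpoint of the local mask chord
# perpendicular to the path direction. On diagonal stretches the
# rounded pair midpoints can sit a consistent half-pixel off the
# medial line, which rounds to a one-pixel lateral bias; the chord
# midpoint removes it. Gaps opened by rounding are re-bridged so the
# result stays an 8-connected chain.
recentre_path <- function(points, mask, span = 3L, max_shift = 1) {
  n <- nrow(points)
  if (n < 2 * span + 1) return(points)
  h <- nrow(mask); w <- ncol(mask)
  chord_half <- function(pos, u, sgn, lim = 15) {
    for (t in seq(0.5, lim, by = 0.5)) {
      q <- round(pos + sgn * t * u)
      if (q[1] < 1 || q[1] > h || q[2] < 1 || q[2] > w ||
          !mask[q[1], q[2]]) return(t - 0.5)
    }
    lim
  }
  ha <- hb <- rep(NA_real_, n)
  uu <- matrix(NA_real_, n, 2)
  for (k in seq_len(n)) {
    k0 <- max(1L, k - span); k1 <- min(n, k + span)
    tg <- points[k1, ] - points[k0, ]
    nt <- sqrt(sum(tg^2))
    if (nt == 0) next
    u <- c(-tg[2], tg[1]) / nt
    uu[k, ] <- u
    ha[k] <- chord_half(points[k, ], u, 1)
    hb[k] <- chord_half(points[k, ], u, -1)
  }
  med_chord <- stats::median(ha + hb, na.rm = TRUE)
  out <- points
  for (k in seq_len(n)) {
    if (is.na(ha[k])) next
    # only correct small rasterization biases on regular-width chords:
    # an asymmetric or widened chord means a one-sided protrusion
    # (spine base) or junction, where the midpoint is not the centreline
    if (!is.na(med_chord) && ha[k] + hb[k] > 1.3 * med_chord + 1) next
    shift <- (ha[k] - hb[k]) / 2
    if (abs(shift) > max_shift) next
    q <- round(points[k, ] + uu[k, ] * shift)
    if (q[1] >= 1 && q[1] <= h && q[2] >= 1 && q[2] <= w &&
        mask[q[1], q[2]])
      out[k, ] <- q
  }
  # dedupe consecutive repeats and bridge any rounding gaps
  keep <- c(TRUE, rowSums(abs(diff(out))) > 0)
  out <- out[keep, , drop = FALSE]
  if (nrow(out) < 2) return(out)
  chain <- out[1, , drop = FALSE]
  for (k in 2:nrow(out)) {
    if (max(abs(out[k, ] - out[k - 1, ])) > 1L)
      chain <- rbind(chain, link_missing_points(out[k - 1, ], out[k, ]))
    chain <- rbind(chain, out[k, , drop = FALSE])
  }
  chain
}

# Extend a path beyond both ends along the stroke direction, stepping
# one pixel at a time and re-centring on the midpoint of the local
# mask chord perpendicular to the direction; stops when the chord
# vanishes (tube end) or the frame/mask is left. Recovers the rounded
# end caps, which yield no symmetric pairs.
extend_path_ends <- function(points, mask, max_ext = 12L) {
  n <- nrow(points)
  if (n < 5) return(points)
  h <- nrow(mask); w <- ncol(mask)
  chord_half <- function(pos, u, sgn, lim = 15) {
    for (t in seq(0.5, lim, by = 0.5)) {
      q <- round(pos + sgn * t * u)
      if (q[1] < 1 || q[1] > h || q[2] < 1 || q[2] > w ||
          !mask[q[1], q[2]]) return(t - 0.5)
    }
    lim
  }
  grow <- function(points, at_end) {
    n <- nrow(points)
    idx <- if (at_end) c(n - 4L, n) else c(5L, 1L)
    tg <- points[idx[2], ] - points[idx[1], ]
    nt <- sqrt(sum(tg^2))
    if (nt == 0) return(points)
    tg <- tg / nt
    u <- c(-tg[2], tg[1])
    cur <- as.numeric(points[idx[2], ])
    added <- matrix(0L, 0, 2)
    w0 <- NA_real_
    for (s in seq_len(max_ext)) {
      nxt <- cur + tg
      q <- round(nxt)
      if (q[1] < 1 || q[1] > h || q[2] < 1 || q[2] > w ||
          !mask[q[1], q[2]]) break
      a <- chord_half(nxt, u, 1)
      b <- chord_half(nxt, u, -1)
      if (a + b < 1) break
      if (is.na(w0)) w0 <- a + b
      # a ballooning chord means the walk entered a blob (a spine or a
      # junction), not the tapering tube end: stop
      if (a + b > 1.6 * w0 + 1) break
      # cap the re-centring shift: an asymmetric chord at a protrusion
      # must not steer the extension into the spine
      ctr <- nxt + u * max(min((a - b) / 2, 1), -1)
      qc <- round(ctr)
      if (qc[1] < 1 || qc[1] > h || qc[2] < 1 || qc[2] > w ||
          !mask[qc[1], qc[2]]) break
      if (nrow(added) == 0L || any(qc != added[nrow(added), ]))
        added <- rbind(added, qc)
      cur <- ctr
    }
    if (!nrow(added)) return(points)
    if (at_end) rbind(points, added)
    else rbind(added[rev(seq_len(nrow(added))), , drop = FALSE], points)
  }
  points <- grow(points, TRUE)
  grow(points, FALSE)
}

# A path that runs off the dendrite into a tangentially attached spine
# makes a sharp turn near its end (a smooth continuation leaves no
# junction for spur pruning to find). Truncate a path end when the
# chord direction turns by more than ~75 degrees within max_cut points
# of that end.
truncate_sharp_ends <- function(points, max_cut = 22, span = 4L,
                                max_turn = 75 * pi / 180) {
  n <- nrow(points)
  if (n < 2 * span + 3) return(points)
  turn_at <- function(j) {
    a <- points[j, ] - points[j - span, ]
    b <- points[j + span, ] - points[j, ]
    na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
    if (na == 0 || nb == 0) return(0)
    acos(pmin(pmax(sum(a * b) / (na * nb), -1), 1))
  }
  jj <- (span + 1):(n - span)
  turns <- vapply(jj, turn_at, 0)
  sharp <- jj[turns > max_turn]
  lo <- 1L; hi <- n
  head_cut <- sharp[sharp - 1 < max_cut]
  if (length(head_cut)) lo <- max(head_cut)
  tail_cut <- sharp[n - sharp < max_cut]
  if (length(tail_cut)) hi <- min(tail_cut)
  if (hi - lo + 1L < 2L) return(points)
  points[lo:hi, , drop = FALSE]
}

# nearest non-NA width within a growing window around pt
nearest_width <- function(width_map, pt, max_r = 5L) {
  h <- nrow(width_map); w <- ncol(width_map)
  for (r in 0:max_r) {
    ii <- max(1, pt[1] - r):min(h, pt[1] + r)
    jj <- max(1, pt[2] - r):min(w, pt[2] + r)
    v <- width_map[ii, jj, drop = FALSE]
    if (any(!is.na(v))) {
      iw <- which(!is.na(v), arr.ind = TRUE)
      d2 <- (ii[iw[, 1]] - pt[1])^2 + (jj[iw[, 2]] - pt[2])^2
      return(v[iw[which.min(d2), , drop = FALSE]])
    }
  }
  NA_real_
}

path_tangent <- function(points) {
  n <- nrow(points)
  if (n == 1L) return(0)
  nxt <- points[c(2:n, n), , drop = FALSE]
  prv <- points[c(1, 1:(n - 1)), , drop = FALSE]
  atan2(nxt[, 1] - prv[, 1], nxt[, 2] - prv[, 2])
}

skeleton_degree <- function(skel) {
  h <- nrow(skel); w <- ncol(skel)
  px <- which(skel == 1L, arr.ind = TRUE)
  deg <- matrix(0L, h, w)
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    ii <- px[, 1] + dy; jj <- px[, 2] + dx
    ok <- ii >= 1 & ii <= h & jj >= 1 & jj <= w
    deg[px[ok, , drop = FALSE]] <- deg[px[ok, , drop = FALSE]] +
      skel[cbind(ii[ok], jj[ok])]
  }
  deg
}

# crossing number A(p): 0->1 transitions around the 8-neighbour circle;
# 1 for line ends and interior line points, >= 3 at true branch points
# (a simple neighbour count misreads 8-connected staircase corners)
skeleton_crossings <- function(skel) {
  h <- nrow(skel); w <- ncol(skel)
  px <- which(skel == 1L, arr.ind = TRUE)
  circ_dy <- c(-1, -1, 0, 1, 1, 1, 0, -1)
  circ_dx <- c(0, 1, 1, 1, 0, -1, -1, -1)
  nb <- matrix(0L, nrow(px), 8)
  for (k in 1:8) {
    ii <- px[, 1] + circ_dy[k]; jj <- px[, 2] + circ_dx[k]
    ok <- ii >= 1 & ii <= h & jj >= 1 & jj <= w
    nb[ok, k] <- skel[cbind(ii[ok], jj[ok])]
  }
  trans <- rowSums((nb == 0L) & (nb[, c(2:8, 1)] == 1L))
  A <- matrix(0L, h, w)
  A[px] <- trans
  A
}

neighbours8 <- function(pt, h, w) {
  ii <- pt[1] + c(-1, -1, -1, 0, 0, 1, 1, 1)
  jj <- pt[2] + c(-1, 0, 1, -1, 1, -1, 0, 1)
  ok <- ii >= 1 & ii <= h & jj >= 1 & jj <= w
  cbind(ii[ok], jj[ok])
}

# Iteratively delete dead-end branches shorter than spur_length: walk
# from each endpoint; if a junction (>= 3 neighbours) is reached within
# spur_length steps the walked chain is a spur and is removed.
prune_spurs <- function(skel, spur_length) {
  h <- nrow(skel); w <- ncol(skel)
  repeat {
    deg <- skeleton_degree(skel)
    ends <- which(skel == 1L & deg == 1L, arr.ind = TRUE)
    if (nrow(ends) == 0L) return(skel)
    removed <- FALSE
    A <- skeleton_crossings(skel)
    for (e in seq_len(nrow(ends))) {
      cur <- ends[e, ]
      if (!skel[cur[1], cur[2]]) next
      chain <- matrix(cur, 1)
      seen <- paste(cur[1], cur[2])
      hit_junction <- FALSE
      while (nrow(chain) < spur_length) {
        nb <- neighbours8(cur, h, w)
        nb <- nb[skel[nb] == 1L, , drop = FALSE]
        nb <- nb[!(paste(nb[, 1], nb[, 2]) %in% seen), , drop = FALSE]
        if (nrow(nb) == 0L) break              # isolated short chain
        if (any(A[nb] >= 3L)) {                # reached a branch point
          hit_junction <- TRUE
          break
        }
        if (nrow(nb) > 2L) break               # genuinely ambiguous: keep
        if (nrow(nb) == 2L && max(abs(nb[1, ] - nb[2, ])) > 1L)
          break                                # diverging directions: keep
        cur <- nb[1, ]                         # staircase pair: walk on
        chain <- rbind(chain, cur)
        seen <- c(seen, paste(cur[1], cur[2]))
      }
      if (hit_junction) {
        skel[chain] <- 0L
        removed <- TRUE
      }
    }
    if (!removed) return(skel)
  }
}

# Decompose a 1-px skeleton into ordered simple paths: dead-end spurs
# shorter than spur_length are pruned, junction pixels (>= 3 skeleton
# neighbours) split the skeleton, and each remaining segment is ordered
# by walking from one of its endpoints.
trace_skeleton <- function(skel, spur_length = 5) {
  if (!any(skel == 1L)) return(list())
  skel <- prune_spurs(skel, spur_length)
  junction <- skel == 1L & skeleton_crossings(skel) >= 3L
  seg_mask <- skel
  seg_mask[junction] <- 0L
  labs <- cpp_label_components(seg_mask)
  nlab <- max(labs)
  paths <- list()
  for (lb in seq_len(nlab)) {
    pts <- which(labs == lb, arr.ind = TRUE)
    dimnames(pts) <- NULL
    if (nrow(pts) < 2 && nlab > 1) next
    paths[[length(paths) + 1L]] <-
      list(points = order_segment(pts),
           junction = segment_touches_junction(pts, junction))
  }
  paths
}

segment_touches_junction <- function(pts, junction) {
  h <- nrow(junction); w <- ncol(junction)
  for (k in seq_len(nrow(pts))) {
    ii <- max(1, pts[k, 1] - 1):min(h, pts[k, 1] + 1)
    jj <- max(1, pts[k, 2] - 1):min(w, pts[k, 2] + 1)
    if (any(junction[ii, jj])) return(TRUE)
  }
  FALSE
}

# order the pixels of a degree-<=2 segment by walking from an endpoint
order_segment <- function(pts) {
  n <- nrow(pts)
  if (n <= 2) return(pts)
  key <- paste(pts[, 1], pts[, 2])
  idx <- seq_len(n)
  names(idx) <- key
  adj <- vector("list", n)
  for (k in idx) {
    nb <- integer(0)
    for (dy in -1:1) for (dx in -1:1) {
      if (dy == 0 && dx == 0) next
      kk <- idx[paste(pts[k, 1] + dy, pts[k, 2] + dx)]
      if (!is.na(kk)) nb <- c(nb, kk)
    }
    adj[[k]] <- nb
  }
  degs <- lengths(adj)
  start <- if (any(degs <= 1)) which(degs <= 1)[1] else 1L
  visited <- logical(n)
  ord <- integer(n)
  cur <- start
  for (k in seq_len(n)) {
    ord[k] <- cur
    visited[cur] <- TRUE
    nxt <- adj[[cur]][!visited[adj[[cur]]]]
    if (!length(nxt)) break
    cur <- nxt[1]
  }
  pts[ord[ord > 0], , drop = FALSE]
}

#' Extract the dendrite backbone from an image
#'
#' Runs the full multiscale sweep: wavelet gradient, modulus maxima and
#' symmetric pairing at every configured scale, then assembles the
#' pooled pairs into backbone paths.
#'
#' @param image Preprocessed numeric matrix.
#' @param mask Binary foreground mask (see [foreground_mask()]).
#' @param config A [wavelet_config()].
#' @return A list with `paths` (see [extract_backbone()]), `pairs` (the
#'   pooled pair table) and `fields` (gradient field per scale).
#' @export
dendrite_backbone <- function(image, mask, config = wavelet_config()) {
  fields <- list()
  pairs <- list()
  for (s in config$scales) {
    fld <- wavelet_gradient(image, config, s)
    pts <- modulus_maxima(fld, config$mm_threshold)
    pr <- pair_symmetric_points(pts, fld, mask, s, config)
    fields[[as.character(s)]] <- fld
    pairs[[as.character(s)]] <- pr
  }
  pooled <- do.call(rbind, pairs)
  paths <- extract_backbone(pooled, dim(image), config, mask)
  list(paths = paths, pairs = pooled, fields = fields)
}
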