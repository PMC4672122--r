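# Boundary localization: march from each backbone point perpendicular
# to the local line direction until the pixel intensity drops below a
# threshold alpha; pixels with I(p) >= alpha belong to the line. Gaps
# between consecutive boundary points are closed with discrete lines.

#' Configuration for boundary search
#'
#' @param alpha_mode `"fraction_of_backbone"` (default): the per-point
#'   threshold is `alpha` times the intensity at the backbone point,
#'   robust to intensity variation along the dendrite; or `"global"`:
#'   `alpha` is an absolute intensity in `[0, 1]`.
#' @param alpha Fraction or absolute intensity (> 0).
#' @param max_search Maximum marching distance in pixels; must be at
#'   least the expected dendrite half-width.
#' @return A `boundary_config` list.
#' @export
boundary_config <- function(alpha_mode = c("fraction_of_backbone", "global"),
                            alpha = 0.5, max_search = 30L) {
  alpha_mode <- match.arg(alpha_mode)
  if (alpha <= 0) stop("alpha must be positive")
  structure(list(alpha_mode = alpha_mode, alpha = alpha,
                 max_search = as.integer(max_search)),
            class = "boundary_config")
}

#' Local line (tangent) direction at a point
#'
#' The tangent is the gradient direction rotated by `pi/2`. When the
#' gradient vanishes at the point, the supplied fallback (typically the
#' backbone chord direction) is returned instead.
#'
#' @param field A `gradient_field` from [wavelet_gradient()].
#' @param point Integer `(row, col)`.
#' @param fallback Angle in radians used when the gradient is zero.
#' @return Tangent angle in radians.
#' @export
local_line_direction <- function(field, point, fallback = NA_real_) {
  m <- field$modulus[point[1], point[2]]
  if (m == 0) return(fallback)
  field$angle[point[1], point[2]] + pi / 2
}

#' Search the dendrite boundary from a backbone path
#'
#' For each backbone point, marches along both directions perpendicular
#' to the local tangent; the last pixel with intensity `>= alpha`
#' before the first pixel `< alpha` is the boundary point on that side.
#' Backbone points whose own intensity is below alpha are flagged and
#' skipped; the search aborts (no boundary point on that side) after
#' `max_search` steps.
#'
#' @param image Numeric matrix (preprocessed).
#' @param backbone A backbone path (list with `points` and `tangent`)
#'   from [extract_backbone()].
#' @param config A [boundary_config()].
#' @return A `boundary_point_set`: list with `side1`, `side2` (ordered
#'   integer (row, col) matrices), `flagged` (indices of skipped
#'   backbone points), `index1`/`index2` (backbone index of each
#'   boundary point) and `closed = FALSE`.
#' @export
search_boundary <- function(image, backbone, config = boundary_config()) {
  assert_image(image)
  pts <- backbone$points
  if (is.null(pts) || nrow(pts) == 0L) stop("backbone is empty")
  tangents <- backbone$tangent
  h <- nrow(image); w <- ncol(image)
  side1 <- side2 <- matrix(integer(0), 0, 2)
  idx1 <- idx2 <- integer(0)
  flagged <- integer(0)
  for (k in seq_len(nrow(pts))) {
    p <- pts[k, ]
    alpha <- if (config$alpha_mode == "global") config$alpha
             else config$alpha * image[p[1], p[2]]
    if (image[p[1], p[2]] < alpha) { flagged <- c(flagged, k); next }
    nrm <- c(sin(tangents[k] + pi / 2), cos(tangents[k] + pi / 2))
    for (sgn in c(1, -1)) {
      bp <- march_to_edge(image, p, sgn * nrm, alpha, config$max_search)
      if (is.null(bp)) next
      if (sgn > 0) { side1 <- rbind(side1, bp); idx1 <- c(idx1, k) }
      else { side2 <- rbind(side2, bp); idx2 <- c(idx2, k) }
    }
  }
  structure(list(side1 = side1, side2 = side2, flagged = flagged,
                 index1 = idx1, index2 = idx2, closed = FALSE),
            class = "boundary_point_set")
}

# march from p along unit direction u; return the last pixel >= alpha
# before the first pixel < alpha, or NULL when max_search is exhausted
# or the frame is left without the intensity dropping.
march_to_edge <- function(image, p, u, alpha, max_search) {
  h <- nrow(image); w <- ncol(image)
  last <- c(p[1], p[2])
  for (t in seq(0.5, max_search, by = 0.5)) {
    q <- round(p + t * u)
    if (q[1] < 1 || q[1] > h || q[2] < 1 || q[2] > w) return(NULL)
    if (all(q == last)) next
    if (image[q[1], q[2]] < alpha) return(as.integer(last))
    last <- q
  }
  NULL
}

#' Discrete line between two boundary points
#'
#' Returns the interior pixels of the 8-connected digital (Bresenham)
#' line from `p1` to `p2`, endpoints excluded. Two 8-adjacent points
#' have no missed boundary points between them, so the result is empty.
#'
#' @param p1,p2 Integer `(row, col)` points; must differ.
#' @return Integer (row, col) matrix of interior pixels (possibly
#'   0-row).
#' @export
link_missing_points <- function(p1, p2) {
  p1 <- as.integer(p1); p2 <- as.integer(p2)
  if (all(p1 == p2)) stop("p1 and p2 must be distinct points")
  if (max(abs(p2 - p1)) <= 1L) return(matrix(integer(0), 0, 2))
  # integer midpoint line along the major axis
  y0 <- p1[1]; x0 <- p1[2]; y1 <- p2[1]; x1 <- p2[2]
  steep <- abs(y1 - y0) > abs(x1 - x0)
  if (steep) { t <- y0; y0 <- x0; x0 <- t; t <- y1; y1 <- x1; x1 <- t }
  flip <- x0 > x1
  if (flip) { t <- x0; x0 <- x1; x1 <- t; t <- y0; y0 <- y1; y1 <- t }
  dx <- x1 - x0; dy <- abs(y1 - y0)
  err <- dx %/% 2L
  ys <- if (y0 < y1) 1L else -1L
  n <- dx + 1L
  yy <- integer(n); y <- y0
  for (k in seq_len(n)) {
    yy[k] <- y
    err <- err - dy
    if (err < 0L) { y <- y + ys; err <- err + dx }
  }
  pts <- if (steep) cbind(x0:x1, yy) else cbind(yy, x0:x1)
  if (flip) pts <- pts[rev(seq_len(n)), , drop = FALSE]
  out <- pts[-c(1, n), , drop = FALSE]
  dimnames(out) <- NULL
  out
}

#' Fill missed boundary points
#'
#' Applies [link_missing_points()] between every pair of consecutive
#' non-adjacent points on each side of the boundary, restoring
#' 8-connectivity. Already-connected sides are returned unchanged.
#'
#' @param boundary A `boundary_point_set` from [search_boundary()].
#' @return The boundary with gaps filled (fill pixels carry the
#'   backbone index of the preceding anchor point).
#' @export
fill_boundary <- function(boundary) {
  fill_side <- function(side, idx) {
    if (nrow(side) < 2) return(list(side = side, idx = idx))
    out <- side[1, , drop = FALSE]
    oidx <- idx[1]
    for (k in 2:nrow(side)) {
      if (all(side[k - 1, ] == side[k, ])) next  # duplicate boundary pixel
      gap <- link_missing_points(side[k - 1, ], side[k, ])
      if (nrow(gap)) {
        out <- rbind(out, gap)
        oidx <- c(oidx, rep(idx[k - 1], nrow(gap)))
      }
      out <- rbind(out, side[k, , drop = FALSE])
      oidx <- c(oidx, idx[k])
    }
    list(side = out, idx = oidx)
  }
  f1 <- fill_side(boundary$side1, boundary$index1)
  f2 <- fill_side(boundary$side2, boundary$index2)
  boundary$side1 <- f1$side; boundary$index1 <- f1$idx
  boundary$side2 <- f2$side; boundary$index2 <- f2$idx
  boundary
}

#' Locate the dendrite boundary for every backbone path
#'
#' @param image Preprocessed numeric matrix.
#' @param paths List of backbone paths ([extract_backbone()]).
#' @param config A [boundary_config()].
#' @return A list of filled `boundary_point_set`s, one per path.
#' @export
dendrite_boundary <- function(image, paths, config = boundary_config()) {
  lapply(paths, function(p) fill_boundary(search_boundary(image, p, config)))
}
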