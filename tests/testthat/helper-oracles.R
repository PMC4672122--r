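# Brute-force reference implementations ("oracles") used to validate
# the package operators on small random inputs. These deliberately use
# naive loops and the raw set/lattice definitions, independent of the
# package's code paths.

clampi <- function(v, lo, hi) pmin(pmax(v, lo), hi)

oracle_median_filter <- function(img, w) {
  h <- nrow(img); wd <- ncol(img); r <- w %/% 2
  out <- img
  for (i in 1:h) for (j in 1:wd) {
    ii <- clampi((i - r):(i + r), 1, h)
    jj <- clampi((j - r):(j + r), 1, wd)
    v <- sort(as.vector(img[ii, jj]))
    out[i, j] <- v[(length(v) + 1) / 2]
  }
  out
}

# exhaustive between-class-variance maximization; candidates are the
# distinct observed values, classes {x < t} vs {x >= t}, ties -> lowest t
oracle_otsu_threshold <- function(vals) {
  cand <- sort(unique(vals))
  if (length(cand) < 2) return(NA_real_)
  best <- -1; bestT <- NA_real_
  for (t in cand[-1]) {
    lo <- vals[vals < t]; hi <- vals[vals >= t]
    w0 <- length(lo) / length(vals); w1 <- 1 - w0
    bcv <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (bcv > best + 1e-15) { best <- bcv; bestT <- t }
  }
  bestT
}

oracle_remove_isolated <- function(mask, n, include_center = FALSE) {
  h <- nrow(mask); w <- ncol(mask)
  out <- mask * 0L
  for (i in 1:h) for (j in 1:w) {
    if (!mask[i, j]) next
    cnt <- 0
    for (di in -1:1) for (dj in -1:1) {
      if (!include_center && di == 0 && dj == 0) next
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && ii <= h && jj >= 1 && jj <= w) cnt <- cnt + mask[ii, jj]
    }
    if (cnt > n) out[i, j] <- 1L
  }
  out
}

# A (+) B = {x | reflected B translated to x intersects A}
oracle_binary_dilate <- function(mask, off) {
  h <- nrow(mask); w <- ncol(mask)
  out <- mask * 0L
  for (i in 1:h) for (j in 1:w) {
    for (k in seq_len(nrow(off))) {
      ii <- i - off[k, 1]; jj <- j - off[k, 2]
      if (ii >= 1 && ii <= h && jj >= 1 && jj <= w && mask[ii, jj]) {
        out[i, j] <- 1L; break
      }
    }
  }
  out
}

oracle_binary_erode <- function(mask, off, outside = 0L) {
  h <- nrow(mask); w <- ncol(mask)
  out <- mask * 0L
  for (i in 1:h) for (j in 1:w) {
    fit <- 1L
    for (k in seq_len(nrow(off))) {
      ii <- i + off[k, 1]; jj <- j + off[k, 2]
      v <- if (ii >= 1 && ii <= h && jj >= 1 && jj <= w) mask[ii, jj] else outside
      if (!v) { fit <- 0L; break }
    }
    out[i, j] <- fit
  }
  out
}

oracle_gray_erode <- function(f, off, val) {
  h <- nrow(f); w <- ncol(f)
  out <- f * 0
  for (i in 1:h) for (j in 1:w) {
    m <- Inf
    for (k in seq_len(nrow(off))) {
      ii <- clampi(i + off[k, 1], 1, h); jj <- clampi(j + off[k, 2], 1, w)
      m <- min(m, f[ii, jj] - val[k])
    }
    out[i, j] <- m
  }
  out
}

oracle_gray_dilate <- function(f, off, val) {
  h <- nrow(f); w <- ncol(f)
  out <- f * 0
  for (i in 1:h) for (j in 1:w) {
    m <- -Inf
    for (k in seq_len(nrow(off))) {
      ii <- clampi(i - off[k, 1], 1, h); jj <- clampi(j - off[k, 2], 1, w)
      m <- max(m, f[ii, jj] + val[k])
    }
    out[i, j] <- m
  }
  out
}

oracle_hit_miss_node <- function(patch, off, hit, miss) {
  h <- nrow(patch); w <- ncol(patch)
  ci <- (h + 1) %/% 2; cj <- (w + 1) %/% 2
  vh <- vm <- numeric(nrow(off))
  for (k in seq_len(nrow(off))) {
    v <- patch[clampi(ci + off[k, 1], 1, h), clampi(cj + off[k, 2], 1, w)]
    vh[k] <- v - hit[k]
    vm[k] <- v - miss[k]
  }
  min(vh) - max(vm)
}

# integer midpoint (Bresenham) digital line, endpoints included;
# written in the classic octant form, independent of the package's
# error-accumulating variant
oracle_digital_line <- function(p1, p2) {
  y0 <- p1[1]; x0 <- p1[2]; y1 <- p2[1]; x1 <- p2[2]
  steep <- abs(y1 - y0) > abs(x1 - x0)
  if (steep) { tmp <- y0; y0 <- x0; x0 <- tmp; tmp <- y1; y1 <- x1; x1 <- tmp }
  flip <- x0 > x1
  if (flip) { tmp <- x0; x0 <- x1; x1 <- tmp; tmp <- y0; y0 <- y1; y1 <- tmp }
  dx <- x1 - x0; dy <- abs(y1 - y0)
  err <- dx %/% 2
  ys <- if (y0 < y1) 1L else -1L
  y <- y0
  pts <- matrix(0L, 0, 2)
  for (x in x0:x1) {
    pts <- rbind(pts, if (steep) c(x, y) else c(y, x))
    err <- err - dy
    if (err < 0) { y <- y + ys; err <- err + dx }
  }
  if (flip) pts <- pts[rev(seq_len(nrow(pts))), , drop = FALSE]
  pts
}

# explicit Perona-Malik scheme, direct R iteration
oracle_pm_diffuse <- function(img, iters, kappa, dt) {
  h <- nrow(img); w <- ncol(img)
  cur <- img
  for (t in seq_len(iters)) {
    pad <- cur[clampi(0:(h + 1), 1, h), clampi(0:(w + 1), 1, w)]
    ctr <- pad[2:(h + 1), 2:(w + 1)]
    dN <- pad[1:h, 2:(w + 1)] - ctr
    dS <- pad[3:(h + 2), 2:(w + 1)] - ctr
    dW <- pad[2:(h + 1), 1:w] - ctr
    dE <- pad[2:(h + 1), 3:(w + 2)] - ctr
    g <- function(d) exp(-(d / kappa)^2)
    cur <- ctr + dt * (dN * g(dN) + dS * g(dS) + dW * g(dW) + dE * g(dE))
  }
  cur
}

# full 2D convolution (correlation orientation) with replicate padding
oracle_convolve2 <- function(img, kern) {
  h <- nrow(img); w <- ncol(img)
  ry <- nrow(kern) %/% 2; rx <- ncol(kern) %/% 2
  out <- img * 0
  for (i in 1:h) for (j in 1:w) {
    s <- 0
    for (di in -ry:ry) for (dj in -rx:rx)
      s <- s + kern[di + ry + 1, dj + rx + 1] *
        img[clampi(i + di, 1, h), clampi(j + dj, 1, w)]
    out[i, j] <- s
  }
  out
}

# ---- shared fixtures ----------------------------------------------------

# vertical bright strip: columns [c0, c0+w-1] at `fore`, rest `back`
strip_image <- function(h, w, c0, width, fore = 0.8, back = 0.1) {
  img <- matrix(back, h, w)
  img[, c0:(c0 + width - 1)] <- fore
  img
}

# geometric spine-class oracle: head = deep interior (large inscribed
# distance), neck/elongation from the extent along the principal axis
oracle_spine_class <- function(img) {
  thr <- (max(img) + min(img)) / 2
  fg <- which(img > thr, arr.ind = TRUE)
  bg <- which(img <= thr, arr.ind = TRUE)
  dmax <- max(vapply(seq_len(nrow(fg)), function(k)
    sqrt(min((fg[k, 1] - bg[, 1])^2 + (fg[k, 2] - bg[, 2])^2)), 0))
  if (dmax < 2.2) return("thin")
  ctr <- colMeans(fg)
  cc <- sweep(fg, 2, ctr)
  ev <- eigen(crossprod(cc) / nrow(cc), symmetric = TRUE)$vectors
  len <- diff(range(cc %*% ev[, 1])) + 1
  if (len >= 9.5) "mushroom" else "stubby"
}

expect_rel_equal <- function(a, b, rel = 1e-4, abs_floor = 1e-8) {
  d <- abs(a - b)
  s <- pmax(abs(a), abs(b))
  testthat::expect_true(all(d <= pmax(rel * s, abs_floor)),
                        label = sprintf("max rel dev %.3g",
                                        max(d / pmax(s, abs_floor))))
}

# small separable 3-class toy problem on 6x6 patches (class labels
# reuse the spine class names so the 3-output model applies unchanged)
toy_library <- function(n_per_class, seed = 1, noise = 0.02) {
  with_seed(seed, {
    imgs <- list(); labs <- character(0)
    for (cl in 1:3) {
      for (k in seq_len(n_per_class)) {
        img <- matrix(0.1, 6, 6)
        if (cl == 1) img[2:5, 2:3] <- 0.9       # left block
        if (cl == 2) img[2:5, 4:5] <- 0.9       # right block
        if (cl == 3) img[c(2, 5), 2:5] <- 0.9   # two bars
        img <- img + matrix(rnorm(36, 0, noise), 6, 6)
        imgs[[length(imgs) + 1L]] <- img
        labs <- c(labs, c("mushroom", "stubby", "thin")[cl])
      }
    }
    list(images = imgs, labels = labs)
  })
}

toy_model <- function(seed = 2) {
  rmsnn_model(input_size = c(6, 6), n_maps = c(1, 1), se_size = 1,
              n_hidden = 4, seed = seed)
}
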