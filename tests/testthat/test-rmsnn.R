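# Morphology operators, Hit-Miss features, forward/backward passes,
# training and cross-validation of the RMSNN.

rand_mask <- function(h, w, p = 0.5) matrix(rbinom(h * w, 1, p), h, w)

test_that("binary morphology matches the set definitions exactly", {
  se3 <- se_square(3L)
  one <- matrix(0L, 7, 7); one[4, 4] <- 1L
  expect_identical(sum(binary_dilation(one, se3)), 9L)
  expect_true(all(binary_dilation(matrix(0L, 5, 5), se3) == 0L))
  # L-shaped SE on random masks
  seL <- rbind(c(0L, 0L), c(1L, 0L), c(0L, 1L))
  set.seed(71)
  for (rep in 1:10) {
    m <- rand_mask(8, 8)
    expect_identical(binary_dilation(m, seL), oracle_binary_dilate(m, seL))
    expect_identical(binary_erosion(m, seL), oracle_binary_erode(m, seL))
  }
})

test_that("binary Hit-Miss finds exact pattern positions", {
  hit <- rbind(c(0L, 0L), c(-1L, 0L), c(1L, 0L))   # vertical 3-bar
  miss <- rbind(c(0L, -1L), c(0L, 1L))             # flanked by background
  m <- matrix(0L, 7, 7); m[3:5, 4] <- 1L
  hm <- hit_miss_binary(m, hit, miss)
  expect_identical(which(hm == 1L), which(matrix(seq_len(49), 7, 7) == 25L))
  expect_true(all(hit_miss_binary(matrix(0L, 6, 6), hit, miss) == 0L))
  expect_error(hit_miss_binary(m, hit, rbind(c(0L, 0L))), "disjoint")
  # brute force on random masks: A (-) H intersect Ac (-) M
  set.seed(72)
  for (rep in 1:10) {
    m <- rand_mask(8, 8)
    ref <- oracle_binary_erode(m, hit) *
      oracle_binary_erode(1L - m, miss, outside = 1L)
    expect_identical(hit_miss_binary(m, hit, miss), ref)
  }
})

test_that("weighted gray erosion/dilation match exhaustive scans", {
  off <- se_square(3L)
  flat <- structuring_element(off, 0)
  cst <- matrix(0.42, 6, 6)
  expect_equal(gray_erosion(cst, flat), cst)
  expect_equal(gray_dilation(cst, flat), cst)
  set.seed(73)
  for (rep in 1:10) {
    f <- matrix(runif(36), 6, 6)
    se <- structuring_element(off, runif(nrow(off), -0.5, 0.5))
    expect_equal(gray_erosion(f, se), oracle_gray_erode(f, off, se$values))
    expect_equal(gray_dilation(f, se), oracle_gray_dilate(f, off, se$values))
    # shift covariance of erosion
    expect_equal(gray_erosion(f + 0.3, se), gray_erosion(f, se) + 0.3)
    # duality: -((-f) erode reflected b) = f dilate b
    refl <- structuring_element(-off, se$values)
    expect_equal(-gray_erosion(-f, refl), gray_dilation(f, se))
  }
})

test_that("hit_miss_node is exact and gray-shift invariant", {
  off <- se_disk(4)
  zero <- list(offsets = off, hit = numeric(nrow(off)),
               miss = numeric(nrow(off)))
  expect_equal(hit_miss_node(matrix(0.7, 9, 9), zero), 0)
  set.seed(74)
  for (rep in 1:20) {
    patch <- matrix(runif(81), 9, 9)
    se <- list(offsets = off, hit = runif(nrow(off), -1, 1),
               miss = runif(nrow(off), -1, 1))
    a <- hit_miss_node(patch, se)
    expect_equal(a, oracle_hit_miss_node(patch, off, se$hit, se$miss))
    cshift <- runif(1, -5, 5)
    expect_equal(hit_miss_node(patch + cshift, se), a, tolerance = 1e-12)
  }
})

test_that("forward pass: sigmoid(0) baseline, closed form, determinism", {
  m <- rmsnn_model(input_size = c(6, 6), n_maps = c(1, 1), se_size = 1,
                   n_hidden = 2, seed = 3)
  m$W1[] <- 0; m$b1[] <- 0; m$W2[] <- 0; m$b2[] <- 0
  img <- matrix(runif(36), 6, 6)
  out <- rmsnn_forward(m, img)
  expect_equal(unname(out$scores), rep(0.5, 3))
  expect_identical(rmsnn_forward(m, img), rmsnn_forward(m, img))
  expect_error(rmsnn_forward(m, matrix(0, 4, 4)), "expects")
  # scalar closed form on a 1x1 image: feature a = -(miss - hit) for the
  # single-offset SE; output o = sigmoid(w2 * sigmoid(w1 * a))
  m1 <- rmsnn_model(input_size = c(1, 1), n_maps = 1L, se_shape = "square",
                    se_size = 1L, n_hidden = 1, seed = 4)
  m1$se_offsets <- matrix(c(0L, 0L), 1, 2)
  m1$layers[[1]]$hit <- matrix(0.2, 1, 1)
  m1$layers[[1]]$miss <- matrix(-0.1, 1, 1)
  m1$W1 <- matrix(1.5, 1, 1); m1$b1 <- 0
  m1$W2 <- matrix(c(2, -1, 0.5), 3, 1); m1$b2 <- rep(0, 3)
  a <- (0.8 - 0.2) - (0.8 - (-0.1))
  hsig <- 1 / (1 + exp(-1.5 * a))
  expect_equal(unname(rmsnn_forward(m1, matrix(0.8, 1, 1))$scores),
               1 / (1 + exp(-c(2, -1, 0.5) * hsig)), tolerance = 1e-12)
})

test_that("whole-network output is invariant to gray shifts", {
  m <- rmsnn_model(seed = 11)
  set.seed(75)
  img <- matrix(runif(400), 20, 20)
  base <- rmsnn_forward(m, img)$scores
  for (cshift in c(-0.4, 0.25, 3)) {
    expect_equal(rmsnn_forward(m, img + cshift)$scores, base,
                 tolerance = 1e-10)
  }
})

test_that("analytic gradients match central finite differences", {
  set.seed(76)
  m <- rmsnn_model(input_size = c(4, 4), n_maps = c(1, 1), se_size = 1,
                   n_hidden = 2, seed = 6)
  img <- matrix(runif(16), 4, 4)   # distinct values: unique arg-extrema
  target <- c(1, 0, 0)
  lambda <- 0.01; w0 <- 1
  pen_grad <- function(w) (2 * w / w0^2) / (1 + (w / w0)^2)^2
  gr <- rmsnn_gradients(m, img, target)
  analytic <- c(
    unlist(lapply(gr$layers, function(l) c(l$hit, l$miss))),
    as.vector(gr$W1) + lambda * pen_grad(as.vector(m$W1)), gr$b1,
    as.vector(gr$W2) + lambda * pen_grad(as.vector(m$W2)), gr$b2)
  p0 <- rmsnn_get_params(m)
  cost <- function(p) {
    mm <- rmsnn_set_params(m, p)
    sc <- rmsnn_forward(mm, img)$scores
    regularized_cost(0.5 * sum((target - sc)^2), mm, lambda, w0)
  }
  eps <- 1e-6
  fd <- vapply(seq_along(p0), function(k) {
    up <- p0; up[k] <- up[k] + eps
    dn <- p0; dn[k] <- dn[k] - eps
    (cost(up) - cost(dn)) / (2 * eps)
  }, 0)
  expect_rel_equal(analytic, fd, rel = 1e-4, abs_floor = 1e-7)
})

test_that("regularized cost has the stated fixed points and limits", {
  m <- rmsnn_model(input_size = c(4, 4), n_maps = 1L, se_size = 1,
                   n_hidden = 1, seed = 7)
  m$W1[] <- 0; m$W2[] <- 0
  expect_equal(complexity_penalty(m, w0 = 1), 0)
  expect_equal(regularized_cost(0.3, m, lambda = 2), 0.3)
  m$W1[1] <- 1  # single weight at w0 -> penalty 1/(1+1)
  expect_equal(complexity_penalty(m, w0 = 1), 0.5)
  pen <- function(w) (w / 1)^2 / (1 + (w / 1)^2)
  ws <- c(0.1, 0.5, 1, 3, 10, 100)
  expect_true(all(diff(pen(ws)) > 0))     # monotone in |w|
  expect_lt(1 - pen(1e4), 1e-7)           # saturates at 1
})

test_that("a zero-error sample leaves the model unchanged", {
  m <- rmsnn_model(input_size = c(4, 4), n_maps = 1L, se_size = 1,
                   n_hidden = 2, seed = 8)
  img <- matrix(runif(16), 4, 4)
  sc <- rmsnn_forward(m, img)$scores
  gr <- rmsnn_gradients(m, img, as.numeric(sc))
  expect_equal(gr$E, 0)
  expect_true(all(abs(gr$W1) == 0) && all(abs(gr$W2) == 0))
  expect_true(all(vapply(gr$layers, function(l)
    all(l$hit == 0) && all(l$miss == 0), TRUE)))
})

test_that("training solves a separable toy problem and is deterministic", {
  toy <- toy_library(10, seed = 9)
  cfg <- training_config(eta = 0.1, max_epochs = 500, mse_target = 5e-3,
                         lambda = 0, seed = 3, patience = 0)
  fit <- rmsnn_train(toy_model(), toy$images, toy$labels, cfg)
  expect_lt(tail(fit$mean_error, 1), 5e-3)
  expect_equal(mean(rmsnn_predict(fit$model, toy$images) == toy$labels), 1)
  # error curve decreases overall
  expect_lt(tail(fit$mean_error, 1), fit$mean_error[1] / 10)
  fit2 <- rmsnn_train(toy_model(), toy$images, toy$labels, cfg)
  expect_identical(fit$model[names(fit$model) != "arch"],
                   fit2$model[names(fit2$model) != "arch"])
})

test_that("weight elimination drives more classifier weights to zero", {
  toy <- toy_library(10, seed = 10)
  base <- training_config(eta = 0.05, max_epochs = 300, mse_target = 0,
                          lambda = 0, seed = 4, patience = 0)
  reg <- base; reg$lambda <- 0.01
  fit0 <- rmsnn_train(toy_model(5), toy$images, toy$labels, base)
  fit1 <- rmsnn_train(toy_model(5), toy$images, toy$labels, reg)
  near_zero <- function(model, tol = 0.01)
    sum(abs(model$W1) < tol) + sum(abs(model$W2) < tol)
  expect_gt(near_zero(fit1$model), near_zero(fit0$model))
})

test_that("stratified CV bookkeeping conserves counts; oracle is perfect", {
  lib <- make_spine_library(12, seed = 30, noise = FALSE,
                            presentation = "isolated")
  oracle <- function(train_images, train_labels) {
    function(images) vapply(images, oracle_spine_class, "")
  }
  cv <- rmsnn_cross_validate(lib$images, lib$labels, rmsnn_model(seed = 1),
                             folds = 4, seed = 5, classifier = oracle)
  expect_equal(unname(rowSums(cv$confusion)), rep(12, 3))
  expect_equal(unname(cv$confusion), diag(c(12, 12, 12)))
  expect_equal(unname(cv$per_class_accuracy), rep(100, 3))
  expect_error(rmsnn_cross_validate(lib$images[1:9], lib$labels[1:9],
                                    rmsnn_model(seed = 1), folds = 4),
               "at least")
})

test_that("models survive a JSON round trip", {
  m <- rmsnn_model(seed = 12)
  path <- tempfile(fileext = ".json")
  save_rmsnn(m, path)
  m2 <- load_rmsnn(path)
  img <- matrix(runif(400), 20, 20)
  expect_equal(rmsnn_forward(m2, img)$scores, rmsnn_forward(m, img)$scores)
})
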