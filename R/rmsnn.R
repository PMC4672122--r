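# Regularized morphological shared-weight neural network (RMSNN):
# gray-scale Hit-Miss feature extraction layers with learned
# structuring elements shared across window positions, a fully
# connected sigmoid classifier, per-sample gradient descent with
# weight-elimination regularization.

#' Structuring-element domains
#'
#' `se_disk(r)` is the set of integer offsets with `dy^2 + dx^2 <= r^2`;
#' `se_square(w)` the full `w x w` block centred at the origin. Offsets
#' are in raster order (row, then column), which also fixes the
#' deterministic tie-break of min/max subgradients during training.
#'
#' @param r Disk radius in pixels.
#' @return Integer matrix of (dy, dx) offsets.
#' @export
se_disk <- function(r) {
  g <- as.integer(-r):as.integer(r)
  off <- as.matrix(expand.grid(dx = g, dy = g))[, c(2, 1), drop = FALSE]
  off <- off[off[, 1]^2 + off[, 2]^2 <= r^2, , drop = FALSE]
  off <- off[order(off[, 1], off[, 2]), , drop = FALSE]
  storage.mode(off) <- "integer"
  colnames(off) <- c("dy", "dx")
  off
}

#' @rdname se_disk
#' @param w Square side in pixels.
#' @export
se_square <- function(w) {
  r0 <- -(w %/% 2); r1 <- w - 1 + r0
  off <- as.matrix(expand.grid(dx = r0:r1, dy = r0:r1))[, c(2, 1), drop = FALSE]
  off <- off[order(off[, 1], off[, 2]), , drop = FALSE]
  storage.mode(off) <- "integer"
  colnames(off) <- c("dy", "dx")
  off
}

#' Binary morphology
#'
#' Set-definition binary dilation, erosion and Hit-Miss transform.
#' Dilation: positions where the reflected SE intersects the
#' foreground. Erosion: positions where the SE fits inside the
#' foreground (pixels beyond the frame count as background). The
#' Hit-Miss transform is the intersection of the foreground eroded by
#' the hit SE and the background (complement, extending beyond the
#' frame) eroded by the miss SE; the hit and miss SEs must be disjoint.
#'
#' @param mask Binary 0/1 matrix.
#' @param se Integer (dy, dx) offset matrix ([se_disk()], [se_square()],
#'   or hand-built).
#' @return Integer 0/1 matrix.
#' @export
binary_dilation <- function(mask, se) {
  assert_mask(mask)
  cpp_binary_dilate(as_int_mask(mask), se)
}

#' @rdname binary_dilation
#' @export
binary_erosion <- function(mask, se) {
  assert_mask(mask)
  cpp_binary_erode(as_int_mask(mask), se, 0L)
}

#' @rdname binary_dilation
#' @param hit,miss Disjoint offset matrices for the Hit and Miss SEs.
#' @export
hit_miss_binary <- function(mask, hit, miss) {
  assert_mask(mask)
  if (nrow(merge(as.data.frame(hit), as.data.frame(miss))) > 0)
    stop("hit and miss SEs must be disjoint in the binary Hit-Miss transform")
  m <- as_int_mask(mask)
  comp <- 1L - m
  e1 <- cpp_binary_erode(m, hit, 0L)
  e2 <- cpp_binary_erode(comp, miss, 1L)  # background extends off-frame
  e1 * e2
}

#' Gray-scale morphology with weighted structuring elements
#'
#' Erosion `(f (-) b)(s,t) = min_x f(s+x) - b(x)` measures the minimum
#' gap between the image and the translated SE; dilation
#' `(f (+) b)(s,t) = max_x f(s-x) + b(x)` is its dual and measures how
#' well the SE fits above the image. Borders are replicate-padded.
#'
#' @param f Numeric matrix.
#' @param se A weighted SE: list with `offsets` (integer (dy, dx)
#'   matrix) and `values` (numeric, one per offset); see
#'   [structuring_element()].
#' @return Numeric matrix.
#' @export
gray_erosion <- function(f, se) {
  assert_image(f, "f")
  cpp_gray_erode(f, se$offsets, se$values)
}

#' @rdname gray_erosion
#' @export
gray_dilation <- function(f, se) {
  assert_image(f, "f")
  cpp_gray_dilate(f, se$offsets, se$values)
}

#' Build a weighted structuring element
#'
#' @param offsets Integer (dy, dx) offset matrix.
#' @param values Numeric SE values, one per offset (default flat 0).
#' @return A list with `offsets` and `values`.
#' @export
structuring_element <- function(offsets, values = 0) {
  storage.mode(offsets) <- "integer"
  list(offsets = offsets, values = rep_len(values, nrow(offsets)))
}

#' Gray-scale Hit-Miss feature of a patch
#'
#' Computes, at the centre of the patch,
#' `a_y = min_x (a(x) - t_hit(x)) - max_x (a(x) - t_miss(x))`
#' where both extrema run over the SE domain translated to the patch
#' centre (replicate padding). The result is invariant to adding a
#' constant to the patch.
#'
#' @param patch Numeric matrix covering the SE domain.
#' @param se_pair List with `offsets` (shared domain), `hit` and `miss`
#'   value vectors (the miss SE is taken as applied, i.e. reflected).
#' @return Scalar feature value.
#' @export
hit_miss_node <- function(patch, se_pair) {
  assert_image(patch, "patch")
  res <- cpp_hit_miss_map(patch, se_pair$offsets, se_pair$hit, se_pair$miss)
  ci <- (nrow(patch) + 1L) %/% 2L
  cj <- (ncol(patch) + 1L) %/% 2L
  res$map[ci, cj]
}

#' Construct an untrained RMSNN model
#'
#' The feature-extraction phase is a stack of Hit-Miss layers; each
#' feature map owns one Hit/Miss SE pair shared across all window
#' positions, takes one map of the previous layer (the subimage for the
#' first layer) as input, and keeps the input size via replicate
#' padding at stride 1. The classification phase is a fully connected
#' sigmoid network reading the flattened last feature layer, with one
#' output node per class.
#'
#' Classifier weights and biases are initialized uniformly in
#' `[-init_range, init_range]`; SE values uniformly in
#' `[-se_init_range, se_init_range]` (small, to break the symmetry
#' between maps while starting each Hit-Miss node near the
#' local-contrast operator that flat SEs compute).
#'
#' @param input_size `c(rows, cols)` of the subimage window.
#' @param n_maps Integer vector: feature maps per layer.
#' @param se_shape `"disk"` or `"square"`.
#' @param se_size Disk radius or square side in pixels.
#' @param n_hidden Hidden sigmoid units in the classifier.
#' @param classes Class labels (one output node each).
#' @param init_range Half-width of the uniform classifier init.
#' @param se_init_range Half-width of the uniform SE init.
#' @param seed Integer seed for the initialization.
#' @return An `rmsnn_model` list.
#' @export
rmsnn_model <- function(input_size = c(20L, 20L), n_maps = c(2L, 2L),
                        se_shape = c("disk", "square"), se_size = 4L,
                        n_hidden = 10L,
                        classes = c("mushroom", "stubby", "thin"),
                        init_range = 1, se_init_range = 0.1, seed = 1L) {
  se_shape <- match.arg(se_shape)
  off <- if (se_shape == "disk") se_disk(se_size) else se_square(se_size)
  K <- nrow(off)
  n_classes <- length(classes)
  nf <- n_maps[length(n_maps)] * prod(input_size)
  with_seed(seed, {
    layers <- lapply(seq_along(n_maps), function(l) {
      nm <- n_maps[l]
      prev <- if (l == 1L) 1L else n_maps[l - 1L]
      list(parent = as.integer(1L + (seq_len(nm) - 1L) %% prev),
           hit = matrix(runif(K * nm, -se_init_range, se_init_range), K, nm),
           miss = matrix(runif(K * nm, -se_init_range, se_init_range), K, nm))
    })
    model <- list(input_size = as.integer(input_size),
                  se_offsets = off, layers = layers,
                  W1 = matrix(runif(n_hidden * nf, -init_range, init_range),
                              n_hidden, nf),
                  b1 = runif(n_hidden, -init_range, init_range),
                  W2 = matrix(runif(n_classes * n_hidden, -init_range,
                                    init_range), n_classes, n_hidden),
                  b2 = runif(n_classes, -init_range, init_range),
                  classes = classes,
                  arch = list(n_maps = as.integer(n_maps),
                              se_shape = se_shape, se_size = se_size,
                              n_hidden = as.integer(n_hidden),
                              init_range = init_range,
                              se_init_range = se_init_range, seed = seed))
    class(model) <- "rmsnn_model"
    model
  })
}

#' Re-initialize an RMSNN model with a new seed
#'
#' Re-draws all weights and SE values with the architecture of an
#' existing model; used by cross-validation to start each fold fresh.
#'
#' @param model An `rmsnn_model`.
#' @param seed New initialization seed.
#' @return A fresh `rmsnn_model`.
#' @export
rmsnn_reinit <- function(model, seed) {
  a <- model$arch
  rmsnn_model(input_size = model$input_size, n_maps = a$n_maps,
              se_shape = a$se_shape, se_size = a$se_size,
              n_hidden = a$n_hidden, classes = model$classes,
              init_range = a$init_range, se_init_range = a$se_init_range,
              seed = seed)
}

#' Training configuration
#'
#' @param eta Learning rate of the per-sample gradient descent.
#' @param max_epochs Maximum training epochs.
#' @param mse_target Error level at which training stops (per-sample
#'   squared error `E = 1/2 sum (t - O)^2`, aggregated per epoch by
#'   `stop_metric`).
#' @param lambda Weight-elimination regularization factor (>= 0).
#' @param w0 Weight scale of the elimination penalty (> 0).
#' @param seed Seed for the per-epoch presentation order.
#' @param shuffle Reshuffle the presentation order every epoch.
#' @param regularize_ses Also penalize SE values (default: classifier
#'   connection weights only).
#' @param patience Epoch window for plateau detection (0 disables): stop
#'   when the stop metric improved by less than `patience_tol`
#'   (relative) over the last `patience` epochs.
#' @param patience_tol Relative improvement threshold for the plateau
#'   stop.
#' @param stop_metric `"mean"` or `"median"` per-sample error.
#' @return A `training_config` list.
#' @export
training_config <- function(eta = 0.0015, max_epochs = 15000L,
                            mse_target = 1e-3, lambda = 1e-4, w0 = 1,
                            seed = 1L, shuffle = TRUE,
                            regularize_ses = FALSE, patience = 50L,
                            patience_tol = 1e-3,
                            stop_metric = c("mean", "median")) {
  if (eta <= 0) stop("eta must be > 0")
  if (lambda < 0) stop("lambda must be >= 0")
  if (w0 <= 0) stop("w0 must be > 0")
  structure(list(eta = eta, max_epochs = as.integer(max_epochs),
                 mse_target = mse_target, lambda = lambda, w0 = w0,
                 seed = as.integer(seed), shuffle = shuffle,
                 regularize_ses = regularize_ses,
                 patience = as.integer(patience),
                 patience_tol = patience_tol,
                 stop_metric = match.arg(stop_metric)),
            class = "training_config")
}

#' Forward pass of the RMSNN
#'
#' @param model An `rmsnn_model`.
#' @param subimage Numeric matrix matching the model input size.
#' @param keep Also return feature maps and the flattened feature
#'   vector.
#' @return List with `scores` (named, in `(0, 1)`, one per class) and
#'   `hidden`; with `keep`, also `feature_maps` and `features`.
#' @export
rmsnn_forward <- function(model, subimage, keep = FALSE) {
  out <- cpp_msnn_forward(subimage, model, keep)
  names(out$scores) <- model$classes
  out
}

#' Analytic gradients of the per-sample error
#'
#' Returns the gradients of `E = 1/2 sum (t - O)^2` with respect to
#' every model parameter, with min/max subgradients routed to the first
#' raster-order arg-extremum of each Hit-Miss window. Exposed mainly
#' for gradient verification.
#'
#' @param model An `rmsnn_model`.
#' @param subimage Input subimage.
#' @param target One-hot numeric vector (one per class).
#' @return List of gradients (`layers`, `W1`, `b1`, `W2`, `b2`) plus
#'   the sample error `E` and the forward `scores`.
#' @export
rmsnn_gradients <- function(model, subimage, target) {
  cpp_msnn_grad(subimage, target, model)
}

#' Weight-elimination penalty and regularized cost
#'
#' The complexity penalty of a weight `w` is
#' `(w/w0)^2 / (1 + (w/w0)^2)`: near zero for small weights (which are
#' driven to zero) and saturating at 1 for large ones. The regularized
#' cost is `R = E_s + lambda * E_c` with `E_c` summed over the
#' classifier connection weights (and the SE values when
#' `include_ses`).
#'
#' @param model An `rmsnn_model`.
#' @param w0 Weight scale (> 0).
#' @param include_ses Include SE values in the sum.
#' @return `complexity_penalty`: the scalar `E_c`.
#' @export
complexity_penalty <- function(model, w0 = 1, include_ses = FALSE) {
  pen <- function(w) sum((w / w0)^2 / (1 + (w / w0)^2))
  ec <- pen(model$W1) + pen(model$W2)
  if (include_ses)
    for (lay in model$layers) ec <- ec + pen(lay$hit) + pen(lay$miss)
  ec
}

#' @rdname complexity_penalty
#' @param sample_error The performance term `E_s`.
#' @param lambda Regularization factor.
#' @return `regularized_cost`: the scalar `R = E_s + lambda * E_c`.
#' @export
regularized_cost <- function(sample_error, model, lambda, w0 = 1,
                             include_ses = FALSE) {
  sample_error + lambda * complexity_penalty(model, w0, include_ses)
}

#' Train an RMSNN by per-sample gradient descent
#'
#' Samples are presented sequentially (reshuffled every epoch from
#' `config$seed`); after each sample the classifier weights and the
#' shared SEs (updates accumulated over all window positions) are
#' updated. Training stops when the per-epoch error statistic reaches
#' `mse_target`, plateaus, or `max_epochs` is hit; divergence aborts
#' with an error.
#'
#' @param model An `rmsnn_model`.
#' @param images List of subimage matrices.
#' @param labels Factor or character vector over `model$classes`.
#' @param config A [training_config()].
#' @return List with the trained `model`, `mean_error` and
#'   `median_error` curves (one value per epoch), `epochs` and the stop
#'   reason `stopped`.
#' @export
rmsnn_train <- function(model, images, labels, config = training_config()) {
  if (!length(images)) stop("empty training library")
  lab <- as.integer(factor(as.character(labels), levels = model$classes))
  if (any(is.na(lab))) stop("labels outside model$classes")
  res <- cpp_msnn_train(images, lab, model, unclass(config))
  class(res$model) <- "rmsnn_model"
  res$model$classes <- model$classes
  res$model$arch <- model$arch
  res
}

#' Classify subimages with a trained RMSNN
#'
#' @param model A trained `rmsnn_model`.
#' @param images List of subimage matrices (or a single matrix).
#' @param type `"class"` for hard labels, `"score"` for the raw output
#'   matrix.
#' @return Factor of predicted classes, or an `n x n_classes` score
#'   matrix.
#' @export
rmsnn_predict <- function(model, images, type = c("class", "score")) {
  type <- match.arg(type)
  if (is.matrix(images)) images <- list(images)
  sc <- cpp_msnn_predict(images, model)
  colnames(sc) <- model$classes
  if (type == "score") return(sc)
  factor(model$classes[max.col(sc, ties.method = "first")],
         levels = model$classes)
}

#' Stratified k-fold cross-validation of the RMSNN
#'
#' Folds are stratified to preserve class ratios; each fold trains a
#' freshly initialized model and is scored on the held-out samples.
#' The confusion matrix follows the convention rows = actual class,
#' columns = predicted class.
#'
#' @param images List of subimage matrices.
#' @param labels Factor/character labels.
#' @param model Template `rmsnn_model` (architecture; weights are
#'   re-drawn per fold).
#' @param config A [training_config()].
#' @param folds Number of folds; every class needs at least `folds`
#'   samples.
#' @param repeats Number of independent repetitions of the whole CV.
#' @param seed Seed for fold assignment and per-fold initialization.
#' @param classifier Optional override: a function
#'   `function(train_images, train_labels)` returning a prediction
#'   function `function(images) -> factor`; used in place of the RMSNN
#'   (e.g. to validate the CV bookkeeping with a known classifier).
#' @param verbose Print per-fold progress.
#' @return List with `confusion` (mean counts over repeats),
#'   `confusion_percent` (rows normalized to 100), `per_class_accuracy`
#'   (named, %), `accuracy` (overall, %), and `folds` (per-fold
#'   summaries).
#' @export
rmsnn_cross_validate <- function(images, labels, model = rmsnn_model(),
                                 config = training_config(), folds = 10L,
                                 repeats = 1L, seed = 1L,
                                 classifier = NULL, verbose = FALSE) {
  labels <- factor(as.character(labels), levels = model$classes)
  n <- length(images)
  if (any(table(labels) < folds))
    stop("every class needs at least `folds` samples")
  conf_sum <- matrix(0, length(model$classes), length(model$classes),
                     dimnames = list(actual = model$classes,
                                     predicted = model$classes))
  fold_log <- list()
  for (r in seq_len(repeats)) {
    fold_id <- with_seed(seed + 7919L * r, {
      id <- integer(n)
      for (cl in model$classes) {
        idx <- which(labels == cl)
        id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
      }
      id
    })
    for (f in seq_len(folds)) {
      tr <- which(fold_id != f); te <- which(fold_id == f)
      if (is.null(classifier)) {
        fold_seed <- seed + 1000L * r + f
        m0 <- rmsnn_reinit(model, fold_seed)
        cfg <- config; cfg$seed <- fold_seed
        fit <- rmsnn_train(m0, images[tr], labels[tr], cfg)
        pred <- rmsnn_predict(fit$model, images[te])
        info <- list(repeat_ = r, fold = f, epochs = fit$epochs,
                     stopped = fit$stopped,
                     final_error = tail(fit$mean_error, 1))
      } else {
        pf <- classifier(images[tr], labels[tr])
        pred <- factor(as.character(pf(images[te])), levels = model$classes)
        info <- list(repeat_ = r, fold = f)
      }
      tab <- table(actual = labels[te], predicted = pred)
      conf_sum <- conf_sum + as.matrix(tab)
      info$fold_accuracy <- 100 * mean(pred == labels[te])
      fold_log[[length(fold_log) + 1L]] <- info
      if (verbose)
        message(sprintf("repeat %d fold %d: accuracy %.1f%%", r, f,
                        info$fold_accuracy))
    }
  }
  conf <- conf_sum / repeats
  pct <- 100 * conf / rowSums(conf)
  list(confusion = conf, confusion_percent = pct,
       per_class_accuracy = diag(pct),
       accuracy = 100 * sum(diag(conf)) / sum(conf), folds = fold_log)
}

# ---- parameter (de)serialization ---------------------------------------

#' Flatten / restore RMSNN parameters
#'
#' Parameter order: per layer hit then miss SE values (column-major
#' over maps), then `W1`, `b1`, `W2`, `b2`. Used for gradient checking
#' and model IO.
#'
#' @param model An `rmsnn_model`.
#' @return `rmsnn_get_params`: numeric vector of all parameters.
#' @export
rmsnn_get_params <- function(model) {
  v <- numeric(0)
  for (lay in model$layers) v <- c(v, as.vector(lay$hit), as.vector(lay$miss))
  c(v, as.vector(model$W1), model$b1, as.vector(model$W2), model$b2)
}

#' @rdname rmsnn_get_params
#' @param params Numeric vector as produced by `rmsnn_get_params`.
#' @return `rmsnn_set_params`: the model with parameters replaced.
#' @export
rmsnn_set_params <- function(model, params) {
  pos <- 0L
  take <- function(k) {
    out <- params[pos + seq_len(k)]
    pos <<- pos + k
    out
  }
  for (l in seq_along(model$layers)) {
    K <- nrow(model$layers[[l]]$hit); nm <- ncol(model$layers[[l]]$hit)
    model$layers[[l]]$hit <- matrix(take(K * nm), K, nm)
    model$layers[[l]]$miss <- matrix(take(K * nm), K, nm)
  }
  model$W1 <- matrix(take(length(model$W1)), nrow(model$W1), ncol(model$W1))
  model$b1 <- take(length(model$b1))
  model$W2 <- matrix(take(length(model$W2)), nrow(model$W2), ncol(model$W2))
  model$b2 <- take(length(model$b2))
  if (pos != length(params)) stop("parameter vector length mismatch")
  model
}

#' Save / load an RMSNN model as JSON
#'
#' @param model An `rmsnn_model`.
#' @param path Output path.
#' @return `save_rmsnn`: the path, invisibly. `load_rmsnn`: the model.
#' @export
save_rmsnn <- function(model, path) {
  payload <- list(input_size = model$input_size, classes = model$classes,
                  arch = model$arch, se_offsets = model$se_offsets,
                  params = rmsnn_get_params(model))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_rmsnn
#' @export
load_rmsnn <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  a <- payload$arch
  model <- rmsnn_model(input_size = payload$input_size,
                       n_maps = a$n_maps, se_shape = a$se_shape,
                       se_size = a$se_size, n_hidden = a$n_hidden,
                       classes = payload$classes,
                       init_range = a$init_range,
                       se_init_range = a$se_init_range, seed = a$seed)
  rmsnn_set_params(model, payload$params)
}
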