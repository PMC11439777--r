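# Network construction, the training loop (stochastic gradient-based
# minimization of categorical cross-entropy with online augmentation,
# including the mixed augmentation schedule), and the performance measure.

#' Training hyperparameters
#'
#' @param input_resolution square input size in pixels (default 256, the
#'   full-scale setting; desk-scale runs use 96).
#' @param batch_size minibatch size (default 16).
#' @param learning_rate optimizer learning rate (default 1e-4).
#' @param epochs number of passes over the training split.
#' @param augment_mode augmentation mode applied online to training batches
#'   (ignored when `schedule` is mixed).
#' @param schedule either `list(type = "fixed")` or
#'   `list(type = "mixed", first=, second=, switch_fraction=)`: a mixed
#'   schedule uses `first` for epochs `1..ceiling(switch_fraction * epochs)`
#'   and `second` afterwards.
#' @param optimizer `"adam"` (default) or `"sgd"`. The stated learning rate
#'   of 1e-4 is characteristic of adaptive optimizers; plain SGD at that
#'   rate barely moves a fresh network within desk-scale epoch budgets.
#' @param filters conv filter counts of the compact architecture.
#' @param seed integer seed controlling initialization, shuffling and
#'   augmentation draws.
#' @return a `phyto_hyperparameters` list.
#' @export
hyperparameters <- function(input_resolution = 256, batch_size = 16,
                            learning_rate = 1e-4, epochs = 5,
                            augment_mode = "medium",
                            schedule = list(type = "fixed"),
                            optimizer = "adam",
                            filters = c(16, 32, 64), seed = 0) {
  check_range(batch_size, "batch_size", 1, Inf, integer = TRUE)
  check_range(learning_rate, "learning_rate", 0, Inf, lo_open = TRUE)
  check_range(epochs, "epochs", 1, Inf, integer = TRUE)
  check_range(input_resolution, "input_resolution", 16, Inf, integer = TRUE)
  if (identical(schedule$type, "mixed")) {
    check_range(schedule$switch_fraction, "switch_fraction", 0, 1,
                lo_open = TRUE, hi_open = TRUE)
    augment_mode(schedule$first); augment_mode(schedule$second)
  } else if (!identical(schedule$type, "fixed")) {
    stop_validation("schedule$type must be 'fixed' or 'mixed'")
  }
  structure(list(input_resolution = as.integer(input_resolution),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 epochs = as.integer(epochs),
                 augment_mode = augment_mode, schedule = schedule,
                 optimizer = optimizer, filters = filters,
                 seed = as.integer(seed)),
            class = "phyto_hyperparameters")
}

#' Augmentation mode in force at a given epoch
#'
#' @param h a [hyperparameters()] object.
#' @param epoch epoch index (1-based).
#' @return a mode name.
#' @export
mode_for_epoch <- function(h, epoch) {
  if (identical(h$schedule$type, "mixed")) {
    if (epoch <= ceiling(h$schedule$switch_fraction * h$epochs))
      h$schedule$first else h$schedule$second
  } else h$augment_mode
}

#' Build an (untrained) classification network
#'
#' The `"compact"` architecture is a desk-scale CNN designed to train from
#' scratch within a few CPU epochs: inputs are centered, a stride-2 3x3 conv
#' stem (its leading filters initialized as trainable opponent-color
#' detectors, the rest He-normal) feeds two further 3x3 conv blocks
#' separated by 2x2 max pooling; every block is summarized by global
#' average *and* global max pooling, the stacked multi-scale feature vector
#' is batch-normalized, and a dense softmax head maps it to the classes
#' `(healthy, infected)`. The dense head starts at zero so a fresh network
#' outputs exactly uniform class probabilities.
#'
#' The `"paper"` architecture name is reserved for the full-scale published
#' reference network; its exact layer list is not available in this
#' distribution, so requesting it raises a configuration error rather than
#' shipping an approximation of its published weight count.
#'
#' @param arch `"compact"` or `"paper"`.
#' @param input_size square input resolution in pixels.
#' @param filters conv filter counts (3 positive integers).
#' @param seed integer seed for deterministic initialization.
#' @return a `phyto_classifier` with a `weight_count` field equal to the
#'   exact number of trainable parameters.
#' @export
build_network <- function(arch = "compact", input_size = 96,
                          filters = c(16, 32, 64), seed = 0) {
  if (identical(arch, "paper"))
    stop_config(paste(
      "arch 'paper': the exact layer list of the full-scale reference",
      "network (published weight count 2,960,514) is not available in this",
      "distribution and is not approximated; use arch = 'compact'"))
  if (!identical(arch, "compact"))
    stop_config(sprintf("unknown architecture '%s'", as.character(arch)[1]))
  if (length(filters) != 3 || any(filters < 1))
    stop_config("filters must be 3 positive integers (zero conv filters are invalid)")
  if (input_size %% 8 != 0)
    stop_config("compact architecture needs input_size divisible by 8")
  f <- as.integer(filters)
  weights <- with_seed(derive_seed(seed, 71L), {
    he <- function(k, cin, cout)
      array(rnorm(k * k * cin * cout, 0, sqrt(2 / (k * k * cin))),
            c(k, k, cin, cout))
    W1 <- he(3, 3, f[1])
    # informed stem initialization: the first filters start as 3x3 box
    # opponent-color detectors (browning R-G, greenness G-B, luminance and
    # their negations) so symptom-colored pixels are first-class features
    # from step one; all stem filters remain trainable.
    opp <- list(c(1, -1, 0), c(-1, 1, 0), c(0, 1, -1), c(0, -1, 1),
                c(1, 1, 1) / 3)
    for (q in seq_len(min(length(opp), f[1])))
      W1[, , , q] <- array(rep(opp[[q]] / 9, each = 9), c(3, 3, 3))
    list(W1 = W1, b1 = numeric(f[1]),
         W2 = he(3, f[1], f[2]), b2 = numeric(f[2]),
         W3 = he(3, f[2], f[3]), b3 = numeric(f[3]),
         gamma = rep(1, 2L * sum(f)), beta = numeric(2L * sum(f)),
         Wd = matrix(0, 2L * sum(f), 2), bd = numeric(2))
  })
  structure(list(arch = arch, input_size = as.integer(input_size),
                 filters = f, classes = c("healthy", "infected"),
                 weights = weights,
                 bn_mean = numeric(2L * sum(f)),
                 bn_var = rep(1, 2L * sum(f)),
                 logit_scale = 24,
                 weight_count = sum(vapply(weights, length, 1L)),
                 seed = as.integer(seed)),
            class = "phyto_classifier")
}

# load a manifest's images into memory as H x W x 3 x N
.load_manifest_images <- function(manifest, resolution) {
  dir <- attr(manifest, "manifest_dir") %||% "."
  n <- nrow(manifest)
  x <- array(0, c(resolution, resolution, 3, n))
  for (i in seq_len(n)) {
    p <- manifest$path[i]
    if (!file.exists(p)) p <- file.path(dir, manifest$path[i])
    img <- png::readPNG(p)
    if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
    if (dim(img)[3] > 3) img <- img[, , 1:3, drop = FALSE]
    if (!all(dim(img)[1:2] == c(resolution, resolution)))
      img <- resize_bilinear(img, resolution, resolution)
    x[, , , i] <- img
  }
  list(x = x, y = manifest$label, split = manifest$split)
}

#' Bilinear image resize
#'
#' @param img H x W x C array.
#' @param H,W target size.
#' @return resized array.
#' @export
resize_bilinear <- function(img, H, W) {
  hs <- dim(img)[1]; ws <- dim(img)[2]
  ys <- pmin(pmax((seq_len(H) - 0.5) / H * hs - 0.5, 0), hs - 1)
  xs <- pmin(pmax((seq_len(W) - 0.5) / W * ws - 0.5, 0), ws - 1)
  i0 <- floor(ys); j0 <- floor(xs)
  fy <- matrix(ys - i0, H, W); fx <- matrix(xs - j0, H, W, byrow = TRUE)
  i1 <- pmin(i0 + 1, hs - 1); j1 <- pmin(j0 + 1, ws - 1)
  out <- array(0, c(H, W, dim(img)[3]))
  for (k in seq_len(dim(img)[3])) {
    m <- img[, , k]
    out[, , k] <- (1 - fy) * ((1 - fx) * m[i0 + 1, j0 + 1] + fx * m[i0 + 1, j1 + 1]) +
      fy * ((1 - fx) * m[i1 + 1, j0 + 1] + fx * m[i1 + 1, j1 + 1])
  }
  out
}

#' Train the compact classifier on a labeled dataset
#'
#' Minimizes categorical cross-entropy by stochastic gradient-based
#' optimization over the manifest's training split, applying the scheduled
#' augmentation mode online to every training image, and evaluates the
#' validation split (unaugmented) after each epoch.
#'
#' @param h a [hyperparameters()] object.
#' @param manifest a manifest from [build_dataset()] / [read_manifest()],
#'   with both classes present in both splits.
#' @param data optional in-memory dataset `list(x = HxWx3xN array,
#'   y = labels, split = splits)` bypassing the manifest (used for toy
#'   problems); `manifest` may then be `NULL`.
#' @return a list with `classifier` (trained `phyto_classifier`) and `trace`
#'   (one row per epoch: losses, accuracies, augmentation mode).
#' @export
train <- function(h, manifest = NULL, data = NULL) {
  if (!inherits(h, "phyto_hyperparameters"))
    stop_validation("h must come from hyperparameters()")
  if (is.null(data)) {
    if (is.null(manifest)) stop_validation("either manifest or data is required")
    data <- .load_manifest_images(manifest, h$input_resolution)
  }
  y <- data$y; split <- data$split
  for (sp in c("train", "val")) {
    cls <- unique(y[split == sp])
    if (length(cls) < 2)
      stop_validation(sprintf("split '%s' does not contain both classes", sp))
  }

  net <- build_network("compact", input_size = h$input_resolution,
                       filters = h$filters, seed = h$seed)
  y_idx <- match(y, net$classes)
  if (anyNA(y_idx)) stop_validation("labels must be 'healthy'/'infected'")
  tr_idx <- which(split == "train")
  va_idx <- which(split == "val")
  opt <- .make_optimizer(h$optimizer, net$weights, h$learning_rate)

  trace <- data.frame()
  for (e in seq_len(h$epochs)) {
    mode <- mode_for_epoch(h, e)
    ord <- with_seed(derive_seed(h$seed, 600L + e), sample(tr_idx))
    losses <- c(); correct <- 0L; seen <- 0L
    for (b0 in seq(1, length(ord), by = h$batch_size)) {
      idx <- ord[b0:min(b0 + h$batch_size - 1, length(ord))]
      xb <- array(0, c(h$input_resolution, h$input_resolution, 3, length(idx)))
      for (q in seq_along(idx))
        xb[, , , q] <- augment(data$x[, , , idx[q], drop = TRUE], mode,
                               seed = derive_seed(h$seed, e, idx[q]))
      fw <- .forward_net(net, xb, training = TRUE)
      yi <- y_idx[idx]
      pl <- fw$probs[cbind(seq_along(idx), yi)]
      loss <- -mean(log(pmax(pl, 1e-12)))
      if (!is.finite(loss))
        phyto_stop("phytosynth_training_error",
                   sprintf("non-finite loss at epoch %d (batch starting %d)", e, b0))
      losses <- c(losses, loss)
      correct <- correct + sum(max.col(fw$probs) == yi)
      seen <- seen + length(idx)
      g <- .backward_net(net, fw, yi)
      net$weights <- opt$step(net$weights, g)
      net$bn_mean <- 0.9 * net$bn_mean + 0.1 * fw$bn_mu
      net$bn_var <- 0.9 * net$bn_var + 0.1 * fw$bn_v
    }
    ev <- .evaluate_net(net, data$x, y_idx, va_idx)
    trace <- rbind(trace, data.frame(
      epoch = e, mode = mode,
      train_loss = mean(losses), train_acc = correct / seen,
      val_loss = ev$loss, val_acc = ev$acc
    ))
  }
  list(classifier = net, trace = trace)
}

.evaluate_net <- function(net, x, y_idx, idx, batch = 64L) {
  loss <- 0; correct <- 0L
  for (b0 in seq(1, length(idx), by = batch)) {
    ii <- idx[b0:min(b0 + batch - 1, length(idx))]
    fw <- .forward_net(net, x[, , , ii, drop = FALSE])
    pl <- fw$probs[cbind(seq_along(ii), y_idx[ii])]
    loss <- loss + sum(-log(pmax(pl, 1e-12)))
    correct <- correct + sum(max.col(fw$probs) == y_idx[ii])
  }
  list(loss = loss / length(idx), acc = correct / length(idx))
}

#' Class probabilities for images
#'
#' @param object a `phyto_classifier`.
#' @param x an H x W x 3 array or H x W x 3 x N batch; images are resized to
#'   the classifier's input resolution when needed.
#' @param ... unused.
#' @return an N x 2 matrix of probabilities, columns `(healthy, infected)`,
#'   each row summing to 1.
#' @export
predict.phyto_classifier <- function(object, x, ...) {
  if (length(dim(x)) == 3) x <- array(x, c(dim(x), 1))
  r <- object$input_size
  if (!all(dim(x)[1:2] == c(r, r))) {
    xr <- array(0, c(r, r, 3, dim(x)[4]))
    for (i in seq_len(dim(x)[4]))
      xr[, , , i] <- resize_bilinear(x[, , , i, drop = TRUE], r, r)
    x <- xr
  }
  n <- dim(x)[4]
  probs <- matrix(0, n, 2, dimnames = list(NULL, object$classes))
  for (b0 in seq(1, n, by = 64)) {
    ii <- b0:min(b0 + 63, n)
    probs[ii, ] <- .forward_net(object, x[, , , ii, drop = FALSE])$probs
  }
  probs
}

#' Predicted labels for images
#'
#' Ties on the probability vector resolve to the first class (healthy).
#'
#' @inheritParams predict.phyto_classifier
#' @return character vector of labels.
#' @export
classify <- function(object, x) {
  p <- predict(object, x)
  object$classes[max.col(p, ties.method = "first")]
}

#' Misclassification fraction of a classifier on an evaluation set
#'
#' `error_rate` divides the number of falsely labeled images by the total
#' number of images; [accuracy()] is its exact complement.
#'
#' @param object a `phyto_classifier`.
#' @param manifest_or_set a manifest (all rows are evaluated) or a list
#'   `list(x =, y =)`.
#' @return scalar fraction in `[0, 1]`.
#' @export
error_rate <- function(object, manifest_or_set) {
  set <- if (is.data.frame(manifest_or_set))
    .load_manifest_images(manifest_or_set, object$input_size)
  else manifest_or_set
  if (is.null(set$x) || length(set$y) == 0)
    stop_validation("evaluation set is empty")
  mean(classify(object, set$x) != set$y)
}

#' Classification accuracy (1 - error rate)
#' @inheritParams error_rate
#' @return scalar fraction in `[0, 1]`.
#' @export
accuracy <- function(object, manifest_or_set) 1 - error_rate(object, manifest_or_set)
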