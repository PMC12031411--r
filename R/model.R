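# CNN-LSTM activity classifier: dataset assembly, training, inference.

#' CNN-LSTM network specification
#'
#' The full-scale architecture: sequence input, 1D convolution (filter size
#' 100, 100 filters), bidirectional LSTM (500 hidden units, sequence
#' output), dropout 0.2, bidirectional LSTM (500 hidden units, last-step
#' output), fully connected + softmax over the five activity classes.
#' `reduced_network_spec()` is a desk-scale variant (50 filters of width
#' 20 applied with stride 20, 100 hidden units) that preserves the layer
#' structure at a fraction of the runtime.
#'
#' @param conv_filters Number of convolution filters.
#' @param conv_filter_size Convolution filter width (time steps).
#' @param conv_stride Convolution stride.
#' @param lstm_hidden Hidden units per LSTM direction.
#' @param dropout Dropout probability between the two LSTM layers.
#' @param num_classes Number of output classes.
#' @param conv_activation `"none"` (default; the recurrent layers supply
#'   the nonlinearity) or `"relu"`.
#' @return A list of class `network_spec`.
#' @export
network_spec <- function(conv_filters = 100, conv_filter_size = 100,
                         conv_stride = 1, lstm_hidden = 500, dropout = 0.2,
                         num_classes = 5, conv_activation = "none") {
  stopifnot(conv_filters > 0, conv_filter_size > 0, conv_stride > 0,
            lstm_hidden > 0, dropout >= 0, dropout < 1, num_classes > 1)
  structure(list(conv_filters = conv_filters,
                 conv_filter_size = conv_filter_size,
                 conv_stride = conv_stride, lstm_hidden = lstm_hidden,
                 dropout = dropout, num_classes = num_classes,
                 conv_activation = conv_activation),
            class = "network_spec")
}

#' @rdname network_spec
#' @export
reduced_network_spec <- function() {
  network_spec(conv_filters = 50, conv_filter_size = 20, conv_stride = 20,
               lstm_hidden = 100)
}

#' Training configuration
#'
#' Defaults follow the reference recipe: Adam, at most 100 epochs, initial
#' learning rate 0.002, mini-batch size 50, gradient threshold 1, 70/30
#' train/test split, no early stopping.
#'
#' @param max_epochs Maximum training epochs.
#' @param learning_rate Initial Adam learning rate.
#' @param batch_size Mini-batch size.
#' @param gradient_clip Global gradient-norm threshold.
#' @param train_fraction Training share of the 70/30 split.
#' @param seed Integer seed for shuffling, initialization and dropout.
#' @param verbose Print per-epoch loss.
#' @return A list of class `train_config`.
#' @export
train_config <- function(max_epochs = 100, learning_rate = 0.002,
                         batch_size = 50, gradient_clip = 1,
                         train_fraction = 0.7, seed = 1, verbose = FALSE) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  structure(list(max_epochs = max_epochs, learning_rate = learning_rate,
                 batch_size = batch_size, gradient_clip = gradient_clip,
                 train_fraction = train_fraction, seed = as.integer(seed),
                 verbose = verbose),
            class = "train_config")
}

#' Labelled training example
#'
#' @param features A `feature_matrix` (see [build_feature_matrix()]).
#' @param label A non-Uncertain activity class.
#' @param cage_id Optional cage identifier.
#' @return A list of class `labeled_example`.
#' @export
labeled_example <- function(features, label, cage_id = NA_character_) {
  if (!label %in% activity_classes()) {
    stop("label must be one of ", paste(activity_classes(), collapse = ", "),
         " (Uncertain sections are excluded from training)")
  }
  structure(list(features = features, label = label, cage_id = cage_id),
            class = "labeled_example")
}

#' Labels of a list of examples
#' @param examples List of [labeled_example()]s.
#' @return Character vector of labels.
#' @export
example_labels <- function(examples) {
  vapply(examples, function(e) e$label, character(1))
}

#' Undersample the majority Resting class
#'
#' Resting dominates home-cage datasets; to cut redundant data it is
#' randomly undersampled (uniform, without replacement) until its count
#' equals that of StationaryActivity, the second most common class. Other
#' classes are untouched; nothing happens if Resting is not in excess.
#'
#' @param examples List of [labeled_example()]s.
#' @param seed Integer seed for the uniform draw.
#' @return Sub-list of `examples` (original order preserved).
#' @export
undersample_majority <- function(examples, seed = 1) {
  labs <- example_labels(examples)
  n_rest <- sum(labs == "Resting")
  n_stat <- sum(labs == "StationaryActivity")
  if (n_rest <= n_stat) return(examples)
  set.seed(seed)
  keep_rest <- sort(sample(which(labs == "Resting"), n_stat))
  keep <- sort(c(keep_rest, which(labs != "Resting")))
  examples[keep]
}

#' Stratified train/test split
#'
#' @param examples List of [labeled_example()]s (>= 10).
#' @param cfg A [train_config()]; uses its `train_fraction` and `seed`.
#' @param chronological Split by list position instead of a stratified
#'   random draw (leakage-conscious evaluation of time-ordered sections);
#'   the first `train_fraction` of examples become the training set.
#' @return List with `train` and `test` example lists (disjoint,
#'   exhaustive; per-class proportions preserved in the stratified mode).
#'   A class with fewer than 2 members is kept whole in the training set,
#'   with a warning.
#' @export
split_dataset <- function(examples, cfg = train_config(),
                          chronological = FALSE) {
  if (length(examples) < 10) stop("need at least 10 examples to split")
  if (chronological) {
    n_tr <- round(cfg$train_fraction * length(examples))
    return(list(train = examples[seq_len(n_tr)],
                test = examples[(n_tr + 1):length(examples)]))
  }
  labs <- example_labels(examples)
  set.seed(cfg$seed)
  train_idx <- integer(0)
  for (cl in unique(labs)) {
    idx <- which(labs == cl)
    if (length(idx) < 2) {
      warning("class ", cl, " has fewer than 2 examples; kept whole in train")
      train_idx <- c(train_idx, idx)
    } else {
      n_tr <- round(cfg$train_fraction * length(idx))
      n_tr <- min(max(n_tr, 1L), length(idx) - 1L)
      train_idx <- c(train_idx, sample(idx, n_tr))
    }
  }
  train_idx <- sort(train_idx)
  list(train = examples[train_idx],
       test = examples[setdiff(seq_along(examples), train_idx)])
}

#' Train the CNN-LSTM activity classifier
#'
#' Cross-entropy training with Adam, mini-batches, and global-norm gradient
#' clipping; deterministic for a fixed `cfg$seed` under single-threaded
#' BLAS.
#'
#' @param examples List of [labeled_example()]s with identically shaped
#'   feature matrices; at least two classes.
#' @param spec A [network_spec()].
#' @param cfg A [train_config()].
#' @param classes Class order used for the output layer (default
#'   [activity_classes()]).
#' @return A list of class `cagevibe_model` with elements `params`, `spec`,
#'   `classes`, `input_dim` and `history` (per-epoch mean training loss).
#' @export
train_classifier <- function(examples, spec = network_spec(),
                             cfg = train_config(),
                             classes = activity_classes()) {
  labs <- example_labels(examples)
  if (length(unique(labs)) < 2) stop("need at least 2 classes to train")
  classes <- intersect(classes, unique(labs))
  d <- dim(examples[[1]]$features)
  for (e in examples) {
    if (!all(dim(e$features) == d)) {
      stop("feature matrices differ in shape: ",
           paste(dim(e$features), collapse = "x"), " vs ",
           paste(d, collapse = "x"))
    }
  }
  if (spec$num_classes != length(classes)) {
    spec$num_classes <- length(classes)   # classes actually present
  }
  set.seed(cfg$seed)
  params <- nn_init(spec, d[1], d[2])
  state <- adam_init(params)
  y <- match(labs, classes)
  n <- length(examples)
  history <- numeric(cfg$max_epochs)
  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- sample(n)
    losses <- c()
    for (b0 in seq(1, n, by = cfg$batch_size)) {
      idx <- ord[b0:min(b0 + cfg$batch_size - 1, n)]
      X <- stack_features(lapply(examples[idx], `[[`, "features"))
      Y <- matrix(0, length(classes), length(idx))
      Y[cbind(y[idx], seq_along(idx))] <- 1
      fwd <- nn_forward(params, X, spec, train = TRUE)
      bk <- nn_backward(params, X, Y, spec, fwd)
      st <- adam_step(params, bk$grads, state, cfg$learning_rate,
                      clip = cfg$gradient_clip)
      params <- st$params; state <- st$state
      losses <- c(losses, bk$loss)
    }
    history[epoch] <- mean(losses)
    if (cfg$verbose) {
      message(sprintf("epoch %d/%d  loss %.4f", epoch, cfg$max_epochs,
                      history[epoch]))
    }
  }
  structure(list(params = params, spec = spec, classes = classes,
                 input_dim = d, history = history),
            class = "cagevibe_model")
}

#' Predict activity classes for feature matrices
#'
#' @param object A trained `cagevibe_model`.
#' @param features One `feature_matrix` or a list of them (all shaped like
#'   the training input).
#' @param ... Unused.
#' @return List with `probabilities` (matrix, one row per example, columns
#'   = classes, rows sum to 1) and `label` (argmax class; ties resolved by
#'   class order).
#' @export
predict.cagevibe_model <- function(object, features, ...) {
  if (is.matrix(features)) features <- list(features)
  d <- dim(features[[1]])
  if (!all(d == object$input_dim)) {
    stop("feature shape ", paste(d, collapse = "x"),
         " does not match the training shape ",
         paste(object$input_dim, collapse = "x"))
  }
  X <- stack_features(features)
  fwd <- nn_forward(object$params, X, object$spec, train = FALSE)
  probs <- t(fwd$probs)
  colnames(probs) <- object$classes
  list(probabilities = probs,
       label = object$classes[max.col(probs, ties.method = "first")])
}

#' Number of learnable parameters of a model or spec
#'
#' @param x A `cagevibe_model`, or a [network_spec()] (then `in_channels`
#'   is required).
#' @param in_channels,in_len Input dimensions when `x` is a spec.
#' @return Integer parameter count.
#' @export
n_params <- function(x, in_channels = NULL, in_len = NULL) {
  params <- if (inherits(x, "cagevibe_model")) x$params else {
    stopifnot(!is.null(in_channels))
    nn_init(x, in_channels, in_len, seed = 0)
  }
  s <- 0
  rec <- function(p) {
    if (is.list(p)) lapply(p, rec) else s <<- s + length(p)
    invisible(NULL)
  }
  rec(params)
  s
}

#' Save / load a trained model
#'
#' Serialization is a plain `saveRDS` of the model object; a reloaded model
#' produces bit-identical predictions.
#'
#' @param model A `cagevibe_model`.
#' @param path File path.
#' @return `save_model()`: `path` invisibly; `load_model()`: the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "cagevibe_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "cagevibe_model")) stop("not a cagevibe model file")
  model
}
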