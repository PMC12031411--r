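tiny_spec <- function() {
  network_spec(conv_filters = 3, conv_filter_size = 4, conv_stride = 2,
               lstm_hidden = 4, dropout = 0, num_classes = 3)
}

test_that("analytic gradients match numeric differentiation", {
  ns <- asNamespace("cagevibe")
  spec <- tiny_spec()
  set.seed(1)
  C <- 5; L <- 12; B <- 3
  X <- array(rnorm(C * L * B), c(C, L, B))
  Y <- matrix(0, 3, B); Y[cbind(c(1, 3, 2), 1:B)] <- 1
  params <- ns$nn_init(spec, C, L, seed = 2)
  loss_fn <- function(p) {
    fwd <- ns$nn_forward(p, X, spec, train = FALSE)
    -mean(log(pmax(colSums(fwd$probs * Y), 1e-12)))
  }
  fwd <- ns$nn_forward(params, X, spec, train = FALSE)
  bk <- ns$nn_backward(params, X, Y, spec, fwd)
  modify <- function(p, path, i, d) {
    if (length(path) == 1) { p[[path]][i] <- p[[path]][i] + d; p }
    else { p[[path[1]]] <- modify(p[[path[1]]], path[-1], i, d); p }
  }
  eps <- 1e-6
  paths <- list("conv_W", "conv_b", c("l1f", "Wx"), c("l1f", "Wh"),
                c("l1f", "b"), c("l1b", "Wx"), c("l2f", "Wx"),
                c("l2b", "Wh"), c("l2b", "b"), "dense_W", "dense_b")
  set.seed(99)
  for (path in paths) {
    g_an <- bk$grads
    for (nm in path) g_an <- g_an[[nm]]
    for (i in sample(length(g_an), min(5, length(g_an)))) {
      g_num <- (loss_fn(modify(params, path, i, eps)) -
                loss_fn(modify(params, path, i, -eps))) / (2 * eps)
      expect_lt(abs(g_num - g_an[i]) /
                  max(1e-8, abs(g_num) + abs(g_an[i])), 1e-4)
    }
  }
})

make_constant_examples <- function(n_per_class = 20, seed = 7) {
  set.seed(seed)
  classes <- activity_classes()
  examples <- list()
  for (ci in seq_along(classes)) {
    for (r in seq_len(n_per_class)) {
      fm <- matrix(ci / 5, 8, 40) + matrix(rnorm(8 * 40, 0, 0.02), 8, 40)
      examples <- c(examples, list(labeled_example(fm, classes[ci])))
    }
  }
  examples
}

test_that("the network memorizes separable constant-feature classes", {
  examples <- make_constant_examples()
  spec <- network_spec(conv_filters = 8, conv_filter_size = 5,
                       conv_stride = 5, lstm_hidden = 8, dropout = 0.2)
  cfg <- train_config(max_epochs = 20, batch_size = 20, seed = 3)
  m <- train_classifier(examples, spec, cfg)
  pred <- predict(m, lapply(examples, `[[`, "features"))
  expect_equal(mean(pred$label == example_labels(examples)), 1)
  # probabilities live on the simplex
  expect_equal(rowSums(pred$probabilities), rep(1, length(examples)),
               tolerance = 1e-6)
  expect_true(all(pred$probabilities >= 0))
  # a training example maps back to its own label with high confidence
  p1 <- predict(m, examples[[1]]$features)
  expect_equal(p1$label, examples[[1]]$label)
  expect_gt(max(p1$probabilities), 0.5)
})

test_that("checkpoints reload to identical predictions", {
  examples <- make_constant_examples(n_per_class = 6)
  spec <- network_spec(conv_filters = 4, conv_filter_size = 5,
                       conv_stride = 5, lstm_hidden = 4)
  m <- train_classifier(examples, spec,
                        train_config(max_epochs = 2, batch_size = 10,
                                     seed = 3))
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(m, path)
  m2 <- load_model(path)
  feats <- lapply(examples[1:8], `[[`, "features")
  expect_identical(predict(m, feats)$probabilities,
                   predict(m2, feats)$probabilities)
})

test_that("training is deterministic given the seed", {
  examples <- make_constant_examples(n_per_class = 6)
  spec <- network_spec(conv_filters = 4, conv_filter_size = 5,
                       conv_stride = 5, lstm_hidden = 4)
  cfg <- train_config(max_epochs = 2, batch_size = 10, seed = 11)
  m1 <- train_classifier(examples, spec, cfg)
  m2 <- train_classifier(examples, spec, cfg)
  expect_identical(m1$params, m2$params)
})

test_that("shape mismatches error before training or prediction", {
  examples <- make_constant_examples(n_per_class = 4)
  examples[[3]]$features <- matrix(0, 8, 39)
  expect_error(train_classifier(examples, tiny_spec()), "shape")
  good <- make_constant_examples(n_per_class = 6)
  m <- train_classifier(good, network_spec(conv_filters = 4,
                                           conv_filter_size = 5,
                                           conv_stride = 5,
                                           lstm_hidden = 4),
                        train_config(max_epochs = 1, batch_size = 10))
  expect_error(predict(m, matrix(0, 8, 39)), "shape")
})

test_that("Resting is undersampled to the StationaryActivity support", {
  fm <- matrix(0, 2, 4)
  mk <- function(lab, n) {
    lapply(seq_len(n), function(i) labeled_example(fm, lab))
  }
  ex <- c(mk("Resting", 100), mk("StationaryActivity", 40),
          mk("Walking", 10))
  out <- undersample_majority(ex, seed = 1)
  counts <- table(example_labels(out))
  expect_equal(unname(counts[["Resting"]]), 40)
  expect_equal(unname(counts[["StationaryActivity"]]), 40)
  expect_equal(unname(counts[["Walking"]]), 10)
  # already balanced input is untouched
  ex2 <- c(mk("Resting", 30), mk("StationaryActivity", 40))
  expect_identical(undersample_majority(ex2, seed = 1), ex2)
  # study-scale counts: 50,985 Resting reduced to the 30,102 Stationary
  n <- table(example_labels(undersample_majority(
    c(mk("Resting", 5099), mk("StationaryActivity", 3010)), seed = 2)))
  expect_equal(unname(n[["Resting"]]), 3010)
})

test_that("the stratified split is exhaustive, disjoint and seeded", {
  examples <- make_constant_examples(n_per_class = 20)
  cfg <- train_config(seed = 5)
  sp <- split_dataset(examples, cfg)
  expect_equal(length(sp$train) + length(sp$test), 100)
  expect_equal(length(sp$train), 70)
  # per-class proportions preserved
  tr <- table(example_labels(sp$train))
  expect_true(all(tr == 14))
  sp2 <- split_dataset(examples, cfg)
  expect_identical(example_labels(sp2$train), example_labels(sp$train))
  expect_error(split_dataset(examples[1:5], cfg), "at least 10")
  # chronological mode keeps list order
  spc <- split_dataset(examples, cfg, chronological = TRUE)
  expect_identical(spc$train, examples[1:70])
  expect_identical(spc$test, examples[71:100])
})

test_that("parameter counts are reported for both network scales", {
  expect_equal(n_params(reduced_network_spec(), 40), 402655)
  expect_gt(n_params(network_spec(), 40), 8e6)
})
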