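test_that("default architecture has seven conv blocks and a consistent parameter count", {
  cfg <- model_config()
  expect_equal(cfg$n_conv, 7L)
  m <- build_model(cfg, seed = 1)
  expect_equal(length(m$params$conv_w), 7L)

  # hand-summed parameter count for a tiny fixed configuration:
  # conv1 3x3x1x4 + 4 bias + BN 2*4 = 48; conv2 3x3x4x8 + 8 + 16 = 312;
  # fc 8*2 + 2 = 18  => 378
  tiny <- model_config(n_conv_layers = 2, channels = c(4, 8),
                       pool_after = 1, input_size = 16)
  expect_equal(count_params(tiny), 9 * 4 + 4 + 8 + 9 * 4 * 8 + 8 + 16 + 18)
  expect_equal(count_params(tiny), 378)
  mt <- build_model(tiny, seed = 1)
  # the stored parameters really have that many elements
  expect_equal(sum(lengths(cephcam:::flatten_params(mt$params))), 378)

  expect_error(model_config(n_conv_layers = 3, channels = c(4, 8)),
               "one entry per")
})

test_that("softmax outputs are probabilities for arbitrary inputs", {
  m <- build_model(model_config(n_conv_layers = 2, channels = c(4, 8),
                                pool_after = 1, input_size = 16), seed = 2)
  set.seed(1)
  x <- array(rnorm(16 * 16 * 1 * 5, 0, 10), dim = c(16, 16, 1, 5))
  fwd <- cephcam:::cnn_forward(m, x, train = FALSE)
  expect_true(all(fwd$probs > 0 & fwd$probs < 1))
  expect_equal(colSums(fwd$probs), rep(1, 5), tolerance = 1e-6)
})

test_that("learning-rate schedule follows the step decay", {
  cfg <- train_config()
  expect_equal(lr_schedule(0, cfg), 1e-3)
  expect_equal(lr_schedule(200, cfg), 1e-3 * 0.95^2)
  expect_equal(lr_schedule(99, cfg), 1e-3)
  expect_equal(lr_schedule(100, cfg), 1e-3 * 0.95)
  cfg1 <- train_config(lr_decay = 1)
  expect_equal(lr_schedule(c(0, 150, 999), cfg1), rep(1e-3, 3))
})

test_that("cross-validation splits reproduce the cohort arithmetic", {
  # 1317 class I -> folds of 263 test / 1054 train
  f1 <- make_cv_splits(rep("classI", 1317), k = 5, seed = 1)
  expect_equal(length(f1[[1]]$test), 263L)
  expect_equal(length(f1[[1]]$train), 1054L)
  # 1377 class II -> 275 test / 1102 train
  f2 <- make_cv_splits(rep("classII", 1377), k = 5, seed = 1)
  expect_equal(length(f2[[3]]$test), 275L)
  expect_equal(length(f2[[3]]$train), 1102L)
})

test_that("cv folds are disjoint, stratified, and cover the remainder in training", {
  labels <- rep(c("classI", "classII"), c(23, 17))
  folds <- make_cv_splits(labels, k = 5, seed = 3)
  tests <- lapply(folds, `[[`, "test")
  expect_equal(length(Reduce(intersect, tests)), 0L)
  for (f in folds) {
    expect_equal(sort(union(f$train, f$test)), seq_along(labels))
    # per-class test size = floor(n/k)
    expect_equal(sum(labels[f$test] == "classI"), 4L)
    expect_equal(sum(labels[f$test] == "classII"), 3L)
  }
  # exact division: every fold test size n/k
  fx <- make_cv_splits(rep(c("a", "b"), each = 5), k = 5, seed = 1)
  expect_true(all(vapply(fx, function(f) length(f$test), numeric(1)) == 2))
  expect_error(make_cv_splits(rep("a", 4), k = 5), "at least k")
})

test_that("training is deterministic, learns a separable set, and handles edge cases", {
  fx <- tiny_trained_model()
  m <- fx$model
  ev <- evaluate_classifier(m, fx$blobs$images, fx$blobs$labels)
  expect_equal(ev$accuracy, 1.0)
  expect_true(all(ev$predictions$score >= 0.5 & ev$predictions$score <= 1))

  # determinism: same seeds -> identical loss curve
  cfg <- model_config(n_conv_layers = 2, channels = c(4, 8),
                      pool_after = 1, input_size = 16)
  blobs <- make_blob_set(6)
  tc <- train_config(epochs = 3, batch_size = 4, augment = FALSE, seed = 5)
  m1 <- train_classifier(build_model(cfg, seed = 7), blobs$images,
                         blobs$labels, tc)
  m2 <- train_classifier(build_model(cfg, seed = 7), blobs$images,
                         blobs$labels, tc)
  expect_identical(m1$log, m2$log)
  expect_identical(m1$params$fc_w, m2$params$fc_w)

  # epochs = 0: untouched parameters, empty log
  m0 <- build_model(cfg, seed = 7)
  m0t <- train_classifier(m0, blobs$images, blobs$labels,
                          train_config(epochs = 0, seed = 1))
  expect_identical(m0t$params, m0$params)
  expect_equal(nrow(m0t$log), 0L)

  # single-class data refused
  expect_error(train_classifier(build_model(cfg, seed = 1),
                                blobs$images[1:6], rep("classI", 6),
                                train_config(epochs = 1)),
               "both classes")
})

test_that("training loss decreases on a noiseless separable set", {
  imgs <- c(lapply(1:10, function(i) make_blob_image(1, i, noise = 0)),
            lapply(1:10, function(i) make_blob_image(2, 50 + i, noise = 0)))
  labs <- rep(c("classI", "classII"), each = 10)
  cfg <- model_config(n_conv_layers = 2, channels = c(4, 8),
                      pool_after = 1, input_size = 16, dropout_rate = 0)
  m <- train_classifier(build_model(cfg, seed = 2), imgs, labs,
                        train_config(epochs = 15, batch_size = 20,
                                     augment = FALSE, seed = 4))
  loss <- m$log$loss
  expect_lt(loss[15], loss[5])
  # allow small wiggles after warm-up, no large increases
  expect_true(all(diff(loss[5:15]) < 0.05))
})

test_that("evaluation accuracy is the fraction of correct predictions", {
  fx <- tiny_trained_model()
  ev <- evaluate_classifier(fx$model, fx$blobs$images[1:4],
                            c("classI", "classI", "classI", "classI"))
  expect_equal(ev$accuracy, 1.0)
  flipped <- evaluate_classifier(fx$model, fx$blobs$images[1:4],
                                 rep("classII", 4))
  expect_equal(flipped$accuracy, 0.0)
})
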