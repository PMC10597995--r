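test_that("channel gradients have the closed form w/(H*W) on active channels", {
  fx <- tiny_trained_model()
  m <- fx$model
  img <- fx$blobs$images[[1]]
  G <- channel_gradients(m, img, target_class = "classII", score = "logit")
  A <- attr(G, "activations")
  d <- dim(A)
  w <- m$params$fc_w[2, ]
  for (ch in seq_len(d[3])) {
    expected <- ifelse(A[, , ch] > 0, w[ch] / (d[1] * d[2]), 0)
    expect_equal(G[, , ch], expected, tolerance = 1e-12)
  }
})

test_that("a channel disconnected from the head has identically zero gradient", {
  fx <- tiny_trained_model()
  m <- fx$model
  m$params$fc_w[, 3] <- 0
  G <- channel_gradients(m, fx$blobs$images[[2]], target_class = "classII")
  expect_true(all(G[, , 3] == 0))
})

test_that("backprop channel gradients match finite differences of the head score", {
  fx <- tiny_trained_model()
  m <- fx$model
  img <- fx$blobs$images[[5]]
  for (sc in c("logit", "prob")) {
    G <- channel_gradients(m, img, target_class = 2, score = sc)
    A <- attr(G, "activations")
    set.seed(31)
    eps <- 1e-5
    for (t in 1:10) {
      k <- sample(length(A), 1)
      Ap <- A; Ap[k] <- A[k] + eps
      Am <- A; Am[k] <- A[k] - eps
      num <- (cephcam:::head_forward(m, Ap, 2, sc) -
                cephcam:::head_forward(m, Am, 2, sc)) / (2 * eps)
      denom <- max(abs(num), abs(G[k]), 1e-10)
      expect_lt(abs(num - G[k]) / denom, 1e-4)
    }
  }
})

test_that("weighted activations follow Mi = Gi * ReLU(Ai)", {
  A <- array(c(-1, -2, -0.5, -3), dim = c(2, 2, 1))
  G <- array(2, dim = c(2, 2, 1))
  expect_equal(weighted_activations(G, A), array(0, dim = c(2, 2, 1)))
  expect_equal(weighted_activations(array(0, dim = dim(A)), abs(A)),
               array(0, dim = c(2, 2, 1)))
  expect_equal(weighted_activations(array(2, dim = c(1, 1, 1)),
                                    array(3, dim = c(1, 1, 1)))[1, 1, 1], 6)
  expect_error(weighted_activations(array(1, c(2, 2, 1)),
                                    array(1, c(3, 3, 1))), "mismatch")
})

test_that("channel combination matches hand arithmetic and handles degenerate maps", {
  # two channels of hand-written 2x2 grids
  M1 <- matrix(c(0.2, 0.4, 0.6, 0.8), 2, 2)
  M2 <- matrix(c(1, 0, 0, 1), 2, 2)
  Mi <- array(c(M1, M2), dim = c(2, 2, 2))
  a1 <- mean(M1); a2 <- mean(M2)
  hand <- pmax(a1 * M1 + a2 * M2, 0)
  hand <- (hand - min(hand)) / (max(hand) - min(hand))
  expect_equal(combine_channels(Mi), hand, tolerance = 1e-12)

  expect_equal(combine_channels(array(0, c(2, 2, 3))), matrix(0, 2, 2))
  expect_error(combine_channels(array(1, c(2, 2, 0))), "at least one")

  # upsampling returns the requested resolution in [0, 1]
  up <- combine_channels(Mi, out_size = 8)
  expect_equal(dim(up), c(8, 8))
  expect_true(all(up >= 0 & up <= 1))
})

test_that("scaling all Mi by lambda leaves the normalized map unchanged", {
  set.seed(12)
  Mi <- array(runif(4 * 4 * 3), dim = c(4, 4, 3))
  base <- combine_channels(Mi)
  for (lam in c(0.1, 3, 42)) {
    expect_equal(combine_channels(lam * Mi), base, tolerance = 1e-9)
  }
  # and the pre-normalization map scales by lambda^2: check via the
  # single-channel constant case alpha * Mi = c^2
  Mc <- array(0.5, dim = c(2, 2, 1))
  alpha <- mean(Mc)
  expect_equal(alpha * Mc[1, 1, 1], 0.25)
})

test_that("saliency maps are normalized and peak at one for non-degenerate inputs", {
  fx <- tiny_trained_model()
  s <- saliency_map(fx$model, fx$blobs$images[[25]])
  expect_equal(dim(s), c(16, 16))
  expect_true(all(s >= 0 & s <= 1))
  expect_equal(max(s), 1)
})

test_that("score-cam variant reduces to the normalized activation for one live channel", {
  fx <- tiny_trained_model()
  m <- fx$model
  img <- fx$blobs$images[[30]]
  # silence all but one channel of the last conv layer
  keep <- 2
  for (ch in seq_len(dim(m$params$conv_w[[2]])[4])) {
    if (ch != keep) {
      m$params$gamma[[2]][ch] <- 0
      m$params$beta[[2]][ch] <- -10  # force dead (negative pre-ReLU)
    }
  }
  s <- scorecam_map(m, img, target_class = 2)
  A <- last_conv_activations(m, img)
  up <- img_resize(pmax(A[, , keep], 0), 16)
  up <- up / max(up)
  expect_equal(unclass(s)[, ], cephcam:::minmax(pmax(up, 0)),
               tolerance = 1e-6)

  # all channels dead -> zero map
  for (ch in seq_len(dim(m$params$conv_w[[2]])[4])) {
    m$params$gamma[[2]][ch] <- 0
    m$params$beta[[2]][ch] <- -10
  }
  s0 <- scorecam_map(m, img, target_class = 2)
  expect_true(all(s0 == 0))
})

test_that("cohort explanation emits one map per predicted-positive image", {
  fx <- tiny_trained_model()
  imgs <- setNames(fx$blobs$images, sprintf("im%02d", seq_along(fx$blobs$images)))
  maps <- explain_cohort(fx$model, imgs)
  preds <- attr(maps, "predictions")
  expect_equal(length(maps), sum(preds$predicted == "classII"))
  expect_true(all(names(maps) %in% preds$id[preds$predicted == "classII"]))
  for (s in maps[1:3]) {
    expect_true(all(s >= 0 & s <= 1))
    expect_equal(max(s), 1)
  }
  # cohort with no positives -> empty with warning
  neg <- imgs[preds$predicted == "classI"][1:5]
  expect_warning(m0 <- explain_cohort(fx$model, neg), "no positive")
  expect_length(m0, 0)
})
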