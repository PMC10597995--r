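test_that("global map equals the brute-force pixelwise mean", {
  set.seed(21)
  maps <- lapply(1:20, function(i) matrix(runif(64), 8, 8))
  G <- global_map(maps)
  expect_equal(G$G, brute_mean(maps), tolerance = 1e-7)
  expect_equal(G$n, 20L)

  # identical maps -> the map itself; two constants -> their midpoint
  m0 <- matrix(0.42, 4, 4)
  expect_equal(global_map(list(m0, m0, m0))$G, m0)
  expect_equal(global_map(list(matrix(0, 2, 2), matrix(1, 2, 2)))$G,
               matrix(0.5, 2, 2))
  expect_error(global_map(list()), "no maps")
})

test_that("averaging is linear over cohort concatenation and stays in [0,1]", {
  set.seed(22)
  a <- lapply(1:7, function(i) matrix(runif(36), 6, 6))
  b <- lapply(1:13, function(i) matrix(runif(36), 6, 6))
  Gab <- global_map(c(a, b))$G
  Ga <- global_map(a)$G
  Gb <- global_map(b)$G
  expect_equal(Gab, (7 * Ga + 13 * Gb) / 20, tolerance = 1e-7)
  expect_true(all(Gab >= 0 & Gab <= 1))
})

test_that("averaged skull is the renormalized mean image", {
  # all-0 plus all-1 averages to a constant 0.5, which the display
  # renormalization maps to zeros (constant-image convention)
  imgs <- list(matrix(0, 3, 3), matrix(1, 3, 3))
  expect_equal(brute_mean(imgs), matrix(0.5, 3, 3))
  expect_equal(averaged_skull(imgs), matrix(0, 3, 3))
  set.seed(23)
  ims <- lapply(1:5, function(i) matrix(runif(25), 5, 5))
  expect_equal(averaged_skull(ims), cephcam:::minmax(brute_mean(ims)),
               tolerance = 1e-12)
  img <- matrix(runif(9), 3, 3)
  expect_equal(averaged_skull(list(img, img)), cephcam:::minmax(img))
})

test_that("severity maps partition by bin and report empty bins", {
  set.seed(24)
  maps <- lapply(1:30, function(i) matrix(runif(16), 4, 4))
  ANB <- c(rep(6.5, 10), rep(7.5, 10), rep(9.5, 10))
  sm <- severity_maps(maps, ANB)
  expect_equal(names(sm$maps), c("[6,7)", "[7,8)", "[9,Inf)"))
  expect_equal(sm$empty_bins, "[8,9)")
  expect_equal(unname(sm$counts), c(10L, 10L, 0L, 10L))
  expect_equal(sm$maps[["[7,8)"]]$G, brute_mean(maps[11:20]),
               tolerance = 1e-7)
  expect_error(severity_maps(maps[1:2], c(2, 3)), "empty")
})

test_that("thresholding keeps the boundary and counts by enumeration", {
  expect_equal(sum(threshold_map(matrix(0.2, 5, 5))$mask), 0)
  m <- matrix(c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8, 0.9), 3, 3)
  tm <- threshold_map(m, 0.3)
  expect_equal(sum(tm$mask), 7L)          # values >= 0.3
  expect_true(tm$mask[which(m == 0.3)])   # exactly 0.3 is retained
  expect_equal(sort(tm$retained), seq(0.3, 0.9, by = 0.1))
})

test_that("class score and hot surface follow their definitions", {
  G <- matrix(0.6, 4, 4)
  region <- matrix(TRUE, 4, 4)
  expect_equal(as.numeric(class_score(G, region)), 0.6)
  expect_false(attr(class_score(G, region), "flagged"))

  cold <- matrix(0.1, 4, 4)
  cs <- class_score(cold, region)
  expect_equal(as.numeric(cs), 0)
  expect_true(attr(cs, "flagged"))
  expect_equal(hot_surface(cold, region), 0)

  half <- matrix(c(rep(0.4, 8), rep(0.8, 8)), 4, 4)
  expect_equal(as.numeric(class_score(half, region)), 0.6)
  expect_equal(hot_surface(half, region), 1)

  mixed <- matrix(c(rep(0.2, 8), rep(0.8, 8)), 4, 4)
  expect_equal(hot_surface(mixed, region), 0.5)
  expect_equal(as.numeric(class_score(mixed, region)), 0.8)
  # all-pixel averaging mode
  expect_equal(as.numeric(class_score(mixed, region, mode = "all")), 0.5)

  expect_error(class_score(G, matrix(TRUE, 3, 3)), "shape")
  expect_error(hot_surface(G, matrix(FALSE, 4, 4)), "empty region")
})

test_that("metric bounds hold on random maps", {
  set.seed(25)
  region <- matrix(FALSE, 6, 6); region[2:5, 2:5] <- TRUE
  for (i in 1:30) {
    G <- matrix(runif(36), 6, 6)
    cs <- as.numeric(class_score(G, region))
    hs <- hot_surface(G, region)
    expect_true(hs >= 0 && hs <= 1)
    expect_true(cs == 0 || (cs >= 0.3 && cs <= 1))
    if (hs > 0) expect_gte(cs, 0.3)
  }
})

test_that("alignment mode none is the identity; rigid recovers planted shifts", {
  set.seed(26)
  maps <- lapply(1:3, function(i) matrix(runif(64 * 64), 64, 64))
  al <- align_maps(maps, mode = "none")
  expect_identical(al$maps, maps)
  expect_length(al$excluded, 0)

  # single map aligns to itself
  ref <- generate_sample(phantom_params(image_size = 64, severity = 3,
                                        seed = 2))$image
  al1 <- align_maps(list(ref * 0 + 1), images = list(ref), reference = ref,
                    mode = "rigid")
  expect_equal(al1$transforms$dx, 0)
  expect_equal(al1$transforms$dy, 0)

  # planted integer shift is recovered within 1 px
  for (sh in list(c(5, 3), c(-4, 6), c(0, -7))) {
    shifted <- cephcam:::shift_matrix(ref, sh[1], sh[2])
    al <- align_maps(list(shifted), images = list(shifted),
                     reference = ref, mode = "rigid")
    expect_lte(abs(al$transforms$dx[1] - sh[1]), 1)
    expect_lte(abs(al$transforms$dy[1] - sh[2]), 1)
    # applying the alignment moves the map back onto the reference
    realigned <- al$maps[[1]]
    inner <- 15:50
    expect_gt(cor(as.numeric(realigned[inner, inner]),
                  as.numeric(ref[inner, inner])), 0.95)
  }
})

test_that("uncorrelated images are excluded with a warning in rigid mode", {
  set.seed(27)
  ref <- matrix(runif(32 * 32), 32, 32)
  junk <- matrix(runif(32 * 32), 32, 32)
  expect_warning(
    al <- align_maps(list(junk), images = list(junk), reference = ref,
                     mode = "rigid", corr_floor = 0.5),
    "excluded")
  expect_equal(al$excluded, 1L)
  expect_length(al$maps, 0)
})

test_that("top-fraction masks and the permutation IoU baseline behave sanely", {
  set.seed(28)
  G <- matrix(runif(400), 20, 20)
  tm <- top_fraction_mask(G, 0.1)
  expect_equal(sum(tm), 40L)
  target <- matrix(FALSE, 20, 20); target[1:10, 1:10] <- TRUE
  # a candidate equal to the target has IoU 1, far above chance
  res <- iou_random_baseline(target, target, n_perm = 100, seed = 1)
  expect_equal(res$iou, 1)
  expect_lt(res$baseline_q95, 1)
  expect_gt(res$iou, res$baseline_mean)
})
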