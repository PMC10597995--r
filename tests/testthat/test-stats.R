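test_that("mixed ANOVA matches an independent sums-of-squares oracle", {
  # hand-sized balanced table: 2 bins x 2 regions x 3 subjects per bin
  set.seed(41)
  tab <- simulate_metric_table(n_per_bin = 3, bins = c("b1", "b2"),
                               regions = c("r1", "r2"), bin_slope = 0.05,
                               region_offsets = c(0, 0.08),
                               subject_sd = 0.03, noise_sd = 0.02, seed = 5)
  res <- mixed_anova(tab)
  or <- oracle_split_plot(tab)
  eff <- res$effects
  expect_equal(eff$F[eff$effect == "angle"], unname(or$F["angle"]),
               tolerance = 1e-9)
  expect_equal(eff$F[eff$effect == "structure"], unname(or$F["structure"]),
               tolerance = 1e-9)
  expect_equal(eff$F[eff$effect == "interaction"],
               unname(or$F["interaction"]), tolerance = 1e-9)
  expect_equal(eff$p, unname(or$p[c("angle", "structure", "interaction")]),
               tolerance = 1e-9)
  expect_equal(eff$df1, unname(or$df[c("bin", "region", "interaction")]))
  expect_equal(eff$df2, unname(or$df[c("subj", "error", "error")]))
  # sums of squares are conserved
  expect_equal(sum(or$ss[c("bin", "subj", "region", "interaction",
                           "error")]),
               unname(or$ss["total"]), tolerance = 1e-9)
})

test_that("mixed ANOVA agrees with the oracle on a larger balanced design", {
  tab <- simulate_metric_table(n_per_bin = 8, bin_slope = 0.02,
                               region_offsets = c(0, 0.05, -0.03, 0.1),
                               seed = 9)
  res <- mixed_anova(tab)
  or <- oracle_split_plot(tab)
  expect_equal(res$effects$F,
               unname(or$F[c("angle", "structure", "interaction")]),
               tolerance = 1e-9)
  # marginal means reproduce simple group averages
  mm <- res$marginal_means$bin
  for (i in seq_len(nrow(mm)))
    expect_equal(mm$value[i], mean(tab$value[tab$bin == mm$bin[i]]))
})

test_that("constant tables are reported as zero-F with a flag", {
  tab <- expand.grid(subject = sprintf("s%02d", 1:8),
                     region = c("r1", "r2"), stringsAsFactors = FALSE)
  tab$bin <- ifelse(as.integer(substring(tab$subject, 2)) <= 4, "b1", "b2")
  tab$value <- 0.5
  res <- mixed_anova(tab)
  expect_true(all(res$effects$F == 0))
  expect_true(all(res$effects$p == 1))
  expect_true(all(res$effects$flagged))
})

test_that("incomplete designs are rejected naming the subject", {
  tab <- simulate_metric_table(n_per_bin = 3, bins = c("b1", "b2"),
                               regions = c("r1", "r2"), seed = 2)
  tab <- tab[-2, ]  # drop one region for subject s0001
  expect_error(mixed_anova(tab), "s0001")
  expect_error(mixed_anova(data.frame(subject = 1, bin = "a",
                                      region = "r", value = 1)),
               "at least 2")
})

test_that("Bonferroni adjustment is min(1, p*m), monotone, never below raw p", {
  expect_equal(bonferroni_adjust(0.01, 5), 0.05)
  expect_equal(bonferroni_adjust(0.5, 4), 1.0)
  expect_equal(bonferroni_adjust(c(0.2, 0.04), 1), c(0.2, 0.04))
  set.seed(3)
  p <- runif(20)
  for (m in c(1, 3, 10)) {
    adj <- bonferroni_adjust(p, m)
    expect_true(all(adj >= p))
    expect_true(all(adj <= 1))
    # monotone in p (ties allowed once capped at 1)
    expect_true(all(diff(adj[order(p)]) >= -1e-12))
  }
  expect_error(bonferroni_adjust(1.4, 2), "p")
})

test_that("post hoc bin comparisons adjust over the family of all pairs", {
  tab <- simulate_metric_table(n_per_bin = 10, bin_slope = 0.06,
                               subject_sd = 0.01, noise_sd = 0.02,
                               seed = 11)
  ph <- posthoc_bins(tab)
  expect_equal(nrow(ph), choose(4, 2))
  expect_equal(ph$p_adj, pmin(1, ph$p * 6))
  # the extreme-bin contrast has the largest estimate and rejects
  extreme <- ph[ph$bin1 == "[6,7)" & ph$bin2 == "[9,Inf)", ]
  expect_equal(extreme$estimate, max(ph$estimate), tolerance = 1e-9)
  expect_lt(extreme$p_adj, 0.05)
})

test_that("planted monotone severity effects are detected with high power", {
  n_rej <- 0
  for (r in 1:50) {
    tab <- simulate_metric_table(n_per_bin = 10, bin_slope = 0.03,
                                 subject_sd = 0.02, noise_sd = 0.04,
                                 seed = 7000 + r)
    res <- mixed_anova(tab)
    p <- res$effects$p[res$effects$effect == "angle"]
    if (p < 0.05) n_rej <- n_rej + 1
  }
  expect_gt(n_rej / 50, 0.8)
})

test_that("report bundle round-trips through JSON and writes one panel per bin", {
  dir <- withr::local_tempdir()
  tab <- simulate_metric_table(n_per_bin = 4, bin_slope = 0.05, seed = 13)
  res <- list(class_score = mixed_anova(tab, value = "value"))
  maps <- lapply(1:12, function(i) matrix(runif(16), 4, 4))
  sm <- severity_maps(maps, ANB = rep(c(6.5, 7.5, 8.5), each = 4))
  paths <- write_report(res, tab, sm, dir = dir)
  expect_true(file.exists(file.path(dir, "summary.json")))
  js <- jsonlite::read_json(file.path(dir, "summary.json"),
                            simplifyVector = TRUE)
  expect_equal(js$class_score$effects$F,
               res$class_score$effects$F, tolerance = 1e-9)
  expect_equal(js$class_score$means_by_bin$value,
               res$class_score$marginal_means$bin$value, tolerance = 1e-9)
  # one heat-map panel per non-empty severity bin
  pngs <- list.files(dir, pattern = "^map_.*png$")
  expect_length(pngs, 3)
  # marginal means in the report equal group means recomputed from the CSV
  means <- read.csv(file.path(dir, "means_by_bin_class_score.csv"))
  met <- read.csv(file.path(dir, "metrics.csv"))
  for (i in seq_len(nrow(means)))
    expect_equal(means$value[i],
                 mean(met$value[met$bin == means$bin[i]]), tolerance = 1e-9)
})
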