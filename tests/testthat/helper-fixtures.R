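# Shared fixtures, built once per test run.

# trivially separable two-blob image set (bright blob left vs right)
make_blob_image <- function(side, seed, n = 16, noise = 0.02) {
  cephcam:::with_seed(seed, {
    img <- matrix(0.1, n, n)
    cc <- if (side == 1) 2:(n %/% 2 - 1) else (n %/% 2 + 2):(n - 1)
    img[(n %/% 4):(3 * n %/% 4), cc] <- 0.9
    img + matrix(rnorm(n * n, 0, noise), n, n)
  })
}

make_blob_set <- function(n_per_class = 20, n = 16) {
  imgs <- c(lapply(seq_len(n_per_class), function(i) make_blob_image(1, i, n)),
            lapply(seq_len(n_per_class), function(i)
              make_blob_image(2, 1000 + i, n)))
  list(images = imgs,
       labels = rep(c("classI", "classII"), each = n_per_class))
}

# small trained model on the blob set, cached across test files
.fixture_env <- new.env(parent = emptyenv())

tiny_trained_model <- function() {
  if (is.null(.fixture_env$model)) {
    blobs <- make_blob_set(20)
    cfg <- model_config(n_conv_layers = 2, channels = c(4, 8),
                        pool_after = 1, input_size = 16)
    m <- build_model(cfg, seed = 1)
    m <- train_classifier(m, blobs$images, blobs$labels,
                          train_config(epochs = 25, batch_size = 8,
                                       augment = FALSE, seed = 3))
    .fixture_env$model <- m
    .fixture_env$blobs <- blobs
  }
  list(model = .fixture_env$model, blobs = .fixture_env$blobs)
}

# independent brute-force elementwise mean
brute_mean <- function(mats) {
  out <- mats[[1]] * 0
  for (m in mats) out <- out + m
  out / length(mats)
}

# independent two-argument-arctangent angle oracle (degrees at vertex N)
oracle_angle <- function(N, P, Q) {
  a1 <- atan2(P[2] - N[2], P[1] - N[1])
  a2 <- atan2(Q[2] - N[2], Q[1] - N[1])
  d <- abs(a1 - a2) * 180 / pi
  if (d > 180) d <- 360 - d
  d
}

# independent split-plot sums-of-squares decomposition (balanced designs)
oracle_split_plot <- function(df) {
  df$subject <- factor(df$subject); df$bin <- factor(df$bin)
  df$region <- factor(df$region)
  gm <- mean(df$value)
  n_b <- nlevels(df$bin); n_r <- nlevels(df$region)
  subj <- unique(df[, c("subject", "bin")])
  n_s <- nrow(subj) / n_b             # subjects per bin (balanced)
  mean_bin <- tapply(df$value, df$bin, mean)
  mean_reg <- tapply(df$value, df$region, mean)
  mean_subj <- tapply(df$value, df$subject, mean)
  mean_cell <- tapply(df$value, list(df$bin, df$region), mean)
  ss_bin <- n_s * n_r * sum((mean_bin - gm)^2)
  ss_subj_within <- n_r * sum((mean_subj -
                                 mean_bin[subj$bin[match(names(mean_subj),
                                                         subj$subject)]])^2)
  ss_reg <- n_s * n_b * sum((mean_reg - gm)^2)
  ss_int <- n_s * sum((sweep(sweep(mean_cell, 1, mean_bin), 2,
                             mean_reg) + gm)^2)
  ss_tot <- sum((df$value - gm)^2)
  ss_err <- ss_tot - ss_bin - ss_subj_within - ss_reg - ss_int
  df_bin <- n_b - 1
  df_subj <- n_b * (n_s - 1)
  df_reg <- n_r - 1
  df_int <- df_bin * df_reg
  df_err <- df_subj * df_reg
  F_bin <- (ss_bin / df_bin) / (ss_subj_within / df_subj)
  F_reg <- (ss_reg / df_reg) / (ss_err / df_err)
  F_int <- (ss_int / df_int) / (ss_err / df_err)
  list(ss = c(bin = ss_bin, subj = ss_subj_within, region = ss_reg,
              interaction = ss_int, error = ss_err, total = ss_tot),
       F = c(angle = F_bin, structure = F_reg, interaction = F_int),
       df = c(bin = df_bin, subj = df_subj, region = df_reg,
              interaction = df_int, error = df_err),
       p = c(angle = stats::pf(F_bin, df_bin, df_subj, lower.tail = FALSE),
             structure = stats::pf(F_reg, df_reg, df_err,
                                   lower.tail = FALSE),
             interaction = stats::pf(F_int, df_int, df_err,
                                     lower.tail = FALSE)))
}
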