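#' Mixed two-way (split-plot) ANOVA on an ROI metric table
#'
#' Severity bin is the between-subjects factor, anatomical structure the
#' within-subjects factor; the bin effect is tested against the
#' subject-within-bin error stratum and the structure and interaction
#' effects against the subject-by-structure stratum (classical split-plot
#' decomposition, fitted with `aov` and an `Error(subject/region)` term).
#' A completely constant response yields zero sums of squares; such
#' effects are reported with F = 0, p = 1 and flagged.
#'
#' @param table data frame with columns `subject`, `bin`, `region` and the
#'   metric column; the within-subject design must be complete (every
#'   subject measured in every region exactly once) and each subject must
#'   sit in exactly one bin.
#' @param value name of the metric column.
#' @return object of class `anova_result`: list with `effects` (data
#'   frame: effect, df1, df2, ss, F, p, flagged), `marginal_means` (per
#'   bin and per region), `posthoc` (Bonferroni-adjusted pairwise bin
#'   comparisons), `n_subjects`.
#' @export
mixed_anova <- function(table, value = "value") {
  stopifnot(is.data.frame(table),
            all(c("subject", "bin", "region", value) %in% names(table)))
  df <- data.frame(subject = factor(table$subject),
                   bin = factor(table$bin),
                   region = factor(table$region),
                   value = as.numeric(table[[value]]))
  if (nlevels(df$bin) < 2 || nlevels(df$region) < 2)
    stop("need at least 2 bins and 2 regions", call. = FALSE)
  # completeness: each subject x region exactly once
  tab <- table(df$subject, df$region)
  bad <- rownames(tab)[apply(tab != 1, 1, any)]
  if (length(bad) > 0)
    stop("incomplete within-subject design for subject(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  sub_bin <- unique(df[, c("subject", "bin")])
  if (anyDuplicated(sub_bin$subject) > 0)
    stop("subjects assigned to more than one bin", call. = FALSE)
  if (min(table(sub_bin$bin)) < 2)
    stop("need at least 2 subjects per bin", call. = FALSE)

  fit <- aov(value ~ bin * region + Error(subject / region), data = df)
  sm <- summary(fit)
  rows <- list()
  grab <- function(stratum_tab, effects) {
    st <- as.data.frame(stratum_tab[[1]])
    st$term <- trimws(rownames(st))
    resid <- st[st$term == "Residuals", ]
    for (ef in effects) {
      r <- st[st$term == ef, ]
      if (nrow(r) == 0) next
      f <- r[["F value"]]
      p <- r[["Pr(>F)"]]
      flag <- FALSE
      if (!is.finite(f) || r[["Sum Sq"]] < 1e-12) {
        f <- 0; p <- 1; flag <- TRUE
      }
      rows[[length(rows) + 1]] <<- data.frame(
        effect = ef, df1 = r$Df, df2 = resid$Df, ss = r[["Sum Sq"]],
        F = f, p = p, flagged = flag, stringsAsFactors = FALSE)
    }
  }
  nm <- names(sm)
  grab(sm[[grep("subject$", nm)]], "bin")
  grab(sm[[grep("subject:region", nm)]], c("region", "bin:region"))
  effects <- do.call(rbind, rows)
  effects$effect <- c(bin = "angle", region = "structure",
                      `bin:region` = "interaction")[effects$effect]

  mm_bin <- stats::aggregate(value ~ bin, df, mean)
  mm_region <- stats::aggregate(value ~ region, df, mean)
  structure(list(effects = effects,
                 marginal_means = list(bin = mm_bin, region = mm_region),
                 posthoc = posthoc_bins(df, value = "value"),
                 n_subjects = nlevels(df$subject)),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat("Mixed two-way ANOVA (", x$n_subjects, "subjects )\n")
  print(x$effects, row.names = FALSE)
  invisible(x)
}

#' Bonferroni adjustment
#'
#' `p_adj = min(1, p * m)` for a family of `m` comparisons.
#'
#' @param p numeric vector of raw p-values in \[0, 1\].
#' @param m number of comparisons in the family (default: `length(p)`).
#' @return adjusted p-values.
#' @export
bonferroni_adjust <- function(p, m = length(p)) {
  stopifnot(m >= 1, all(p >= 0 & p <= 1, na.rm = TRUE))
  pmin(1, p * m)
}

#' Pairwise post hoc comparisons between severity bins
#'
#' Welch t-tests on per-subject means (averaged over regions) for every
#' bin pair, Bonferroni-adjusted over the family of all pairs.
#'
#' @param table metric table as in [mixed_anova()].
#' @param value metric column name.
#' @return data frame: bin1, bin2, estimate, p, p_adj.
#' @export
posthoc_bins <- function(table, value = "value") {
  df <- data.frame(subject = factor(table$subject),
                   bin = factor(table$bin),
                   value = as.numeric(table[[value]]))
  subj <- stats::aggregate(value ~ subject + bin, df, mean)
  bins <- levels(df$bin)
  pairs <- utils::combn(bins, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- subj$value[subj$bin == pairs[1, j]]
    b <- subj$value[subj$bin == pairs[2, j]]
    # essentially-constant groups carry no evidence against the null
    p <- tryCatch(stats::t.test(b, a)$p.value, error = function(e) 1)
    data.frame(bin1 = pairs[1, j], bin2 = pairs[2, j],
               estimate = mean(b) - mean(a), p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- bonferroni_adjust(out$p, m = nrow(out))
  out
}

#' Simulate an ROI metric table
#'
#' Generative model mirroring the phantom study's metric structure: value
#' = baseline + bin slope + region offset + subject random intercept +
#' noise. Used for null calibration (slope and offsets 0) and power
#' analyses of the mixed ANOVA.
#'
#' @param n_per_bin subjects per severity bin.
#' @param bins bin labels.
#' @param regions region labels.
#' @param bin_slope additive increase per bin step.
#' @param region_offsets optional numeric vector (one per region).
#' @param subject_sd standard deviation of the subject random intercept.
#' @param noise_sd residual standard deviation.
#' @param baseline grand mean.
#' @param seed integer seed.
#' @return metric table with columns subject, bin, region, value.
#' @export
simulate_metric_table <- function(n_per_bin = 10, bins = bin_labels(),
                                  regions = c("cranial_base",
                                              "frontal_sinus", "parietal",
                                              "vertebrae"),
                                  bin_slope = 0, region_offsets = NULL,
                                  subject_sd = 0.02, noise_sd = 0.04,
                                  baseline = 0.45, seed = 1) {
  if (is.null(region_offsets)) region_offsets <- numeric(length(regions))
  with_seed(seed, {
    rows <- list()
    sid <- 0
    for (b in seq_along(bins)) {
      for (s in seq_len(n_per_bin)) {
        sid <- sid + 1
        u <- rnorm(1, 0, subject_sd)
        val <- baseline + bin_slope * (b - 1) + region_offsets + u +
          rnorm(length(regions), 0, noise_sd)
        rows[[sid]] <- data.frame(subject = sprintf("s%04d", sid),
                                  bin = bins[b], region = regions,
                                  value = val, stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
}

#' Write the analysis report bundle
#'
#' Writes the marginal-mean tables (CSV), the machine-readable JSON
#' summary, and one PNG heat-map panel per non-empty severity bin
#' (activation map over its averaged-skull backdrop).
#'
#' @param anova_results named list of `anova_result` objects (one per
#'   metric).
#' @param metrics the per-subject metric table ([roi_metrics()]).
#' @param sev_maps result of [severity_maps()] (optional).
#' @param dir output directory.
#' @return invisible character vector of written paths.
#' @export
write_report <- function(anova_results, metrics, sev_maps = NULL,
                         dir = "report") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  p <- file.path(dir, "metrics.csv")
  write.csv(metrics, p, row.names = FALSE)
  paths <- c(paths, p)
  summary <- list()
  for (nm in names(anova_results)) {
    res <- anova_results[[nm]]
    write.csv(res$marginal_means$bin,
              file.path(dir, paste0("means_by_bin_", nm, ".csv")),
              row.names = FALSE)
    write.csv(res$marginal_means$region,
              file.path(dir, paste0("means_by_region_", nm, ".csv")),
              row.names = FALSE)
    paths <- c(paths, file.path(dir, paste0("means_by_bin_", nm, ".csv")),
               file.path(dir, paste0("means_by_region_", nm, ".csv")))
    summary[[nm]] <- list(
      effects = res$effects,
      means_by_bin = res$marginal_means$bin,
      means_by_region = res$marginal_means$region,
      posthoc = res$posthoc)
  }
  jp <- file.path(dir, "summary.json")
  jsonlite::write_json(summary, jp, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  paths <- c(paths, jp)
  if (!is.null(sev_maps)) {
    for (lb in names(sev_maps$maps)) {
      gp <- file.path(dir, paste0("map_", gsub("[^0-9A-Za-z]", "_", lb),
                                  ".png"))
      save_overlay_png(sev_maps$maps[[lb]]$G,
                       sev_maps$maps[[lb]]$backdrop, gp)
      paths <- c(paths, gp)
    }
  }
  invisible(paths)
}
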