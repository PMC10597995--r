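#' End-to-end phantom study
#'
#' Runs the complete pipeline under synthetic-phantom study conditions:
#' generates a two-class cohort, standardizes the images, trains the CNN
#' on the first cross-validation fold (80/20), measures held-out
#' accuracy, builds the global activation map of the predicted Class II
#' test images and quantifies how well its top-decile pixels recover the
#' planted discriminative regions against a random-placement baseline;
#' then generates severity-binned cohorts over several seeds, computes
#' per-subject saliency maps and ROI metrics with the trained model, the
#' per-bin Spearman trends of class score and hot surface, and the mixed
#' two-way ANOVA on the first severity cohort.
#'
#' @param seed master seed; all randomness derives from it.
#' @param n_per_class cohort size per class for classifier training.
#' @param image_size phantom/classifier image side.
#' @param epochs training epochs.
#' @param n_per_bin subjects per severity bin in each severity cohort.
#' @param n_seeds number of severity-cohort seeds for the trend analysis.
#' @param top_q top fraction of saliency pixels used for region recovery.
#' @param verbose print progress.
#' @return list with elements `accuracy`, `iou` (observed, baseline mean
#'   and q95), `spearman` (per-seed data frame), `anova` (per metric),
#'   `bin_means`, `model`, `global` (global activation map), plus the
#'   training log.
#' @export
run_phantom_study <- function(seed = 1, n_per_class = 400,
                              image_size = 128, epochs = 30,
                              n_per_bin = 20, n_seeds = 5, top_q = 0.1,
                              verbose = FALSE) {
  pp <- phantom_params(image_size = image_size, seed = 1)
  pc <- preproc_config(target_size = image_size)
  say <- function(...) if (verbose) message(...)

  say("generating training cohort (", 2 * n_per_class, " phantoms)")
  cohort <- generate_cohort(c(classI = n_per_class, classII = n_per_class),
                            pp, seed = derive_seed(seed, 11))
  imgs <- lapply(cohort$samples, function(s) preprocess_image(s$image, pc))
  labels <- cohort$manifest$label

  folds <- make_cv_splits(labels, k = 5, seed = derive_seed(seed, 13))
  tr <- folds[[1]]$train
  te <- folds[[1]]$test

  say("training CNN (", epochs, " epochs)")
  model <- build_model(model_config(input_size = image_size),
                       seed = derive_seed(seed, 17))
  model <- train_classifier(model, imgs[tr], labels[tr],
                            train_config(epochs = epochs,
                                         seed = derive_seed(seed, 19)),
                            augment_config = pc, verbose = verbose)
  ev <- evaluate_classifier(model, imgs[te], labels[te])
  say("held-out accuracy: ", round(ev$accuracy, 4))

  say("saliency maps for predicted Class II test images")
  maps <- explain_cohort(model, setNames(imgs[te], cohort$manifest$id[te]))
  G <- global_map(lapply(maps, unclass),
                  backdrop = averaged_skull(imgs[te]))
  # planted discriminative regions: the severity-scaled structures plus
  # the jaws (which carry the geometric retrusion)
  te_c2 <- te[labels[te] == "classII"]
  planted <- consensus_masks(cohort$samples[te_c2])
  union_mask <- Reduce(`|`, planted)
  iou <- iou_random_baseline(top_fraction_mask(G, top_q), union_mask,
                             n_perm = 200, seed = derive_seed(seed, 23))

  say("severity cohorts (", n_seeds, " seeds x ", 4 * n_per_bin,
      " phantoms)")
  bins <- bin_labels()
  spear <- list()
  metrics1 <- NULL
  sevmaps1 <- NULL
  for (s in seq_len(n_seeds)) {
    co <- generate_cohort(setNames(rep(n_per_bin, 4), bins), pp,
                          seed = derive_seed(seed, 100 + s))
    im <- lapply(co$samples, function(x) preprocess_image(x$image, pc))
    sm <- explain_cohort(model, setNames(im, co$manifest$id))
    keep <- match(names(sm), co$manifest$id)
    masks <- consensus_masks(co$samples,
                             regions = setdiff(phantom_region_names,
                                               "jaws"))
    met <- roi_metrics(lapply(sm, unclass), masks,
                       bins = co$manifest$bin[keep])
    # per-bin means over subjects and planted structures
    bm_cs <- stats::aggregate(class_score ~ bin, met, mean)
    bm_hs <- stats::aggregate(hot_surface ~ bin, met, mean)
    ord_cs <- match(bins, bm_cs$bin)
    ord_hs <- match(bins, bm_hs$bin)
    spear[[s]] <- data.frame(
      seed = s,
      class_score = cor(seq_along(bins), bm_cs$class_score[ord_cs],
                        method = "spearman"),
      hot_surface = cor(seq_along(bins), bm_hs$hot_surface[ord_hs],
                        method = "spearman"))
    if (s == 1) {
      metrics1 <- met
      sevmaps1 <- severity_maps(lapply(sm, unclass),
                                co$manifest$ANB[keep])
    }
  }
  spearman <- do.call(rbind, spear)

  say("mixed two-way ANOVA on the first severity cohort")
  anova <- list(
    class_score = mixed_anova(metrics1, value = "class_score"),
    hot_surface = mixed_anova(metrics1, value = "hot_surface"))

  list(accuracy = ev$accuracy,
       iou = iou,
       spearman = spearman,
       anova = anova,
       metrics = metrics1,
       severity_maps = sevmaps1,
       global = G,
       model = model,
       n_test = length(te),
       n_maps = length(maps))
}
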