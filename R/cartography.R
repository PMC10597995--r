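#' Align saliency maps on their source images
#'
#' With `mode = "none"` (the default for pre-aligned cohorts) maps pass
#' through unchanged. With `mode = "rigid"` a translation (plus an
#' optional rotation searched over `rotations`) is estimated for each
#' source image against the reference by FFT cross-correlation, and the
#' inverse shift is applied to the corresponding map. Maps whose best
#' normalized correlation falls below `corr_floor` are excluded with a
#' warning.
#'
#' @param maps list of saliency matrices (shared shape).
#' @param images list of source images (same length/shape as `maps`),
#'   required for `mode = "rigid"`.
#' @param reference reference image; default = first image.
#' @param mode `"none"` or `"rigid"`.
#' @param rotations candidate rotation angles (degrees) searched in the
#'   rigid mode; `0` = translation only.
#' @param corr_floor minimum normalized cross-correlation.
#' @return list with `maps` (aligned), `transforms` (data frame: dx, dy,
#'   angle, correlation), `excluded` (indices).
#' @export
align_maps <- function(maps, images = NULL, reference = NULL,
                       mode = c("none", "rigid"), rotations = 0,
                       corr_floor = 0.2) {
  mode <- match.arg(mode)
  stopifnot(length(maps) >= 1)
  dims <- lapply(maps, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]])))
    stop("maps must share one shape", call. = FALSE)
  if (mode == "none")
    return(list(maps = maps,
                transforms = data.frame(dx = rep(0, length(maps)), dy = 0,
                                        angle = 0, correlation = NA_real_),
                excluded = integer(0)))
  stopifnot(!is.null(images), length(images) == length(maps))
  ref <- reference %||% images[[1]]
  tr <- vector("list", length(maps))
  out <- vector("list", length(maps))
  excluded <- integer(0)
  for (i in seq_along(maps)) {
    best <- list(corr = -Inf, dx = 0, dy = 0, angle = 0)
    for (ang in rotations) {
      img <- if (ang != 0) apply_rigid(images[[i]], angle = ang) else
        images[[i]]
      est <- xcorr_shift(ref, img)
      if (est$corr > best$corr)
        best <- list(corr = est$corr, dx = est$dx, dy = est$dy, angle = ang)
    }
    tr[[i]] <- data.frame(dx = best$dx, dy = best$dy, angle = best$angle,
                          correlation = best$corr)
    if (best$corr < corr_floor) {
      warning("map ", i, " excluded: correlation ",
              round(best$corr, 3), " below floor")
      excluded <- c(excluded, i)  # out[[i]] stays NULL
    } else {
      m <- maps[[i]]
      if (best$angle != 0) m <- apply_rigid(m, angle = best$angle)
      out[[i]] <- shift_matrix(m, -best$dx, -best$dy)
    }
  }
  keep <- setdiff(seq_along(maps), excluded)
  list(maps = out[keep], transforms = do.call(rbind, tr),
       excluded = excluded)
}

# estimates the displacement (dx right, dy down) of img relative to ref
# by the peak of the circular FFT cross-correlation, with the peak's
# normalized correlation value
xcorr_shift <- function(ref, img) {
  a <- ref - mean(ref); b <- img - mean(img)
  cc <- Re(fft(fft(b) * Conj(fft(a)), inverse = TRUE)) / length(a)
  peak <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  n <- dim(ref)
  wrap <- function(k, m) if (k - 1 > m / 2) k - 1 - m else k - 1
  denom <- sqrt(sum(a^2) * sum(b^2))
  list(dx = wrap(peak[2], n[2]), dy = wrap(peak[1], n[1]),
       corr = if (denom > 0) max(cc) / denom else 0)
}

# shift matrix content by (dx right, dy down), zero fill
shift_matrix <- function(m, dx, dy) {
  out <- matrix(0, nrow(m), ncol(m))
  sr <- seq_len(nrow(m)); sc <- seq_len(ncol(m))
  rs <- sr + dy; cs <- sc + dx
  ok_r <- rs >= 1 & rs <= nrow(m); ok_c <- cs >= 1 & cs <= ncol(m)
  out[rs[ok_r], cs[ok_c]] <- m[sr[ok_r], sc[ok_c]]
  out
}

#' Global activation map
#'
#' Pixelwise mean of N aligned saliency maps: `G = (1/N) sum_i S_i`.
#'
#' @param maps nonempty list of aligned saliency matrices.
#' @param stratum label carried in the result (e.g. a severity bin).
#' @param backdrop optional averaged-skull image ([averaged_skull()]).
#' @return object of class `global_map`: list with `G`, `n`, `stratum`,
#'   `backdrop`.
#' @export
global_map <- function(maps, stratum = "all", backdrop = NULL) {
  if (length(maps) == 0) stop("no maps to average", call. = FALSE)
  dims <- lapply(maps, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]])))
    stop("maps must share one shape", call. = FALSE)
  G <- Reduce(`+`, lapply(maps, unclass)) / length(maps)
  structure(list(G = G, n = length(maps), stratum = stratum,
                 backdrop = backdrop),
            class = "global_map")
}

#' @export
print.global_map <- function(x, ...) {
  cat("global_map (", x$stratum, "): mean of", x$n, "maps,",
      nrow(x$G), "x", ncol(x$G), "\n")
  invisible(x)
}

#' Averaged skull backdrop
#'
#' Pixelwise mean of the aligned source images, min-max renormalized for
#' display.
#'
#' @param images nonempty list of aligned grayscale matrices.
#' @return matrix in \[0, 1\].
#' @export
averaged_skull <- function(images) {
  if (length(images) == 0) stop("no images to average", call. = FALSE)
  minmax(Reduce(`+`, images) / length(images))
}

#' Severity-stratified global activation maps
#'
#' Partitions per-subject maps by the ANB severity bin and computes one
#' global activation map per non-empty bin; empty bins are reported, not
#' dropped silently.
#'
#' @param maps list of saliency matrices.
#' @param ANB numeric vector of ANB angles, one per map.
#' @param edges severity bin edges ([severity_bin()]).
#' @param backdrops optional named list of per-bin backdrops.
#' @return list with `maps` (named list of `global_map`), `empty_bins`
#'   (character), `counts` (named integer).
#' @export
severity_maps <- function(maps, ANB, edges = c(6, 7, 8, 9),
                          backdrops = NULL) {
  stopifnot(length(maps) == length(ANB))
  bins <- severity_bin(ANB, edges)
  labs <- bin_labels(edges)
  counts <- setNames(integer(length(labs)), labs)
  out <- list()
  for (lb in labs) {
    members <- which(!is.na(bins) & bins == lb)
    counts[lb] <- length(members)
    if (length(members) > 0)
      out[[lb]] <- global_map(maps[members], stratum = lb,
                              backdrop = backdrops[[lb]])
  }
  if (all(counts == 0))
    stop("all severity bins are empty", call. = FALSE)
  list(maps = out, empty_bins = labs[counts == 0], counts = counts)
}

as_map_matrix <- function(G) {
  if (inherits(G, "global_map")) G$G else unclass(G)
}

#' Suprathreshold mask of an activation map
#'
#' Pixels below the threshold are eliminated; the boundary is kept
#' (values exactly equal to the threshold are retained).
#'
#' @param G activation map matrix (in \[0, 1\]) or `global_map`.
#' @param threshold discriminating-pixel threshold.
#' @return list with `mask` (logical matrix) and `retained` (numeric
#'   vector of the surviving values).
#' @export
threshold_map <- function(G, threshold = 0.3) {
  G <- as_map_matrix(G)
  mask <- G >= threshold
  list(mask = mask, retained = G[mask])
}

check_region <- function(G, region) {
  if (!identical(dim(G), dim(region)))
    stop("region mask shape does not match the map", call. = FALSE)
  if (!any(region)) stop("empty region mask", call. = FALSE)
  invisible(TRUE)
}

#' Class score of a region
#'
#' Mean activation over the suprathreshold pixels inside the region. If no
#' region pixel reaches the threshold the score is 0 and flagged
#' (`attr(, "flagged")`). `mode = "all"` averages over all region pixels
#' instead (sensitivity analysis).
#'
#' @param G activation map (matrix or `global_map`).
#' @param region logical region mask, same shape.
#' @param threshold discriminating-pixel threshold.
#' @param mode `"suprathreshold"` (default) or `"all"`.
#' @return numeric score in `{0} U [threshold, 1]`, with attribute
#'   `flagged`.
#' @export
class_score <- function(G, region, threshold = 0.3,
                        mode = c("suprathreshold", "all")) {
  mode <- match.arg(mode)
  G <- as_map_matrix(G)
  check_region(G, region)
  vals <- G[region]
  if (mode == "all")
    return(structure(mean(vals), flagged = FALSE))
  hot <- vals[vals >= threshold]
  if (length(hot) == 0) return(structure(0, flagged = TRUE))
  structure(mean(hot), flagged = FALSE)
}

#' Hot surface of a region
#'
#' Fraction of the region's pixels whose activation reaches the
#' threshold.
#'
#' @inheritParams class_score
#' @return fraction in \[0, 1\].
#' @export
hot_surface <- function(G, region, threshold = 0.3) {
  G <- as_map_matrix(G)
  check_region(G, region)
  mean(G[region] >= threshold)
}

#' Per-subject (or per-bin) ROI metric table
#'
#' Applies [class_score()] and [hot_surface()] to each map and each
#' region, yielding the tidy table consumed by the mixed ANOVA.
#'
#' @param maps named list of activation maps (per subject, or per-bin
#'   global maps).
#' @param masks named list of logical region masks (shared across maps).
#' @param bins character vector: severity bin of each map (recycled).
#' @param threshold discriminating-pixel threshold.
#' @return data frame with columns subject, bin, region, class_score,
#'   hot_surface, flagged.
#' @export
roi_metrics <- function(maps, masks, bins = NA_character_, threshold = 0.3) {
  ids <- names(maps) %||% as.character(seq_along(maps))
  bins <- rep_len(bins, length(maps))
  rows <- list()
  for (i in seq_along(maps)) {
    for (rg in names(masks)) {
      cs <- class_score(maps[[i]], masks[[rg]], threshold)
      rows[[length(rows) + 1]] <-
        data.frame(subject = ids[i], bin = bins[i], region = rg,
                   class_score = as.numeric(cs),
                   hot_surface = hot_surface(maps[[i]], masks[[rg]],
                                             threshold),
                   flagged = attr(cs, "flagged"),
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Consensus region masks of a phantom cohort
#'
#' Pixelwise majority vote of the per-sample ground-truth masks, giving
#' one mask per region at map resolution.
#'
#' @param samples list of `phantom_sample` objects.
#' @param regions region names to include.
#' @return named list of logical matrices.
#' @export
consensus_masks <- function(samples,
                            regions = phantom_region_names) {
  stopifnot(length(samples) >= 1)
  setNames(lapply(regions, function(rg) {
    Reduce(`+`, lapply(samples, function(s) s$masks[[rg]] * 1)) /
      length(samples) > 0.5
  }), regions)
}

#' Intersection-over-union of two masks
#' @param a,b logical matrices.
#' @return IoU in \[0, 1\].
#' @export
mask_iou <- function(a, b) {
  u <- sum(a | b)
  if (u == 0) return(0)
  sum(a & b) / u
}

#' Top-fraction mask of an activation map
#'
#' Logical mask of the `q` highest-valued pixels (e.g. the top decile for
#' `q = 0.1`).
#'
#' @param G activation map.
#' @param q fraction of pixels to retain.
#' @return logical matrix.
#' @export
top_fraction_mask <- function(G, q = 0.1) {
  G <- as_map_matrix(G)
  k <- max(1, round(length(G) * q))
  thr <- sort(as.numeric(G), decreasing = TRUE)[k]
  G >= thr
}

#' Random-placement IoU baseline
#'
#' Distribution of the IoU between the target mask and random circular
#' translations of the candidate mask — the chance level for region
#' recovery at equal mask area.
#'
#' @param candidate logical mask (e.g. top-decile saliency pixels).
#' @param target logical mask (planted regions).
#' @param n_perm number of random placements.
#' @param seed integer seed.
#' @return list with `iou` (observed), `baseline` (numeric vector),
#'   `baseline_mean`, `baseline_q95`.
#' @export
iou_random_baseline <- function(candidate, target, n_perm = 200, seed = 1) {
  obs <- mask_iou(candidate, target)
  nr <- nrow(candidate); nc <- ncol(candidate)
  base <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      dy <- sample.int(nr, 1) - 1L
      dx <- sample.int(nc, 1) - 1L
      shifted <- candidate[((seq_len(nr) - 1L + dy) %% nr) + 1L,
                           ((seq_len(nc) - 1L + dx) %% nc) + 1L]
      mask_iou(shifted, target)
    }, numeric(1))
  })
  list(iou = obs, baseline = base, baseline_mean = mean(base),
       baseline_q95 = unname(stats::quantile(base, 0.95)))
}
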