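#' Parameters for the synthetic cephalogram phantom
#'
#' The phantom emulates the causal structure the analysis pipeline assumes
#' rather than anatomy: two classes separated by mandibular retrusion (the
#' B-point moves posteriorly with severity) plus secondary morphological
#' effects planted in named skull regions whose intensity/thickness grows
#' with severity. Severity maps affinely to the ANB angle,
#' `ANB = 4 + severity` degrees, so bin membership is exactly controllable;
#' the baseline geometry uses SNA = 80.5 and SNB = 76.5 - severity, hence
#' severity 0 is Class I and severity above 2 covers the Class II severity
#' bins (ANB >= 6).
#'
#' @param image_size image side in pixels (>= 32).
#' @param severity continuous severity >= 0 (degrees of ANB excess over 4).
#' @param planted_regions named vector of effect-size multipliers for the
#'   secondary regions (`cranial_base`, `frontal_sinus`, `parietal`,
#'   `vertebrae`); the `jaws` region always carries the geometric
#'   retrusion signal.
#' @param noise_sd standard deviation of additive Gaussian intensity noise
#'   (clipped to \[0, 1\]).
#' @param jitter length-2 numeric: maximum rigid translation (pixels) and
#'   rotation (degrees) applied to the whole sample; `c(0, 0)` keeps
#'   samples pre-aligned.
#' @param seed integer seed; the same seed gives bit-identical output.
#' @return an object of class `phantom_params`.
#' @export
phantom_params <- function(image_size = 256, severity = 0,
                           planted_regions = c(cranial_base = 1,
                                               frontal_sinus = 1,
                                               parietal = 1, vertebrae = 1),
                           noise_sd = 0.03, jitter = c(0, 0), seed = 1) {
  stopifnot(severity >= 0, noise_sd >= 0, length(jitter) == 2,
            all(jitter >= 0))
  if (image_size < 32)
    stop("image_size too small to place all structures (minimum 32)",
         call. = FALSE)
  known <- c("cranial_base", "frontal_sinus", "parietal", "vertebrae")
  eff <- setNames(numeric(4), known)
  eff[intersect(names(planted_regions), known)] <-
    planted_regions[intersect(names(planted_regions), known)]
  structure(list(image_size = as.integer(image_size), severity = severity,
                 planted_regions = eff, noise_sd = noise_sd,
                 jitter = as.numeric(jitter), seed = as.integer(seed)),
            class = "phantom_params")
}

phantom_region_names <- c("cranial_base", "frontal_sinus", "parietal",
                          "vertebrae", "jaws")

# landmark placement: S and N fixed, A and B placed on rays from N making
# the requested SNA/SNB angles with the N->S ray, on the inferior side
phantom_landmarks <- function(L, SNA, SNB) {
  S <- c(0.34, 0.32) * L
  N <- c(0.80, 0.34) * L
  u <- S - N
  phi0 <- atan2(u[2], u[1])
  place <- function(theta_deg, r) {
    th <- theta_deg * pi / 180
    cand1 <- N + r * c(cos(phi0 - th), sin(phi0 - th))
    cand2 <- N + r * c(cos(phi0 + th), sin(phi0 + th))
    if (cand1[2] > cand2[2]) cand1 else cand2  # inferior (larger y)
  }
  rbind(S = S, N = N, A = place(SNA, 0.36 * L), B = place(SNB, 0.52 * L))
}

dist_to_segment <- function(xg, yg, p1, p2) {
  vx <- p2[1] - p1[1]; vy <- p2[2] - p1[2]
  len2 <- vx^2 + vy^2
  t <- ((xg - p1[1]) * vx + (yg - p1[2]) * vy) / len2
  t <- pmin(pmax(t, 0), 1)
  sqrt((xg - (p1[1] + t * vx))^2 + (yg - (p1[2] + t * vy))^2)
}

ellipse_d <- function(xg, yg, ctr, rx, ry) {
  sqrt(((xg - ctr[1]) / rx)^2 + ((yg - ctr[2]) / ry)^2)
}

#' Generate one synthetic cephalogram sample
#'
#' Draws the phantom (cranial vault arc, cranial base band, frontal sinus,
#' vertebral column, jaws) on a dark background, plants severity-scaled
#' intensity/thickness perturbations in the configured regions, adds
#' Gaussian noise and optional rigid jitter, and returns the image together
#' with landmarks, per-region ground-truth masks and the true label.
#'
#' @param params a [phantom_params()].
#' @return an object of class `phantom_sample`: list with `image` (matrix
#'   in \[0,1\]), `landmarks` (4x2 matrix, rows S/N/A/B), `masks` (named
#'   list of logical matrices), `angles` (SNA/SNB/ANB), `true_class`,
#'   `true_severity` (degrees ANB), `bin`, and `params`.
#' @export
generate_sample <- function(params) {
  stopifnot(inherits(params, "phantom_params"))
  with_seed(params$seed, generate_sample_impl(params))
}

generate_sample_impl <- function(params) {
  L <- params$image_size
  sev <- params$severity
  eff <- params$planted_regions
  SNA <- 80.5
  SNB <- 76.5 - sev
  lm <- phantom_landmarks(L, SNA, SNB)
  xg <- matrix(rep(seq_len(L), each = L), L, L)   # column index (x)
  yg <- matrix(rep(seq_len(L), times = L), L, L)  # row index (y)

  canvas <- matrix(0.05, L, L)
  masks <- list()
  put <- function(canvas, where, value) {
    canvas[where] <- pmax(canvas[where], value)
    canvas
  }

  # cranial vault (ellipse band); upper-left quadrant = parietal analogue
  vc <- c(0.52, 0.42) * L
  dv <- ellipse_d(xg, yg, vc, 0.36 * L, 0.30 * L)
  upper_left <- xg < vc[1] & yg < vc[2]
  w_v <- 0.055
  w_par <- w_v * (1 + 0.10 * sev * eff["parietal"])
  vault <- abs(dv - 1) < w_v & !upper_left
  parietal <- abs(dv - 1) < w_par & upper_left
  canvas <- put(canvas, vault, 0.50)
  canvas <- put(canvas, parietal, 0.50 + 0.025 * sev * eff["parietal"])
  masks$parietal <- parietal

  # cranial base: band from sella towards a point just below nasion
  dcb <- dist_to_segment(xg, yg, lm["S", ], c(0.76, 0.40) * L)
  cbase <- dcb < max(0.016 * L, 1)
  canvas <- put(canvas, cbase, 0.45 + 0.02 * sev * eff["cranial_base"])
  masks$cranial_base <- cbase

  # frontal sinus: soft blob antero-superior to nasion
  fs_r <- pmax(c(0.035, 0.045) * L, 1.2) *
    (1 + 0.04 * sev * eff["frontal_sinus"])
  dfs <- ellipse_d(xg, yg, c(lm["N", 1] + 0.03 * L, 0.20 * L),
                   fs_r[1], fs_r[2])
  sinus <- dfs < 1
  canvas <- canvas + (0.30 + 0.035 * sev * eff["frontal_sinus"]) *
    exp(-dfs^2) * (dfs < 2)
  masks$frontal_sinus <- sinus

  # cervical vertebrae analogue: column of four bodies
  vert <- matrix(FALSE, L, L)
  for (k in 0:3) {
    dk <- ellipse_d(xg, yg, c(0.30 * L, (0.56 + 0.095 * k) * L),
                    max(0.035 * L, 1.2), max(0.030 * L, 1.2))
    vert <- vert | dk < 1
  }
  canvas <- put(canvas, vert, 0.38 + 0.030 * sev * eff["vertebrae"])
  masks$vertebrae <- vert

  # jaws: maxilla blob at A, mandibular body to B, chin at B (retruded
  # with severity through the landmark geometry itself)
  dmx <- ellipse_d(xg, yg, lm["A", ], max(0.045 * L, 1.2),
                   max(0.035 * L, 1.2))
  condyle <- lm["B", ] + c(-0.16, -0.14) * L
  dmd <- dist_to_segment(xg, yg, condyle, lm["B", ])
  dch <- ellipse_d(xg, yg, lm["B", ], max(0.032 * L, 1.2),
                   max(0.032 * L, 1.2))
  body <- dmd < max(0.020 * L, 1)
  jaws <- dmx < 1 | body | dch < 1
  canvas <- put(canvas, dmx < 1, 0.55)
  canvas <- put(canvas, body, 0.55)
  canvas <- put(canvas, dch < 1, 0.60)
  masks$jaws <- jaws

  masks <- masks[phantom_region_names]
  if (any(!vapply(masks, any, logical(1))))
    stop("image_size too small to place all structures", call. = FALSE)

  image <- clamp01(canvas +
                     if (params$noise_sd > 0)
                       matrix(rnorm(L * L, 0, params$noise_sd), L, L)
                     else 0)

  # optional rigid jitter of the whole sample (image, masks, landmarks)
  if (any(params$jitter > 0)) {
    dx <- runif(1, -params$jitter[1], params$jitter[1])
    dy <- runif(1, -params$jitter[1], params$jitter[1])
    ang <- runif(1, -params$jitter[2], params$jitter[2])
    image <- apply_rigid(image, angle = ang, dx = dx, dy = dy, fill = 0.05)
    masks <- lapply(masks, function(m)
      apply_rigid(m * 1, angle = ang, dx = dx, dy = dy, fill = 0) > 0.5)
    lm <- transform_points(lm, L, angle = ang, dx = dx, dy = dy)
    rownames(lm) <- c("S", "N", "A", "B")
  }

  ang <- compute_angles(lm)
  structure(list(image = image, landmarks = lm, masks = masks,
                 angles = ang,
                 true_class = classify_angles(ang["ANB"], ang["SNA"],
                                              ang["SNB"]),
                 true_severity = unname(ang["ANB"]),
                 # guard the half-open bin edges against float round-off
                 # in the angle recovery (well within the 0.1 deg contract)
                 bin = severity_bin(round(ang["ANB"], 6)),
                 params = params),
            class = "phantom_sample")
}

#' @export
print.phantom_sample <- function(x, ...) {
  cat("phantom_sample:", nrow(x$image), "x", ncol(x$image),
      "| class:", x$true_class, "| ANB:", round(x$angles["ANB"], 2),
      "| bin:", ifelse(is.na(x$bin), "none", x$bin), "\n")
  invisible(x)
}

# severity draw for a requested stratum (class label or bin label)
draw_severity <- function(stratum) {
  if (stratum == "classI") return(runif(1, 0, 0.4))
  if (stratum == "classII") return(runif(1, 6, 10.5) - 4)
  labs <- bin_labels()
  if (stratum %in% labs) {
    lo <- c(6, 7, 8, 9)[match(stratum, labs)]
    hi <- if (lo < 9) lo + 1 else 10.5
    return(runif(1, lo, hi) - 4)
  }
  stop("unknown stratum: ", stratum, call. = FALSE)
}

#' Generate a phantom cohort
#'
#' Generates `counts[i]` samples for each requested stratum (class labels
#' `classI`/`classII` or severity-bin labels such as `"[6,7)"`), with
#' per-sample seeds derived from `seed`. Optionally writes 8-bit grayscale
#' PNGs, region-label mask PNGs (ids 1-5) and a CSV manifest to `dir`.
#'
#' @param counts named integer vector/list of per-stratum sample counts;
#'   an empty request yields an empty manifest and writes nothing.
#' @param params template [phantom_params()] (severity and seed are
#'   overridden per sample).
#' @param seed integer master seed for the cohort.
#' @param dir optional output directory; `NULL` keeps the cohort in memory.
#' @return list with `manifest` (data frame: id, path, mask_path, SNA,
#'   SNB, ANB, label, bin, seed) and `samples` (named list of
#'   `phantom_sample`).
#' @export
generate_cohort <- function(counts, params = phantom_params(), seed = 1,
                            dir = NULL) {
  counts <- unlist(counts)
  if (length(counts) == 0 || sum(counts) == 0) {
    man <- data.frame(id = character(0), path = character(0),
                      mask_path = character(0), SNA = numeric(0),
                      SNB = numeric(0), ANB = numeric(0),
                      label = character(0), bin = character(0),
                      seed = integer(0), stringsAsFactors = FALSE)
    return(list(manifest = man, samples = list()))
  }
  stopifnot(all(counts >= 1), !is.null(names(counts)))
  strata <- rep(names(counts), times = counts)
  n <- length(strata)
  samples <- vector("list", n)
  rows <- vector("list", n)
  if (!is.null(dir)) dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(n)) {
    si <- derive_seed(seed, i)
    sev <- with_seed(derive_seed(seed, 500000 + i), draw_severity(strata[i]))
    p <- params
    p$severity <- sev
    p$seed <- si
    smp <- generate_sample(p)
    # the generator must reproduce the requested stratum exactly
    want_bin <- strata[i] %in% bin_labels()
    if (want_bin && !identical(smp$bin, strata[i]))
      stop("internal: generated bin ", smp$bin, " != requested ", strata[i])
    if (!want_bin && !identical(smp$true_class, strata[i]))
      stop("internal: generated class ", smp$true_class,
           " != requested ", strata[i])
    id <- sprintf("s%04d", i)
    path <- mask_path <- NA_character_
    if (!is.null(dir)) {
      path <- file.path(dir, paste0(id, ".png"))
      mask_path <- file.path(dir, paste0(id, "_mask.png"))
      png::writePNG(smp$image, path)
      lab <- matrix(0, nrow(smp$image), ncol(smp$image))
      for (k in seq_along(phantom_region_names))
        lab[smp$masks[[phantom_region_names[k]]]] <- k
      png::writePNG(lab / 255, mask_path)
    }
    samples[[i]] <- smp
    rows[[i]] <- data.frame(id = id, path = path, mask_path = mask_path,
                            SNA = smp$angles["SNA"], SNB = smp$angles["SNB"],
                            ANB = smp$angles["ANB"], label = smp$true_class,
                            bin = ifelse(is.na(smp$bin), NA_character_,
                                         smp$bin),
                            seed = si, stringsAsFactors = FALSE)
  }
  man <- do.call(rbind, rows)
  rownames(man) <- NULL
  names(samples) <- man$id
  if (!is.null(dir))
    write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  list(manifest = man, samples = samples)
}

#' Read masks from a label PNG written by [generate_cohort()]
#' @param path path to a `*_mask.png` label image.
#' @return named list of logical region masks.
#' @export
read_mask_png <- function(path) {
  lab <- round(png::readPNG(path) * 255)
  setNames(lapply(seq_along(phantom_region_names), function(k) lab == k),
           phantom_region_names)
}
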