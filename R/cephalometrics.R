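#' Cephalometric angles from the four Steiner landmarks
#'
#' Computes the SNA, SNB and ANB angles from a landmark set containing the
#' sella (S), nasion (N), maxillary A-point and mandibular B-point. SNA is
#' the (unsigned) angle at N between the rays N->S and N->A, SNB the
#' analogous angle towards B, and ANB is defined through the standard
#' identity ANB = SNA - SNB (signed).
#'
#' @param landmarks a matrix with rows named `"S"`, `"N"`, `"A"`, `"B"` and
#'   two columns (x, y pixel coordinates), or a named list of length-2
#'   numeric vectors.
#' @return named numeric vector with elements `SNA`, `SNB`, `ANB` (degrees).
#' @examples
#' lm <- rbind(S = c(0, 0), N = c(100, 0), A = c(150, 30), B = c(150, 45))
#' compute_angles(lm)
#' @export
compute_angles <- function(landmarks) {
  lm <- as_landmark_matrix(landmarks)
  v <- function(p) lm[p, ] - lm["N", ]
  ang <- function(p) {
    u <- v("S"); w <- v(p)
    if (sqrt(sum(w^2)) == 0) stop("coincident landmarks: N and ", p, call. = FALSE)
    atan2(u[1] * w[2] - u[2] * w[1], sum(u * w)) * 180 / pi
  }
  if (sqrt(sum(v("S")^2)) == 0) stop("coincident landmarks: S and N", call. = FALSE)
  sna <- abs(ang("A"))
  snb <- abs(ang("B"))
  c(SNA = unname(sna), SNB = unname(snb), ANB = unname(sna - snb))
}

as_landmark_matrix <- function(landmarks) {
  if (is.list(landmarks)) landmarks <- do.call(rbind, landmarks)
  landmarks <- as.matrix(landmarks)
  need <- c("S", "N", "A", "B")
  if (!all(need %in% rownames(landmarks)))
    stop("landmarks must contain rows S, N, A, B", call. = FALSE)
  storage.mode(landmarks) <- "double"
  if (any(!is.finite(landmarks[need, ])))
    stop("non-finite landmark coordinates", call. = FALSE)
  landmarks[need, 1:2, drop = FALSE]
}

#' Class I / Class II labeling from cephalometric angles
#'
#' Applies the study's labeling rules in precedence order: borderline
#' cases (-1 <= ANB <= 1) are excluded first; then Class II mandibular
#' retrognathia requires ANB > 4 and SNB < 76; then Class I (physiological)
#' requires ANB in \[0, 5\], SNA in \[79, 85\] and SNB < 77; anything else
#' (including the undefined gap ANB > 4 with 76 <= SNB < 77) is
#' `excluded_other`.
#'
#' @param ANB,SNA,SNB angles in degrees (vectorized).
#' @return character vector with values `"classI"`, `"classII"`,
#'   `"excluded_borderline"`, `"excluded_other"`.
#' @examples
#' classify_angles(ANB = 7, SNA = 81, SNB = 74)    # classII
#' classify_angles(ANB = 0.5, SNA = 80, SNB = 76.5) # excluded_borderline
#' @export
classify_angles <- function(ANB, SNA, SNB) {
  n <- max(length(ANB), length(SNA), length(SNB))
  ANB <- rep_len(ANB, n); SNA <- rep_len(SNA, n); SNB <- rep_len(SNB, n)
  if (any(!is.finite(c(ANB, SNA, SNB))))
    stop("angles must be finite", call. = FALSE)
  out <- rep("excluded_other", n)
  is_c1 <- ANB >= 0 & ANB <= 5 & SNA >= 79 & SNA <= 85 & SNB < 77
  is_c2 <- ANB > 4 & SNB < 76
  is_bl <- ANB >= -1 & ANB <= 1
  out[is_c1] <- "classI"
  out[is_c2] <- "classII"
  out[is_bl] <- "excluded_borderline"
  out
}

#' Steiner-style severity bin of the ANB angle
#'
#' Class II subjects are stratified by ANB into half-open bins, by default
#' \[6,7), \[7,8), \[8,9), \[9,Inf). Angles below the lowest edge fall in no
#' bin (`NA`).
#'
#' @param ANB angle in degrees (vectorized).
#' @param edges increasing numeric vector of lower bin edges; the last bin
#'   is open-ended.
#' @return character vector of bin labels such as `"[8,9)"`, or `NA` below
#'   the first edge.
#' @examples
#' severity_bin(c(5.5, 6.5, 9))
#' @export
severity_bin <- function(ANB, edges = c(6, 7, 8, 9)) {
  stopifnot(is.numeric(edges), length(edges) >= 1, !is.unsorted(edges))
  labs <- bin_labels(edges)
  idx <- findInterval(ANB, edges)
  out <- rep(NA_character_, length(ANB))
  out[idx >= 1] <- labs[idx[idx >= 1]]
  out[!is.finite(ANB)] <- NA_character_
  out
}

bin_labels <- function(edges = c(6, 7, 8, 9)) {
  hi <- c(edges[-1], Inf)
  sprintf("[%g,%g)", edges, hi)
}

#' Selection and labeling pipeline for a cohort manifest
#'
#' Reproduces the cohort bookkeeping of the study design: starting from a
#' manifest with SNA/SNB/ANB columns, (1) keep only subjects matching the
#' Class I or Class II malocclusion-type rules, (2) exclude borderline
#' cases (ANB in \[-1, 1\]), and report the per-stage counts together with
#' the filtered manifest (with `label` and `bin` columns attached).
#'
#' @param manifest data frame with numeric columns `SNA`, `SNB`, `ANB`.
#' @param edges severity bin edges passed to [severity_bin()].
#' @return list with `manifest` (filtered, labeled) and `counts` (named
#'   list: input, after_type_filter, after_borderline, classI, classII,
#'   excluded).
#' @export
apply_selection_pipeline <- function(manifest, edges = c(6, 7, 8, 9)) {
  manifest <- as.data.frame(manifest)
  need <- c("SNA", "SNB", "ANB")
  if (nrow(manifest) > 0 && !all(need %in% names(manifest)))
    stop("manifest lacks angle columns: ",
         paste(setdiff(need, names(manifest)), collapse = ", "), call. = FALSE)
  n_in <- nrow(manifest)
  if (n_in == 0) {
    out <- manifest
    out$label <- character(0)
    out$bin <- character(0)
    return(list(manifest = out,
                counts = list(input = 0L, after_type_filter = 0L,
                              after_borderline = 0L, classI = 0L,
                              classII = 0L, excluded = 0L)))
  }
  lab <- classify_angles(manifest$ANB, manifest$SNA, manifest$SNB)
  # stage 1: malocclusion-type filter (Class I or Class II rules match,
  # before the borderline exclusion is applied)
  type_ok <- (manifest$ANB > 4 & manifest$SNB < 76) |
    (manifest$ANB >= 0 & manifest$ANB <= 5 &
       manifest$SNA >= 79 & manifest$SNA <= 85 & manifest$SNB < 77)
  n_type <- sum(type_ok)
  keep <- lab %in% c("classI", "classII")
  out <- manifest[keep, , drop = FALSE]
  out$label <- lab[keep]
  out$bin <- ifelse(out$label == "classII",
                    severity_bin(out$ANB, edges), NA_character_)
  rownames(out) <- NULL
  list(manifest = out,
       counts = list(input = n_in,
                     after_type_filter = as.integer(n_type),
                     after_borderline = as.integer(sum(keep)),
                     classI = as.integer(sum(out$label == "classI")),
                     classII = as.integer(sum(out$label == "classII")),
                     excluded = as.integer(n_in - sum(keep))))
}
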