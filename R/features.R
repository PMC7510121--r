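# Per-bead measurements and the canonical 46-metric phenotypic profile.

#' Per-bead measurements
#'
#' One record per segmented instance: centroid, area, intensity statistics
#' measured on the raw (pre-normalization) image, and shape descriptors
#' from the mask geometry. Eccentricity comes from the eigenvalues of the
#' pixel-coordinate covariance (0 = circular, 1 = line-like); solidity is
#' mask area over convex-hull area, clamped to (0, 1].
#'
#' @param img a [fluor_image()] (the raw image).
#' @param seg a [segmentation_result()] congruent with `img`.
#' @return a data frame with columns `label_id, centroid_r, centroid_c,
#'   area_px, mean_intensity, median_intensity, max_intensity,
#'   min_intensity, integrated_intensity, eccentricity, solidity`.
#' @export
bead_records <- function(img, seg) {
  if (!identical(as.integer(dim(img$pixels)), seg$shape))
    stop("image and segmentation shapes differ")
  h <- seg$shape[1]
  rows <- lapply(seg$instances, function(inst) {
    v <- img$pixels[inst$idx]
    r <- (inst$idx - 1L) %% h + 1L
    c <- (inst$idx - 1L) %/% h + 1L
    data.frame(label_id = inst$label_id,
               centroid_r = mean(r), centroid_c = mean(c),
               area_px = length(inst$idx),
               mean_intensity = mean(v), median_intensity = stats::median(v),
               max_intensity = max(v), min_intensity = min(v),
               integrated_intensity = sum(v),
               eccentricity = mask_eccentricity(r, c),
               solidity = mask_solidity(r, c))
  })
  if (length(rows) == 0L)
    return(data.frame(label_id = integer(0), centroid_r = numeric(0),
                      centroid_c = numeric(0), area_px = integer(0),
                      mean_intensity = numeric(0), median_intensity = numeric(0),
                      max_intensity = numeric(0), min_intensity = numeric(0),
                      integrated_intensity = numeric(0),
                      eccentricity = numeric(0), solidity = numeric(0)))
  do.call(rbind, rows)
}

mask_eccentricity <- function(r, c) {
  if (length(r) < 2) return(0)
  cv <- stats::cov(cbind(r, c))
  ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
  if (ev[1] <= 0) return(0)
  sqrt(max(0, 1 - ev[2] / ev[1]))
}

mask_solidity <- function(r, c) {
  n <- length(r)
  if (n < 3) return(1)
  pts <- unique(cbind(r, c))
  if (nrow(pts) < 3) return(1)
  hull <- grDevices::chull(pts)
  hp <- pts[hull, , drop = FALSE]
  m <- nrow(hp)
  if (m < 3) return(1)
  # shoelace area of the hull polygon through pixel centers, plus a
  # half-perimeter boundary correction so a convex pixel set scores ~1
  x <- hp[, 2]; y <- hp[, 1]
  area <- abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
  per <- sum(sqrt(diff(c(x, x[1]))^2 + diff(c(y, y[1]))^2))
  conv_area <- area + per / 2 + 1
  min(1, n / conv_area)
}

#' All pairwise inter-bead distances
#'
#' Euclidean centroid distances for all `C(n, 2)` unordered bead pairs;
#' empty when fewer than two beads.
#'
#' @param records a [bead_records()] data frame.
#' @return numeric vector of distances in pixels.
#' @export
pairwise_distances <- function(records) {
  if (nrow(records) < 2) return(numeric(0))
  as.vector(stats::dist(cbind(records$centroid_r, records$centroid_c)))
}

METRIC_NAMES <- sprintf("m%02d", 1:46)

METRIC_LABELS <- c(
  "bead count", "total bead area", "mean bead area", "SEM bead area",
  "min bead area",
  "fraction area [0,50)", "fraction area [50,100)", "fraction area [100,200)",
  "fraction area [200,400)", "fraction area [400,Inf)",
  "NN distance mean", "NN distance median", "NN distance sd",
  "NN distance min", "NN distance max",
  "fraction beads area < 100 px", "mean pairwise distance",
  "median pairwise distance", "sd pairwise distance", "SEM pairwise distance",
  "fraction pairwise < 150 px", "fraction pairwise < 300 px",
  "p10 pairwise distance", "p90 pairwise distance",
  "median bead area", "max bead area", "p10 bead area", "p25 bead area",
  "p75 bead area", "p90 bead area", "sd bead area",
  "median bead intensity", "mean bead intensity", "SEM bead intensity",
  "sd of mean bead intensity", "p10 bead intensity", "p90 bead intensity",
  "p25 bead intensity", "p75 bead intensity", "max bead intensity",
  "min bead intensity", "total integrated intensity",
  "mean eccentricity", "mean solidity", "CV bead area",
  "CV pairwise distance")

#' The canonical 46-metric phenotypic profile of one image
#'
#' Fills the fixed 46-slot feature vector describing a beading pattern.
#' Anchored slots follow the field's numbering: m16 = percentage of beads
#' with area below 100 px, m17 = average pairwise inter-bead distance, m20
#' = its SEM, m21/m22 = fractions of pairwise distances below 150/300 px,
#' m25/m26 = median/max bead size, m32 = median bead intensity, m35 = sd of
#' mean bead intensity, m37 = 90th percentile of bead intensity. "Bead
#' intensity" is the distribution over beads of per-bead mean intensity.
#' Percentiles use linear interpolation between order statistics
#' (`quantile` type 7). Metrics whose statistic needs more beads than the
#' image has (e.g. any distance metric with fewer than 2 beads) are `NA`
#' and flagged in the `undefined` attribute.
#'
#' @param records a [bead_records()] data frame.
#' @param distances pairwise distances; computed from `records` if `NULL`.
#' @return a named numeric vector of length 46 (class `feature_vector46`)
#'   with attributes `undefined` (logical per slot) and `labels`.
#' @export
feature_vector <- function(records, distances = NULL) {
  if (is.null(distances)) distances <- pairwise_distances(records)
  a <- records$area_px
  mi <- records$mean_intensity
  n <- nrow(records)
  q <- function(x, p) if (length(x)) stats::quantile(x, p, names = FALSE, type = 7) else NA_real_
  sd0 <- function(x) if (length(x) > 1) stats::sd(x) else NA_real_
  nn <- if (n >= 2) {
    dm <- as.matrix(stats::dist(cbind(records$centroid_r, records$centroid_c)))
    diag(dm) <- Inf
    apply(dm, 1, min)
  } else numeric(0)
  v <- c(
    n,                                     # m01
    sum(a),                                # m02
    if (n) mean(a) else NA,                # m03
    sem(a),                                # m04
    if (n) min(a) else NA,                 # m05
    if (n) mean(a < 50) else NA,           # m06
    if (n) mean(a >= 50 & a < 100) else NA,    # m07
    if (n) mean(a >= 100 & a < 200) else NA,   # m08
    if (n) mean(a >= 200 & a < 400) else NA,   # m09
    if (n) mean(a >= 400) else NA,         # m10
    if (n >= 2) mean(nn) else NA,          # m11
    if (n >= 2) stats::median(nn) else NA, # m12
    sd0(nn),                               # m13
    if (n >= 2) min(nn) else NA,           # m14
    if (n >= 2) max(nn) else NA,           # m15
    if (n) mean(a < 100) else NA,          # m16
    if (length(distances)) mean(distances) else NA,          # m17
    if (length(distances)) stats::median(distances) else NA, # m18
    sd0(distances),                        # m19
    sem(distances),                        # m20
    if (length(distances)) mean(distances < 150) else NA,    # m21
    if (length(distances)) mean(distances < 300) else NA,    # m22
    q(distances, 0.10),                    # m23
    q(distances, 0.90),                    # m24
    if (n) stats::median(a) else NA,       # m25
    if (n) max(a) else NA,                 # m26
    q(a, 0.10), q(a, 0.25), q(a, 0.75), q(a, 0.90),  # m27-m30
    sd0(a),                                # m31
    if (n) stats::median(mi) else NA,      # m32
    if (n) mean(mi) else NA,               # m33
    sem(mi),                               # m34
    sd0(mi),                               # m35
    q(mi, 0.10), q(mi, 0.90), q(mi, 0.25), q(mi, 0.75),  # m36-m39
    if (n) max(mi) else NA,                # m40
    if (n) min(mi) else NA,                # m41
    sum(records$integrated_intensity),     # m42
    if (n) mean(records$eccentricity) else NA,  # m43
    if (n) mean(records$solidity) else NA, # m44
    if (n > 1) stats::sd(a) / mean(a) else NA,  # m45
    if (length(distances) > 1) stats::sd(distances) / mean(distances) else NA) # m46
  v <- as.numeric(v)
  names(v) <- METRIC_NAMES
  structure(v, undefined = stats::setNames(is.na(v), METRIC_NAMES),
            labels = METRIC_LABELS, class = "feature_vector46")
}

#' @export
print.feature_vector46 <- function(x, ...) {
  cat("<feature_vector46>\n")
  df <- data.frame(metric = METRIC_NAMES, value = round(as.numeric(x), 3),
                   label = METRIC_LABELS)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Profile a list of images into a feature table
#'
#' @param items list of `list(img, seg, meta)` triples, or of
#'   `synthetic_scene` objects (then `seg` defaults to the scene truth and
#'   `meta` to the rendered image's metadata).
#' @param seg_list optional list of [segmentation_result()] overriding the
#'   per-item segmentation.
#' @return a data frame with metadata columns (`animal_id, region,
#'   condition`) followed by `m01..m46`.
#' @export
feature_table <- function(items, seg_list = NULL) {
  rows <- lapply(seq_along(items), function(i) {
    it <- items[[i]]
    if (inherits(it, "synthetic_scene")) {
      img <- it$rendered
      seg <- seg_list[[i]] %||% it$truth
      meta <- img$meta
    } else {
      img <- it$img; seg <- seg_list[[i]] %||% it$seg; meta <- it$meta %||% img$meta
    }
    fv <- feature_vector(bead_records(img, seg))
    cbind(data.frame(animal_id = meta$animal_id %||% sprintf("img_%03d", i),
                     region = meta$region %||% "unknown",
                     condition = meta$condition %||% NA_character_),
          as.data.frame(as.list(as.numeric(fv)), col.names = METRIC_NAMES))
  })
  do.call(rbind, rows)
}

#' Per-group mean and SEM of each metric
#'
#' @param tbl a [feature_table()] data frame.
#' @param by names of grouping columns (default `"condition"`).
#' @return long data frame `group, metric, mean, sem, n`; `NA` (undefined)
#'   entries are excluded from each metric's `n`.
#' @export
population_summary <- function(tbl, by = "condition") {
  grp <- interaction(tbl[by], drop = TRUE, sep = "/")
  rows <- list()
  for (g in levels(grp)) {
    d <- tbl[grp == g, METRIC_NAMES, drop = FALSE]
    for (m in METRIC_NAMES) {
      x <- d[[m]][!is.na(d[[m]])]
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, metric = m,
        mean = if (length(x)) mean(x) else NA_real_,
        sem = sem(x), n = length(x))
    }
  }
  do.call(rbind, rows)
}

#' Bonferroni-corrected significance level
#'
#' `family_alpha / n_comparisons`, with the display value truncated to 3
#' decimal places following the common printed convention (0.05 over 3
#' comparisons is reported as 0.016).
#'
#' @param family_alpha family-wise alpha (default 0.05).
#' @param n_comparisons number of comparisons (>= 1).
#' @return list with `alpha` (truncated display value) and `alpha_full`.
#' @export
bonferroni_alpha <- function(family_alpha = 0.05, n_comparisons) {
  stopifnot(n_comparisons >= 1)
  full <- family_alpha / n_comparisons
  list(alpha = trunc(full * 1000) / 1000, alpha_full = full)
}
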