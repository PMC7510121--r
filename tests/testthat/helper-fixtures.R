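# Shared fixture builders. Everything is generated in code at test time.

# A disc-shaped instance mask centered at (r, c).
disc_instance <- function(r, c, radius, shape, score = 1, label_id = 1L) {
  rows <- max(1, floor(r - radius - 1)):min(shape[1], ceiling(r + radius + 1))
  cols <- max(1, floor(c - radius - 1)):min(shape[2], ceiling(c + radius + 1))
  d <- sqrt(outer((rows - r)^2, (cols - c)^2, `+`))
  sel <- which(d <= radius, arr.ind = TRUE)
  idx <- (cols[sel[, 2]] - 1L) * shape[1] + rows[sel[, 1]]
  instance_mask(idx, score = score, label_id = label_id, shape = shape)
}

# A rectangular instance mask (rows r0:r1, cols c0:c1).
rect_instance <- function(r0, r1, c0, c1, shape, score = 1, label_id = 1L) {
  idx <- as.vector(outer(r0:r1, (c0:c1 - 1L) * shape[1], `+`))
  instance_mask(idx, score = score, label_id = label_id, shape = shape)
}

# Rasterize an arbor skeleton into a logical dendrite mask (pixels within
# `halo` px of any segment).
skeleton_mask <- function(skel, halo = 2) {
  shape <- skel$shape
  m <- matrix(FALSE, shape[1], shape[2])
  segs <- skel$segments
  for (k in seq_len(nrow(segs))) {
    rr <- max(1, floor(min(segs$r0[k], segs$r1[k]) - halo - 1)):
          min(shape[1], ceiling(max(segs$r0[k], segs$r1[k]) + halo + 1))
    cc <- max(1, floor(min(segs$c0[k], segs$c1[k]) - halo - 1)):
          min(shape[2], ceiling(max(segs$c0[k], segs$c1[k]) + halo + 1))
    pts <- expand.grid(r = rr, c = cc)
    d <- beadmorph:::point_segment_distances_one(pts$r, pts$c, segs[k, ])
    m[rr, cc] <- m[rr, cc] | matrix(d <= halo, length(rr), length(cc))
  }
  m
}

# Hand-built two-bead record table used for worked-example checks.
two_bead_records <- function() {
  data.frame(label_id = 1:2,
             centroid_r = c(1, 4), centroid_c = c(1, 5),
             area_px = c(50L, 150L),
             mean_intensity = c(100, 120),
             median_intensity = c(100, 120),
             max_intensity = c(100, 120), min_intensity = c(100, 120),
             integrated_intensity = c(50 * 100, 150 * 120),
             eccentricity = c(0.2, 0.3), solidity = c(1, 1))
}

# Exhaustive matching oracle: enumerate all injective pred->truth
# assignments over pairs with IoU >= iou_min and return the maximum
# number of matches (ties resolved toward larger total IoU).
brute_force_match <- function(pred, truth, iou_min = 0.3) {
  np <- length(pred$instances); nt <- length(truth$instances)
  iou <- matrix(0, np, nt)
  if (np && nt)
    for (i in 1:np) for (j in 1:nt)
      iou[i, j] <- mask_iou(pred$instances[[i]], truth$instances[[j]])
  best <- c(n = 0, total = 0)
  recurse <- function(i, used, n, total) {
    if (i > np) {
      if (n > best[["n"]] || (n == best[["n"]] && total > best[["total"]]))
        best <<- c(n = n, total = total)
      return(invisible())
    }
    recurse(i + 1, used, n, total)  # leave pred i unmatched
    for (j in seq_len(nt)) {
      if (!used[j] && iou[i, j] >= iou_min) {
        used[j] <- TRUE
        recurse(i + 1, used, n + 1, total + iou[i, j])
        used[j] <- FALSE
      }
    }
  }
  recurse(1, rep(FALSE, nt), 0, 0)
  best
}

# Memoised default-profile populations used by the classification and
# acceptance tests (rendered once per test run).
classification_populations <- local({
  cache <- NULL
  function(n_per_class = 60L, seed = 7L) {
    key <- paste(n_per_class, seed)
    if (!is.null(cache) && identical(cache$key, key)) return(cache$value)
    profs <- default_profiles()
    young <- generate_population(profs$young, n_per_class, shape = c(512L, 512L),
                                 seed = derive_seed(seed, 1))
    aged <- generate_population(profs$aged, n_per_class, shape = c(512L, 512L),
                                seed = derive_seed(seed, 2))
    tbl <- feature_table(c(young, aged))
    cache <<- list(key = key, value = tbl)
    tbl
  }
})

# Placement-level population statistics (no rendering): truth-instance
# count and mean pairwise inter-centroid distance per scene.
placement_stats <- function(profile, n_scenes, seed, shape = c(512L, 512L)) {
  pop <- generate_population(profile, n_scenes, shape = shape, seed = seed,
                             render = FALSE, n_droplets = 0L)
  t(vapply(pop, function(sc) {
    h <- shape[1]
    cen <- t(vapply(sc$truth$instances, function(i)
      c(mean((i$idx - 1L) %% h + 1L), mean((i$idx - 1L) %/% h + 1L)),
      numeric(2)))
    c(count = length(sc$truth$instances),
      m17 = if (nrow(cen) >= 2) mean(stats::dist(cen)) else NA_real_)
  }, numeric(2)))
}
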