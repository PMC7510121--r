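# Synthetic PVD-like fluorescence scenes with paired ground truth.
#
# The simulator emulates what the pipeline consumes: a menorah-bearing
# dendritic arbor, bright bubble-like beads on the dendrites, off-dendrite
# autofluorescent droplet confounders, a Gaussian PSF, and Poisson +
# Gaussian camera noise. Every scene carries exact instance masks for its
# beads (and none for droplets), so segmentation, evaluation, profiling and
# classification can all be exercised without microscope data.

#' Condition profile for the scene generator
#'
#' The generative knobs that encode a biological condition: how many beads
#' an image carries, how big they are, which branch orders they sit on, and
#' how strongly new beads nucleate near existing ones (spatially correlated
#' beading, the mechanism by which dense aged beading shortens inter-bead
#' distances).
#'
#' @param name one of `"young"`, `"aged"`, `"cold_shock"`.
#' @param count_mean,count_sd normal mean/sd of the per-image bead count
#'   (clamped at 0).
#' @param area_mean,area_sd normal mean/sd of per-bead mask area in pixels
#'   (clamped at 20 px).
#' @param order_weights length-4 non-negative placement probabilities over
#'   branch orders 1..4; must sum to 1.
#' @param cluster_strength probability in `[0, 1]` that a new bead is
#'   placed within `cluster_radius` of a nucleation focus (one of the
#'   first `n_foci` beads) instead of uniformly.
#' @param cluster_radius attraction radius in pixels.
#' @param n_foci number of nucleation foci for clustered placement.
#' @return an object of class `condition_profile`.
#' @export
condition_profile <- function(name, count_mean, count_sd, area_mean, area_sd,
                              order_weights = rep(0.25, 4),
                              cluster_strength = 0, cluster_radius = 50,
                              n_foci = 3L) {
  stopifnot(count_mean > 0, area_mean > 0, length(order_weights) == 4,
            all(order_weights >= 0), cluster_strength >= 0, cluster_strength <= 1)
  if (abs(sum(order_weights) - 1) > 1e-8)
    stop("order_weights must sum to 1")
  structure(list(name = name, count_mean = count_mean, count_sd = count_sd,
                 area_mean = area_mean, area_sd = area_sd,
                 order_weights = order_weights,
                 cluster_strength = cluster_strength,
                 cluster_radius = cluster_radius,
                 n_foci = as.integer(n_foci)),
            class = "condition_profile")
}

#' Shipped condition profiles
#'
#' The default study conditions: `young` (sparse, uniformly placed beads),
#' `aged` (many beads, placed evenly over all branch orders but spatially
#' correlated, so beading is dense where it occurs), and `cold_shock`
#' (intermediate count, strongly biased to distal order-3/4 branches).
#'
#' @return a named list of [condition_profile()] objects.
#' @export
default_profiles <- function() {
  list(
    young = condition_profile("young", 30, 10, 150, 40, rep(0.25, 4), 0),
    aged = condition_profile("aged", 100, 25, 120, 35, rep(0.25, 4),
                             cluster_strength = 0.8, cluster_radius = 250,
                             n_foci = 1L),
    cold_shock = condition_profile("cold_shock", 70, 20, 150, 40,
                                   c(0.05, 0.15, 0.40, 0.40), 0)
  )
}

#' Generate a menorah-like dendritic arbor
#'
#' One order-1 primary dendrite spanning the image horizontally, with
#' `n_menorahs` order-2 stems branching alternately dorsally and ventrally,
#' each carrying two horizontal order-3 arms and two order-4 terminal
#' branches that continue away from the primary. Distal (order-3/4)
#' branches therefore occupy the vertical extremes of the frame, as PVD
#' candelabra reach toward the dorsal and ventral body wall.
#'
#' @param shape `(height, width)`, each at least 256.
#' @param n_menorahs number of candelabra units (>= 1).
#' @param seed integer RNG seed; the skeleton is deterministic given it.
#' @param region `"anterior"` or `"posterior"` (metadata only).
#' @return an object of class `arbor_skeleton` with `segments` (data frame
#'   `r0, c0, r1, c1, order`), `shape` and `region`.
#' @export
generate_arbor <- function(shape, n_menorahs = 8L, seed = 1L, region = "anterior") {
  shape <- as.integer(shape)
  if (any(shape < 256)) stop("arbor frame must be at least 256 x 256")
  if (n_menorahs < 1) stop("n_menorahs must be >= 1")
  margin <- 12
  h <- shape[1]; w <- shape[2]
  with_seed(seed, {
    segs <- data.frame(r0 = h / 2, c0 = margin, r1 = h / 2, c1 = w - margin,
                       order = 1L)
    spacing <- (w - 2 * margin) / n_menorahs
    for (j in seq_len(n_menorahs)) {
      x <- margin + (j - 0.5) * spacing + stats::runif(1, -0.15, 0.15) * spacing
      x <- min(max(x, margin), w - margin)
      dirn <- if (j %% 2 == 1) -1 else 1  # alternate dorsal/ventral
      stem_len <- 0.32 * h * stats::runif(1, 0.85, 1.15)
      tip_r <- min(max(h / 2 + dirn * stem_len, margin), h - margin)
      segs <- rbind(segs, data.frame(r0 = h / 2, c0 = x, r1 = tip_r, c1 = x,
                                     order = 2L))
      for (side in c(-1, 1)) {
        arm_len <- 0.35 * spacing * stats::runif(1, 0.7, 1.3)
        ax <- min(max(x + side * arm_len, margin), w - margin)
        segs <- rbind(segs, data.frame(r0 = tip_r, c0 = x, r1 = tip_r, c1 = ax,
                                       order = 3L))
        term_len <- 0.12 * h * stats::runif(1, 0.7, 1.3)
        tr <- min(max(tip_r + dirn * term_len, margin), h - margin)
        segs <- rbind(segs, data.frame(r0 = tip_r, c0 = ax, r1 = tr, c1 = ax,
                                       order = 4L))
      }
    }
    structure(list(segments = segs, shape = shape, region = region),
              class = "arbor_skeleton")
  })
}

#' @export
print.arbor_skeleton <- function(x, ...) {
  cat(sprintf("<arbor_skeleton> %d segments (orders %s) on %d x %d, region %s\n",
              nrow(x$segments),
              paste(sort(unique(x$segments$order)), collapse = ","),
              x$shape[1], x$shape[2], x$region))
  invisible(x)
}

seg_lengths <- function(segs) {
  sqrt((segs$r1 - segs$r0)^2 + (segs$c1 - segs$c0)^2)
}

# Distance from point (r, c) to every segment of the skeleton.
point_segment_distances <- function(r, c, segs) {
  dr <- segs$r1 - segs$r0; dc <- segs$c1 - segs$c0
  len2 <- dr^2 + dc^2
  t <- ((r - segs$r0) * dr + (c - segs$c0) * dc) / pmax(len2, 1e-12)
  t <- pmin(pmax(t, 0), 1)
  sqrt((segs$r0 + t * dr - r)^2 + (segs$c0 + t * dc - c)^2)
}

# Sample one point uniformly (by arc length) on the segments of one order.
sample_point_on_order <- function(segs, ord) {
  s <- segs[segs$order == ord, , drop = FALSE]
  L <- seg_lengths(s)
  k <- sample.int(nrow(s), 1L, prob = L)
  t <- stats::runif(1)
  c(r = s$r0[k] + t * (s$r1[k] - s$r0[k]),
    c = s$c0[k] + t * (s$c1[k] - s$c0[k]))
}

#' Place beads on an arbor according to a condition profile
#'
#' Bead count is drawn from the profile's count distribution (clamped at
#' 0); each bead's branch order from `order_weights`; its position is
#' uniform along segments of that order, except that with probability
#' `cluster_strength` the bead is instead placed within `cluster_radius`
#' of one of the first `n_foci` beads (nucleation foci), modelling
#' spatially correlated beading. The target mask area is drawn from the area
#' distribution and converted to a radius via `area = pi * r^2`.
#'
#' @param skeleton an [generate_arbor()] skeleton.
#' @param profile a [condition_profile()].
#' @param seed integer RNG seed.
#' @return a data frame with one row per bead: `r, c, radius, peak, order`.
#' @export
place_beads <- function(skeleton, profile, seed = 1L) {
  segs <- skeleton$segments
  with_seed(seed, {
    n <- max(0L, as.integer(round(stats::rnorm(1, profile$count_mean,
                                               profile$count_sd))))
    out <- data.frame(r = numeric(0), c = numeric(0), radius = numeric(0),
                      peak = numeric(0), order = integer(0))
    if (n == 0L) return(out)
    for (i in seq_len(n)) {
      ord <- sample.int(4L, 1L, prob = profile$order_weights)
      p <- sample_point_on_order(segs, ord)
      if (nrow(out) > 0 && profile$cluster_strength > 0 &&
          stats::runif(1) < profile$cluster_strength) {
        # attach near a nucleation focus, but keep enough center spacing
        # that clustered beads stay distinct instances
        anchor <- out[sample.int(min(nrow(out), profile$n_foci), 1L), ]
        for (try in 1:80) {
          ord2 <- sample.int(4L, 1L, prob = profile$order_weights)
          q <- sample_point_on_order(segs, ord2)
          near <- sqrt((q["r"] - anchor$r)^2 + (q["c"] - anchor$c)^2) <=
            profile$cluster_radius
          spaced <- min(sqrt((q["r"] - out$r)^2 + (q["c"] - out$c)^2)) >= 13
          if (near && spaced) { p <- q; ord <- ord2; break }
        }
      }
      area <- max(20, stats::rnorm(1, profile$area_mean, profile$area_sd))
      out <- rbind(out, data.frame(r = p[["r"]], c = p[["c"]],
                                   radius = sqrt(area / pi),
                                   peak = stats::runif(1, 0.6, 1.0),
                                   order = ord))
    }
    out
  })
}

#' Place autofluorescent droplet confounders
#'
#' Droplets mimic beads in size and brightness but sit off the dendrite
#' (centers at least `min_dist` px from every skeleton segment) and never
#' enter the ground truth.
#'
#' @param skeleton an [generate_arbor()] skeleton.
#' @param n number of droplets (>= 0).
#' @param seed integer RNG seed.
#' @param area_mean,area_sd droplet area distribution (defaults match the
#'   bead area distribution).
#' @param min_dist minimum center-to-skeleton distance in px (default 10).
#' @return a data frame `r, c, radius, peak`.
#' @export
place_droplets <- function(skeleton, n, seed = 1L, area_mean = 150,
                           area_sd = 40, min_dist = 10) {
  stopifnot(n >= 0)
  h <- skeleton$shape[1]; w <- skeleton$shape[2]
  segs <- skeleton$segments
  with_seed(seed, {
    out <- data.frame(r = numeric(0), c = numeric(0), radius = numeric(0),
                      peak = numeric(0))
    for (i in seq_len(n)) {
      placed <- FALSE
      for (try in seq_len(1000L)) {
        r <- stats::runif(1, 5, h - 5); c <- stats::runif(1, 5, w - 5)
        if (min(point_segment_distances(r, c, segs)) >= min_dist) {
          area <- max(20, stats::rnorm(1, area_mean, area_sd))
          out <- rbind(out, data.frame(r = r, c = c, radius = sqrt(area / pi),
                                       peak = stats::runif(1, 0.6, 1.0)))
          placed <- TRUE
          break
        }
      }
      if (!placed) stop("could not place droplet ", i,
                        " away from the skeleton after 1000 trials")
    }
    out
  })
}

# Gaussian kernel vector for sigma (radius 3*sigma).
gauss_kernel <- function(sigma) {
  k <- max(1L, as.integer(ceiling(3 * sigma)))
  g <- exp(-(seq(-k, k))^2 / (2 * sigma^2))
  g / sum(g)
}

# Separable Gaussian convolution of a small patch, zero-padded boundary.
blur_patch <- function(p, sigma) {
  g <- gauss_kernel(sigma)
  k <- (length(g) - 1L) %/% 2L
  nr <- nrow(p); nc <- ncol(p)
  P <- matrix(0, nr + 2L * k, nc + 2L * k)
  P[k + seq_len(nr), k + seq_len(nc)] <- p
  A <- matrix(0, nr, nc + 2L * k)
  for (s in seq_along(g))
    A <- A + g[s] * P[(s - 1L) + seq_len(nr), , drop = FALSE]
  B <- matrix(0, nr, nc)
  for (s in seq_along(g))
    B <- B + g[s] * A[, (s - 1L) + seq_len(nc), drop = FALSE]
  B
}

# Anti-aliased disc profile on a local grid; returns list(rows, cols, m).
disc_patch <- function(center_r, center_c, radius, shape, pad = 3) {
  pr <- ceiling(radius + pad)
  rows <- max(1L, floor(center_r - pr)):min(shape[1], ceiling(center_r + pr))
  cols <- max(1L, floor(center_c - pr)):min(shape[2], ceiling(center_c + pr))
  d <- sqrt(outer((rows - center_r)^2, (cols - center_c)^2, `+`))
  list(rows = rows, cols = cols, m = pmin(pmax(radius + 0.5 - d, 0), 1))
}

# Ground-truth mask of one bead: the noiseless disc profile blurred by the
# PSF and thresholded at half its peak. Returns sorted linear indices.
bead_truth_idx <- function(center_r, center_c, radius, shape, psf_sigma) {
  p <- disc_patch(center_r, center_c, radius, shape, pad = 3 * psf_sigma + 2)
  b <- blur_patch(p$m, psf_sigma)
  sel <- which(b >= 0.5 * max(b), arr.ind = TRUE)
  sort((p$cols[sel[, 2]] - 1L) * shape[1] + p$rows[sel[, 1]])
}

# Build truth instances from bead placements, merging beads whose masks
# overlap into a single instance (masks must be disjoint for unambiguous
# matching). Returns list(instances, per_bead_areas, component_of_bead).
build_truth <- function(beads, shape, psf_sigma) {
  n <- nrow(beads)
  if (n == 0L)
    return(list(instances = list(), areas = numeric(0), component = integer(0)))
  masks <- lapply(seq_len(n), function(i)
    bead_truth_idx(beads$r[i], beads$c[i], beads$radius[i], shape, psf_sigma))
  # union-find over overlapping masks
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(i - 1L)) {
    dd <- sqrt((beads$r[i] - beads$r[j])^2 + (beads$c[i] - beads$c[j])^2)
    if (dd < beads$radius[i] + beads$radius[j] + 2 &&
        length(intersect(masks[[i]], masks[[j]])) > 0L) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  comp_ids <- sort(unique(comp))
  insts <- lapply(seq_along(comp_ids), function(k) {
    idx <- sort(unique(unlist(masks[comp == comp_ids[k]])))
    instance_mask(idx, score = 1, label_id = k, shape = shape)
  })
  list(instances = insts, areas = lengths(masks),
       component = match(comp, comp_ids))
}

#' Render a synthetic fluorescence scene
#'
#' Dendrites are drawn as bright soft tubes, beads and droplets as
#' radially symmetric blobs of their radius; the noiseless scene is
#' convolved with a Gaussian PSF, then Poisson noise (on signal plus
#' background) and Gaussian read noise are added. Ground-truth masks are
#' the pre-noise bead profiles thresholded at half peak; overlapping beads
#' merge into one truth instance, droplets contribute none.
#'
#' @param skeleton an [generate_arbor()] skeleton.
#' @param beads data frame from [place_beads()].
#' @param droplets data frame from [place_droplets()] (may have 0 rows).
#' @param render_params list overriding any of `psf_sigma_px` (1.5),
#'   `background_level` (40), `poisson_scale` (1; 0 disables Poisson
#'   noise), `gauss_sd` (4; 0 disables read noise), `dendrite_width_px`
#'   (1.5), `dendrite_amp` (100), `bead_amp` (400).
#' @param seed integer RNG seed for the noise.
#' @param meta metadata list attached to the rendered image.
#' @return an object of class `synthetic_scene`: `skeleton`, `beads`,
#'   `droplets`, `rendered` ([fluor_image()]), `truth`
#'   ([segmentation_result()]), `bead_areas_px` (per-bead truth areas
#'   before merging), `bead_component` (truth instance of each bead),
#'   `seed`.
#' @export
render_scene <- function(skeleton, beads, droplets = NULL,
                         render_params = list(), seed = 1L, meta = list()) {
  rp <- utils::modifyList(list(psf_sigma_px = 1.5, background_level = 40,
                               poisson_scale = 1, gauss_sd = 4,
                               dendrite_width_px = 1.5, dendrite_amp = 100,
                               bead_amp = 400), render_params)
  stopifnot(rp$psf_sigma_px > 0)
  shape <- skeleton$shape
  canvas <- matrix(0, shape[1], shape[2])
  segs <- skeleton$segments
  wd <- rp$dendrite_width_px
  for (k in seq_len(nrow(segs))) {
    rr <- max(1L, floor(min(segs$r0[k], segs$r1[k]) - 5)):
          min(shape[1], ceiling(max(segs$r0[k], segs$r1[k]) + 5))
    cc <- max(1L, floor(min(segs$c0[k], segs$c1[k]) - 5)):
          min(shape[2], ceiling(max(segs$c0[k], segs$c1[k]) + 5))
    pts <- expand.grid(r = rr, c = cc)
    d <- point_segment_distances_one(pts$r, pts$c, segs[k, ])
    v <- rp$dendrite_amp * exp(-d^2 / (2 * wd^2))
    canvas[rr, cc] <- pmax(canvas[rr, cc], matrix(v, length(rr), length(cc)))
  }
  blobs <- rbind(
    if (nrow(beads)) data.frame(r = beads$r, c = beads$c,
                                radius = beads$radius, peak = beads$peak),
    if (!is.null(droplets) && nrow(droplets))
      droplets[, c("r", "c", "radius", "peak")]
  )
  if (!is.null(blobs) && nrow(blobs)) {
    for (k in seq_len(nrow(blobs))) {
      p <- disc_patch(blobs$r[k], blobs$c[k], blobs$radius[k], shape)
      amp <- rp$bead_amp * blobs$peak[k]
      canvas[p$rows, p$cols] <- pmax(canvas[p$rows, p$cols], amp * p$m)
    }
  }
  blurred <- as.matrix(EBImage::imageData(EBImage::gblur(canvas, sigma = rp$psf_sigma_px)))
  expected <- pmax(blurred, 0) + rp$background_level
  img <- with_seed(seed, {
    out <- expected
    if (rp$poisson_scale > 0) {
      lam <- as.vector(expected) * rp$poisson_scale
      out <- matrix(stats::rpois(length(lam), lam) / rp$poisson_scale,
                    shape[1], shape[2])
    }
    if (rp$gauss_sd > 0)
      out <- out + matrix(stats::rnorm(length(out), 0, rp$gauss_sd),
                          shape[1], shape[2])
    pmax(out, 0)
  })
  tr <- build_truth(beads, shape, rp$psf_sigma_px)
  structure(list(
    skeleton = skeleton, beads = beads,
    droplets = droplets %||% data.frame(),
    rendered = fluor_image(img, meta),
    truth = segmentation_result(tr$instances, shape, backend = "truth",
                                params = list(psf_sigma_px = rp$psf_sigma_px)),
    bead_areas_px = tr$areas, bead_component = tr$component,
    render_params = rp, seed = seed), class = "synthetic_scene")
}

point_segment_distances_one <- function(r, c, seg) {
  dr <- seg$r1 - seg$r0; dc <- seg$c1 - seg$c0
  len2 <- dr^2 + dc^2
  t <- ((r - seg$r0) * dr + (c - seg$c0) * dc) / max(len2, 1e-12)
  t <- pmin(pmax(t, 0), 1)
  sqrt((seg$r0 + t * dr - r)^2 + (seg$c0 + t * dc - c)^2)
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("<synthetic_scene> %d beads (%d truth instances), %d droplets, %d x %d, seed %d\n",
              nrow(x$beads), length(x$truth$instances), nrow(x$droplets),
              x$skeleton$shape[1], x$skeleton$shape[2], x$seed))
  invisible(x)
}

#' Generate a population of synthetic scenes
#'
#' Independent scenes under one condition profile, with per-scene seeds
#' derived from a master seed (fully reproducible).
#'
#' @param profile a [condition_profile()].
#' @param n_images number of scenes (>= 1).
#' @param shape frame shape, default `c(512, 512)`.
#' @param seed master seed.
#' @param n_droplets droplet confounders per scene (default 8).
#' @param n_menorahs candelabra per arbor (default 8).
#' @param render if `FALSE`, skip rendering the intensity image (truth
#'   masks and placements are still produced); used for placement-level
#'   statistics.
#' @param render_params passed to [render_scene()].
#' @param region region metadata for all scenes.
#' @return a list of `synthetic_scene` objects.
#' @export
generate_population <- function(profile, n_images, shape = c(512L, 512L),
                                seed = 1L, n_droplets = 8L, n_menorahs = 8L,
                                render = TRUE, render_params = list(),
                                region = "anterior") {
  stopifnot(n_images >= 1)
  lapply(seq_len(n_images), function(i) {
    s <- derive_seed(seed, i)
    skel <- generate_arbor(shape, n_menorahs = n_menorahs,
                           seed = derive_seed(s, 1), region = region)
    beads <- place_beads(skel, profile, seed = derive_seed(s, 2))
    drops <- place_droplets(skel, n_droplets, seed = derive_seed(s, 3),
                            area_mean = profile$area_mean,
                            area_sd = profile$area_sd)
    meta <- list(animal_id = sprintf("sim_%s_%03d", profile$name, i),
                 region = region, condition = profile$name)
    if (render) {
      render_scene(skel, beads, drops, render_params = render_params,
                   seed = derive_seed(s, 4), meta = meta)
    } else {
      rp <- utils::modifyList(list(psf_sigma_px = 1.5), render_params)
      tr <- build_truth(beads, shape, rp$psf_sigma_px)
      structure(list(skeleton = skel, beads = beads, droplets = drops,
                     rendered = NULL,
                     truth = segmentation_result(tr$instances, shape,
                                                 backend = "truth"),
                     bead_areas_px = tr$areas, bead_component = tr$component,
                     render_params = rp, seed = s),
                class = "synthetic_scene")
    }
  })
}
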