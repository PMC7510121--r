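# Pluggable per-tile instance segmenters.
#
# Any function `(pixels, spec) -> list of instance_mask` (tile-local
# coordinates, mask shape = tile size) plugs into segment_image() /
# stitch_and_merge(). Shipped backends: a configurable noisy ground-truth
# oracle (manufactures TP/FP/FN cases on demand for testing) and a
# classical Laplacian-of-Gaussian blob baseline. A CNN backend is a
# documented configuration schema only; see cnn_backend_config().

#' Oracle noise configuration
#'
#' Controls how the ground-truth oracle corrupts the truth: dropped beads
#' are the false-negative source, spurious blobs the false-positive source,
#' dilation/erosion perturbs mask boundaries, and emitted scores are drawn
#' from a clipped normal. Drop decisions are deterministic per truth
#' instance (not per tile), so a bead visible in two overlapping tiles is
#' dropped consistently.
#'
#' @param drop_rate fraction of truth beads omitted, in `[0, 1]`.
#' @param spurious_rate expected spurious blobs per tile (Poisson mean).
#' @param dilate_px boundary perturbation in px; negative erodes.
#' @param score_mean,score_sd emitted score distribution, clipped to
#'   `[0, 1]`.
#' @param seed integer seed controlling all oracle randomness.
#' @return an object of class `oracle_noise`.
#' @export
oracle_noise <- function(drop_rate = 0, spurious_rate = 0, dilate_px = 0L,
                         score_mean = 1, score_sd = 0, seed = 1L) {
  stopifnot(drop_rate >= 0, drop_rate <= 1, spurious_rate >= 0)
  structure(list(drop_rate = drop_rate, spurious_rate = spurious_rate,
                 dilate_px = as.integer(dilate_px), score_mean = score_mean,
                 score_sd = score_sd, seed = as.integer(seed)),
            class = "oracle_noise")
}

# Dilate (k > 0) or erode (k < 0) a sparse mask within a frame.
morph_idx <- function(idx, shape, k) {
  if (k == 0L || length(idx) == 0L) return(idx)
  r <- (idx - 1L) %% shape[1] + 1L
  c <- (idx - 1L) %/% shape[1] + 1L
  pad <- abs(k) + 1L
  r0 <- max(1L, min(r) - pad); r1 <- min(shape[1], max(r) + pad)
  c0 <- max(1L, min(c) - pad); c1 <- min(shape[2], max(c) + pad)
  m <- matrix(0L, r1 - r0 + 1L, c1 - c0 + 1L)
  m[cbind(r - r0 + 1L, c - c0 + 1L)] <- 1L
  br <- EBImage::makeBrush(2L * abs(k) + 1L, shape = "disc")
  m2 <- if (k > 0) EBImage::dilate(m, br) else EBImage::erode(m, br)
  sel <- which(as.matrix(EBImage::imageData(m2)) > 0, arr.ind = TRUE)
  if (nrow(sel) == 0L) return(integer(0))
  sort((sel[, 2] + c0 - 2L) * shape[1] + (sel[, 1] + r0 - 1L))
}

#' Oracle per-tile segmentation
#'
#' Emits the truth instances that lie fully inside the tile, corrupted
#' according to an [oracle_noise()] configuration: each truth instance is
#' independently dropped with probability `drop_rate` (consistently across
#' tiles), survivors are dilated/eroded by `dilate_px`, Poisson-many
#' spurious discs are added at least 5 px away from all truth pixels, and
#' scores are drawn from the configured distribution.
#'
#' @param pixels tile intensity matrix (unused by the oracle; part of the
#'   backend contract).
#' @param truth_in_tile list of [instance_mask()] in tile-local
#'   coordinates, each fully inside the tile.
#' @param noise an [oracle_noise()].
#' @param tile_key integer distinguishing tiles for the spurious/score RNG
#'   stream.
#' @return list of [instance_mask()] in tile-local coordinates.
#' @export
oracle_segment <- function(pixels, truth_in_tile, noise = oracle_noise(),
                           tile_key = 0L) {
  size <- dim(pixels)
  out <- list()
  with_seed(derive_seed(noise$seed, tile_key + 1L), {
    for (inst in truth_in_tile) {
      if (hash_unif(noise$seed, inst$label_id) < noise$drop_rate) next
      idx <- morph_idx(inst$idx, size, noise$dilate_px)
      if (length(idx) == 0L) next
      sc <- if (noise$score_sd > 0)
        min(1, max(0, stats::rnorm(1, noise$score_mean, noise$score_sd)))
      else min(1, max(0, noise$score_mean))
      out[[length(out) + 1L]] <- instance_mask(idx, score = sc,
                                               label_id = inst$label_id,
                                               shape = size)
    }
    n_sp <- if (noise$spurious_rate > 0) stats::rpois(1, noise$spurious_rate) else 0L
    if (n_sp > 0L) {
      truth_px <- unlist(lapply(truth_in_tile, function(i) i$idx))
      tr <- (truth_px - 1L) %% size[1] + 1L
      tc <- (truth_px - 1L) %/% size[1] + 1L
      base_lab <- 100000L + tile_key * 1000L
      placed <- 0L
      for (s in seq_len(n_sp)) {
        for (try in 1:200) {
          rr <- stats::runif(1, 8, size[1] - 8)
          cc <- stats::runif(1, 8, size[2] - 8)
          if (length(truth_px) == 0L ||
              min(sqrt((tr - rr)^2 + (tc - cc)^2)) >= 5 + 7) {
            rad <- max(2, stats::rnorm(1, 7, 1.5))
            p <- disc_patch(rr, cc, rad, size, pad = 1)
            sel <- which(p$m >= 0.5, arr.ind = TRUE)
            idx <- sort((p$cols[sel[, 2]] - 1L) * size[1] + p$rows[sel[, 1]])
            sc <- if (noise$score_sd > 0)
              min(1, max(0, stats::rnorm(1, noise$score_mean, noise$score_sd)))
            else min(1, max(0, noise$score_mean))
            placed <- placed + 1L
            out[[length(out) + 1L]] <- instance_mask(idx, score = sc,
                                                     label_id = base_lab + placed,
                                                     shape = size)
            break
          }
        }
      }
    }
  })
  out
}

#' Build an oracle backend bound to a ground-truth result
#'
#' Returns a per-tile backend closure over the source-image truth: for each
#' tile it selects the truth instances entirely contained in the tile
#' (every bead that fits in some tile is emitted by at least one tile when
#' `stride < tile`), maps them to tile-local coordinates, and passes them
#' through [oracle_segment()].
#'
#' @param truth a [segmentation_result()] with ground-truth instances.
#' @param noise an [oracle_noise()].
#' @return a backend function `(pixels, spec) -> list of instance_mask`.
#' @export
oracle_backend <- function(truth, noise = oracle_noise()) {
  force(truth); force(noise)
  function(pixels, spec) {
    size <- as.integer(dim(pixels)[1])
    h <- truth$shape[1]
    in_tile <- list()
    for (inst in truth$instances) {
      r <- (inst$idx - 1L) %% h + 1L + spec$pad["top"]
      c <- (inst$idx - 1L) %/% h + 1L + spec$pad["left"]
      lr <- r - spec$row0 + 1L; lc <- c - spec$col0 + 1L
      if (all(lr >= 1L & lr <= size & lc >= 1L & lc <= size)) {
        in_tile[[length(in_tile) + 1L]] <-
          instance_mask((lc - 1L) * size + lr, score = 1,
                        label_id = inst$label_id, shape = c(size, size))
      }
    }
    key <- as.integer((spec$row0 * 131L + spec$col0) %% 100000L)
    oracle_segment(pixels, in_tile, noise, tile_key = key)
  }
}

#' Classical blob-detection baseline
#'
#' A traditional intensity-based segmenter used as a contrast baseline:
#' multi-scale Laplacian-of-Gaussian (difference-of-Gaussian) blob
#' candidates are thresholded, grown to half-peak masks, filtered by area,
#' and optionally restricted to blobs near the dendrite (droplets sit off
#' the dendrite, so the proximity filter suppresses that confounder).
#' Scores are detection responses normalized to the strongest blob in the
#' tile.
#'
#' @param pixels tile intensity matrix.
#' @param log_sigmas blob scales in px (defaults `c(3, 5, 7)`).
#' @param detect_thresh minimum normalized DoG response (default 0.08 of
#'   the tile's dynamic range).
#' @param min_area,max_area mask area bounds in px.
#' @param dendrite_proximity_px if not `NULL`, keep only blobs whose
#'   centroid lies within this distance of the dendrite mask.
#' @param dendrite_mask optional logical matrix marking dendrite pixels;
#'   estimated from the tile when `NULL` and a proximity filter is
#'   requested.
#' @return list of [instance_mask()] in tile-local coordinates.
#' @export
blob_baseline_segment <- function(pixels, log_sigmas = c(3, 5, 7),
                                  detect_thresh = 0.08, min_area = 20,
                                  max_area = 2000,
                                  dendrite_proximity_px = NULL,
                                  dendrite_mask = NULL) {
  size <- dim(pixels)
  rng <- max(pixels) - min(pixels)
  if (rng <= 0) return(list())
  img <- (pixels - min(pixels)) / rng
  best_resp <- matrix(-Inf, size[1], size[2])
  best_sig <- matrix(log_sigmas[1], size[1], size[2])
  smooth1 <- list()
  for (s in log_sigmas) {
    g1 <- as.matrix(EBImage::imageData(EBImage::gblur(img, sigma = s)))
    g2 <- as.matrix(EBImage::imageData(EBImage::gblur(img, sigma = 1.6 * s)))
    resp <- (g1 - g2)  # DoG approximation to scale-normalized LoG
    upd <- resp > best_resp
    best_resp[upd] <- resp[upd]
    best_sig[upd] <- s
    smooth1[[as.character(s)]] <- g1
  }
  # 3x3 local maxima of the best response above threshold
  pk <- local_maxima(best_resp) & best_resp > detect_thresh
  peaks <- which(pk, arr.ind = TRUE)
  if (nrow(peaks) == 0L) return(list())
  ord <- order(-best_resp[pk])
  peaks <- peaks[ord, , drop = FALSE]
  resp_vals <- best_resp[pk][ord]
  claimed <- matrix(FALSE, size[1], size[2])
  out <- list()
  for (k in seq_len(nrow(peaks))) {
    pr <- peaks[k, 1]; pc <- peaks[k, 2]
    if (claimed[pr, pc]) next
    s <- best_sig[pr, pc]
    sm <- smooth1[[as.character(s)]]
    rad <- ceiling(3.5 * s)
    rows <- max(1L, pr - rad):min(size[1], pr + rad)
    cols <- max(1L, pc - rad):min(size[2], pc + rad)
    patch <- sm[rows, cols, drop = FALSE]
    bg <- stats::quantile(patch, 0.2, names = FALSE)
    thr <- bg + 0.5 * (sm[pr, pc] - bg)
    lab <- EBImage::bwlabel(patch >= thr)
    lab <- as.matrix(EBImage::imageData(lab))
    comp <- lab[pr - rows[1] + 1L, pc - cols[1] + 1L]
    if (comp == 0) next
    sel <- which(lab == comp, arr.ind = TRUE)
    area <- nrow(sel)
    idx <- sort((cols[sel[, 2]] - 1L) * size[1] + rows[sel[, 1]])
    already <- claimed[idx]
    if (mean(already) > 0.3) next
    claimed[idx] <- TRUE
    if (area < min_area || area > max_area) next
    out[[length(out) + 1L]] <- list(idx = idx, resp = resp_vals[k],
                                    cen = c(mean(rows[sel[, 1]]), mean(cols[sel[, 2]])))
  }
  if (length(out) == 0L) return(list())
  if (!is.null(dendrite_proximity_px)) {
    if (is.null(dendrite_mask)) dendrite_mask <- estimate_dendrite_mask(img)
    if (any(dendrite_mask)) {
      dmap <- as.matrix(EBImage::imageData(EBImage::distmap(1 - dendrite_mask)))
      out <- Filter(function(b) {
        dmap[round(b$cen[1]), round(b$cen[2])] <= dendrite_proximity_px
      }, out)
    }
  }
  if (length(out) == 0L) return(list())
  mx <- max(vapply(out, function(b) b$resp, numeric(1)))
  lapply(seq_along(out), function(i)
    instance_mask(out[[i]]$idx, score = out[[i]]$resp / mx,
                  label_id = i, shape = size))
}

local_maxima <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  p <- matrix(-Inf, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- m
  res <- matrix(TRUE, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    res <- res & m >= p[(2:(nr + 1L)) + dr, (2:(nc + 1L)) + dc]
  }
  res
}

# Rough dendrite mask: a robust background threshold (the arbor is dim but
# above background) followed by selection of elongated connected
# components — the arbor spans the frame, while beads and droplets are
# compact blobs.
estimate_dendrite_mask <- function(img) {
  sm <- as.matrix(EBImage::imageData(EBImage::gblur(img, sigma = 1.5)))
  thr <- stats::median(sm) + 4 * stats::mad(sm)
  bw <- sm > thr
  lab <- as.matrix(EBImage::imageData(EBImage::bwlabel(bw)))
  if (max(lab) == 0) return(bw)
  px <- which(lab > 0)
  r <- (px - 1L) %% nrow(img) + 1L
  c <- (px - 1L) %/% nrow(img) + 1L
  ids <- lab[px]
  extent <- vapply(seq_len(max(lab)), function(k) {
    sel <- ids == k
    if (!any(sel)) return(0)
    max(diff(range(r[sel])), diff(range(c[sel])))
  }, numeric(1))
  keep <- which(extent >= 0.2 * min(dim(img)))
  matrix(lab %in% keep, nrow(img), ncol(img))
}

#' Blob-baseline backend for [segment_image()]
#' @param ... parameters forwarded to [blob_baseline_segment()].
#' @return a backend function `(pixels, spec) -> list of instance_mask`.
#' @export
blob_backend <- function(...) {
  args <- list(...)
  function(pixels, spec) do.call(blob_baseline_segment, c(list(pixels), args))
}

#' Recorded CNN backend configuration
#'
#' The training protocol for a Mask R-CNN-style instance-segmentation
#' backend, recorded as a configuration schema: network training runs on
#' GPU infrastructure outside this package, and a trained model plugs in
#' through the same per-tile backend contract as the shipped backends.
#'
#' @return a named list documenting the training configuration.
#' @export
cnn_backend_config <- function() {
  list(architecture = "mask-rcnn (ResNet-101 + FPN)",
       pretrained = "imagenet",
       epochs_head = 20L, epochs_full = 400L,
       holdout_frac = 0.20,
       augmentations = c("fliplr", "flipud", "rot90", "shear"),
       tile = 1024L, stride = 512L,
       score_min = 0.7, overlap_max = 0.30,
       checkpoint = "lowest-validation-loss")
}
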