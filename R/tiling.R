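# Tiling of large images and raster-order stitching of per-tile instances.
#
# A 2048 x 2048 projection is split into 9 overlapping 1024 tiles
# (stride 512); non-conforming sizes are symmetrically padded first.

#' Plan an overlapping tile grid
#'
#' Lays a regular grid of square tiles over an image, padding it
#' symmetrically (extra pixel to the bottom/right) when the grid does not
#' fit exactly. Per axis the number of grid positions is
#' `n = max(1, ceiling((dim - tile)/stride) + 1)` at multiples of `stride`,
#' and the padded dimension is `stride*(n-1) + tile`. A 2048 x 2048 image
#' with the default tile 1024 / stride 512 yields exactly 9 tiles and no
#' padding.
#'
#' @param shape `(height, width)` of the source image.
#' @param tile tile side in pixels (default 1024).
#' @param stride grid step in pixels, `1 <= stride <= tile` (default 512,
#'   i.e. 50% overlap).
#' @return a list of class `tile_plan` with `pad` (top, bottom, left,
#'   right), `padded` (height, width), `tile`, `stride` and `tiles`, a list
#'   of specs `(row0, col0, size, pad)` with 1-based origins in padded
#'   coordinates, in raster order (top-left to bottom-right).
#' @export
plan_tiles <- function(shape, tile = 1024L, stride = 512L) {
  if (tile < 1 || stride < 1 || stride > tile)
    stop("need tile >= 1 and 1 <= stride <= tile")
  shape <- as.integer(shape)
  n_ax <- pmax(1L, as.integer(ceiling((shape - tile) / stride)) + 1L)
  padded <- as.integer(stride * (n_ax - 1L) + tile)
  extra <- padded - shape
  pad <- c(top = extra[1] %/% 2L, bottom = extra[1] - extra[1] %/% 2L,
           left = extra[2] %/% 2L, right = extra[2] - extra[2] %/% 2L)
  tiles <- list()
  for (i in seq_len(n_ax[1]) - 1L) {
    for (j in seq_len(n_ax[2]) - 1L) {
      tiles[[length(tiles) + 1L]] <- list(
        row0 = i * stride + 1L, col0 = j * stride + 1L,
        size = as.integer(tile), pad = pad)
    }
  }
  structure(list(pad = pad, padded = padded, shape = shape,
                 tile = as.integer(tile), stride = as.integer(stride),
                 n_rows = n_ax[1], n_cols = n_ax[2], tiles = tiles),
            class = "tile_plan")
}

#' @export
print.tile_plan <- function(x, ...) {
  cat(sprintf("<tile_plan> %d x %d tiles of %d px (stride %d) over %d x %d, pad (%s)\n",
              x$n_rows, x$n_cols, x$tile, x$stride, x$shape[1], x$shape[2],
              paste(x$pad, collapse = ",")))
  invisible(x)
}

# Half-sample symmetric reflection of index i into 1..n (edge pixel is
# repeated: ... 2 1 | 1 2 ...
reflect_index <- function(i, n) {
  m <- ((i - 1L) %% (2L * n) + 2L * n) %% (2L * n)
  ifelse(m < n, m + 1L, 2L * n - m)
}

#' Extract tiles from an image
#'
#' Cuts the tiles of a [plan_tiles()] grid out of the image, filling padded
#' borders by mirror reflection of the boundary pixels.
#'
#' @param img a [fluor_image()].
#' @param plan a `tile_plan` produced for `dim(img$pixels)`.
#' @return a list with one element per tile: `list(spec, pixels)` where
#'   `pixels` is a `tile x tile` matrix.
#' @export
extract_tiles <- function(img, plan) {
  if (!identical(as.integer(dim(img$pixels)), plan$shape))
    stop("plan was made for a different image shape")
  m <- img$pixels
  h <- plan$shape[1]; w <- plan$shape[2]
  lapply(plan$tiles, function(sp) {
    rows <- reflect_index(sp$row0 + seq_len(sp$size) - 1L - plan$pad["top"], h)
    cols <- reflect_index(sp$col0 + seq_len(sp$size) - 1L - plan$pad["left"], w)
    list(spec = sp, pixels = m[rows, cols, drop = FALSE])
  })
}

# Map an instance's tile-local pixel indices to source-image indices,
# dropping pixels that fall into the padding. Returns integer(0) if the
# whole mask lies outside the source frame.
tile_idx_to_source <- function(idx, spec, source_shape) {
  size <- spec$size
  r <- (idx - 1L) %% size + 1L
  c <- (idx - 1L) %/% size + 1L
  rs <- r + spec$row0 - 1L - spec$pad["top"]
  cs <- c + spec$col0 - 1L - spec$pad["left"]
  keep <- rs >= 1L & rs <= source_shape[1] & cs >= 1L & cs <= source_shape[2]
  sort(as.integer((cs[keep] - 1L) * source_shape[1] + rs[keep]))
}

#' Stitch per-tile detections and merge duplicates
#'
#' Combines per-tile instance masks into one result over the source image
#' using the raster-order merge rule: tiles are visited top-left to
#' bottom-right; within a tile candidates are taken in descending score
#' (ties by ascending label); a candidate is dropped unless its predicted
#' probability exceeds `score_min` (strictly greater than 0.7 by default),
#' and is then kept only if it does not overlap any already-kept mask by
#' more than `overlap_max` of its own area (strictly more than 30% by
#' default discards). Masks are mapped back to source coordinates with the
#' padding removed; a mask empty after clipping is dropped.
#'
#' @param per_tile list of `list(spec, instances)` where `instances` are
#'   [instance_mask()] objects in tile-local coordinates.
#' @param source_shape `(height, width)` of the source image.
#' @param score_min keep only scores strictly greater than this (default
#'   0.7).
#' @param overlap_max discard a candidate whose overlap with any kept mask
#'   exceeds this fraction of the candidate's area (default 0.30).
#' @param backend backend name recorded in the result.
#' @return a [segmentation_result()] with instances relabeled 1..K in keep
#'   order; `params` records the thresholds used.
#' @export
stitch_and_merge <- function(per_tile, source_shape, score_min = 0.7,
                             overlap_max = 0.30, backend = "stitched") {
  source_shape <- as.integer(source_shape)
  ord <- order(vapply(per_tile, function(t) t$spec$row0, numeric(1)),
               vapply(per_tile, function(t) t$spec$col0, numeric(1)))
  kept <- list()
  kept_bb <- NULL  # bounding boxes of kept masks for pruning
  for (t in per_tile[ord]) {
    insts <- t$instances
    if (length(insts) == 0L) next
    sc <- vapply(insts, function(i) i$score, numeric(1))
    lb <- vapply(insts, function(i) i$label_id, numeric(1))
    for (k in order(-sc, lb)) {
      cand <- insts[[k]]
      if (!(cand$score > score_min)) next
      if (!identical(as.integer(cand$shape), rep(as.integer(t$spec$size), 2L)))
        stop(sprintf("backend mask shape %s does not match tile size %d at tile (%d,%d)",
                     paste(cand$shape, collapse = "x"), t$spec$size,
                     t$spec$row0, t$spec$col0))
      idx <- tile_idx_to_source(cand$idx, t$spec, source_shape)
      if (length(idx) == 0L) next
      bb <- c(min((idx - 1L) %% source_shape[1]), max((idx - 1L) %% source_shape[1]),
              min((idx - 1L) %/% source_shape[1]), max((idx - 1L) %/% source_shape[1]))
      ok <- TRUE
      if (length(kept)) {
        for (j in seq_along(kept)) {
          kb <- kept_bb[j, ]
          if (bb[1] > kb[2] || bb[2] < kb[1] || bb[3] > kb[4] || bb[4] < kb[3]) next
          ov <- length(intersect(idx, kept[[j]]$idx)) / length(idx)
          if (ov > overlap_max) { ok <- FALSE; break }
        }
      }
      if (ok) {
        kept[[length(kept) + 1L]] <- instance_mask(idx, score = cand$score,
                                                   label_id = length(kept) + 1L,
                                                   shape = source_shape)
        kept_bb <- rbind(kept_bb, bb)
      }
    }
  }
  segmentation_result(kept, source_shape, backend = backend,
                      params = list(score_min = score_min, overlap_max = overlap_max))
}

#' Segment a full image through a tiled backend
#'
#' Plans tiles, extracts them, runs a per-tile backend, and stitches the
#' detections with [stitch_and_merge()].
#'
#' @param img a [fluor_image()].
#' @param backend a function `(pixels, spec) -> list of instance_mask` in
#'   tile-local coordinates; see [oracle_backend()] and [blob_backend()].
#' @param tile,stride tile grid parameters (defaults 1024/512).
#' @param score_min,overlap_max merge thresholds, see [stitch_and_merge()].
#' @param backend_name name recorded in the result.
#' @return a [segmentation_result()].
#' @export
segment_image <- function(img, backend, tile = 1024L, stride = 512L,
                          score_min = 0.7, overlap_max = 0.30,
                          backend_name = "backend") {
  plan <- plan_tiles(dim(img$pixels), tile = tile, stride = stride)
  tiles <- extract_tiles(img, plan)
  per_tile <- lapply(tiles, function(t) {
    insts <- tryCatch(backend(t$pixels, t$spec), error = function(e)
      stop(sprintf("backend failed on tile (%d,%d): %s",
                   t$spec$row0, t$spec$col0, conditionMessage(e))))
    list(spec = t$spec, instances = insts)
  })
  res <- stitch_and_merge(per_tile, dim(img$pixels), score_min = score_min,
                          overlap_max = overlap_max, backend = backend_name)
  res$params$tile <- as.integer(tile)
  res$params$stride <- as.integer(stride)
  res
}
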