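# Instance masks, segmentation results, and their on-disk form.

#' Construct an instance mask
#'
#' One detected (or ground-truth) bead: a set of foreground pixels in the
#' source image, a foreground-probability score, and a label unique within
#' its segmentation result. Pixels are stored sparsely as sorted 1-based
#' linear indices (column-major, as in R matrices).
#'
#' @param pixels either a logical/0-1 matrix of the full source shape or an
#'   integer vector of linear pixel indices.
#' @param score foreground probability in `[0, 1]`; 1 for ground truth.
#' @param label_id positive integer label.
#' @param shape `(height, width)` of the source image; required when
#'   `pixels` is an index vector.
#' @return an object of class `instance_mask` with elements `idx`, `score`,
#'   `label_id`, `shape`.
#' @export
instance_mask <- function(pixels, score = 1, label_id = 1L, shape = NULL) {
  if (is.matrix(pixels)) {
    shape <- dim(pixels)
    idx <- which(pixels != 0)
  } else {
    if (is.null(shape)) stop("`shape` is required when `pixels` is an index vector")
    idx <- sort(unique(as.integer(pixels)))
  }
  if (length(idx) < 1L) stop("instance mask must have >= 1 foreground pixel")
  if (any(idx < 1L) || any(idx > prod(shape))) stop("mask pixels outside the image frame")
  if (!is.finite(score) || score < 0 || score > 1) stop("score must be in [0, 1]")
  if (label_id < 1) stop("label_id must be a positive integer")
  structure(list(idx = as.integer(idx), score = as.numeric(score),
                 label_id = as.integer(label_id), shape = as.integer(shape)),
            class = "instance_mask")
}

#' Dense binary matrix for one instance mask
#' @param inst an [instance_mask()].
#' @return a 0/1 integer matrix of the source shape.
#' @export
as_mask_matrix <- function(inst) {
  m <- matrix(0L, inst$shape[1L], inst$shape[2L])
  m[inst$idx] <- 1L
  m
}

#' Intersection-over-union of two instance masks
#' @param a,b [instance_mask()] objects on the same source shape.
#' @return the Jaccard index in `[0, 1]`.
#' @export
mask_iou <- function(a, b) {
  i <- length(intersect(a$idx, b$idx))
  u <- length(a$idx) + length(b$idx) - i
  i / u
}

#' Construct a segmentation result
#'
#' An ordered set of instance masks over one source image, with provenance
#' (which backend, which thresholds).
#'
#' @param instances list of [instance_mask()]; label ids must be unique.
#' @param shape `(height, width)` of the source image.
#' @param backend backend name string.
#' @param params named list of thresholds/parameters used.
#' @return an object of class `segmentation_result`.
#' @export
segmentation_result <- function(instances, shape, backend = "unknown", params = list()) {
  shape <- as.integer(shape)
  labs <- vapply(instances, function(i) i$label_id, integer(1))
  if (anyDuplicated(labs)) stop("label_ids must be unique within a result")
  for (i in instances) {
    if (!identical(as.integer(i$shape), shape))
      stop("instance mask shape does not match source shape")
  }
  structure(list(instances = instances, shape = shape,
                 backend = backend, params = params),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("<segmentation_result> %d instances on %d x %d (backend: %s)\n",
              length(x$instances), x$shape[1], x$shape[2], x$backend))
  invisible(x)
}

#' @export
length.segmentation_result <- function(x) length(x$instances)

#' Write a segmentation result to disk
#'
#' Serializes a result as a human-inspectable pair of files: `<path>.tif`, a
#' 16-bit labeled image (0 = background, k = pixels of instance k), and
#' `<path>.json`, a sidecar holding shape, provenance, and per-instance
#' scores. Instances whose pixels collide in the label plane (post-merge
#' overlaps are legal) additionally carry run-length records in the sidecar
#' so the round trip is lossless.
#'
#' @param result a [segmentation_result()].
#' @param path output path stem (no extension).
#' @return `path`, invisibly.
#' @seealso [read_masks()]
#' @export
write_masks <- function(result, path) {
  shape <- result$shape
  plane <- matrix(0L, shape[1], shape[2])
  for (inst in result$instances) plane[inst$idx] <- inst$label_id
  recs <- lapply(result$instances, function(inst) {
    rec <- list(label_id = inst$label_id, score = inst$score)
    got <- which(plane == inst$label_id)
    if (!identical(as.integer(got), inst$idx)) {
      r <- rle_encode(inst$idx)
      rec$rle_starts <- r$starts
      rec$rle_lengths <- r$lengths
    }
    rec
  })
  doc <- list(shape = shape, backend = result$backend,
              params = result$params, instances = recs)
  tiff::writeTIFF(plane / 65535, paste0(path, ".tif"), bits.per.sample = 16)
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA),
             paste0(path, ".json"))
  invisible(path)
}

#' Read a segmentation result from disk
#'
#' @param path path stem used with [write_masks()].
#' @param source_shape expected `(height, width)`; a mismatch with the
#'   stored shape is a format error.
#' @return a [segmentation_result()] identical to the one written.
#' @export
read_masks <- function(path, source_shape = NULL) {
  doc <- jsonlite::fromJSON(paste0(path, ".json"), simplifyVector = TRUE)
  shape <- as.integer(doc$shape)
  if (!is.null(source_shape) && !identical(as.integer(source_shape), shape))
    stop("stored mask shape (", paste(shape, collapse = "x"),
         ") does not match expected shape")
  plane <- round(tiff::readTIFF(paste0(path, ".tif")) * 65535)
  if (!identical(as.integer(dim(plane)), shape))
    stop("label image shape does not match sidecar shape")
  n <- if (is.data.frame(doc$instances)) nrow(doc$instances) else length(doc$instances)
  insts <- vector("list", n %||% 0L)
  if (n > 0) {
    for (k in seq_len(n)) {
      rec <- if (is.data.frame(doc$instances)) lapply(doc$instances, `[[`, k)
             else doc$instances[[k]]
      rs <- rec$rle_starts
      if (!is.null(rs) && length(rs) > 0 && !all(is.na(rs))) {
        idx <- rle_decode(rs[!is.na(rs)], rec$rle_lengths[!is.na(rec$rle_lengths)])
      } else {
        idx <- which(plane == rec$label_id)
      }
      insts[[k]] <- instance_mask(idx, score = rec$score,
                                  label_id = rec$label_id, shape = shape)
    }
  }
  segmentation_result(insts, shape, backend = doc$backend %||% "unknown",
                      params = as.list(doc$params))
}
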