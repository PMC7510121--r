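# Instance-level evaluation: one-to-one IoU matching, precision, recall,
# per-bead Jaccard.

#' Match predicted to ground-truth instances
#'
#' Computes all prediction x truth IoUs and matches greedily in descending
#' IoU, accepting pairs with IoU >= `iou_min`; each prediction and each
#' truth instance appears in at most one match. Leftover predictions are
#' false positives, leftover truths false negatives. Ties are broken by
#' ascending (pred label, truth label) for determinism.
#'
#' @param pred,truth [segmentation_result()] objects on the same source
#'   shape.
#' @param iou_min minimum IoU for a true positive (default 0.3; safely
#'   below the typical per-bead Jaccard of a good segmenter, ~0.7).
#' @return an object of class `match_result` with `matches` (data frame
#'   `pred_label, truth_label, iou`), `fp_labels`, `fn_labels`, `n_tp`,
#'   `n_fp`, `n_fn` and the `iou_min` used.
#' @export
match_instances <- function(pred, truth, iou_min = 0.3) {
  if (!identical(pred$shape, truth$shape))
    stop("prediction and truth have different source shapes")
  np <- length(pred$instances); nt <- length(truth$instances)
  plab <- vapply(pred$instances, function(i) i$label_id, integer(1))
  tlab <- vapply(truth$instances, function(i) i$label_id, integer(1))
  cand <- NULL
  if (np > 0 && nt > 0) {
    h <- pred$shape[1]
    bb <- function(inst) {
      r <- (inst$idx - 1L) %% h; c <- (inst$idx - 1L) %/% h
      c(min(r), max(r), min(c), max(c))
    }
    pbb <- t(vapply(pred$instances, bb, numeric(4)))
    tbb <- t(vapply(truth$instances, bb, numeric(4)))
    for (i in seq_len(np)) for (j in seq_len(nt)) {
      if (pbb[i, 1] > tbb[j, 2] || pbb[i, 2] < tbb[j, 1] ||
          pbb[i, 3] > tbb[j, 4] || pbb[i, 4] < tbb[j, 3]) next
      iou <- mask_iou(pred$instances[[i]], truth$instances[[j]])
      if (iou >= iou_min)
        cand <- rbind(cand, c(i, j, iou))
    }
  }
  matches <- data.frame(pred_label = integer(0), truth_label = integer(0),
                        iou = numeric(0))
  used_p <- logical(np); used_t <- logical(nt)
  if (!is.null(cand)) {
    ord <- order(-cand[, 3], plab[cand[, 1]], tlab[cand[, 2]])
    for (k in ord) {
      i <- cand[k, 1]; j <- cand[k, 2]
      if (used_p[i] || used_t[j]) next
      used_p[i] <- TRUE; used_t[j] <- TRUE
      matches <- rbind(matches, data.frame(pred_label = plab[i],
                                           truth_label = tlab[j],
                                           iou = cand[k, 3]))
    }
  }
  structure(list(matches = matches,
                 fp_labels = plab[!used_p], fn_labels = tlab[!used_t],
                 n_tp = nrow(matches), n_fp = sum(!used_p), n_fn = sum(!used_t),
                 iou_min = iou_min),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> TP %d, FP %d, FN %d (iou_min %.2f)\n",
              x$n_tp, x$n_fp, x$n_fn, x$iou_min))
  invisible(x)
}

#' Segmentation scores from a match result
#'
#' Precision = TP / (TP + FP), recall = TP / (TP + FN); the mean and sd of
#' the matched-pair Jaccard indices measure pixel-level accuracy. With no
#' predictions, precision is undefined (`NA`) and recall 0 (when truths
#' exist).
#'
#' @param match a [match_result()].
#' @return an object of class `evaluation_scores` with `precision`,
#'   `recall`, `mean_jaccard`, `jaccard_sd`, `per_bead_jaccard` and the
#'   counts.
#' @export
score_matches <- function(match) {
  tp <- match$n_tp; fp <- match$n_fp; fn <- match$n_fn
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  pj <- match$matches$iou
  structure(list(precision = precision, recall = recall,
                 mean_jaccard = if (length(pj)) mean(pj) else NA_real_,
                 jaccard_sd = if (length(pj) > 1) stats::sd(pj) else NA_real_,
                 per_bead_jaccard = pj,
                 n_tp = tp, n_fp = fp, n_fn = fn),
            class = "evaluation_scores")
}

#' @export
print.evaluation_scores <- function(x, ...) {
  cat(sprintf("<evaluation_scores> precision %.3f, recall %.3f, mean Jaccard %.3f (TP %d FP %d FN %d)\n",
              x$precision, x$recall, x$mean_jaccard, x$n_tp, x$n_fp, x$n_fn))
  invisible(x)
}

#' Stratified performance summary
#'
#' Summarizes per-image precision/recall overall and split into images with
#' a low (`< threshold`) and high (`>= threshold`) number of ground-truth
#' beads (the conventional split at 100 beads).
#'
#' @param per_image data frame with columns `precision`, `recall`,
#'   `truth_count`.
#' @param threshold bead-count split point (default 100).
#' @return a data frame with one row per stratum (`low`, `high`, `overall`;
#'   empty strata are absent) and columns `stratum, n, precision_mean,
#'   precision_sem, recall_mean, recall_sem`.
#' @export
stratified_report <- function(per_image, threshold = 100) {
  stopifnot(all(c("precision", "recall", "truth_count") %in% names(per_image)))
  strata <- list(low = per_image$truth_count < threshold,
                 high = per_image$truth_count >= threshold,
                 overall = rep(TRUE, nrow(per_image)))
  rows <- lapply(names(strata), function(nm) {
    d <- per_image[strata[[nm]], , drop = FALSE]
    if (nrow(d) == 0) return(NULL)
    data.frame(stratum = nm, n = nrow(d),
               precision_mean = mean(d$precision, na.rm = TRUE),
               precision_sem = sem(d$precision),
               recall_mean = mean(d$recall, na.rm = TRUE),
               recall_sem = sem(d$recall))
  })
  do.call(rbind, rows)
}

#' Droplet rejection rate on a synthetic scene
#'
#' The "true negative" measure only a simulator can provide: the fraction
#' of placed droplet confounders that the segmenter correctly ignored. A
#' droplet counts as detected when some predicted instance's centroid falls
#' inside the droplet's disc.
#'
#' @param pred a [segmentation_result()].
#' @param scene a `synthetic_scene`.
#' @return `1 - detected/placed`, or `NA` if no droplets were placed.
#' @export
droplet_rejection_rate <- function(pred, scene) {
  drops <- scene$droplets
  if (is.null(drops) || nrow(drops) == 0) return(NA_real_)
  h <- pred$shape[1]
  cens <- lapply(pred$instances, function(i) {
    c(mean((i$idx - 1L) %% h + 1L), mean((i$idx - 1L) %/% h + 1L))
  })
  detected <- vapply(seq_len(nrow(drops)), function(k) {
    any(vapply(cens, function(cc) {
      sqrt((cc[1] - drops$r[k])^2 + (cc[2] - drops$c[k])^2) <= drops$radius[k]
    }, logical(1)))
  }, logical(1))
  1 - mean(detected)
}
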