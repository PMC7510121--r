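test_that("a perfect prediction yields all TPs with unit Jaccard", {
  shape <- c(64L, 64L)
  truth <- segmentation_result(
    list(disc_instance(15, 15, 4, shape, label_id = 1L),
         disc_instance(40, 45, 5, shape, label_id = 2L)), shape)
  m <- match_instances(truth, truth)
  expect_equal(m$n_tp, 2); expect_equal(m$n_fp, 0); expect_equal(m$n_fn, 0)
  expect_true(all(m$matches$iou == 1))
  s <- score_matches(m)
  expect_equal(s$precision, 1); expect_equal(s$recall, 1)
  expect_equal(s$mean_jaccard, 1)
})

test_that("the constructed 8-TP / 1-FP / 2-FN case scores 8/9 and 0.8", {
  shape <- c(200L, 200L)
  centers <- cbind(r = seq(20, 180, length.out = 10),
                   c = rep(c(60, 140), 5))
  truth <- segmentation_result(lapply(1:10, function(k)
    disc_instance(centers[k, 1], centers[k, 2], 5, shape, label_id = k)), shape)
  preds <- lapply(1:8, function(k)
    disc_instance(centers[k, 1], centers[k, 2], 5, shape, score = 0.9,
                  label_id = k))
  preds[[9]] <- disc_instance(100, 100, 5, shape, score = 0.8, label_id = 9L)
  pred <- segmentation_result(preds, shape)
  m <- match_instances(pred, truth)
  expect_equal(c(m$n_tp, m$n_fp, m$n_fn), c(8L, 1L, 2L))
  s <- score_matches(m)
  expect_equal(s$precision, 8 / 9)
  expect_equal(s$recall, 0.8)
})

test_that("two predictions over one truth: the better IoU wins, the other is FP", {
  shape <- c(64L, 64L)
  truth <- segmentation_result(list(disc_instance(30, 30, 6, shape)), shape)
  pred <- segmentation_result(
    list(disc_instance(30, 30, 6, shape, score = 0.9, label_id = 1L),
         disc_instance(30, 34, 6, shape, score = 0.9, label_id = 2L)), shape)
  m <- match_instances(pred, truth)
  expect_equal(m$n_tp, 1)
  expect_equal(m$matches$pred_label, 1L)
  expect_equal(m$fp_labels, 2L)
})

test_that("swapping prediction and truth swaps FP with FN and precision with recall", {
  shape <- c(100L, 100L)
  a <- segmentation_result(lapply(1:4, function(k)
    disc_instance(20 * k, 30, 4, shape, label_id = k)), shape)
  b <- segmentation_result(lapply(1:3, function(k)
    disc_instance(20 * k, 30, 4, shape, label_id = k)), shape)
  mab <- match_instances(a, b); mba <- match_instances(b, a)
  expect_equal(mab$n_fp, mba$n_fn)
  expect_equal(mab$n_fn, mba$n_fp)
  sab <- score_matches(mab); sba <- score_matches(mba)
  expect_equal(sab$precision, sba$recall)
  expect_equal(sab$recall, sba$precision)
})

test_that("empty predictions follow the undefined-precision convention", {
  shape <- c(50L, 50L)
  truth <- segmentation_result(lapply(1:5, function(k)
    disc_instance(8 * k, 25, 3, shape, label_id = k)), shape)
  none <- segmentation_result(list(), shape)
  s <- score_matches(match_instances(none, truth))
  expect_true(is.na(s$precision))
  expect_equal(s$recall, 0)
})

test_that("greedy matching equals exhaustive optimal assignment on small fixtures", {
  shape <- c(80L, 80L)
  set.seed(404)
  for (rep in 1:30) {
    nt <- sample(1:6, 1); np <- sample(1:6, 1)
    truth <- segmentation_result(lapply(seq_len(nt), function(k)
      disc_instance(runif(1, 10, 70), runif(1, 10, 70), runif(1, 3, 7),
                    shape, label_id = k)), shape)
    pred <- segmentation_result(lapply(seq_len(np), function(k)
      disc_instance(runif(1, 10, 70), runif(1, 10, 70), runif(1, 3, 7),
                    shape, score = 0.9, label_id = k)), shape)
    greedy <- match_instances(pred, truth)
    brute <- brute_force_match(pred, truth)
    expect_equal(greedy$n_tp, unname(brute[["n"]]),
                 info = sprintf("fixture %d", rep))
  }
})

test_that("boundary-perturbed masks land in the expected Jaccard corridor", {
  prof <- default_profiles()$young
  sc <- generate_population(prof, 1, shape = c(512L, 512L), seed = 91)[[1]]
  seg <- segment_image(sc$rendered,
                       oracle_backend(sc$truth, oracle_noise(dilate_px = 1)),
                       tile = 256, stride = 128)
  s <- score_matches(match_instances(seg, sc$truth))
  expect_lt(s$mean_jaccard, 1)
  expect_gt(s$mean_jaccard, 0.3)
})

test_that("the stratified report splits at the bead-count threshold", {
  per_image <- data.frame(precision = c(0.9, 0.8, 0.95),
                          recall = c(0.92, 0.85, 0.9),
                          truth_count = c(30, 120, 150))
  rep <- stratified_report(per_image)
  expect_setequal(rep$stratum, c("low", "high", "overall"))
  expect_equal(rep$n[rep$stratum == "low"], 1)
  expect_equal(rep$n[rep$stratum == "high"], 2)
  low_only <- stratified_report(per_image[1, , drop = FALSE])
  expect_false("high" %in% low_only$stratum)
})

test_that("population recall under a noisy oracle tracks the configured drop rate", {
  prof <- default_profiles()$aged
  pop <- generate_population(prof, 6, shape = c(512L, 512L), seed = 55)
  tp <- 0; fn <- 0
  for (i in seq_along(pop)) {
    sc <- pop[[i]]
    seg <- segment_image(sc$rendered,
                         oracle_backend(sc$truth,
                                        oracle_noise(drop_rate = 0.08,
                                                     seed = 100 + i)),
                         tile = 256, stride = 128)
    m <- match_instances(seg, sc$truth)
    tp <- tp + m$n_tp; fn <- fn + m$n_fn
  }
  recall <- tp / (tp + fn)
  n <- tp + fn
  expect_lt(abs(recall - 0.92), 3 * sqrt(0.92 * 0.08 / n))
})
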