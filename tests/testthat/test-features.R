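test_that("bead records measure uniform discs exactly", {
  shape <- c(40L, 40L)
  inst <- disc_instance(20, 20, 3.5, shape)
  img <- fluor_image(matrix(100, 40, 40))
  rec <- bead_records(img, segmentation_result(list(inst), shape))
  expect_equal(rec$area_px, length(inst$idx))
  expect_equal(rec$mean_intensity, 100)
  expect_equal(rec$median_intensity, 100)
  expect_equal(rec$integrated_intensity, 100 * length(inst$idx))
  expect_equal(rec$centroid_r, 20, tolerance = 0.5)
  expect_equal(rec$centroid_c, 20, tolerance = 0.5)
  expect_lt(rec$eccentricity, 0.1)
  expect_gt(rec$solidity, 0.9)

  # a 1-px-wide line is maximally eccentric
  line <- rect_instance(10, 10, 5, 25, shape, label_id = 1L)
  rl <- bead_records(img, segmentation_result(list(line), shape))
  expect_gt(rl$eccentricity, 0.99)
})

test_that("pairwise distances enumerate all unordered pairs", {
  rec <- data.frame(centroid_r = c(0, 3), centroid_c = c(0, 4))
  expect_equal(pairwise_distances(rec), 5)
  rec3 <- data.frame(centroid_r = c(0, 0, 0), centroid_c = c(0, 3, 6))
  expect_setequal(pairwise_distances(rec3), c(3, 6, 3))
  expect_equal(mean(pairwise_distances(rec3)), 4)
  expect_length(pairwise_distances(rec[1, , drop = FALSE]), 0)
})

test_that("the worked two-bead fixture reproduces the anchored metrics by hand", {
  rec <- two_bead_records()
  fv <- feature_vector(rec)
  expect_length(as.numeric(fv), 46)
  expect_equal(unname(fv["m01"]), 2)
  expect_equal(unname(fv["m02"]), 200)
  expect_equal(unname(fv["m16"]), 0.5)       # one of two beads < 100 px
  expect_equal(unname(fv["m17"]), 5)         # 3-4-5 centroids
  expect_equal(unname(fv["m21"]), 1)         # the single pair is < 150 px
  expect_equal(unname(fv["m25"]), 100)       # median of {50, 150}
  expect_equal(unname(fv["m26"]), 150)
  expect_equal(unname(fv["m32"]), 110)       # median of {100, 120}
  expect_equal(unname(fv["m35"]), sd(c(100, 120)))
  expect_equal(unname(fv["m37"]), unname(quantile(c(100, 120), 0.9)))
  # SEM of a single pairwise distance is undefined
  expect_true(attr(fv, "undefined")[["m20"]])
})

test_that("zero beads leave only the counting metrics defined", {
  img <- fluor_image(matrix(1, 10, 10))
  rec <- bead_records(img, segmentation_result(list(), c(10L, 10L)))
  fv <- feature_vector(rec)
  expect_equal(unname(fv["m01"]), 0)
  expect_equal(unname(fv["m02"]), 0)
  und <- attr(fv, "undefined")
  expect_true(all(und[c("m03", "m17", "m25", "m32", "m43")]))
})

test_that("feature invariants hold on random scenes", {
  sc <- generate_population(default_profiles()$aged, 1,
                            shape = c(512L, 512L), seed = 17)[[1]]
  rec <- bead_records(sc$rendered, sc$truth)
  fv <- feature_vector(rec)
  expect_equal(unname(fv["m02"]), sum(rec$area_px))
  expect_equal(unname(fv["m01"] * fv["m03"]), unname(fv["m02"]))
  expect_equal(sum(fv[sprintf("m%02d", 6:10)]), 1)
  frac <- fv[c("m06", "m07", "m08", "m09", "m10", "m16", "m21", "m22")]
  expect_true(all(frac >= 0 & frac <= 1))
  expect_true(fv["m28"] <= fv["m25"] && fv["m25"] <= fv["m29"] &&
              fv["m29"] <= fv["m30"])

  # m17 equals an independent brute-force double loop
  n <- nrow(rec)
  acc <- 0; cnt <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    acc <- acc + sqrt((rec$centroid_r[i] - rec$centroid_r[j])^2 +
                      (rec$centroid_c[i] - rec$centroid_c[j])^2)
    cnt <- cnt + 1
  }
  expect_equal(unname(fv["m17"]), acc / cnt)
  expect_equal(cnt, choose(n, 2))

  # distance metrics are invariant under bead relabeling
  perm <- sample(n)
  fv2 <- feature_vector(rec[perm, ])
  expect_equal(as.numeric(fv2), as.numeric(fv))
})

test_that("population summaries compute SEM and respect undefined entries", {
  tbl <- rbind(
    data.frame(animal_id = "a", region = "anterior", condition = "young",
               t(setNames(rep(1, 46), beadmorph:::METRIC_NAMES))),
    data.frame(animal_id = "b", region = "anterior", condition = "young",
               t(setNames(rep(2, 46), beadmorph:::METRIC_NAMES))),
    data.frame(animal_id = "c", region = "anterior", condition = "young",
               t(setNames(rep(3, 46), beadmorph:::METRIC_NAMES))))
  tbl$m17[3] <- NA
  s <- population_summary(tbl)
  m01 <- s[s$metric == "m01", ]
  expect_equal(m01$mean, 2)
  expect_equal(m01$sem, sd(1:3) / sqrt(3))
  m17 <- s[s$metric == "m17", ]
  expect_equal(m17$n, 2)
  expect_equal(m17$mean, 1.5)

  same <- population_summary(tbl[c(1, 1), ])
  expect_equal(same$sem[same$metric == "m01"], 0)
})

test_that("Bonferroni correction reproduces the printed convention", {
  b <- bonferroni_alpha(0.05, 3)
  expect_equal(b$alpha, 0.016)
  expect_equal(b$alpha_full, 0.05 / 3)
  expect_equal(bonferroni_alpha(0.05, 1)$alpha, 0.05)
  expect_equal(bonferroni_alpha(0.06, 2)$alpha, 0.03)
})
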