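make_gaussian_task <- function(n_per_class, shift, seed, p = 46,
                               signal_cols = 17) {
  set.seed(seed)
  x <- matrix(rnorm(2 * n_per_class * p), 2 * n_per_class, p)
  colnames(x) <- sprintf("m%02d", seq_len(p))
  y <- factor(rep(c("a", "b"), each = n_per_class), levels = c("a", "b"))
  x[y == "b", signal_cols] <- x[y == "b", signal_cols] + shift
  list(x = x, y = y)
}

test_that("all four model families separate a wide-margin task perfectly", {
  # classes are two well-separated clusters in feature space
  task <- make_gaussian_task(25, shift = 3, seed = 1, signal_cols = 1:46)
  for (m in c("sde", "svm", "logistic", "knn")) {
    fit <- fit_classifier(task$x, task$y, model = m, seed = 3)
    expect_true(all(predict(fit, task$x) == task$y), info = m)
  }
})

test_that("a degenerate one-learner full-space SDE matches plain LDA", {
  task <- make_gaussian_task(30, shift = 1.5, seed = 5)
  sde <- fit_classifier(task$x, task$y, model = "sde",
                        hyperparams = list(B = 1L, d_sub = 46L, lambda = 1e-10),
                        seed = 2)
  lda <- MASS::lda(task$x, task$y)
  expect_equal(as.character(predict(sde, task$x)),
               as.character(predict(lda, task$x)$class))
})

test_that("KNN with k = 1 memorizes distinct training points", {
  task <- make_gaussian_task(15, shift = 0.5, seed = 9)
  fit <- fit_classifier(task$x, task$y, model = "knn",
                        hyperparams = list(k = 1L))
  expect_equal(mean(predict(fit, task$x) == task$y), 1)
})

test_that("stratified folds balance classes and respect the size limit", {
  y <- factor(rep(c("a", "b"), times = c(23, 37)))
  fold <- beadmorph:::stratified_folds(y, 5, seed = 4)
  for (f in 1:5) {
    expect_lte(diff(range(table(fold))), 2)
    tab <- table(y[fold == f])
    expect_lte(abs(tab[["a"]] - 23 / 5), 1)
    expect_lte(abs(tab[["b"]] - 37 / 5), 1)
  }
  expect_error(beadmorph:::stratified_folds(factor(rep(c("a", "b"),
                                                       c(3, 50))), 5, 1),
               "smallest class")
})

test_that("cross-validation is deterministic and reaches 1 on separable data", {
  task <- make_gaussian_task(60, shift = 3, seed = 11, signal_cols = 1:46)
  r1 <- cross_validate(task$x, task$y, model = "logistic", seed = 21)
  r2 <- cross_validate(task$x, task$y, model = "logistic", seed = 21)
  expect_equal(r1$cv_accuracy, 1)
  expect_identical(r1$per_fold, r2$per_fold)
  expect_identical(r1$auc, r2$auc)
})

test_that("label-permuted data drives every model to chance level", {
  set.seed(33)
  x <- matrix(rnorm(100 * 46), 100, 46)
  colnames(x) <- sprintf("m%02d", 1:46)
  y <- factor(sample(rep(c("a", "b"), 50)))
  for (m in c("sde", "svm", "logistic", "knn")) {
    r <- cross_validate(x, y, model = m, seed = 13)
    expect_true(abs(r$cv_accuracy - 0.5) < 3 * sqrt(0.25 / 100), info = m)
  }
})

test_that("AUC equals the Mann-Whitney statistic and agrees with pROC", {
  set.seed(7)
  for (rep in 1:5) {
    n1 <- sample(5:25, 1); n0 <- sample(5:25, 1)
    scores <- c(rnorm(n0), rnorm(n1, 0.8))
    y <- factor(rep(c("neg", "pos"), c(n0, n1)), levels = c("neg", "pos"))
    got <- roc_auc(scores, y)
    # brute-force pairwise comparison oracle
    s0 <- scores[y == "neg"]; s1 <- scores[y == "pos"]
    u <- mean(outer(s1, s0, function(a, b) (a > b) + 0.5 * (a == b)))
    expect_equal(got$auc, u)
    expect_equal(got$auc,
                 as.numeric(pROC::auc(pROC::roc(y, scores, quiet = TRUE,
                                                direction = "<"))))
    expect_true(all(diff(got$roc_points$fpr) >= 0))
  }
  perfect <- roc_auc(c(1, 2, 3, 10, 11, 12),
                     factor(rep(c("n", "p"), each = 3), levels = c("n", "p")))
  expect_equal(perfect$auc, 1)
  expect_warning(roc_auc(1:3, factor(rep("p", 3))), "single-class")
})

test_that("null scores give chance-level AUC", {
  set.seed(19)
  scores <- rnorm(200)
  y <- factor(rep(c("a", "b"), 100))
  auc <- roc_auc(scores, y)$auc
  expect_lt(abs(auc - 0.5), 3 * sqrt(1 / 12 * (1 / 100 + 1 / 100)))
})

test_that("stepwise selection recovers planted signals and ignores noise", {
  hits <- 0
  for (s in 1:20) {
    task <- make_gaussian_task(40, shift = 2, seed = 100 + s,
                               signal_cols = 17)
    sel <- stepwise_logistic(task$x, task$y)
    if (17 %in% sel$selected) hits <- hits + 1
  }
  expect_gte(hits, 18)  # >= 90% of seeded runs

  # two planted metrics both recovered without a flood of extras
  task2 <- make_gaussian_task(60, shift = 1.8, seed = 301,
                              signal_cols = c(16, 21))
  sel2 <- stepwise_logistic(task2$x, task2$y)
  expect_true(all(c(16, 21) %in% sel2$selected))

  # pure noise: spurious inclusions stay near the AIC false-entry rate
  set.seed(55)
  null_sizes <- vapply(1:5, function(s) {
    task <- make_gaussian_task(40, shift = 0, seed = 400 + s)
    length(stepwise_logistic(task$x, task$y)$selected)
  }, numeric(1))
  expect_lt(mean(null_sizes), 8)
})

test_that("PCA summaries behave on correlated, degenerate and isotropic data", {
  set.seed(23)
  z <- rnorm(50)
  two <- cbind(m01 = z, m02 = 2 * z + 1e-8 * rnorm(50))
  p2 <- pca_summary(two)
  expect_equal(p2$variance_fractions[1], 1, tolerance = 1e-6)
  expect_equal(sum(p2$variance_fractions), 1)

  # isotropic null: the first two fractions exceed 2/46 only through
  # finite-sample eigenvalue inflation, which stays bounded at n = 150
  iso <- matrix(rnorm(150 * 46), 150, 46)
  colnames(iso) <- sprintf("m%02d", 1:46)
  vf <- pca_summary(iso)$variance_fractions
  expect_true(all(diff(vf) <= 1e-12))
  pi2 <- sum(vf[1:2])
  expect_gt(pi2, 2 / 46)
  expect_lt(pi2, 3 * 2 / 46)

  degen <- cbind(iso, m47 = rep(1, 150))
  expect_warning(pca_summary(degen), "zero-variance")
})

test_that("undefined metric entries are imputed from training folds only", {
  task <- make_gaussian_task(30, shift = 3, seed = 71,
                             signal_cols = c(5, 17, 30))
  task$x[sample(length(task$x), 200)] <- NA
  r <- cross_validate(task$x, task$y, model = "sde", seed = 5)
  expect_gt(r$cv_accuracy, 0.8)
  fit <- fit_classifier(task$x, task$y, model = "logistic")
  expect_length(predict(fit, task$x[1:3, , drop = FALSE], type = "score"), 3)
})
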