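# Predicting biological status from the 46-metric profile: PCA summary,
# four classifier families, stratified cross-validation, ROC/AUC, stepwise
# feature selection.
#
# The subspace discriminant ensemble (SDE) is authored here: a majority
# vote over B ridge-regularized linear-discriminant learners, each trained
# on a random feature subspace of dimension d_sub (B = 30, d_sub =
# ceiling(p/2) by convention).

as_feature_matrix <- function(x) {
  if (is.data.frame(x)) {
    cols <- intersect(METRIC_NAMES, names(x))
    if (length(cols) == 0) cols <- names(x)[vapply(x, is.numeric, logical(1))]
    x <- as.matrix(x[, cols, drop = FALSE])
  }
  storage.mode(x) <- "double"
  x
}

# Imputation (per-feature median) and standardization parameters are
# learned on training data only and replayed on any new data.
fit_preproc <- function(x) {
  med <- apply(x, 2, stats::median, na.rm = TRUE)
  med[!is.finite(med)] <- 0
  xi <- x
  for (j in seq_len(ncol(x))) xi[is.na(xi[, j]), j] <- med[j]
  ctr <- colMeans(xi)
  scl <- apply(xi, 2, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  list(median = med, center = ctr, scale = scl)
}

apply_preproc <- function(x, pp) {
  for (j in seq_len(ncol(x))) x[is.na(x[, j]), j] <- pp$median[j]
  sweep(sweep(x, 2, pp$center), 2, pp$scale, `/`)
}

# Ridge-regularized linear discriminant on a feature subset; lambda grows
# until the pooled covariance is invertible.
fit_rlda <- function(x, y01, lambda = 1e-4) {
  mu0 <- colMeans(x[y01 == 0, , drop = FALSE])
  mu1 <- colMeans(x[y01 == 1, , drop = FALSE])
  n0 <- sum(y01 == 0); n1 <- sum(y01 == 1)
  c0 <- sweep(x[y01 == 0, , drop = FALSE], 2, mu0)
  c1 <- sweep(x[y01 == 1, , drop = FALSE], 2, mu1)
  S <- (crossprod(c0) + crossprod(c1)) / max(1, n0 + n1 - 2)
  tr <- mean(diag(S)); if (!is.finite(tr) || tr <= 0) tr <- 1
  w <- NULL
  for (i in 0:8) {
    Sr <- S + (lambda * 10^i) * tr * diag(ncol(x))
    w <- tryCatch(solve(Sr, mu1 - mu0), error = function(e) NULL)
    if (!is.null(w)) break
  }
  thr <- sum(w * (mu0 + mu1)) / 2 - log(n1 / n0)
  list(w = w, threshold = thr)
}

predict_rlda_margin <- function(fit, x) drop(x %*% fit$w) - fit$threshold

#' Fit a biological-status classifier
#'
#' Trains one of the four classifier families on all 46 metrics: `"sde"`
#' (subspace discriminant ensemble), `"svm"` (linear, C = 1), `"logistic"`,
#' or `"knn"` (k = 5, Euclidean). Undefined (`NA`) metric entries are
#' imputed with the training-set per-metric median and features are
#' standardized with training-set mean/sd; both transforms are replayed at
#' prediction time.
#'
#' @param x feature matrix or [feature_table()] data frame (columns
#'   `m01..m46`).
#' @param y two-level factor of class labels; the second level is treated
#'   as the positive class.
#' @param model one of `"sde"`, `"svm"`, `"logistic"`, `"knn"`.
#' @param hyperparams optional overrides: `B`, `d_sub`, `lambda` (sde);
#'   `cost` (svm); `k` (knn).
#' @param seed RNG seed (controls SDE subspace draws).
#' @return an object of class `bead_classifier` with a [predict] method.
#' @export
fit_classifier <- function(x, y, model = c("sde", "svm", "logistic", "knn"),
                           hyperparams = list(), seed = 1L) {
  model <- match.arg(model)
  x <- as_feature_matrix(x)
  y <- droplevels(as.factor(y))
  if (nlevels(y) != 2) stop("exactly two classes are required")
  if (min(table(y)) < 2) stop("each class needs at least 2 training samples")
  pp <- fit_preproc(x)
  xs <- apply_preproc(x, pp)
  hp <- utils::modifyList(list(B = 30L, d_sub = ceiling(ncol(x) / 2),
                               lambda = 1e-4, cost = 1, k = 5L), hyperparams)
  y01 <- as.integer(y) - 1L
  fit <- switch(model,
    sde = with_seed(seed, {
      lapply(seq_len(hp$B), function(b) {
        feats <- sort(sample.int(ncol(xs), hp$d_sub))
        l <- fit_rlda(xs[, feats, drop = FALSE], y01, hp$lambda)
        list(features = feats, fit = l)
      })
    }),
    svm = e1071::svm(xs, y, kernel = "linear", cost = hp$cost, scale = FALSE),
    logistic = suppressWarnings(
      stats::glm.fit(cbind(1, xs), y01, family = stats::binomial())),
    knn = list(x = xs, y = y, k = hp$k))
  structure(list(model = model, fit = fit, levels = levels(y),
                 preproc = pp, hyper = hp, seed = seed,
                 n_features = ncol(x)),
            class = "bead_classifier")
}

#' @export
print.bead_classifier <- function(x, ...) {
  cat(sprintf("<bead_classifier> %s over %d features (classes: %s vs %s)\n",
              x$model, x$n_features, x$levels[1], x$levels[2]))
  invisible(x)
}

#' Predict from a fitted classifier
#'
#' @param object a `bead_classifier`.
#' @param newdata feature matrix or data frame.
#' @param type `"class"` for hard labels, `"score"` for a continuous score
#'   for the positive (second) class.
#' @param ... unused.
#' @return a factor (`"class"`) or numeric vector (`"score"`).
#' @export
predict.bead_classifier <- function(object, newdata,
                                    type = c("class", "score"), ...) {
  type <- match.arg(type)
  x <- apply_preproc(as_feature_matrix(newdata), object$preproc)
  score <- switch(object$model,
    sde = {
      post <- vapply(object$fit, function(l)
        stats::plogis(predict_rlda_margin(l$fit, x[, l$features, drop = FALSE])),
        numeric(nrow(x)))
      if (nrow(x) == 1L) post <- matrix(post, nrow = 1L)
      rowMeans(post)
    },
    svm = {
      pr <- stats::predict(object$fit, x, decision.values = TRUE)
      dv <- drop(attr(pr, "decision.values"))
      # e1071 names the column "A/B": positive decision values vote A;
      # orient so larger scores mean the positive (second) level
      if (startsWith(colnames(attr(pr, "decision.values"))[1],
                     paste0(object$levels[1], "/")))
        dv <- -dv
      stats::plogis(dv)
    },
    logistic = {
      # aliased/rank-deficient coefficients drop out of the linear score
      cf <- object$fit$coefficients
      cf[is.na(cf)] <- 0
      stats::plogis(drop(cbind(1, x) %*% cf))
    },
    knn = {
      pr <- class::knn(object$fit$x, x, object$fit$y, k = object$fit$k,
                       prob = TRUE)
      p <- attr(pr, "prob")
      ifelse(pr == object$levels[2], p, 1 - p)
    })
  if (type == "score") return(score)
  factor(object$levels[(score >= 0.5) + 1L], levels = object$levels)
}

# Stratified fold assignment: within each class, a seeded shuffle is dealt
# round-robin into k folds, so fold sizes differ by <= 1 per class.
stratified_folds <- function(y, k, seed) {
  if (k > min(table(y))) stop("k exceeds the smallest class size")
  fold <- integer(length(y))
  with_seed(seed, {
    for (lv in levels(y)) {
      idx <- which(y == lv)
      fold[idx] <- rep_len(seq_len(k), length(idx))[sample.int(length(idx))]
    }
  })
  fold
}

#' Stratified k-fold cross-validation
#'
#' 5-fold stratified cross-validation of one classifier family, with an
#' optional held-out validation set scored separately. ROC/AUC is computed
#' on the validation set when given, otherwise on the pooled out-of-fold
#' scores.
#'
#' @param x,y features and two-level labels (see [fit_classifier()]).
#' @param model classifier family.
#' @param k number of folds (default 5); must not exceed the smallest
#'   class size.
#' @param seed RNG seed (folds and model fits are deterministic given it).
#' @param validation optional `list(x, y)` held-out set.
#' @param hyperparams passed to [fit_classifier()].
#' @return an object of class `classifier_report`: `model_name`,
#'   `train_accuracy`, `cv_accuracy`, `validation_accuracy`, `per_fold`,
#'   `roc_points`, `auc`, `seed`.
#' @export
cross_validate <- function(x, y, model = "sde", k = 5L, seed = 1L,
                           validation = NULL, hyperparams = list()) {
  x <- as_feature_matrix(x)
  y <- droplevels(as.factor(y))
  fold <- stratified_folds(y, k, seed)
  per_fold <- numeric(k)
  oof <- numeric(length(y))
  for (f in seq_len(k)) {
    tr <- fold != f
    fit <- fit_classifier(x[tr, , drop = FALSE], y[tr], model,
                          hyperparams = hyperparams, seed = derive_seed(seed, f))
    pred <- predict(fit, x[!tr, , drop = FALSE], type = "class")
    per_fold[f] <- mean(pred == y[!tr])
    oof[!tr] <- predict(fit, x[!tr, , drop = FALSE], type = "score")
  }
  full <- fit_classifier(x, y, model, hyperparams = hyperparams, seed = seed)
  train_acc <- mean(predict(full, x, type = "class") == y)
  val_acc <- NA_real_
  if (!is.null(validation)) {
    vy <- factor(validation$y, levels = levels(y))
    val_acc <- mean(predict(full, validation$x, type = "class") == vy)
    roc <- roc_auc(predict(full, validation$x, type = "score"), vy)
  } else {
    roc <- roc_auc(oof, y)
  }
  structure(list(model_name = model, train_accuracy = train_acc,
                 cv_accuracy = mean(per_fold), validation_accuracy = val_acc,
                 per_fold = per_fold, roc_points = roc$roc_points,
                 auc = roc$auc, seed = seed, fit = full),
            class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf("<classifier_report> %s: train %.3f, cv %.3f%s, AUC %.3f\n",
              x$model_name, x$train_accuracy, x$cv_accuracy,
              if (is.na(x$validation_accuracy)) ""
              else sprintf(", validation %.3f", x$validation_accuracy),
              x$auc))
  invisible(x)
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps thresholds over the unique scores; AUC by the trapezoidal rule
#' (equal to the Mann-Whitney U statistic divided by `n_pos * n_neg`).
#'
#' @param scores continuous scores for the positive class.
#' @param labels two-level factor; second level is positive.
#' @return list with `roc_points` (data frame `fpr, tpr, threshold`,
#'   monotone in fpr) and `auc` (`NA` with a warning for a single-class
#'   input).
#' @export
roc_auc <- function(scores, labels) {
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) < 2) {
    warning("single-class input: AUC undefined")
    return(list(roc_points = data.frame(fpr = numeric(0), tpr = numeric(0),
                                        threshold = numeric(0)),
                auc = NA_real_))
  }
  pos <- labels == levels(labels)[2]
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) mean(scores[pos] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[!pos] >= t), numeric(1))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(roc_points = data.frame(fpr = fpr, tpr = tpr, threshold = thr),
       auc = auc)
}

#' Bidirectional stepwise logistic feature selection
#'
#' Starts from the intercept-only logistic model and adds/drops metrics to
#' minimize an information criterion (AIC by default), returning the
#' selected metrics in the order they entered. Identifies the handful of
#' metrics that discriminate two conditions.
#'
#' @param x,y features (columns `m01..m46`) and two-level labels; needs
#'   more than 10 samples.
#' @param criterion `"aic"` or `"bic"`.
#' @return list with `selected` (integer metric indices, in entry order;
#'   empty if nothing beats the intercept), `names`, and `model` (the
#'   final `glm`).
#' @export
stepwise_logistic <- function(x, y, criterion = c("aic", "bic")) {
  criterion <- match.arg(criterion)
  x <- as_feature_matrix(x)
  y <- droplevels(as.factor(y))
  if (nrow(x) <= 10) stop("stepwise selection needs more than 10 samples")
  pp <- fit_preproc(x)
  xs <- apply_preproc(x, pp)
  colnames(xs) <- colnames(x) %||% sprintf("m%02d", seq_len(ncol(x)))
  df <- data.frame(.y = as.integer(y) - 1L, xs, check.names = FALSE)
  null <- stats::glm(.y ~ 1, family = stats::binomial(), data = df)
  upper <- stats::as.formula(paste(".y ~", paste(colnames(xs), collapse = " + ")))
  kpen <- if (criterion == "aic") 2 else log(nrow(x))
  fit <- suppressWarnings(stats::step(null, scope = list(lower = ~1, upper = upper),
                                      direction = "both", trace = 0, k = kpen))
  steps <- fit$anova$Step
  added <- character(0)
  for (s in steps[-1]) {
    term <- trimws(sub("^[+-]", "", s))
    if (startsWith(s, "+ ") || startsWith(s, "+")) {
      if (grepl("^\\+", s)) added <- c(added, term)
    }
    if (grepl("^-", s)) added <- setdiff(added, term)
  }
  final_terms <- attr(stats::terms(fit), "term.labels")
  added <- added[added %in% final_terms]
  added <- c(added, setdiff(final_terms, added))
  sel <- match(added, colnames(xs))
  list(selected = sel, names = added, model = fit, criterion = criterion)
}

#' Correlation-based principal component analysis of a feature table
#'
#' PCA on standardized (unit-variance) metrics; zero-variance metrics are
#' dropped with a warning, undefined entries imputed with the per-metric
#' median.
#'
#' @param x feature matrix or [feature_table()] data frame.
#' @param standardize scale features to unit variance (default `TRUE`,
#'   i.e. PCA on the correlation matrix).
#' @return an object of class `pca_summary` with `component_loadings`,
#'   `variance_fractions` (non-negative, non-increasing, summing to 1) and
#'   `scores`.
#' @export
pca_summary <- function(x, standardize = TRUE) {
  x <- as_feature_matrix(x)
  if (nrow(x) < 2) stop("need at least 2 samples")
  pp <- fit_preproc(x)
  for (j in seq_len(ncol(x))) x[is.na(x[, j]), j] <- pp$median[j]
  v <- apply(x, 2, stats::var)
  if (any(v == 0 | !is.finite(v))) {
    warning("dropping zero-variance features: ",
            paste(colnames(x)[v == 0 | !is.finite(v)], collapse = ", "))
    x <- x[, v > 0 & is.finite(v), drop = FALSE]
  }
  p <- stats::prcomp(x, center = TRUE, scale. = standardize)
  vf <- p$sdev^2 / sum(p$sdev^2)
  structure(list(component_loadings = p$rotation, variance_fractions = vf,
                 scores = p$x), class = "pca_summary")
}

#' @export
print.pca_summary <- function(x, ...) {
  cat(sprintf("<pca_summary> %d components; PC1+PC2 explain %.1f%% of variance\n",
              length(x$variance_fractions),
              100 * sum(x$variance_fractions[1:min(2, length(x$variance_fractions))])))
  invisible(x)
}
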