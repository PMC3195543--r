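# Classification models and the random-subsampling validation protocol:
# stratified 70:30 splits repeated 40 times; linear SVM, Wilcoxon-filtered
# SVM, and random forest; confusion statistics, ROC/AUC, and model-based
# importance. Every data-dependent choice (standardization statistics,
# Wilcoxon filtering, per-split peak identification) is computed from
# training indices only.

#' Stratified random-subsampling splits
#'
#' Generates `n_splits` independent stratified train/test partitions at the
#' given training fraction. Class proportions are preserved per split
#' (rounding per class); train and test are disjoint and cover all samples.
#'
#' @param labels two-class factor/character per sample (each class >= 2).
#' @param n_splits number of repeats.
#' @param train_frac fraction of each class assigned to training.
#' @param seed RNG seed; splits are deterministic given the seed.
#' @param stratified sample within classes (default) or completely at random.
#' @return list of `n_splits` lists with integer `train` and `test` indices.
#' @export
split_resample <- function(labels, n_splits = 40L, train_frac = 0.7,
                           seed = 1L, stratified = TRUE) {
  labels <- as.character(labels)
  tab <- table(labels)
  if (length(tab) != 2L) stop("labels must contain exactly two classes")
  if (any(tab < 2L)) stop("each class needs at least 2 members")
  n <- length(labels)
  with_seed(seed, lapply(seq_len(n_splits), function(i) {
    train <- if (stratified) {
      unlist(lapply(names(tab), function(cl) {
        idx <- which(labels == cl)
        sample(idx, round(train_frac * length(idx)))
      }), use.names = FALSE)
    } else sample.int(n, round(train_frac * n))
    train <- sort(train)
    list(train = train, test = setdiff(seq_len(n), train))
  }))
}

standardize_stats <- function(x_train) {
  mu <- colMeans(x_train)
  sd_ <- apply(x_train, 2L, stats::sd)
  sd_[!is.finite(sd_) | sd_ == 0] <- 1
  list(mean = mu, sd = sd_)
}

apply_standardize <- function(x, st) {
  sweep(sweep(x, 2L, st$mean, "-"), 2L, st$sd, "/")
}

confusion_stats <- function(truth_pos, pred_pos) {
  tp <- sum(truth_pos & pred_pos); fn <- sum(truth_pos & !pred_pos)
  tn <- sum(!truth_pos & !pred_pos); fp <- sum(!truth_pos & pred_pos)
  n <- tp + fp + tn + fn
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       error = (fp + fn) / n,
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
}

#' Fit a classifier on a training split and evaluate it on the test split
#'
#' Supported models: `"svm"` (linear SVM, cost `C`), `"svm_wilcoxon"`
#' (linear SVM on the top-k Wilcoxon-ranked features), `"rf"` (random
#' forest, 500 trees, `sqrt(p)` candidate features per node), and
#' `"rf_wilcoxon"` (random forest on the top-k Wilcoxon features). Feature
#' screening and standardization use training rows only; the fitted model is
#' never modified after training.
#'
#' @param x samples x features matrix (named columns).
#' @param labels two-class labels per sample.
#' @param train,test disjoint integer index vectors.
#' @param model one of `"svm"`, `"svm_wilcoxon"`, `"rf"`, `"rf_wilcoxon"`.
#' @param k number of Wilcoxon-selected features for filtered models.
#' @param positive the positive (caries-active) class label.
#' @param cost linear SVM regularization constant.
#' @param ntree random forest size.
#' @param ranking optional precomputed training-set `importance_ranking`
#'   (must have been computed on training rows only).
#' @param seed optional seed for the stochastic forest fit.
#' @return list with confusion counts and rates (`tp`, `fp`, `tn`, `fn`,
#'   `error`, `sensitivity`, `specificity`), continuous decision `scores`
#'   on the test set (higher = more case-like), `selected` features,
#'   training `stats` (standardization), and `importance` (forests only).
#' @export
fit_predict <- function(x, labels, train, test,
                        model = c("svm", "svm_wilcoxon", "rf", "rf_wilcoxon"),
                        k = 100L, positive = "case", cost = 1,
                        ntree = 500L, ranking = NULL, seed = NULL) {
  model <- match.arg(model)
  x <- as.matrix(x)
  labels <- as.character(labels)
  if (length(intersect(train, test))) stop("train and test overlap")
  y_train <- factor(labels[train] == positive, levels = c(FALSE, TRUE),
                    labels = c("neg", "pos"))
  if (length(unique(y_train)) < 2L)
    stop("degenerate training split: one class only")
  selected <- colnames(x)
  if (model %in% c("svm_wilcoxon", "rf_wilcoxon")) {
    if (is.null(ranking))
      ranking <- rank_features(x[train, , drop = FALSE], labels[train],
                               positive = positive)
    selected <- top_k(ranking, min(k, nrow(ranking)))
  }
  xs <- x[, selected, drop = FALSE]
  st <- standardize_stats(xs[train, , drop = FALSE])
  x_tr <- apply_standardize(xs[train, , drop = FALSE], st)
  x_te <- apply_standardize(xs[test, , drop = FALSE], st)

  fit_one <- function() {
    if (model %in% c("svm", "svm_wilcoxon")) {
      fit <- e1071::svm(x_tr, y_train, kernel = "linear", cost = cost,
                        scale = FALSE)
      pr <- stats::predict(fit, x_te, decision.values = TRUE)
      dv <- drop(attr(pr, "decision.values"))
      # orient decision values so higher means more case-like
      if (grepl("^neg/", colnames(attr(pr, "decision.values"))[1L])) dv <- -dv
      list(pred_pos = pr == "pos", scores = dv, importance = NULL)
    } else {
      fit <- randomForest::randomForest(
        x_tr, y_train, ntree = ntree,
        mtry = max(1L, floor(sqrt(ncol(x_tr)))), importance = TRUE)
      prob <- stats::predict(fit, x_te, type = "prob")[, "pos"]
      list(pred_pos = stats::predict(fit, x_te) == "pos", scores = prob,
           importance = randomForest::importance(fit, type = 1L)[, 1L])
    }
  }
  res <- if (is.null(seed)) fit_one() else with_seed(seed, fit_one())

  truth_pos <- labels[test] == positive
  out <- confusion_stats(truth_pos, res$pred_pos)
  out$scores <- stats::setNames(as.numeric(res$scores), rownames(x)[test])
  out$truth <- truth_pos
  out$selected <- selected
  out$stats <- st
  out$importance <- res$importance
  out$model <- model
  out
}

#' Empirical ROC curve and AUC by threshold sweep
#'
#' Builds the ROC as a staircase over all decision thresholds of the pooled
#' scores (for threshold classifiers this traces the same operating points
#' as varying the misclassification cost) and computes the AUC by the
#' trapezoid rule. Depends on scores only through their ranks.
#'
#' @param scores continuous decision scores, higher = more case-like.
#' @param labels two-class labels.
#' @param positive the positive class label.
#' @return list with `points` (data frame `fpr`, `tpr` from (0,0) to (1,1))
#'   and `auc`.
#' @export
roc_curve <- function(scores, labels, positive = "case") {
  labels <- as.character(labels)
  y <- labels == positive
  if (!any(y) || all(y)) stop("both classes required for a ROC curve")
  ord <- order(scores, decreasing = TRUE)
  ys <- y[ord]
  # collapse threshold ties: keep the last index of each unique score value
  last <- c(diff(scores[ord]) != 0, TRUE)
  tpr <- c(0, cumsum(ys)[last] / sum(y))
  fpr <- c(0, cumsum(!ys)[last] / sum(!y))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1L) + utils::tail(tpr, -1L)) / 2)
  list(points = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

#' Permutation importance aggregated over resampling splits
#'
#' Averages the forest's permutation importance (mean decrease in accuracy)
#' over all splits of an [evaluate()] run and normalizes the result to a
#' maximum of 1.
#'
#' @param report an `eval_report` from [evaluate()] with a forest model.
#' @return An `importance_ranking`-style data frame: `feature`,
#'   `importance` (max 1), `rank`.
#' @export
rf_importance <- function(report) {
  if (is.null(report$importance_by_split) || !length(report$importance_by_split))
    stop("report carries no forest importance (model was not a random forest)")
  feats <- sort(unique(unlist(lapply(report$importance_by_split, names))))
  M <- vapply(report$importance_by_split, function(v) {
    out <- stats::setNames(numeric(length(feats)), feats)
    out[names(v)] <- v
    out
  }, numeric(length(feats)))
  imp <- rowMeans(M)
  mx <- max(imp)
  if (mx > 0) imp <- imp / mx
  ord <- order_desc_stable(imp)
  data.frame(feature = feats[ord], importance = imp[ord],
             rank = seq_along(ord), stringsAsFactors = FALSE)
}
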