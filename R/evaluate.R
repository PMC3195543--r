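#' Evaluate a classifier under random-subsampling validation
#'
#' Runs [split_resample()] x [fit_predict()] and aggregates: mean and SD of
#' test error, sensitivity and specificity over the splits; a pooled ROC
#' over all test-set decision scores with its AUC, plus the SD of per-split
#' AUCs; and, for forest models, permutation importance per split. All
#' feature selection and standardization happens inside each training fold.
#'
#' @param x samples x features matrix, or `NULL` when `feature_builder`
#'   supplies the matrix per split.
#' @param labels two-class labels per sample.
#' @param model,k,positive,cost,ntree see [fit_predict()].
#' @param n_splits,train_frac,seed see [split_resample()].
#' @param splits optional precomputed splits (shared across conditions for
#'   paired comparisons); overrides `n_splits`/`train_frac`.
#' @param feature_builder optional `function(split_index, split)` returning
#'   the feature matrix for all samples, built using training rows only
#'   (e.g. per-split peak identification); called once per split.
#' @param screen_cache optional environment caching training-fold Wilcoxon
#'   rankings across models that share `cache_tag` and splits.
#' @param cache_tag cache key prefix identifying the feature condition.
#' @return An `eval_report`: list with `per_split` (data frame), `summary`
#'   (means and SDs), `roc` (pooled staircase points), `auc`, `auc_sd`,
#'   `selected_by_split`, `importance_by_split`, and the protocol settings.
#' @export
evaluate <- function(x = NULL, labels, model = "svm", k = 100L,
                     n_splits = 40L, train_frac = 0.7, seed = 1L,
                     splits = NULL, feature_builder = NULL,
                     positive = "case", cost = 1, ntree = 500L,
                     screen_cache = NULL, cache_tag = "") {
  labels <- as.character(labels)
  if (is.null(splits))
    splits <- split_resample(labels, n_splits = n_splits,
                             train_frac = train_frac, seed = seed)
  n_splits <- length(splits)
  filtered <- model %in% c("svm_wilcoxon", "rf_wilcoxon")
  per <- vector("list", n_splits)
  scores_all <- numeric(0); truth_all <- logical(0)
  sel <- vector("list", n_splits)
  imp <- list()
  for (i in seq_len(n_splits)) {
    sp <- splits[[i]]
    xi <- if (is.null(feature_builder)) x else feature_builder(i, sp)
    ranking <- NULL
    if (filtered) {
      key <- paste0(cache_tag, "#", i)
      if (!is.null(screen_cache) && !is.null(screen_cache[[key]])) {
        ranking <- screen_cache[[key]]
      } else {
        ranking <- rank_features(xi[sp$train, , drop = FALSE],
                                 labels[sp$train], positive = positive)
        if (!is.null(screen_cache)) screen_cache[[key]] <- ranking
      }
    }
    r <- fit_predict(xi, labels, sp$train, sp$test, model = model, k = k,
                     positive = positive, cost = cost, ntree = ntree,
                     ranking = ranking, seed = seed + 131L * i)
    sauc <- roc_curve(r$scores, labels[sp$test], positive = positive)$auc
    per[[i]] <- data.frame(split = i, tp = r$tp, fp = r$fp, tn = r$tn,
                           fn = r$fn, error = r$error,
                           sensitivity = r$sensitivity,
                           specificity = r$specificity, auc = sauc,
                           n_selected = length(r$selected))
    scores_all <- c(scores_all, r$scores)
    truth_all <- c(truth_all, r$truth)
    sel[[i]] <- r$selected
    if (!is.null(r$importance)) imp[[i]] <- r$importance
  }
  per_split <- do.call(rbind, per)
  pooled <- roc_curve(scores_all, ifelse(truth_all, positive, "other"),
                      positive = positive)
  structure(list(
    model = model, k = if (filtered) k else NA_integer_,
    per_split = per_split,
    summary = list(
      error_mean = mean(per_split$error), error_sd = stats::sd(per_split$error),
      sensitivity_mean = mean(per_split$sensitivity),
      sensitivity_sd = stats::sd(per_split$sensitivity),
      specificity_mean = mean(per_split$specificity),
      specificity_sd = stats::sd(per_split$specificity)),
    roc = pooled$points, auc = pooled$auc,
    auc_sd = stats::sd(per_split$auc),
    selected_by_split = sel, importance_by_split = imp,
    protocol = list(n_splits = n_splits, train_frac = train_frac,
                    seed = seed, cost = cost, ntree = ntree)),
    class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<eval_report> model %s%s, %d splits\n", x$model,
              if (!is.na(x$k)) sprintf(" (top-%d Wilcoxon)", x$k) else "",
              x$protocol$n_splits))
  cat(sprintf("  test error  %5.2f%% +/- %.2f%%\n", 100 * s$error_mean,
              100 * s$error_sd))
  cat(sprintf("  sensitivity %5.2f%% +/- %.2f%%\n", 100 * s$sensitivity_mean,
              100 * s$sensitivity_sd))
  cat(sprintf("  specificity %5.2f%% +/- %.2f%%\n", 100 * s$specificity_mean,
              100 * s$specificity_sd))
  cat(sprintf("  pooled AUC  %.3f (per-split SD %.3f)\n", x$auc, x$auc_sd))
  invisible(x)
}
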