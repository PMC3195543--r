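# Univariate screening: Wilcoxon rank-sum score per feature, ranking, and
# top-k selection for filtered classifiers.

#' Wilcoxon rank-sum discrimination score for one feature
#'
#' Two-sided rank-sum P value between the case and control groups, and the
#' score `-log10(P)` used for ranking. The exact permutation distribution is
#' used for small untied samples (total n <= 25, no ties); otherwise the
#' normal approximation with tie and continuity corrections. Being
#' rank-based, the score is invariant under strictly monotone transforms of
#' the feature values.
#'
#' @param x_case,x_control numeric observations per group (each >= 2).
#' @param base logarithm base for the score (10 by convention).
#' @return list with `p` and `score = -log(p, base)`.
#' @export
wilcoxon_score <- function(x_case, x_control, base = 10) {
  if (length(x_case) < 2L || length(x_control) < 2L)
    stop("each group needs at least 2 observations")
  n <- length(x_case) + length(x_control)
  pooled <- c(x_case, x_control)
  if (max(pooled) == min(pooled))   # no separation at all
    return(list(p = 1, score = 0))
  ties <- anyDuplicated(pooled) > 0L
  exact <- n <= 25L && !ties
  p <- suppressWarnings(
    stats::wilcox.test(x_case, x_control, alternative = "two.sided",
                       exact = exact, correct = TRUE)$p.value)
  if (!is.finite(p)) p <- 1
  list(p = p, score = -log(p, base = base))
}

#' Rank features by Wilcoxon discrimination score
#'
#' Scores every column of a feature matrix with [wilcoxon_score()] and
#' returns features sorted by descending score; ties are broken by original
#' feature order (stable).
#'
#' @param x samples x features numeric matrix with column names.
#' @param labels two-class factor/character per sample; the level named by
#'   `positive` is the case group.
#' @param positive label value of the positive (caries-active) class.
#' @param base score log base.
#' @return An `importance_ranking` data frame: `feature`, `p`, `score`,
#'   `rank`, sorted descending by score.
#' @export
rank_features <- function(x, labels, positive = "case", base = 10) {
  x <- as.matrix(x)
  labels <- as.character(labels)
  if (length(labels) != nrow(x)) stop("labels must match matrix rows")
  is_case <- labels == positive
  if (!any(is_case) || all(is_case))
    stop("both classes must be present for screening")
  p <- vapply(seq_len(ncol(x)), function(j)
    wilcoxon_score(x[is_case, j], x[!is_case, j], base = base)$p, numeric(1))
  score <- -log(p, base = base)
  ord <- order_desc_stable(score)
  out <- data.frame(feature = colnames(x)[ord], p = p[ord], score = score[ord],
                    rank = seq_along(ord), stringsAsFactors = FALSE)
  class(out) <- c("importance_ranking", "data.frame")
  out
}

#' Select the top-k ranked features
#'
#' @param ranking an `importance_ranking` (from [rank_features()]).
#' @param k number of features to keep, `1 <= k <= nrow(ranking)`.
#' @return Character vector of the k highest-scored features, in rank order.
#' @export
top_k <- function(ranking, k) {
  if (k < 1L || k > nrow(ranking)) stop("k out of range")
  ranking$feature[seq_len(k)]
}
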