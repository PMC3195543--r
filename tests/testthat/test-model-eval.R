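blob_data <- function(n = 60, p = 10, sep = 4, seed = 3) {
  cariomics:::with_seed(seed, {
    lab <- rep(c("case", "control"), each = n / 2)
    x <- matrix(rnorm(n * p), n, p, dimnames = list(sprintf("P%03d", 1:n),
                                                    sprintf("f%02d", 1:p)))
    x[lab == "case", 1:3] <- x[lab == "case", 1:3] + sep
    list(x = x, lab = lab)
  })
}

test_that("stratified splits preserve proportions, are disjoint and seeded", {
  lab <- rep(c("case", "control"), c(86, 118))
  s1 <- split_resample(lab, n_splits = 40, train_frac = 0.7, seed = 5)
  s2 <- split_resample(lab, n_splits = 40, train_frac = 0.7, seed = 5)
  expect_identical(s1, s2)
  expect_length(s1, 40)
  for (sp in s1[1:5]) {
    expect_length(intersect(sp$train, sp$test), 0)
    expect_setequal(c(sp$train, sp$test), seq_len(204))
    # 70:30 on 204 with per-class rounding: train 143, test 61
    expect_equal(length(sp$train), 143)
    expect_equal(sum(lab[sp$train] == "case"), round(0.7 * 86))
  }
  expect_error(split_resample(rep("case", 10)), "two classes")
  expect_error(split_resample(c("case", rep("control", 9))), "at least 2")
})

test_that("confusion arithmetic matches the counted definitions", {
  st <- cariomics:::confusion_stats(
    truth_pos = rep(c(TRUE, FALSE), c(10, 20)),
    pred_pos = c(rep(TRUE, 9), FALSE, rep(TRUE, 2), rep(FALSE, 18)))
  expect_equal(st[c("tp", "fn", "fp", "tn")], list(tp = 9, fn = 1, fp = 2, tn = 18))
  expect_equal(st$sensitivity, 0.9)
  expect_equal(st$specificity, 0.9)
  expect_equal(st$error, 0.1)
})

test_that("separable blobs are classified perfectly by every model", {
  d <- blob_data()
  sp <- split_resample(d$lab, n_splits = 3, seed = 2)
  for (m in c("svm", "svm_wilcoxon", "rf")) {
    r <- fit_predict(d$x, d$lab, sp[[1]]$train, sp[[1]]$test, model = m,
                     k = 5, seed = 9)
    expect_equal(r$error, 0)
    expect_equal(r$sensitivity, 1)
    expect_equal(r$specificity, 1)
  }
})

test_that("decision scores separate classes in the right direction", {
  d <- blob_data()
  sp <- split_resample(d$lab, n_splits = 1, seed = 2)[[1]]
  for (m in c("svm", "rf")) {
    r <- fit_predict(d$x, d$lab, sp$train, sp$test, model = m, seed = 9)
    expect_gt(min(r$scores[r$truth]), max(r$scores[!r$truth]))
  }
})

test_that("the ROC staircase and trapezoid AUC match an independent oracle", {
  set.seed(12)
  scores <- rnorm(150)
  lab <- ifelse(scores + rnorm(150) > 0, "case", "control")
  r <- roc_curve(scores, lab)
  expect_equal(r$points$fpr[1], 0)
  expect_equal(r$points$tpr[nrow(r$points)], 1)
  expect_true(all(diff(r$points$fpr) >= 0) && all(diff(r$points$tpr) >= 0))
  skip_if_not_installed("pROC")
  oracle <- as.numeric(pROC::auc(pROC::roc(
    response = lab, predictor = scores, levels = c("control", "case"),
    direction = "<", quiet = TRUE)))
  expect_equal(r$auc, oracle, tolerance = 1e-10)
  # perfect separation and monotone-transform invariance
  expect_equal(roc_curve(ifelse(lab == "case", 1, 0), lab)$auc, 1)
  expect_equal(roc_curve(exp(scores), lab)$auc, r$auc, tolerance = 1e-12)
})

test_that("evaluate aggregates its own per-split results", {
  d <- blob_data(sep = 1)
  r <- evaluate(d$x, d$lab, model = "svm", n_splits = 8, seed = 4)
  expect_equal(r$summary$error_mean, mean(r$per_split$error))
  expect_equal(r$summary$error_sd, stats::sd(r$per_split$error))
  expect_equal(r$auc_sd, stats::sd(r$per_split$auc))
  # per-split identity: error = 1 - (sens*n_pos + spec*n_neg)/n
  for (i in seq_len(nrow(r$per_split))) {
    row <- r$per_split[i, ]
    n_pos <- row$tp + row$fn; n_neg <- row$tn + row$fp
    expect_equal(row$error,
                 1 - (row$sensitivity * n_pos + row$specificity * n_neg) /
                   (n_pos + n_neg),
                 tolerance = 1e-12)
  }
})

test_that("forest importance ranks a planted marker and fades a constant", {
  d <- blob_data(n = 80, p = 8, sep = 2.5, seed = 6)
  x <- cbind(d$x, const = rep(1, 80))
  r <- evaluate(x, d$lab, model = "rf", n_splits = 5, seed = 7)
  imp <- rf_importance(r)
  expect_equal(max(imp$importance), 1)
  expect_true(all(c("f01", "f02", "f03") %in% imp$feature[1:5]))
  expect_lt(imp$importance[imp$feature == "const"], 0.05)
})

test_that("duplicated informative features share (and so lose) importance", {
  d <- blob_data(n = 100, p = 6, sep = 0, seed = 8)
  x <- d$x
  cariomics:::with_seed(13, {
    marker <- rnorm(100) + ifelse(d$lab == "case", 1.5, 0)
    x_lone <- cbind(d$x, m1 = marker)
    x_dup <- cbind(d$x, m1 = marker, m2 = marker + rnorm(100, 0, 0.01))
  })
  # compare unnormalized mean importances: each duplicate is less important
  # than the lone copy was ("substitutability" of correlated markers)
  m_lone <- mean(vapply(evaluate(x_lone, d$lab, model = "rf", n_splits = 5,
                                 seed = 7)$importance_by_split,
                        function(v) v[["m1"]], numeric(1)))
  ev_dup <- evaluate(x_dup, d$lab, model = "rf", n_splits = 5, seed = 7)
  m_dup1 <- mean(vapply(ev_dup$importance_by_split, function(v) v[["m1"]],
                        numeric(1)))
  m_dup2 <- mean(vapply(ev_dup$importance_by_split, function(v) v[["m2"]],
                        numeric(1)))
  expect_lt(m_dup1, m_lone)
  expect_lt(m_dup2, m_lone)
})

test_that("wilcoxon-filtered models select on the training fold only", {
  d <- blob_data(n = 60, p = 20, sep = 2)
  sp <- split_resample(d$lab, n_splits = 1, seed = 3)[[1]]
  r <- fit_predict(d$x, d$lab, sp$train, sp$test, model = "svm_wilcoxon",
                   k = 4, seed = 5)
  ranking <- rank_features(d$x[sp$train, ], d$lab[sp$train])
  expect_equal(r$selected, top_k(ranking, 4))
})
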