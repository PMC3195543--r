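# Patient matching and block fusion of microbial abundances with proteomic
# peak features, and end-to-end orchestration of the three experiments
# (microbial-only, proteomic-only, combined) under a shared split schedule.

#' Match patients and fuse microbial and proteomic feature blocks
#'
#' Inner join on patient id followed by column-wise concatenation of the
#' microbial abundance block and the proteomic peak block. A label conflict
#' for a shared patient is a data-integrity error; patients present in only
#' one block are dropped and reported. Per-block standardization is
#' deliberately deferred to model fitting, where it uses training-fold
#' statistics only.
#'
#' @param a an `abundance_table` (see [to_abundance()]) with labels.
#' @param p a `peak_table` (see [call_peaks()]).
#' @param labels optional named labels for the peak-table patients, used to
#'   cross-check against the abundance labels.
#' @return A `fused_matrix`: list with `x` (patients x features), `labels`,
#'   `blocks` (`"microbial"`/`"proteomic"` per column), and a matching
#'   `report` of dropped patients.
#' @export
match_and_fuse <- function(a, p, labels = NULL) {
  stopifnot(inherits(a, "abundance_table"), inherits(p, "peak_table"))
  ids_a <- rownames(a$abundance)
  ids_p <- rownames(p$intensities)
  common <- intersect(ids_a, ids_p)
  if (!length(common)) stop("no patients shared between the two blocks")
  lab <- a$labels
  if (is.null(lab)) stop("abundance table carries no class labels")
  if (!is.null(labels)) {
    conflict <- common[as.character(lab[common]) != as.character(labels[common])]
    if (length(conflict))
      stop("label mismatch for patient(s): ", paste(conflict, collapse = ", "))
  }
  x <- cbind(a$abundance[common, , drop = FALSE],
             p$intensities[common, , drop = FALSE])
  blocks <- c(rep("microbial", ncol(a$abundance)),
              rep("proteomic", ncol(p$intensities)))
  structure(list(
    x = x, labels = lab[common], blocks = blocks,
    report = list(dropped_from_microbial = setdiff(ids_a, common),
                  dropped_from_proteomic = setdiff(ids_p, common))),
    class = "fused_matrix")
}

#' @export
print.fused_matrix <- function(x, ...) {
  cat(sprintf("<fused_matrix> %d patients x %d features (%d microbial + %d proteomic)\n",
              nrow(x$x), ncol(x$x), sum(x$blocks == "microbial"),
              sum(x$blocks == "proteomic")))
  invisible(x)
}

#' Configuration for a full fusion experiment
#'
#' Bundles the synthetic cohort design, generative models, preprocessing and
#' peak-calling settings, and the validation protocol. Filtered models use
#' `k_microbial` features on the microbial block alone and `k_wide` on the
#' (high-dimensional) proteomic and combined blocks.
#'
#' @param cohort a [cohort_spec()].
#' @param spectrum a [spectrum_model()].
#' @param microbes a [microbe_model()].
#' @param preprocess a [preprocess_config()].
#' @param peak_window,peak_radius,peak_mass_window peak-calling settings
#'   (see [identify_peaks()]); radius defaults to the window.
#' @param per_split_peaks identify peak positions from each split's training
#'   profiles (default, leakage-free) rather than once globally.
#' @param conditions which data conditions to evaluate.
#' @param models classifier set to run on every condition.
#' @param verify_rf_filter additionally run the forest on the top-`k_wide`
#'   Wilcoxon features of the combined data (the dimensionality check).
#' @param k_microbial,k_wide Wilcoxon filter sizes per condition.
#' @param n_splits,train_frac validation protocol.
#' @param null_cohort generate the cohort with all differential effects
#'   zeroed (calibration mode).
#' @param seed master seed for generation, splits and model fits.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(cohort = cohort_spec(),
                              spectrum = spectrum_model(),
                              microbes = microbe_model(),
                              preprocess = preprocess_config(),
                              peak_window = 5L, peak_radius = NULL,
                              peak_mass_window = c(1500, 40000),
                              per_split_peaks = TRUE,
                              conditions = c("microbial", "proteomic",
                                             "combined"),
                              models = c("svm", "svm_wilcoxon", "rf"),
                              verify_rf_filter = TRUE,
                              k_microbial = 20L, k_wide = 100L,
                              n_splits = 40L, train_frac = 0.7,
                              null_cohort = FALSE, seed = 1L) {
  structure(list(cohort = cohort, spectrum = spectrum, microbes = microbes,
                 preprocess = preprocess, peak_window = as.integer(peak_window),
                 peak_radius = peak_radius %||% as.integer(peak_window),
                 peak_mass_window = peak_mass_window,
                 per_split_peaks = per_split_peaks,
                 conditions = match.arg(conditions,
                                        c("microbial", "proteomic", "combined"),
                                        several.ok = TRUE),
                 models = models,
                 verify_rf_filter = verify_rf_filter,
                 k_microbial = as.integer(k_microbial),
                 k_wide = as.integer(k_wide),
                 n_splits = as.integer(n_splits), train_frac = train_frac,
                 null_cohort = null_cohort, seed = as.integer(seed)),
            class = "experiment_config")
}

#' Run the three-condition fusion experiment end to end
#'
#' Generates (or accepts) a cohort, preprocesses the spectra, converts the
#' spot signals to abundances, and evaluates every configured model on the
#' microbial-only, proteomic-only, and combined data under one shared split
#' schedule, so per-split comparisons across conditions are paired. Peak
#' positions are recomputed from each split's training profiles by default.
#'
#' @param config an [experiment_config()].
#' @param cohort optional pregenerated `synthetic_cohort`; defaults to
#'   generating one from the config (null cohort when
#'   `config$null_cohort`).
#' @return An `experiment_result`: list with `reports` (nested
#'   `[condition]][[model]]` [evaluate()] reports), `comparison` (data
#'   frame of summary statistics), `qc` (spectral QC report), `labels`,
#'   and `config`.
#' @export
run_experiment <- function(config = experiment_config(), cohort = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  if (is.null(cohort)) {
    config$cohort$seed <- config$seed
    cohort <- if (config$null_cohort)
      generate_null_cohort(config$cohort, config$spectrum, config$microbes)
    else generate_cohort(config$cohort, config$spectrum, config$microbes)
  }
  pp <- preprocess_cohort(cohort$spectra, config$preprocess)
  profiles <- pp$profiles
  ab <- to_abundance(filter_spots(cohort$spots))
  ids <- intersect(rownames(ab$abundance), names(profiles))
  if (!length(ids)) stop("no patients shared between blocks")
  labels <- as.character(cohort$labels[ids])
  profiles <- profiles[ids]
  x_mic <- ab$abundance[ids, , drop = FALSE]

  splits <- split_resample(labels, n_splits = config$n_splits,
                           train_frac = config$train_frac, seed = config$seed)

  # per-split peak tables (training-profile identification), shared by the
  # proteomic and combined conditions
  peak_mat <- new.env(parent = emptyenv())
  peaks_for_split <- function(i, sp) {
    key <- if (config$per_split_peaks) as.character(i) else "global"
    if (is.null(peak_mat[[key]])) {
      idp <- if (config$per_split_peaks) profiles[sp$train] else profiles
      pt <- call_peaks(profiles, window = config$peak_window,
                       mass_window = config$peak_mass_window,
                       radius = config$peak_radius, identify_on = idp)
      peak_mat[[key]] <- pt$intensities
    }
    peak_mat[[key]]
  }
  builders <- list(
    microbial = NULL,
    proteomic = function(i, sp) peaks_for_split(i, sp),
    combined = function(i, sp) cbind(x_mic, peaks_for_split(i, sp))
  )

  cache <- new.env(parent = emptyenv())
  reports <- list()
  for (cond in intersect(names(builders), config$conditions)) {
    k_cond <- if (cond == "microbial") config$k_microbial else config$k_wide
    x_cond <- if (cond == "microbial") x_mic else NULL
    reports[[cond]] <- list()
    for (m in config$models) {
      reports[[cond]][[m]] <- evaluate(
        x = x_cond, labels = labels, model = m, k = k_cond,
        seed = config$seed, splits = splits,
        feature_builder = builders[[cond]],
        screen_cache = cache, cache_tag = cond)
    }
  }
  if (config$verify_rf_filter && "combined" %in% config$conditions &&
      !"rf_wilcoxon" %in% config$models) {
    reports$combined$rf_wilcoxon <- evaluate(
      x = NULL, labels = labels, model = "rf_wilcoxon", k = config$k_wide,
      seed = config$seed, splits = splits,
      feature_builder = builders$combined,
      screen_cache = cache, cache_tag = "combined")
  }

  comparison <- do.call(rbind, unlist(lapply(names(reports), function(cond) {
    lapply(names(reports[[cond]]), function(m) {
      s <- reports[[cond]][[m]]$summary
      data.frame(condition = cond, model = m,
                 error = s$error_mean, error_sd = s$error_sd,
                 sensitivity = s$sensitivity_mean,
                 specificity = s$specificity_mean,
                 auc = reports[[cond]][[m]]$auc,
                 auc_sd = reports[[cond]][[m]]$auc_sd,
                 stringsAsFactors = FALSE)
    })
  }), recursive = FALSE))
  rownames(comparison) <- NULL

  structure(list(reports = reports, comparison = comparison, qc = pp$qc,
                 labels = stats::setNames(labels, ids), config = config),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("<experiment_result>\n")
  df <- x$comparison
  df$error <- sprintf("%5.2f%% +/- %.2f%%", 100 * df$error, 100 * df$error_sd)
  df$auc <- sprintf("%.3f", df$auc)
  print(df[, c("condition", "model", "error", "sensitivity", "specificity", "auc")],
        row.names = FALSE, digits = 3)
  invisible(x)
}
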