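test_that("cohort spec validates its dimensions", {
  expect_error(cohort_spec(n_case = 0), "n_case")
  expect_error(cohort_spec(n_case = 5, n_control = 1), "n_control")
  expect_error(cohort_spec(n_replicates = 0), "n_replicates")
})

test_that("a cohort is deterministic for a fixed seed and sized correctly", {
  sm <- sparse_model()
  mm <- microbe_model(n_taxa = 20, n_enriched_case = 2,
                      n_enriched_control = 2, seed = 5)
  spec <- cohort_spec(n_case = 4, n_control = 5, n_replicates = 2, seed = 7)
  a <- generate_cohort(spec, sm, mm)
  b <- generate_cohort(spec, sm, mm)
  expect_identical(serialize(a, NULL), serialize(b, NULL))
  expect_length(a$spectra, (4 + 5) * 2)
  expect_equal(nrow(a$spots$signal), 9)
  expect_equal(unname(table(a$labels)[["case"]]), 4)
  # replicate structure: every subject contributes n_replicates spectra
  ids <- vapply(a$spectra, function(s) s$meta$patient_id, character(1))
  expect_true(all(table(ids) == 2))
})

test_that("the emulated study design yields 408 spectra and 204 spot rows", {
  # arithmetic of the default design: (86 + 118) subjects x 2 replicates
  sm <- sparse_model(n_peaks = 3L, n_ticks = 256L)
  mm <- microbe_model(n_taxa = 5, n_enriched_case = 1,
                      n_enriched_control = 1, seed = 5)
  coh <- generate_cohort(cohort_spec(seed = 3), sm, mm)
  expect_length(coh$spectra, 408)
  expect_equal(nrow(coh$spots$signal), 204)
})

test_that("a noiseless single-peak model produces one smooth bump at its centre", {
  cat1 <- data.frame(mz = 5000, height = 40, width = 10, effect = 0)
  sm <- spectrum_model(n_ticks = 2048, peak_catalog = cat1, noise_sd = 0,
                       baseline_amplitude = 0, intensity_scale_sd = 0,
                       height_sd = 0, warp_max = 0, latent_sd = 0)
  s <- cariomics:::with_seed(1, generate_spectrum(sm))
  apex <- which.max(s$intensity)
  expect_lt(abs(s$mz[apex] - 5000), 15)
  # unimodal: increases to the apex and decreases after, within support
  sup <- which(s$intensity > 1e-8)
  expect_true(all(diff(s$intensity[sup[1]:apex]) >= 0))
  expect_true(all(diff(s$intensity[apex:sup[length(sup)]]) <= 0))
})

test_that("warp_max = 0 leaves all spectra on one identical m/z axis", {
  coh <- small_cohort(sm = sparse_model(warp_max = 0))
  axes <- vapply(coh$spectra, function(s) s$mz, numeric(4096))
  expect_true(all(axes == axes[, 1]))
})

test_that("a planted differential effect is recovered from mean peak heights", {
  # Monte-Carlo oracle: case/control log-ratio of mean subject heights for a
  # differential peak approaches the planted effect at large n
  sm <- sparse_model(n_differential = 2L, effect = 0.8)
  k <- which(sm$peak_catalog$effect > 0)[1]
  n <- 200
  h <- cariomics:::with_seed(42, {
    hc <- replicate(n, cariomics:::subject_heights(sm, "case")[k])
    h0 <- replicate(n, cariomics:::subject_heights(sm, "control")[k])
    list(hc = hc, h0 = h0)
  })
  lr <- log(mean(h$hc)) - log(mean(h$h0))
  se <- sqrt(stats::var(log(h$hc)) / n + stats::var(log(h$h0)) / n)
  expect_lt(abs(lr - 0.8), 3 * max(se, 0.05))
})

test_that("null cohorts carry no planted effects and ground truth is emitted", {
  sm <- sparse_model(n_differential = 4L, effect = 1)
  mm <- microbe_model(n_taxa = 20, n_enriched_case = 3,
                      n_enriched_control = 3, seed = 5)
  spec <- cohort_spec(n_case = 4, n_control = 4, seed = 13)
  coh <- generate_cohort(spec, sm, mm)
  nul <- generate_null_cohort(spec, sm, mm)
  expect_equal(nrow(coh$ground_truth$differential_peaks), 4)
  expect_equal(nrow(coh$ground_truth$differential_taxa), 6)
  expect_equal(nrow(nul$ground_truth$differential_peaks), 0)
  expect_equal(nrow(nul$ground_truth$differential_taxa), 0)
  expect_length(coh$ground_truth$peak_mz, nrow(sm$peak_catalog))
})

test_that("null features are distributed identically in law across classes", {
  # KS check on a non-differential taxon's normalized abundances over a
  # larger simulated cohort: must not reject at alpha = 0.01
  mm <- microbe_model(n_taxa = 12, n_enriched_case = 1,
                      n_enriched_control = 1, seed = 5)
  sm <- sparse_model(n_peaks = 3L, n_ticks = 256L)
  coh <- generate_cohort(cohort_spec(n_case = 100, n_control = 100, seed = 17),
                         sm, mm)
  ab <- to_abundance(filter_spots(coh$spots))
  nulltaxa <- setdiff(ab$taxa, coh$ground_truth$differential_taxa$taxon)
  lab <- as.character(coh$labels[rownames(ab$abundance)])
  p <- vapply(nulltaxa[1:5], function(tx)
    suppressWarnings(stats::ks.test(ab$abundance[lab == "case", tx],
                                    ab$abundance[lab == "control", tx]))$p.value,
    numeric(1))
  expect_gt(min(p), 0.01)
})
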