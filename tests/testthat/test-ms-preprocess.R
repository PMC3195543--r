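test_that("cube-root stabilization maps exact cubes and preserves order", {
  s <- flat_spectrum(c(0, 8, 27, -8, 1))
  out <- stabilize_variance(s)
  expect_equal(out$intensity, c(0, 2, 3, -2, 1))
  mono <- flat_spectrum(seq(0, 100, length.out = 50))
  expect_true(all(diff(stabilize_variance(mono)$intensity) >= 0))
  expect_equal(cariomics:::provenance_steps(out), "stabilize_variance")
})

test_that("baseline correction zeroes a constant spectrum and rejects bad windows", {
  s <- flat_spectrum(rep(4.2, 500))
  expect_equal(correct_baseline(s, 51)$intensity, rep(0, 500))
  expect_error(correct_baseline(s, 50), "odd")
  expect_error(correct_baseline(s, 501 * 2 + 1), "larger than spectrum")
  expect_error(preprocess_config(baseline_window = 200), "odd")
})

test_that("a narrow peak on a flat baseline survives correction nearly intact", {
  n <- 4096
  y <- 30 * exp(-0.5 * ((seq_len(n) - 2000) / 6)^2)
  s <- flat_spectrum(y)
  out <- correct_baseline(s, 201)
  expect_gt(max(out$intensity), 0.95 * 30)
  expect_true(all(out$intensity >= 0))
})

test_that("a known decaying baseline is removed to within 2% off-peak", {
  n <- 16384
  u <- seq(0, 1, length.out = n)
  amp <- 20
  base <- amp * exp(-2 * u)
  centers <- seq(1500, 15000, by = 1200)
  y <- base
  ticks <- seq_len(n)
  for (ct in centers) y <- y + 25 * exp(-0.5 * ((ticks - ct) / 8)^2)
  s <- flat_spectrum(y)
  out <- correct_baseline(s, 201)
  off <- rep(TRUE, n)
  for (ct in centers) off[abs(ticks - ct) < 60] <- FALSE
  resid <- out$intensity[off]   # truth off-peak is 0
  expect_lt(stats::median(abs(resid)), 0.02 * amp)
})

test_that("TIC normalization hits its target, is scale-invariant and idempotent", {
  set.seed(1)
  s <- flat_spectrum(runif(2000, 0, 5))
  rng <- c(1500, 16500)
  out <- normalize_tic(s, rng, target = 100)
  expect_equal(cariomics:::in_range_tic(out, rng), 100, tolerance = 1e-12)
  # doubling intensities first changes nothing
  s2 <- s; s2$intensity <- 2 * s2$intensity
  expect_equal(normalize_tic(s2, rng, target = 100)$intensity, out$intensity,
               tolerance = 1e-12)
  # idempotent within 1e-9 relative
  twice <- normalize_tic(out, rng, target = 100)
  expect_lt(max(abs(twice$intensity - out$intensity)) / max(out$intensity), 1e-9)
  zero <- flat_spectrum(rep(0, 100))
  expect_error(normalize_tic(zero, rng, target = 1), "degenerate")
})

test_that("cohort-mean TIC normalization equalizes in-range ion currents", {
  set.seed(2)
  base <- runif(1000, 0, 2)
  spectra <- lapply(c(1, 2, 3), function(f) flat_spectrum(f * base))
  rng <- c(1500, 16500)
  tics <- vapply(spectra, cariomics:::in_range_tic, numeric(1), tic_range = rng)
  target <- mean(tics)
  out <- lapply(spectra, normalize_tic, tic_range = rng, target = target)
  post <- vapply(out, cariomics:::in_range_tic, numeric(1), tic_range = rng)
  expect_equal(post, rep(target, 3), tolerance = 1e-12)
})

test_that("Gaussian smoothing preserves constants, mass, and delta second moment", {
  s <- flat_spectrum(rep(3, 400))
  expect_equal(smooth_spectrum(s, 3)$intensity, rep(3, 400), tolerance = 1e-12)
  # delta spike spreads into a kernel with matching second moment
  d <- flat_spectrum(c(rep(0, 200), 1, rep(0, 200)))
  sm <- smooth_spectrum(d, 4)$intensity
  expect_equal(sum(sm), 1, tolerance = 1e-3)
  m2 <- sum(sm * (seq_along(sm) - 201)^2) / sum(sm)
  expect_equal(m2, 16, tolerance = 0.05)
  # interior-supported signal conserves total intensity within 0.1%
  set.seed(3)
  y <- c(rep(0, 50), runif(300), rep(0, 50))
  s2 <- flat_spectrum(y)
  expect_lt(abs(sum(smooth_spectrum(s2, 5)$intensity) - sum(y)) / sum(y), 1e-3)
})

test_that("landmark matching agrees with exhaustive enumeration on small cases", {
  # all monotone matchings of up to 3x3 landmarks, several geometries
  set.seed(8)
  for (rep in 1:20) {
    nr <- sample(1:3, 1); ns <- sample(1:3, 1)
    ref <- sort(runif(nr, 1000, 1200))
    spec <- sort(ref[sample(nr, ns, replace = TRUE)] * (1 + runif(ns, -3e-3, 3e-3)))
    gap <- 1e-3; maxs <- 2e-3
    pr <- cariomics:::match_landmarks(ref, spec, max_shift = maxs,
                                      gap_penalty = gap)
    cost_dp <- sum(abs(spec[pr$spec] - ref[pr$ref]) / ref[pr$ref]) +
      gap * (nr - nrow(pr) + ns - nrow(pr))
    cost_enum <- enum_match_cost(ref, spec, maxs, gap)
    expect_equal(cost_dp, cost_enum, tolerance = 1e-10)
    if (nrow(pr) > 1) {
      expect_true(all(diff(pr$ref) > 0) && all(diff(pr$spec) > 0))
    }
  }
})

test_that("an outlier landmark stays unmatched when its shift exceeds the gap cost", {
  ref <- c(2000, 3000)
  spec <- c(2000.5, 3000 * (1 + 4e-3))   # second is a 0.4% outlier
  pr <- cariomics:::match_landmarks(ref, spec, max_shift = 5e-3,
                                    gap_penalty = 1e-3)
  # matching the outlier would cost 4e-3 > two gap penalties (2e-3)
  expect_equal(pr$ref, 1L)
  expect_equal(pr$spec, 1L)
})

test_that("alignment corrects a constant relative shift", {
  sm <- sparse_model(warp_max = 0, noise_sd = 0.2, n_ticks = 8192L)
  coh <- small_cohort(n_case = 3, n_control = 3, n_replicates = 1,
                      sm = sm, seed = 21)
  spectra <- lapply(coh$spectra, stabilize_variance)
  spectra <- lapply(spectra, correct_baseline)
  spectra <- lapply(spectra, smooth_spectrum, bandwidth = 1)
  # impose +0.2% on one spectrum
  s <- spectra[[1]]
  shifted <- s
  shifted$intensity <- stats::approx(s$mz, s$intensity,
                                     xout = s$mz / 1.002, rule = 2)$y
  spectra[[1]] <- shifted
  cfg <- preprocess_config()
  aligned <- align_spectra(spectra, cfg)
  # landmark positions of the realigned spectrum agree with the clean one
  l_ref <- cariomics:::find_landmarks(s$intensity, cfg$align_window, 50L)
  l_al <- cariomics:::find_landmarks(aligned[[1]]$intensity, cfg$align_window, 50L)
  d <- vapply(l_ref, function(t) min(abs(l_al - t)), numeric(1))
  expect_lt(stats::median(d), 2)
  # already-aligned spectra pass through essentially unchanged
  aligned0 <- align_spectra(spectra[-1], cfg)
  for (i in seq_along(aligned0)) {
    expect_lt(max(abs(aligned0[[i]]$intensity - spectra[-1][[i]]$intensity)),
              0.08 * max(spectra[-1][[i]]$intensity))
  }
})

test_that("TIC QC excludes exactly the constructed outlier", {
  set.seed(4)
  base <- runif(1000, 1, 2)
  spectra <- lapply(1:10, function(i) {
    f <- 1 + rnorm(1, 0, 0.01)
    flat_spectrum(f * base, patient = sprintf("P%d", i))
  })
  out <- flat_spectrum(5 * base, patient = "P11")
  res <- qc_filter(c(spectra, list(out)), threshold_sd = 2)
  expect_equal(sum(res$report$excluded), 1)
  expect_equal(res$report$patient[res$report$excluded], "P11")
  none <- qc_filter(spectra, threshold_sd = Inf)
  expect_equal(sum(none$report$excluded), 0)
})

test_that("replicate averaging is the pointwise mean per patient", {
  a <- flat_spectrum(rep(1, 100), patient = "P1")
  b <- flat_spectrum(rep(3, 100), patient = "P1", replicate = 2)
  c2 <- flat_spectrum(rep(7, 100), patient = "P2")
  avg <- average_replicates(list(a, b, c2))
  expect_named(avg, c("P1", "P2"))
  expect_equal(avg$P1$intensity, rep(2, 100))
  expect_equal(avg$P2$intensity, rep(7, 100))
  bad <- flat_spectrum(rep(1, 50), patient = "P3")
  expect_error(average_replicates(list(a, bad)), "common axis")
})

test_that("the preprocessing chain records steps in the required order", {
  coh <- small_cohort()
  pp <- preprocess_cohort(coh$spectra)
  steps <- cariomics:::provenance_steps(pp$profiles[[1]])
  expect_equal(steps, c("stabilize_variance", "correct_baseline",
                        "normalize_tic", "smooth", "align",
                        "average_replicates"))
  expect_true(all(pp$profiles[[1]]$intensity >= 0))
})
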