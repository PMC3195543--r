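# Shared small-scale fixtures. Spectral scales are reduced so unit tests
# stay fast; acceptance-level checks build their own cohorts at the scales
# they state.

# sparse, well-resolved spectrum model: a handful of strong peaks
sparse_model <- function(n_peaks = 12L, n_ticks = 4096L, noise_sd = 0.5,
                         warp_max = 0.001, n_differential = 0L, effect = 1,
                         seed = 401L) {
  spectrum_model(n_ticks = n_ticks, n_peaks = n_peaks,
                 n_differential = n_differential, effect = effect,
                 width_frac = 8e-4, height_meanlog = log(30),
                 height_sdlog = 0.3, noise_sd = noise_sd,
                 warp_max = warp_max, seed = seed)
}

# reduced-geometry model for end-to-end runs: cheap but structurally
# faithful (dense-ish peaks, differential block, warp)
reduced_model <- function(seed = 2026L, ...) {
  spectrum_model(n_ticks = 8192L, n_peaks = 300L, n_differential = 30L,
                 seed = seed, ...)
}

small_cohort <- function(n_case = 5L, n_control = 6L, n_replicates = 2L,
                         seed = 11L, sm = sparse_model(),
                         mm = microbe_model(n_taxa = 20L,
                                            n_enriched_case = 2L,
                                            n_enriched_control = 2L,
                                            seed = 5L)) {
  generate_cohort(cohort_spec(n_case = n_case, n_control = n_control,
                              n_replicates = n_replicates, seed = seed),
                  sm, mm)
}

# flat-ish synthetic spectrum helper for preprocessing unit tests
flat_spectrum <- function(values, patient = "P1", ...) {
  n <- length(values)
  mz <- seq(1000, 20000, length.out = n)
  ms_spectrum(seq_len(n), mz, values, patient_id = patient, ...)
}

# exhaustive-enumeration oracle for the two-sided rank-sum P value
# (untied data): enumerates all C(n1+n2, n1) assignments of the pooled
# ranks to the first group
enum_ranksum_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n1)])
  combs <- utils::combn(n1 + n2, n1)
  w_all <- colSums(matrix(seq_len(n1 + n2)[combs], nrow = n1))
  p_le <- mean(w_all <= w_obs)
  p_ge <- mean(w_all >= w_obs)
  min(1, 2 * min(p_le, p_ge))
}

# exhaustive matching oracle: minimal-cost order-preserving one-to-one
# matching of two landmark lists under the same cost model as the DP
enum_match_cost <- function(ref_mz, spec_mz, max_shift, gap_penalty) {
  nr <- length(ref_mz); ns <- length(spec_mz)
  best <- Inf
  # enumerate all monotone partial matchings via subsets
  ref_sets <- unlist(lapply(0:min(nr, ns), function(k)
    utils::combn(nr, k, simplify = FALSE)), recursive = FALSE)
  for (rs in ref_sets) {
    k <- length(rs)
    spec_sets <- utils::combn(ns, k, simplify = FALSE)
    for (ss in spec_sets) {
      cost <- sum(abs(spec_mz[ss] - ref_mz[rs]) / ref_mz[rs])
      if (k && any(abs(spec_mz[ss] - ref_mz[rs]) / ref_mz[rs] > max_shift))
        next
      total <- cost + gap_penalty * (nr - k + ns - k)
      if (total < best) best <- total
    }
  }
  best
}
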