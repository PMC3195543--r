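# Synthetic cohort generator: linear-TOF-like salivary spectra plus a
# checkerboard spot-signal table with planted case/control structure and
# recorded ground truth. The generator defines the simulated study
# conditions; analysis modules never read the ground-truth metadata.

#' Cohort design for the synthetic generator
#'
#' Defaults mirror the emulated clinical study: 86 caries-active children,
#' 118 caries-free children, duplicate spectra per subject on one
#' chip/laser condition.
#'
#' @param n_case number of caries-active subjects (>= 2).
#' @param n_control number of caries-free subjects (>= 2).
#' @param n_replicates spectra acquired per subject (>= 1).
#' @param seed RNG seed making the cohort fully reproducible.
#' @param chip,laser acquisition condition tags (metadata only).
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_case = 86L, n_control = 118L, n_replicates = 2L,
                        seed = 1L, chip = "CM10", laser = "low") {
  n_case <- as.integer(n_case); n_control <- as.integer(n_control)
  n_replicates <- as.integer(n_replicates)
  if (is.na(n_case) || n_case < 2L) stop("n_case must be >= 2")
  if (is.na(n_control) || n_control < 2L) stop("n_control must be >= 2")
  if (is.na(n_replicates) || n_replicates < 1L) stop("n_replicates must be >= 1")
  structure(list(n_case = n_case, n_control = n_control,
                 n_replicates = n_replicates, seed = as.integer(seed),
                 chip = chip, laser = laser),
            class = "cohort_spec")
}

# Quadratic TOF-like tick -> m/z map covering mz_range over n ticks.
make_mz_map <- function(n_ticks, mz_range) {
  r <- sqrt(mz_range[2] / mz_range[1])
  t0 <- (n_ticks - r) / (r - 1)
  a <- mz_range[1] / (1 + t0)^2
  list(mz = a * (seq_len(n_ticks) + t0)^2, t0 = t0, a = a)
}

#' Generative model for synthetic SELDI-TOF spectra
#'
#' Each spectrum is `scale * (sum of Gaussian peaks + decaying baseline)`
#' plus additive noise, sampled on a quadratic tick-to-Dalton axis and
#' observed under a small random m/z miscalibration. Peak width grows
#' proportionally with m/z (linear-TOF broadening). A subset of peaks is
#' differential between classes; within each differential direction a
#' shared per-subject latent factor co-varies the peaks, so block-level
#' separability saturates realistically rather than growing without bound
#' with the number of markers.
#'
#' @param n_ticks number of clock ticks per spectrum.
#' @param mz_range Daltons covered by the axis (must contain `peak_window`).
#' @param n_peaks number of planted peaks.
#' @param peak_window Daltons within which peaks are placed.
#' @param height_meanlog,height_sdlog log-normal peak height parameters.
#' @param width_frac Gaussian peak sigma as a fraction of peak m/z.
#' @param n_differential number of class-differential peaks (half enriched
#'   in cases, half in controls).
#' @param effect absolute case/control log-fold change of differential
#'   peak heights (natural log).
#' @param latent_sd SD of the shared per-subject latent factor added (on the
#'   log scale) to each differential direction's peaks.
#' @param height_sd per-subject, per-peak biological log-scale SD.
#' @param baseline_amplitude,baseline_rate decaying-exponential baseline
#'   amplitude (intensity units) and rate (per axis length).
#' @param noise_sd additive detector noise SD.
#' @param intensity_scale_sd per-spectrum multiplicative log-scale SD.
#' @param warp_max maximal relative m/z miscalibration per spectrum
#'   (uniform in `[-warp_max, warp_max]`).
#' @param peak_catalog optional explicit catalog (data frame with columns
#'   `mz`, `height`, `width`, `effect`) overriding random placement.
#' @param seed seed used to draw the peak catalog.
#' @return A `spectrum_model` list; `$peak_catalog` holds the ground truth.
#' @export
spectrum_model <- function(n_ticks = 65536L, mz_range = c(1000, 45000),
                           n_peaks = 2000L, peak_window = c(1500, 40000),
                           height_meanlog = log(15), height_sdlog = 0.6,
                           width_frac = 1.4e-4,
                           n_differential = 30L, effect = 1.0,
                           latent_sd = 0.45, height_sd = 0.3,
                           baseline_amplitude = 20, baseline_rate = 3,
                           noise_sd = 1, intensity_scale_sd = 0.15,
                           warp_max = 0.001,
                           peak_catalog = NULL, seed = 2026L) {
  stopifnot(n_ticks >= 16L, mz_range[1] > 0, mz_range[1] < mz_range[2],
            peak_window[1] >= mz_range[1], peak_window[2] <= mz_range[2],
            width_frac > 0, warp_max >= 0, n_differential %% 2L == 0L,
            n_differential <= n_peaks)
  map <- make_mz_map(n_ticks, mz_range)
  if (is.null(peak_catalog)) {
    peak_catalog <- with_seed(seed, {
      # jittered log-uniform grid in m/z: with width proportional to m/z and
      # the quadratic tick axis, the spacing/width ratio is then constant
      # along the whole spectrum, so neighbours stay equally resolvable
      grid <- exp(seq(log(peak_window[1]), log(peak_window[2]),
                      length.out = n_peaks + 2L))[-c(1L, n_peaks + 2L)]
      spacing <- log(grid[2L]) - log(grid[1L])
      mzc <- grid * exp(stats::runif(n_peaks, -0.35, 0.35) * spacing)
      height <- stats::rlnorm(n_peaks, height_meanlog, height_sdlog)
      eff <- numeric(n_peaks)
      if (n_differential > 0L) {
        eligible <- which(height >= stats::median(height))
        di <- sample(eligible, n_differential)
        eff[di] <- rep(c(effect, -effect), length.out = n_differential)
      }
      data.frame(mz = mzc, height = height, width = width_frac * mzc,
                 effect = eff)
    })
  } else {
    stopifnot(all(c("mz", "height", "width", "effect") %in% names(peak_catalog)),
              all(peak_catalog$width > 0),
              all(peak_catalog$mz >= mz_range[1] & peak_catalog$mz <= mz_range[2]))
  }
  structure(list(n_ticks = as.integer(n_ticks), mz = map$mz,
                 mz_range = mz_range, peak_window = peak_window,
                 peak_catalog = peak_catalog,
                 latent_sd = latent_sd, height_sd = height_sd,
                 baseline_amplitude = baseline_amplitude,
                 baseline_rate = baseline_rate,
                 noise_sd = noise_sd, intensity_scale_sd = intensity_scale_sd,
                 warp_max = warp_max),
            class = "spectrum_model")
}

baseline_curve <- function(sm) {
  u <- seq(0, 1, length.out = sm$n_ticks)
  sm$baseline_amplitude * (exp(-sm$baseline_rate * u) + 0.1 * (1 - u))
}

# Sum of Gaussian peaks with per-subject heights; each peak touches only its
# +/- 4 sigma neighbourhood.
peak_profile <- function(sm, heights) {
  y <- numeric(sm$n_ticks)
  mz <- sm$mz
  cat <- sm$peak_catalog
  for (k in seq_len(nrow(cat))) {
    c_k <- cat$mz[k]; w_k <- cat$width[k]
    idx <- findInterval(c(c_k - 4 * w_k, c_k + 4 * w_k), mz)
    lo <- max(idx[1L], 1L); hi <- min(idx[2L] + 1L, sm$n_ticks)
    if (lo > hi) next
    seg <- lo:hi
    y[seg] <- y[seg] + heights[k] * exp(-0.5 * ((mz[seg] - c_k) / w_k)^2)
  }
  y
}

# Per-subject peak heights: class effect, shared latent per differential
# direction, independent biological noise. Uses the current RNG stream.
subject_heights <- function(sm, label) {
  cat <- sm$peak_catalog
  z_up <- stats::rnorm(1, 0, sm$latent_sd)
  z_dn <- stats::rnorm(1, 0, sm$latent_sd)
  lat <- ifelse(cat$effect > 0, z_up, ifelse(cat$effect < 0, z_dn, 0))
  cls <- if (identical(label, "case")) cat$effect else 0
  cat$height * exp(cls + lat + stats::rnorm(nrow(cat), 0, sm$height_sd))
}

#' Generate one synthetic spectrum
#'
#' Draws a single replicate from a [spectrum_model()]: the subject's noiseless
#' peak-plus-baseline profile is observed under a random relative m/z
#' miscalibration, scaled by a log-normal per-spectrum factor, and corrupted
#' with additive noise; intensities are clipped at zero. Uses the current RNG
#' stream (seed via [with_seed()] or `set.seed()` for reproducibility).
#'
#' @param sm a `spectrum_model`.
#' @param heights per-peak subject heights; defaults to a fresh draw from
#'   `subject_heights()` for `label`.
#' @param patient_id,label,chip,laser,replicate metadata for the spectrum.
#' @return An [ms_spectrum()].
#' @export
generate_spectrum <- function(sm, heights = NULL, patient_id = "S1",
                              label = "control", chip = "CM10",
                              laser = "low", replicate = 1L) {
  if (is.null(heights)) heights <- subject_heights(sm, label)
  profile <- peak_profile(sm, heights) + baseline_curve(sm)
  delta <- if (sm$warp_max > 0) stats::runif(1, -sm$warp_max, sm$warp_max) else 0
  obs <- if (delta != 0) {
    # content truly at m is read out at m*(1+delta)
    stats::approx(sm$mz, profile, xout = sm$mz / (1 + delta), rule = 2)$y
  } else profile
  scale <- exp(stats::rnorm(1, 0, sm$intensity_scale_sd))
  y <- scale * obs
  if (sm$noise_sd > 0) y <- y + stats::rnorm(sm$n_ticks, 0, sm$noise_sd)
  out <- ms_spectrum(seq_len(sm$n_ticks), sm$mz, pmax(y, 0),
                     patient_id = patient_id, label = label, chip = chip,
                     laser = laser, replicate = replicate)
  out$meta$warp <- delta   # ground-truth miscalibration, for test oracles
  out
}

#' Generative model for the checkerboard microbial array
#'
#' Taxon abundances are log-normal around taxon-specific baselines; two
#' disjoint differential sets model antagonistic communities (taxa enriched
#' in caries-active vs caries-free subjects), each co-varying through a
#' shared per-subject community factor. Spot signals scale with a
#' per-sample DNA amount that the universal-probe lanes also carry, so
#' universal-probe normalization can remove it.
#'
#' @param n_taxa number of probes/taxa on the membrane.
#' @param n_enriched_case,n_enriched_control sizes of the two disjoint
#'   differential taxon sets.
#' @param effect absolute case/control log-fold change for differential taxa.
#' @param dispersion per-sample, per-taxon biological log-scale SD.
#' @param community_sd SD of the shared per-subject community factor.
#' @param base_meanlog,base_sdlog log-normal taxon baseline abundances.
#' @param universal_mean mean universal-probe signal per unit DNA scale.
#' @param universal_cv log-scale SD of universal-lane measurement noise.
#' @param sample_scale_sd log-scale SD of the per-sample DNA amount.
#' @param measurement_cv log-scale SD of per-spot measurement noise.
#' @param flag_rate fraction of spots flagged low-quality.
#' @param seed seed for drawing taxon baselines and differential sets.
#' @return A `microbe_model` list with ground-truth `$effects` per taxon.
#' @export
microbe_model <- function(n_taxa = 82L, n_enriched_case = 6L,
                          n_enriched_control = 6L, effect = 1.3,
                          dispersion = 0.8, community_sd = 0.5,
                          base_meanlog = log(50), base_sdlog = 1.0,
                          universal_mean = 500, universal_cv = 0.05,
                          sample_scale_sd = 0.5, measurement_cv = 0.1,
                          flag_rate = 0.01, seed = 2027L) {
  n_taxa <- as.integer(n_taxa)
  n_diff <- n_enriched_case + n_enriched_control
  if (n_taxa < n_diff) stop("n_taxa must cover both differential sets")
  drawn <- with_seed(seed, {
    base <- stats::rnorm(n_taxa, base_meanlog, base_sdlog)
    di <- sample.int(n_taxa, n_diff)
    list(base = base,
         case_set = sort(di[seq_len(n_enriched_case)]),
         control_set = sort(di[n_enriched_case + seq_len(n_enriched_control)]))
  })
  effects <- numeric(n_taxa)
  effects[drawn$case_set] <- effect
  effects[drawn$control_set] <- -effect
  structure(list(n_taxa = n_taxa,
                 taxa = sprintf("Taxon_%03d", seq_len(n_taxa)),
                 base_log = drawn$base, effects = effects,
                 case_set = drawn$case_set, control_set = drawn$control_set,
                 dispersion = dispersion, community_sd = community_sd,
                 universal_mean = universal_mean, universal_cv = universal_cv,
                 sample_scale_sd = sample_scale_sd,
                 measurement_cv = measurement_cv, flag_rate = flag_rate),
            class = "microbe_model")
}

# Spot-signal table for given subject labels; uses the current RNG stream.
generate_spot_table <- function(mm, ids, labels) {
  n <- length(ids)
  sig <- matrix(0, n, mm$n_taxa, dimnames = list(ids, mm$taxa))
  uni <- matrix(0, n, 2L, dimnames = list(ids, c("UNIV_1", "UNIV_2")))
  for (s in seq_len(n)) {
    d_s <- exp(stats::rnorm(1, 0, mm$sample_scale_sd))
    z_case <- stats::rnorm(1, 0, mm$community_sd)
    z_ctrl <- stats::rnorm(1, 0, mm$community_sd)
    lat <- numeric(mm$n_taxa)
    lat[mm$case_set] <- z_case
    lat[mm$control_set] <- z_ctrl
    cls <- if (labels[s] == "case") mm$effects else 0
    ab <- exp(mm$base_log + cls + lat + stats::rnorm(mm$n_taxa, 0, mm$dispersion))
    sig[s, ] <- d_s * ab * exp(stats::rnorm(mm$n_taxa, 0, mm$measurement_cv))
    uni[s, ] <- d_s * mm$universal_mean * exp(stats::rnorm(2L, 0, mm$universal_cv))
  }
  quality <- matrix(stats::runif(n * mm$n_taxa) >= mm$flag_rate, n, mm$n_taxa,
                    dimnames = dimnames(sig))
  spot_signal_table(cbind(sig, uni), universal = colnames(uni),
                    quality = cbind(quality,
                                    matrix(TRUE, n, 2L,
                                           dimnames = dimnames(uni))),
                    labels = stats::setNames(labels, ids))
}

#' Generate a full synthetic cohort
#'
#' Draws spectra (with replicates), the checkerboard spot-signal table, and
#' class labels for one simulated study, all from `spec$seed`; the result is
#' byte-identical across runs with the same inputs. Ground truth (planted
#' peak positions and effects, differential taxa) is returned alongside for
#' use by test oracles only.
#'
#' @param spec a [cohort_spec()].
#' @param sm a [spectrum_model()].
#' @param mm a [microbe_model()].
#' @return A `synthetic_cohort` list: `spectra` (list of [ms_spectrum()]),
#'   `spots` (a `spot_signal_table`), `labels` (named factor,
#'   levels `control`/`case`), and `ground_truth`.
#' @export
generate_cohort <- function(spec, sm, mm) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(sm, "spectrum_model"),
            inherits(mm, "microbe_model"))
  n <- spec$n_control + spec$n_case
  ids <- sprintf("S%03d", seq_len(n))
  labels <- c(rep("control", spec$n_control), rep("case", spec$n_case))
  with_seed(spec$seed, {
    spectra <- vector("list", n * spec$n_replicates)
    k <- 0L
    for (s in seq_len(n)) {
      h <- subject_heights(sm, labels[s])
      for (r in seq_len(spec$n_replicates)) {
        k <- k + 1L
        spectra[[k]] <- generate_spectrum(sm, heights = h,
                                          patient_id = ids[s],
                                          label = labels[s],
                                          chip = spec$chip,
                                          laser = spec$laser, replicate = r)
      }
    }
    spots <- generate_spot_table(mm, ids, labels)
    diff_peaks <- sm$peak_catalog[sm$peak_catalog$effect != 0, , drop = FALSE]
    structure(list(
      spectra = spectra, spots = spots,
      labels = factor(stats::setNames(labels, ids),
                      levels = c("control", "case")),
      ground_truth = list(
        peak_mz = sm$peak_catalog$mz,
        peak_catalog = sm$peak_catalog,
        differential_peaks = diff_peaks,
        differential_taxa = data.frame(
          taxon = mm$taxa[mm$effects != 0],
          effect = mm$effects[mm$effects != 0])),
      cohort_spec = spec),
      class = "synthetic_cohort")
  })
}

#' Generate a null cohort (no class signal)
#'
#' Identical generative process for both classes: all differential effects
#' (peaks and taxa) are set to zero while every other source of variation is
#' kept. Used for calibration: any downstream classifier should perform at
#' chance on such a cohort.
#'
#' @inheritParams generate_cohort
#' @return A `synthetic_cohort`; see [generate_cohort()].
#' @export
generate_null_cohort <- function(spec, sm, mm) {
  sm$peak_catalog$effect <- 0
  mm$effects[] <- 0
  generate_cohort(spec, sm, mm)
}
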