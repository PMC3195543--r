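# Five-step spectral preprocessing chain: cube-root variance stabilization,
# moving-window baseline subtraction, TIC normalization (1500-16500 Da),
# Gaussian-kernel smoothing, and peak-based dynamic-programming alignment;
# plus the 2-SD TIC quality-control rule and replicate averaging.

#' Preprocessing configuration
#'
#' @param baseline_window moving-window width in time points for baseline
#'   estimation (odd; the classical choice is ~200 points, rounded up to the
#'   odd 201 for a centred window).
#' @param tic_range Daltons over which the total ion current is summed for
#'   normalization and QC.
#' @param smooth_bandwidth Gaussian kernel SD in ticks.
#' @param qc_sd_threshold spectra whose in-range TIC deviates from the cohort
#'   mean by more than this many SDs are excluded.
#' @param tic_target `"cohort_mean"` or a positive number: the post-
#'   normalization in-range ion current.
#' @param align_window local-max half-window (ticks) for alignment landmarks.
#' @param align_n_landmarks number of most-prominent local maxima used as
#'   alignment landmarks per spectrum.
#' @param max_shift maximal relative m/z shift the alignment warp may apply.
#' @param gap_penalty dynamic-programming cost (relative-shift units) of
#'   leaving one landmark unmatched.
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(baseline_window = 201L,
                              tic_range = c(1500, 16500),
                              smooth_bandwidth = 1,
                              qc_sd_threshold = 2,
                              tic_target = "cohort_mean",
                              align_window = 10L,
                              align_n_landmarks = 300L,
                              max_shift = 0.005,
                              gap_penalty = 0.0025) {
  baseline_window <- as.integer(baseline_window)
  if (baseline_window < 3L || baseline_window %% 2L == 0L)
    stop("baseline_window must be odd and >= 3")
  if (tic_range[1] >= tic_range[2]) stop("tic_range must be (low, high)")
  if (smooth_bandwidth < 0) stop("smooth_bandwidth must be >= 0")
  structure(list(baseline_window = baseline_window, tic_range = tic_range,
                 smooth_bandwidth = smooth_bandwidth,
                 qc_sd_threshold = qc_sd_threshold, tic_target = tic_target,
                 align_window = as.integer(align_window),
                 align_n_landmarks = as.integer(align_n_landmarks),
                 max_shift = max_shift, gap_penalty = gap_penalty),
            class = "preprocess_config")
}

#' Cube-root variance stabilization
#'
#' Replaces every intensity y by `sign(y) * |y|^(1/3)`. The signed form
#' tolerates detector ringing below zero; the transform is strictly
#' order-preserving.
#'
#' @param s an [ms_spectrum()].
#' @return The stabilized spectrum, with provenance updated.
#' @export
stabilize_variance <- function(s) {
  s$intensity <- sign(s$intensity) * abs(s$intensity)^(1 / 3)
  add_provenance(s, "stabilize_variance", list(transform = "signed cube root"))
}

# Baseline track: moving-window local minimum smoothed by a moving average
# over the same window.
estimate_baseline <- function(y, window) {
  moving_average(running_min(y, window), window)
}

#' Moving-window baseline subtraction
#'
#' The baseline is estimated as the local minimum over a centred moving
#' window, smoothed by a moving average of the same width; the corrected
#' signal is `max(signal - baseline, 0)`, so output is never negative.
#'
#' @param s an [ms_spectrum()].
#' @param window odd window width in time points.
#' @return The baseline-corrected spectrum.
#' @export
correct_baseline <- function(s, window = 201L) {
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L) stop("window must be odd and >= 3")
  if (window > length(s$intensity)) stop("window larger than spectrum")
  b <- estimate_baseline(s$intensity, window)
  s$intensity <- pmax(s$intensity - b, 0)
  add_provenance(s, "correct_baseline", list(window = window))
}

in_range_tic <- function(s, tic_range) {
  sel <- s$mz >= tic_range[1] & s$mz <= tic_range[2]
  sum(s$intensity[sel])
}

#' Total ion current normalization
#'
#' Scales all intensities so the ion current summed over `tic_range`
#' equals `target`. With the cohort workflow the target is the cohort's mean
#' in-range TIC (see [preprocess_cohort()]); normalization is idempotent and
#' invariant to any prior multiplicative scaling of the spectrum.
#'
#' @param s an [ms_spectrum()].
#' @param tic_range Daltons (low, high) over which ion current is summed.
#' @param target positive number: the desired in-range ion current.
#' @return The normalized spectrum.
#' @export
normalize_tic <- function(s, tic_range = c(1500, 16500), target) {
  stopifnot(is.numeric(target), target > 0)
  tic <- in_range_tic(s, tic_range)
  if (tic <= 0)
    stop("degenerate spectrum: zero ion current in normalization range")
  s$intensity <- s$intensity * (target / tic)
  add_provenance(s, "normalize_tic",
                 list(tic_range = tic_range, target = target, pre_tic = tic))
}

#' Gaussian-kernel smoothing
#'
#' Discrete convolution on the tick axis with a Gaussian kernel of SD
#' `bandwidth` ticks, truncated at 4 SD, weights normalized to sum to 1, and
#' reflective boundary handling (total intensity is conserved up to boundary
#' effects).
#'
#' @param s an [ms_spectrum()].
#' @param bandwidth kernel SD in ticks; 0 is the identity.
#' @return The smoothed spectrum.
#' @export
smooth_spectrum <- function(s, bandwidth = 1) {
  if (bandwidth < 0) stop("bandwidth must be >= 0")
  if (bandwidth > 0) {
    h <- max(1L, ceiling(4 * bandwidth))
    k <- stats::dnorm(-h:h, sd = bandwidth)
    k <- k / sum(k)
    n <- length(s$intensity)
    xp <- c(s$intensity[(h + 1L):2L], s$intensity, s$intensity[(n - 1L):(n - h)])
    s$intensity <- as.numeric(stats::filter(xp, k, sides = 2L))[(h + 1L):(h + n)]
  }
  add_provenance(s, "smooth", list(bandwidth = bandwidth))
}

# ---- peak-based dynamic-programming alignment ------------------------------

# Landmarks: the n_landmarks most prominent strict local maxima (prominence
# measured above the local median). Rank-based selection keeps landmark
# counts stable whether the spectrum is sparse or a dense peak forest.
# Returns tick indices in increasing order.
find_landmarks <- function(y, window, n_landmarks = 300L) {
  w <- 2L * window + 1L
  med_w <- 4L * w + 1L
  med <- local_median(y, med_w + (med_w %% 2L == 0L))
  det <- y - med
  wmax <- running_max(y, w)
  # prominence floor workable in both regimes: in sparse spectra the MAD term
  # sits well above noise maxima; in dense peak forests (where the MAD is at
  # peak scale) the max-referenced term keeps the strong peaks
  floor_ <- min(8 * stats::mad(det), 0.25 * max(det))
  cand <- which(y == wmax & det > floor_)
  # enforce strict maximality: drop candidates tied with another point in
  # their window (plateaus keep no representative; real peaks are smooth)
  keep <- vapply(cand, function(i) {
    lo <- max(1L, i - window); hi <- min(length(y), i + window)
    sum(y[lo:hi] == y[i]) == 1L
  }, logical(1))
  cand <- cand[keep]
  if (length(cand) > n_landmarks)
    cand <- sort(cand[order(det[cand], decreasing = TRUE)[seq_len(n_landmarks)]])
  cand
}

# Sub-tick apex refinement: quadratic interpolation through the apex and its
# neighbours. Shifts estimated from integer apex positions are quantized to
# the grid; the parabola vertex removes that quantization.
refine_apex <- function(y, ticks, mz) {
  n <- length(y)
  vapply(ticks, function(i) {
    if (i <= 1L || i >= n) return(mz[i])
    d1 <- (y[i + 1L] - y[i - 1L]) / 2
    d2 <- y[i + 1L] - 2 * y[i] + y[i - 1L]
    off <- if (d2 < 0) max(-0.5, min(0.5, -d1 / d2)) else 0
    step <- if (off >= 0) mz[min(i + 1L, n)] - mz[i] else mz[i] - mz[i - 1L]
    mz[i] + off * step
  }, numeric(1))
}

# Order-preserving one-to-one matching of spectrum landmarks to reference
# landmarks (both as m/z vectors) by dynamic programming minimizing total
# relative shift with a per-unmatched-landmark gap penalty. Matches with
# relative shift > max_shift are infeasible.
match_landmarks <- function(ref_mz, spec_mz, max_shift = 0.005,
                            gap_penalty = 0.0025) {
  nr <- length(ref_mz); ns <- length(spec_mz)
  if (!nr || !ns) return(data.frame(ref = integer(0), spec = integer(0)))
  # cost[i, j]: relative shift of matching ref i to spec j (Inf if too far)
  D <- matrix(0, nr + 1L, ns + 1L)
  D[1L, ] <- (0:ns) * gap_penalty
  D[, 1L] <- (0:nr) * gap_penalty
  j_idx <- seq_len(ns)
  for (i in seq_len(nr)) {
    cost <- abs(spec_mz - ref_mz[i]) / ref_mz[i]
    cost[cost > max_shift] <- Inf
    a <- pmin(D[i, j_idx] + cost,        # match (diag)
              D[i, j_idx + 1L] + gap_penalty)  # skip ref i (up)
    # D[i+1, j] = min(a_j, D[i+1, j-1] + gap): prefix-min recurrence
    g <- gap_penalty * j_idx
    b <- cummin(pmin(a, c(D[i + 1L, 1L] + gap_penalty, rep(Inf, ns - 1L))) - g) + g
    D[i + 1L, j_idx + 1L] <- b
  }
  # traceback: pick the predecessor attaining the cell value (argmin, with a
  # small tolerance so accumulated rounding cannot derail a match)
  pairs_ref <- integer(0); pairs_spec <- integer(0)
  i <- nr; j <- ns
  eps <- 1e-9
  while (i > 0L && j > 0L) {
    cost <- abs(spec_mz[j] - ref_mz[i]) / ref_mz[i]
    if (cost > max_shift) cost <- Inf
    cand <- c(D[i, j] + cost, D[i, j + 1L] + gap_penalty,
              D[i + 1L, j] + gap_penalty)
    best <- min(cand)
    if (is.finite(cost) && cand[1L] <= best + eps) {
      pairs_ref <- c(i, pairs_ref); pairs_spec <- c(j, pairs_spec)
      i <- i - 1L; j <- j - 1L
    } else if (cand[2L] <= best + eps) {
      i <- i - 1L
    } else {
      j <- j - 1L
    }
  }
  data.frame(ref = pairs_ref, spec = pairs_spec)
}

# Piecewise-linear relative-shift field from matched landmark pairs:
# interpolated linearly between matched pairs, held constant beyond the
# outermost ones, clamped to +/- max_shift.
shift_field <- function(mz, pair_spec_mz, pair_ref_mz, max_shift) {
  delta <- (pair_ref_mz - pair_spec_mz) / pair_spec_mz
  rel <- if (length(delta) == 1L) rep(delta, length(mz)) else
    stats::approx(pair_spec_mz, delta, xout = mz, rule = 2)$y
  pmin(pmax(rel, -max_shift), max_shift)
}

# Apply a relative-shift field: content at m moves to m*(1+rel); intensities
# are resampled back onto the common m/z grid.
apply_shift <- function(s, rel) {
  s$intensity <- stats::approx(s$mz * (1 + rel), s$intensity, xout = s$mz,
                               rule = 2)$y
  s
}

warp_spectrum <- function(s, pair_spec_mz, pair_ref_mz, max_shift) {
  apply_shift(s, shift_field(s$mz, pair_spec_mz, pair_ref_mz, max_shift))
}

#' Peak-based dynamic-programming alignment
#'
#' Aligns a cohort of spectra sharing one tick axis to a common consensus:
#' (1) landmark peaks (strong local maxima) are detected per spectrum;
#' (2) each spectrum's landmarks are matched to reference landmarks by
#' order-preserving dynamic programming minimizing total relative shift,
#' with a gap penalty per unmatched landmark and a maximal relative shift;
#' (3) a piecewise-linear warp interpolated between matched pairs is
#' applied and intensities are resampled onto the common axis.
#'
#' The first pass uses a single sharp spectrum (the one with median
#' in-range ion current) as the reference -- the cohort mean of
#' miscalibrated spectra is blurred by the very shifts being corrected --
#' and then subtracts the cohort-mean applied shift from every warp, so the
#' consensus frame is centred on the cohort rather than inheriting the
#' reference spectrum's own miscalibration. Subsequent passes refine
#' against the mean of the aligned spectra, which is sharp. Spectra in
#' which no landmark is found are passed through with a warning.
#'
#' @param spectra list of [ms_spectrum()] on identical axes (>= 2).
#' @param config a [preprocess_config()] (fields `align_window`,
#'   `align_n_landmarks`, `max_shift`, `gap_penalty`).
#' @param passes number of alignment passes (>= 1; default 2 =
#'   centred single-reference pass plus one mean-reference refinement).
#' @return The list of aligned spectra.
#' @export
align_spectra <- function(spectra, config = preprocess_config(), passes = 2L) {
  if (length(spectra) < 2L) stop("alignment needs at least 2 spectra")
  n <- length(spectra[[1L]]$intensity)
  if (!all(vapply(spectra, function(s) length(s$intensity) == n, logical(1))))
    stop("spectra must share a common axis")
  # shift fields are composed across passes and the original intensities are
  # resampled once per pass from the accumulated field, so narrow peaks are
  # not attenuated by repeated interpolation
  total <- rep(list(numeric(n)), length(spectra))
  aligned <- spectra
  est <- NULL
  for (p in seq_len(passes)) {
    est <- estimate_alignment(aligned, config, centre = (p == 1L))
    total <- mapply(function(a, b)
      pmin(pmax(a + b, -config$max_shift), config$max_shift),
      total, est$fields, SIMPLIFY = FALSE)
    aligned <- mapply(apply_shift, spectra, total, SIMPLIFY = FALSE)
  }
  mapply(function(s, matched, landmarks) {
    if (matched == 0L)
      warning("no landmarks matched; spectrum passed through unaligned")
    add_provenance(s, "align",
                   list(matched = matched, landmarks = landmarks,
                        passes = passes, max_shift = config$max_shift,
                        gap_penalty = config$gap_penalty))
  }, aligned, est$matched, est$landmarks, SIMPLIFY = FALSE)
}

# One alignment pass: estimates a per-spectrum relative-shift field without
# applying it. centre = TRUE uses the median-TIC spectrum as reference and
# subtracts the cohort-mean field.
estimate_alignment <- function(spectra, config, centre = FALSE) {
  mz <- spectra[[1L]]$mz
  ref_int <- if (centre) {
    # sharp single-spectrum reference: median total ion current
    tic <- vapply(spectra, in_range_tic, numeric(1), tic_range = config$tic_range)
    spectra[[order(tic)[(length(tic) + 1L) %/% 2L]]]$intensity
  } else {
    Reduce(`+`, lapply(spectra, `[[`, "intensity")) / length(spectra)
  }
  ref_ticks <- find_landmarks(ref_int, config$align_window,
                              config$align_n_landmarks)
  ref_mz <- refine_apex(ref_int, ref_ticks, mz)
  # matched landmark pairs per spectrum; warps are applied only after the
  # cohort-mean shift is known, so centring needs no second resampling
  pairs <- lapply(spectra, function(s) {
    lm_ticks <- find_landmarks(s$intensity, config$align_window,
                               config$align_n_landmarks)
    if (!length(lm_ticks) || !length(ref_ticks))
      return(NULL)
    lm_mz <- refine_apex(s$intensity, lm_ticks, mz)
    # against a single-spectrum reference two miscalibrations add, so the
    # matching window is doubled; the applied (centred, composed) warp is
    # still clamped to max_shift
    pr <- match_landmarks(ref_mz, lm_mz,
                          max_shift = if (centre) 2 * config$max_shift
                                      else config$max_shift,
                          gap_penalty = if (centre) 2 * config$gap_penalty
                                        else config$gap_penalty)
    if (!nrow(pr)) return(NULL)
    list(spec_mz = lm_mz[pr$spec], ref_mz = ref_mz[pr$ref],
         n_landmarks = length(lm_ticks))
  })
  field_cap <- if (centre) 2 * config$max_shift else config$max_shift
  fields <- lapply(pairs, function(pr) {
    if (is.null(pr)) numeric(length(mz))
    else shift_field(mz, pr$spec_mz, pr$ref_mz, field_cap)
  })
  if (centre) {
    mean_field <- Reduce(`+`, fields) / length(fields)
    fields <- lapply(fields, `-`, mean_field)
  }
  list(fields = fields,
       matched = vapply(pairs, function(pr)
         if (is.null(pr)) 0L else length(pr$spec_mz), integer(1)),
       landmarks = vapply(pairs, function(pr)
         if (is.null(pr)) 0L else pr$n_landmarks, integer(1)))
}

#' TIC quality-control filter
#'
#' Excludes spectra whose in-range total ion current deviates from the
#' cohort mean by more than `threshold_sd` standard deviations. Mean and SD
#' are computed within each chip x laser condition, since the TIC scale
#' differs across acquisition conditions.
#'
#' @param spectra list of [ms_spectrum()] (>= 3).
#' @param threshold_sd exclusion threshold in SD units.
#' @param tic_range Daltons over which ion current is summed.
#' @return list with `kept`, `excluded` (spectra lists) and `report`
#'   (data frame: patient, replicate, condition, tic, z, excluded).
#' @export
qc_filter <- function(spectra, threshold_sd = 2, tic_range = c(1500, 16500)) {
  if (length(spectra) < 3L) stop("qc_filter needs at least 3 spectra")
  tic <- vapply(spectra, in_range_tic, numeric(1), tic_range = tic_range)
  cond <- vapply(spectra, function(s) paste(s$meta$chip, s$meta$laser, sep = "/"),
                 character(1))
  z <- numeric(length(tic))
  for (cd in unique(cond)) {
    i <- cond == cd
    mu <- mean(tic[i]); sd_ <- stats::sd(tic[i])
    z[i] <- if (is.na(sd_) || sd_ == 0) 0 else (tic[i] - mu) / sd_
  }
  out <- abs(z) > threshold_sd
  report <- data.frame(
    patient = vapply(spectra, function(s) s$meta$patient_id, character(1)),
    replicate = vapply(spectra, function(s) s$meta$replicate, integer(1)),
    condition = cond, tic = tic, z = z, excluded = out)
  list(kept = spectra[!out], excluded = spectra[out], report = report)
}

#' Average replicate spectra into one profile per patient
#'
#' Replicates must share a common (post-alignment) axis; the result is the
#' pointwise mean intensity per patient.
#'
#' @param spectra list of [ms_spectrum()].
#' @return Named list of per-patient mean [ms_spectrum()] objects.
#' @export
average_replicates <- function(spectra) {
  if (!length(spectra)) stop("no spectra to average")
  mz0 <- spectra[[1L]]$mz
  ok <- vapply(spectra, function(s)
    length(s$mz) == length(mz0) && max(abs(s$mz - mz0)) < 1e-9, logical(1))
  if (!all(ok)) stop("replicates are not on a common axis; align first")
  ids <- vapply(spectra, function(s) s$meta$patient_id, character(1))
  out <- lapply(split(seq_along(spectra), ids), function(idx) {
    mean_int <- Reduce(`+`, lapply(spectra[idx], `[[`, "intensity")) / length(idx)
    s <- spectra[[idx[1L]]]
    s$intensity <- mean_int
    s$meta$replicate <- NA_integer_
    add_provenance(s, "average_replicates", list(n_replicates = length(idx)))
  })
  out[unique(ids)]
}

#' Run the full preprocessing chain on a cohort
#'
#' Applies, in fixed order: cube-root variance stabilization, moving-window
#' baseline subtraction, the TIC quality-control rule, total ion current
#' normalization to the cohort mean in-range TIC (or a fixed target),
#' Gaussian smoothing, dynamic-programming alignment, and replicate
#' averaging. Provenance on every returned profile records the steps in the
#' order applied.
#'
#' @param spectra list of raw [ms_spectrum()] objects.
#' @param config a [preprocess_config()].
#' @return list with `profiles` (named list, one mean spectrum per patient),
#'   `qc` (the QC report data frame), and `n_excluded`.
#' @export
preprocess_cohort <- function(spectra, config = preprocess_config()) {
  stopifnot(inherits(config, "preprocess_config"))
  spectra <- lapply(spectra, stabilize_variance)
  spectra <- lapply(spectra, correct_baseline, window = config$baseline_window)
  qc <- qc_filter(spectra, threshold_sd = config$qc_sd_threshold,
                  tic_range = config$tic_range)
  spectra <- qc$kept
  if (!length(spectra)) stop("all spectra excluded by TIC QC")
  target <- if (identical(config$tic_target, "cohort_mean")) {
    mean(vapply(spectra, in_range_tic, numeric(1), tic_range = config$tic_range))
  } else config$tic_target
  spectra <- lapply(spectra, normalize_tic, tic_range = config$tic_range,
                    target = target)
  spectra <- lapply(spectra, smooth_spectrum, bandwidth = config$smooth_bandwidth)
  spectra <- align_spectra(spectra, config)
  list(profiles = average_replicates(spectra), qc = qc$report,
       n_excluded = sum(qc$report$excluded))
}
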