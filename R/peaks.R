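# Two-stage peak selection: peak positions are identified on the mean
# profile of the (training) cohort, then every profile is reduced to
# intensities at those shared positions.

#' Identify peak positions on a mean profile
#'
#' A tick is a peak iff its intensity is strictly maximal within
#' `+/- window` ticks and exceeds `min_prominence` above the local median.
#' Averaging profiles before detection keeps peaks that are missing from a
#' few profiles while averaging out single-profile noise. Positions are
#' restricted to `mass_window` (default 1,500-40,000 Da, the less noisy
#' portion of the spectrum).
#'
#' When used inside resampling validation, the mean profile must be computed
#' over training profiles only; see [evaluate()].
#'
#' @param mean_profile an [ms_spectrum()] (typically the cohort mean) or a
#'   numeric intensity vector accompanied by `mz`.
#' @param window half-width (ticks) of the local-max neighbourhood.
#' @param min_prominence required excess over the local median; default
#'   3 x MAD of the detrended signal (scale-free).
#' @param mass_window Daltons (low, high) to which peaks are restricted.
#' @param mz m/z axis, required when `mean_profile` is a bare vector.
#' @return data frame with columns `tick`, `mz`, `intensity`, `prominence`.
#' @export
identify_peaks <- function(mean_profile, window = 5L, min_prominence = NULL,
                           mass_window = c(1500, 40000), mz = NULL) {
  if (inherits(mean_profile, "ms_spectrum")) {
    y <- mean_profile$intensity
    mz <- mean_profile$mz
  } else {
    y <- as.numeric(mean_profile)
    if (is.null(mz)) stop("mz axis required for a bare intensity vector")
  }
  if (mass_window[1] >= mass_window[2]) stop("empty mass window")
  window <- as.integer(window)
  stopifnot(window >= 1L)
  w <- 2L * window + 1L
  med_w <- 16L * window + 1L
  med <- local_median(y, med_w + (med_w %% 2L == 0L))
  det <- y - med
  if (is.null(min_prominence)) {
    # local MAD of the detrended signal: the variance-stabilized noise floor
    # still varies along the axis (it blows up where the raw signal is near
    # zero), so a global scale either over- or under-calls by mass region
    scale_local <- 1.4826 * local_median(abs(det), 16L * med_w + 1L)
    s <- stats::mad(det)
    if (!is.finite(s) || s == 0) s <- stats::sd(det)
    # the 2%-of-largest-prominence term is a dynamic-range floor: residual
    # wiggles far below the spectrum's peaks are not called even where the
    # local noise estimate is minute
    min_prominence <- pmax(3 * pmax(scale_local, 0.05 * s),
                           0.02 * max(det))
  }
  wmax <- running_max(y, w)
  cand <- which(y == wmax & det > min_prominence &
                  mz >= mass_window[1] & mz <= mass_window[2])
  keep <- vapply(cand, function(i) {
    lo <- max(1L, i - window); hi <- min(length(y), i + window)
    sum(y[lo:hi] == y[i]) == 1L
  }, logical(1))
  cand <- cand[keep]
  data.frame(tick = cand, mz = mz[cand], intensity = y[cand],
             prominence = det[cand])
}

#' Assign per-profile intensities at shared peak positions
#'
#' The intensity of a peak in a profile is the mean of that profile's
#' readings within `+/- radius` ticks of the peak position, which damps the
#' effect of a noisy reading at a single m/z position.
#'
#' @param profiles named list of [ms_spectrum()] objects on a common axis
#'   (one per patient).
#' @param peak_ticks integer tick positions of the peaks.
#' @param radius neighbourhood half-width in ticks (`0` = exact reading).
#' @param peak_mz optional m/z positions used to name columns.
#' @return A `peak_table`: list with `peak_mz`, `intensities`
#'   (patients x peaks matrix), and `radius`.
#' @export
assign_intensities <- function(profiles, peak_ticks, radius = 4L,
                               peak_mz = NULL) {
  stopifnot(length(profiles) >= 1L, radius >= 0L)
  n_tick <- length(profiles[[1L]]$intensity)
  if (any(peak_ticks < 1L | peak_ticks > n_tick))
    stop("peak position outside the profile axis")
  if (is.null(peak_mz)) peak_mz <- profiles[[1L]]$mz[peak_ticks]
  ids <- unname(vapply(profiles, function(s) s$meta$patient_id, character(1)))
  Y <- do.call(rbind, lapply(profiles, `[[`, "intensity"))
  M <- matrix(NA_real_, nrow(Y), length(peak_ticks),
              dimnames = list(ids, sprintf("mz_%.1f", peak_mz)))
  for (k in seq_along(peak_ticks)) {
    lo <- max(1L, peak_ticks[k] - radius)
    hi <- min(n_tick, peak_ticks[k] + radius)
    M[, k] <- if (hi > lo) rowMeans(Y[, lo:hi, drop = FALSE]) else Y[, lo]
  }
  if (any(!is.finite(M))) stop("non-finite peak intensity encountered")
  structure(list(peak_mz = peak_mz, intensities = M, radius = radius),
            class = "peak_table")
}

#' Two-stage peak calling on a set of profiles
#'
#' Convenience wrapper: averages the given profiles, identifies peak
#' positions on the mean ([identify_peaks()]), and assigns neighbourhood-mean
#' intensities to every profile ([assign_intensities()]). When called inside
#' resampling validation, pass training profiles via `identify_on` and all
#' profiles via `profiles` so test data never influences peak positions.
#'
#' @param profiles named list of per-patient profiles to quantify.
#' @param window,min_prominence,mass_window see [identify_peaks()].
#' @param radius neighbourhood half-width; defaults to `window`.
#' @param identify_on optional subset of profiles used for peak
#'   identification (defaults to `profiles`).
#' @return A `peak_table`.
#' @export
call_peaks <- function(profiles, window = 5L, min_prominence = NULL,
                       mass_window = c(1500, 40000), radius = NULL,
                       identify_on = NULL) {
  if (is.null(radius)) radius <- window
  idp <- identify_on %||% profiles
  mean_int <- Reduce(`+`, lapply(idp, `[[`, "intensity")) / length(idp)
  pk <- identify_peaks(mean_int, window = window,
                       min_prominence = min_prominence,
                       mass_window = mass_window, mz = idp[[1L]]$mz)
  if (!nrow(pk)) stop("no peaks identified")
  assign_intensities(profiles, pk$tick, radius = radius, peak_mz = pk$mz)
}

#' @export
print.peak_table <- function(x, ...) {
  cat(sprintf("<peak_table> %d patients x %d peaks (m/z %.0f-%.0f Da, radius %d)\n",
              nrow(x$intensities), length(x$peak_mz), min(x$peak_mz),
              max(x$peak_mz), x$radius))
  invisible(x)
}
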