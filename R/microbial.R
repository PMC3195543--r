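# Checkerboard DNA-DNA hybridization: spot-signal tables and their
# conversion to universal-probe-normalized abundances. Image quantification
# is upstream of this package; input starts from background-subtracted spot
# signal values.

#' Construct a spot-signal table
#'
#' Samples x probes background-subtracted signal values from a checkerboard
#' membrane, with the universal-probe standard lanes flagged and a
#' per-spot quality flag (`TRUE` = usable).
#'
#' @param signal numeric matrix (samples x probes), non-negative, with
#'   sample ids as rownames and probe names as colnames.
#' @param universal character vector of universal-probe column names
#'   (standard lanes); at least one, all present in `colnames(signal)`.
#' @param quality logical matrix of the same shape (`TRUE` = good spot);
#'   defaults to all good.
#' @param labels optional named class labels per sample.
#' @return A `spot_signal_table`.
#' @export
spot_signal_table <- function(signal, universal, quality = NULL, labels = NULL) {
  signal <- as.matrix(signal)
  if (is.null(rownames(signal)) || is.null(colnames(signal)))
    stop("signal must carry sample rownames and probe colnames")
  if (any(!is.finite(signal)) || any(signal < 0, na.rm = TRUE))
    stop("signals must be finite and non-negative")
  if (!length(universal) || !all(universal %in% colnames(signal)))
    stop("universal probes must name columns of signal")
  if (is.null(quality)) {
    quality <- matrix(TRUE, nrow(signal), ncol(signal), dimnames = dimnames(signal))
  } else {
    quality <- as.matrix(quality)
    stopifnot(identical(dim(quality), dim(signal)))
  }
  if (!is.null(labels)) {
    labels <- labels[rownames(signal)]
    if (anyNA(labels)) stop("labels must cover every sample")
  }
  structure(list(signal = signal, universal = universal, quality = quality,
                 labels = labels, dropped = character(0)),
            class = "spot_signal_table")
}

#' @export
print.spot_signal_table <- function(x, ...) {
  cat(sprintf("<spot_signal_table> %d samples x %d probes (%d universal), %d flagged spots\n",
              nrow(x$signal), ncol(x$signal), length(x$universal),
              sum(!x$quality, na.rm = TRUE) + sum(is.na(x$signal))))
  invisible(x)
}

#' Mask low-quality spots and drop unusable samples
#'
#' Flagged spots are set to missing; samples whose fraction of missing
#' taxon spots exceeds `max_missing` are dropped and listed in the returned
#' table's `$dropped`.
#'
#' @param t a [spot_signal_table()].
#' @param max_missing maximal tolerated fraction of missing taxon spots per
#'   sample.
#' @return A filtered `spot_signal_table`.
#' @export
filter_spots <- function(t, max_missing = 0.5) {
  stopifnot(inherits(t, "spot_signal_table"))
  sig <- t$signal
  sig[!t$quality] <- NA_real_
  taxa_cols <- setdiff(colnames(sig), t$universal)
  frac_missing <- rowMeans(is.na(sig[, taxa_cols, drop = FALSE]))
  drop <- rownames(sig)[frac_missing > max_missing]
  keep <- setdiff(rownames(sig), drop)
  if (!length(keep)) stop("all samples dropped by spot quality filter")
  out <- t
  out$signal <- sig[keep, , drop = FALSE]
  out$quality <- t$quality[keep, , drop = FALSE]
  out$labels <- if (!is.null(t$labels)) t$labels[keep] else NULL
  out$dropped <- c(t$dropped, drop)
  out
}

#' Convert spot signals to normalized abundances
#'
#' Each sample's taxon signals are put on a common mean-count scale by
#' comparison with that sample's universal-probe standards:
#' `abundance = signal * standard_count / mean(universal signals)`. The
#' universal lanes carry the per-sample DNA amount, so the ratio removes it
#' and abundances become comparable across samples. Missing (quality
#' filtered) spots are imputed as 0, i.e. treated as undetected taxa.
#'
#' @param t a [spot_signal_table()] (typically after [filter_spots()]).
#' @param standard_count mean-count value assigned to the universal standard
#'   signal; a pure unit choice.
#' @return An `abundance_table`: list with `abundance` (samples x taxa
#'   matrix), `taxa`, and `labels`.
#' @export
to_abundance <- function(t, standard_count = 100) {
  stopifnot(inherits(t, "spot_signal_table"), standard_count > 0)
  taxa_cols <- setdiff(colnames(t$signal), t$universal)
  uni <- t$signal[, t$universal, drop = FALSE]
  u <- rowMeans(uni, na.rm = TRUE)
  bad <- !is.finite(u) | u <= 0
  if (any(bad))
    stop("degenerate universal standard for sample(s): ",
         paste(rownames(t$signal)[bad], collapse = ", "))
  ab <- t$signal[, taxa_cols, drop = FALSE] * (standard_count / u)
  ab[is.na(ab)] <- 0
  structure(list(abundance = ab, taxa = taxa_cols, labels = t$labels,
                 standard_count = standard_count, dropped = t$dropped),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("<abundance_table> %d samples x %d taxa (standard_count = %g)\n",
              nrow(x$abundance), length(x$taxa), x$standard_count))
  invisible(x)
}
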