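#' Construct a mass spectrum object
#'
#' A single replicate's linear-TOF trace: integer clock ticks, a strictly
#' increasing m/z axis (Daltons), non-negative intensities, and acquisition
#' metadata. Preprocessing steps return the same structure with the applied
#' step appended to `provenance`, so the full processing history of any
#' spectrum can always be audited.
#'
#' @param tick integer clock indices (monotone increasing).
#' @param mz m/z axis in Daltons, strictly increasing, same length as `tick`.
#' @param intensity intensities (arbitrary units), same length as `mz`.
#' @param patient_id subject identifier.
#' @param label class label (`"case"` = caries-active, `"control"` =
#'   caries-free), or `NA` when unknown.
#' @param chip affinity chip tag (e.g. `"CM10"`, `"Q10"`).
#' @param laser laser intensity tag (`"low"` or `"high"`).
#' @param replicate replicate number within subject/condition.
#' @return An object of class `ms_spectrum`: a list with elements `tick`,
#'   `mz`, `intensity`, `meta`, and `provenance` (list of applied steps).
#' @export
ms_spectrum <- function(tick, mz, intensity, patient_id,
                        label = NA_character_, chip = "CM10", laser = "low",
                        replicate = 1L) {
  tick <- as.integer(tick)
  mz <- as.numeric(mz)
  intensity <- as.numeric(intensity)
  if (length(mz) != length(intensity) || length(mz) != length(tick))
    stop("tick, mz and intensity must have equal length")
  if (any(diff(mz) <= 0)) stop("mz axis must be strictly increasing")
  structure(
    list(
      tick = tick, mz = mz, intensity = intensity,
      meta = list(patient_id = as.character(patient_id),
                  label = as.character(label),
                  chip = chip, laser = laser,
                  replicate = as.integer(replicate)),
      provenance = list()
    ),
    class = "ms_spectrum"
  )
}

add_provenance <- function(s, step, params = list()) {
  s$provenance[[length(s$provenance) + 1L]] <- list(step = step, params = params)
  s
}

#' @export
print.ms_spectrum <- function(x, ...) {
  cat(sprintf(
    "<ms_spectrum> patient %s (%s) %s/%s rep %d: %d points, m/z %.0f-%.0f Da\n",
    x$meta$patient_id, x$meta$label, x$meta$chip, x$meta$laser,
    x$meta$replicate, length(x$mz), min(x$mz), max(x$mz)))
  if (length(x$provenance))
    cat("  steps:", paste(vapply(x$provenance, `[[`, "", "step"), collapse = " -> "), "\n")
  invisible(x)
}

provenance_steps <- function(s) vapply(s$provenance, `[[`, "", "step")

# Read/write spectra as plain TSV (tick, mz, intensity), metadata in the
# filename-independent header comment lines.
#' Write a spectrum to a TSV file
#'
#' Columns `tick`, `mz`, `intensity`; metadata stored in `#key value` header
#' lines so a round trip preserves the object.
#'
#' @param s an `ms_spectrum`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_spectrum_tsv <- function(s, path) {
  con <- file(path, "w")
  on.exit(close(con))
  m <- s$meta
  writeLines(sprintf("#%s\t%s", c("patient_id", "label", "chip", "laser", "replicate"),
                     c(m$patient_id, m$label, m$chip, m$laser, m$replicate)), con)
  writeLines("tick\tmz\tintensity", con)
  utils::write.table(data.frame(s$tick, s$mz, s$intensity), con, sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a spectrum written by [write_spectrum_tsv()]
#'
#' @param path file path.
#' @return An `ms_spectrum`.
#' @export
read_spectrum_tsv <- function(path) {
  lines <- readLines(path, n = 20L)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- do.call(rbind, strsplit(sub("^#", "", hdr), "\t"))
  meta <- stats::setNames(kv[, 2L], kv[, 1L])
  d <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  ms_spectrum(d$tick, d$mz, d$intensity,
              patient_id = meta[["patient_id"]], label = meta[["label"]],
              chip = meta[["chip"]], laser = meta[["laser"]],
              replicate = as.integer(meta[["replicate"]]))
}
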