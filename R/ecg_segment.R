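#' ECG segment
#'
#' Container for a uniformly sampled single-channel ECG (or CPR-artifact)
#' amplitude series. This is the currency of the whole pipeline: every
#' generator, filter and metric consumes and returns `ecg_segment` objects.
#'
#' @param samples Numeric vector of amplitudes (mV-equivalent, arbitrary
#'   linear scale). All values must be finite.
#' @param fs Sampling rate in Hz (> 0).
#' @param label Optional rhythm class, one of `"nsr"`,
#'   `"other_nonshockable"`, `"vf"`, `"rapid_vt"`, `"asystole"`,
#'   `"cpr_artifact"`, `"unknown"`.
#' @param subject_id Optional subject/record identifier.
#'
#' @return An object of class `ecg_segment`: a list with elements
#'   `samples`, `fs`, `label`, `subject_id`.
#' @examples
#' seg <- ecg_segment(sin(2 * pi * 5 * seq(0, 14, by = 1 / 125)), fs = 125)
#' duration(seg)
#' @export
ecg_segment <- function(samples, fs, label = NULL, subject_id = NULL) {
  samples <- as.numeric(samples)
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("'fs' must be a single finite number > 0")
  }
  if (length(samples) && any(!is.finite(samples))) {
    stop("all samples must be finite")
  }
  if (!is.null(label)) {
    label <- match.arg(label, rhythm_labels())
  }
  structure(
    list(samples = samples, fs = as.numeric(fs), label = label,
         subject_id = subject_id),
    class = "ecg_segment"
  )
}

rhythm_labels <- function() {
  c("nsr", "other_nonshockable", "vf", "rapid_vt", "asystole",
    "cpr_artifact", "unknown")
}

#' @export
is_ecg_segment <- function(x) inherits(x, "ecg_segment")

#' Duration of an ECG segment in seconds
#' @param x An `ecg_segment`.
#' @return Length / sampling rate, in seconds.
#' @export
duration <- function(x) {
  stopifnot(is_ecg_segment(x))
  length(x$samples) / x$fs
}

#' @export
length.ecg_segment <- function(x) length(x$samples)

#' @export
print.ecg_segment <- function(x, ...) {
  cat(sprintf("<ecg_segment> %d samples @ %g Hz (%.2f s)",
              length(x$samples), x$fs, duration(x)))
  if (!is.null(x$label)) cat(sprintf("  label=%s", x$label))
  if (!is.null(x$subject_id)) cat(sprintf("  subject=%s", x$subject_id))
  cat("\n")
  invisible(x)
}

# Internal: replace samples, keeping metadata.
set_samples <- function(x, samples) {
  x$samples <- as.numeric(samples)
  x
}

#' Collection of ECG segments with a provenance manifest
#'
#' An ordered list of [ecg_segment()] objects plus a manifest data frame
#' recording where each entry came from (`subject_id`, `artifact_id`,
#' `snr_db`, `label`). Used to hold clean rhythm pools, artifact pools and
#' the corrupted cross-product datasets built by [build_dataset()].
#'
#' @param segments List of `ecg_segment` objects.
#' @param manifest Optional data frame with one row per segment and at
#'   least the columns `subject_id`, `artifact_id`, `snr_db`. If omitted,
#'   a manifest is derived from the segments (artifact/snr set to `NA`).
#' @return An object of class `segment_collection`.
#' @export
segment_collection <- function(segments, manifest = NULL) {
  if (!is.list(segments) || !all(vapply(segments, is_ecg_segment, logical(1)))) {
    stop("'segments' must be a list of ecg_segment objects")
  }
  if (is.null(manifest)) {
    manifest <- data.frame(
      subject_id = vapply(seq_along(segments), function(i) {
        sid <- segments[[i]]$subject_id
        if (is.null(sid)) sprintf("seg%03d", i) else as.character(sid)
      }, character(1)),
      artifact_id = NA_character_,
      snr_db = NA_real_,
      label = vapply(segments, function(s) {
        if (is.null(s$label)) NA_character_ else s$label
      }, character(1)),
      stringsAsFactors = FALSE
    )
  }
  if (nrow(manifest) != length(segments)) {
    stop("manifest must have one row per segment")
  }
  key <- paste(manifest$subject_id, manifest$artifact_id, manifest$snr_db)
  if (anyDuplicated(key)) {
    stop("(subject_id, artifact_id, snr_db) triples must be unique")
  }
  structure(list(segments = segments, manifest = manifest),
            class = "segment_collection")
}

#' @export
length.segment_collection <- function(x) length(x$segments)

#' @export
`[[.segment_collection` <- function(x, i) x$segments[[i]]

#' @export
print.segment_collection <- function(x, ...) {
  cat(sprintf("<segment_collection> %d segments\n", length(x$segments)))
  if (nrow(x$manifest)) {
    print(utils::head(x$manifest, 5))
    if (nrow(x$manifest) > 5) cat(sprintf("... %d more rows\n", nrow(x$manifest) - 5))
  }
  invisible(x)
}
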