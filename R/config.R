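#' Load a run configuration from a YAML file
#'
#' A single file configures every stage. Recognized top-level keys:
#' `preprocess` (fields of [preprocess_config()]), `filter` (fields of
#' [filter_config()] other than `preprocess`), `welch`
#' (`window_s`, `overlap`), `peaks` (`band`, `min_separation`),
#' `harmonic` (`rel_tol`), `evaluation` (`corr_band`), `seed`,
#' `log_level`. Unknown keys (at top level or within a section) are
#' rejected.
#'
#' @param path Path to the YAML file; `NULL` returns the defaults.
#' @return A list with elements `filter` (a [filter_config()] with the
#'   embedded [preprocess_config()]), `evaluation`, `seed`, `log_level`.
#' @export
load_run_config <- function(path = NULL) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  known <- c("preprocess", "filter", "welch", "peaks", "harmonic",
             "evaluation", "seed", "log_level")
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("unknown configuration keys: ", paste(bad, collapse = ", "))
  take <- function(section, allowed) {
    sec <- raw[[section]]
    if (is.null(sec)) return(list())
    extra <- setdiff(names(sec), allowed)
    if (length(extra)) {
      stop(sprintf("unknown keys in '%s': %s", section,
                   paste(extra, collapse = ", ")))
    }
    sec
  }
  pp <- do.call(preprocess_config,
                take("preprocess", c("notch_freq", "notch_q", "wavelet_name",
                                     "decomposition_levels", "smoothing_window")))
  fl <- take("filter", c("power_threshold", "cc_band", "shockable_band",
                         "low_fundamental_cut", "stopband_halfwidth",
                         "power_band", "amplitude_normalization",
                         "strict_end_after_cond2", "recompute_peaks"))
  we <- take("welch", c("window_s", "overlap"))
  if (!is.null(we$window_s)) fl$welch_window_s <- we$window_s
  if (!is.null(we$overlap)) fl$welch_overlap <- we$overlap
  pk <- take("peaks", c("band", "min_separation"))
  if (!is.null(pk$band)) fl$peak_band <- unlist(pk$band)
  if (!is.null(pk$min_separation)) fl$min_peak_separation <- pk$min_separation
  hm <- take("harmonic", c("rel_tol", "max_order"))
  if (!is.null(hm$rel_tol)) fl$harmonic_rel_tol <- hm$rel_tol
  if (!is.null(hm$max_order)) fl$max_harmonic_order <- hm$max_order
  if (!is.null(fl$cc_band)) fl$cc_band <- unlist(fl$cc_band)
  if (!is.null(fl$shockable_band)) fl$shockable_band <- unlist(fl$shockable_band)
  if (!is.null(fl$power_band)) fl$power_band <- unlist(fl$power_band)
  fl$preprocess <- pp
  ev <- take("evaluation", c("corr_band"))
  list(filter = do.call(filter_config, fl),
       evaluation = list(corr_band = if (is.null(ev$corr_band)) c(0.5, 30)
                         else unlist(ev$corr_band)),
       seed = if (is.null(raw$seed)) NULL else as.integer(raw$seed),
       log_level = if (is.null(raw$log_level)) "info" else raw$log_level)
}

#' Serialize a condition trace to JSON
#'
#' @param trace A `condition_trace` (see [condition_trace()]).
#' @param path Optional output path; when omitted the JSON string is
#'   returned.
#' @return The JSON string, invisibly when written to a file.
#' @export
trace_to_json <- function(trace, path = NULL) {
  stopifnot(inherits(trace, "condition_trace"))
  obj <- unclass(trace)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null",
                         na = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

# Derive a stable 31-bit sub-seed from a global seed and a task tag.
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}
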