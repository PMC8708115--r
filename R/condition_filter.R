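#' Configuration for the condition-based CPR filter
#'
#' Collects every tunable of the suppression algorithm. The defaults are
#' the working values of the method: compression fundamentals live in
#' 1-3 Hz, shockable-rhythm dynamics in 3-6 Hz, the 10-15 Hz band power
#' (computed on the unit-variance normalized signal after the first
#' stop-band) discriminates non-shockable from shockable rhythms at a
#' threshold of 0.07, and a fundamental below 1.5 Hz keeps its first
#' harmonic safely below the shockable band.
#'
#' @param power_threshold 10-15 Hz band-power threshold (default 0.07,
#'   on the unit-std normalized scale; recalibrate with
#'   [calibrate_threshold()] for other normalizations).
#' @param cc_band Compression-fundamental search band, Hz (default `c(1, 3)`).
#' @param shockable_band Band holding shockable-rhythm dynamics, Hz
#'   (default `c(3, 6)`).
#' @param low_fundamental_cut Fundamental below which the first harmonic
#'   is always removable, Hz (default 1.5).
#' @param stopband_halfwidth Half-width of each stop-band, Hz (default 0.5).
#' @param power_band Band used for the threshold test, Hz (default `c(10, 15)`).
#' @param amplitude_normalization `"unit_std"` (normalize to unit standard
#'   deviation before spectral analysis, the default) or `"none"`.
#' @param welch_window_s,welch_overlap Welch PSD parameters (default 4 s,
#'   0.5).
#' @param peak_band Peak search band, Hz (default `c(0.5, 30)`).
#' @param min_peak_separation Minimum peak spacing, Hz (default 0.5).
#' @param harmonic_rel_tol Relative tolerance of the divisibility test
#'   (default 0.08).
#' @param max_harmonic_order Highest compression-harmonic order ever
#'   targeted by a stop-band (default 3; higher harmonics carry
#'   negligible power and are left alone).
#' @param strict_end_after_cond2 If `TRUE`, a declined second stop-band
#'   ends the run; if `FALSE` (default) the third condition is still
#'   evaluated (it can then only fire via a low fundamental, whose doubled
#'   frequency stays below the shockable band).
#' @param recompute_peaks If `TRUE`, peaks are re-estimated on the signal
#'   after the first stop-band before the divisibility test; default
#'   `FALSE` (the original peak set is reused).
#' @param preprocess A [preprocess_config()].
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(power_threshold = 0.07,
                          cc_band = c(1, 3),
                          shockable_band = c(3, 6),
                          low_fundamental_cut = 1.5,
                          stopband_halfwidth = 0.5,
                          power_band = c(10, 15),
                          amplitude_normalization = c("unit_std", "none"),
                          welch_window_s = 4,
                          welch_overlap = 0.5,
                          peak_band = c(0.5, 30),
                          min_peak_separation = 0.5,
                          harmonic_rel_tol = 0.08,
                          max_harmonic_order = 3,
                          strict_end_after_cond2 = FALSE,
                          recompute_peaks = FALSE,
                          preprocess = preprocess_config()) {
  amplitude_normalization <- match.arg(amplitude_normalization)
  if (power_threshold <= 0) stop("power_threshold must be > 0")
  if (cc_band[2] > shockable_band[1] + 1e-9 && cc_band[2] != shockable_band[1]) {
    stop("cc_band must end at or below the start of shockable_band")
  }
  if (stopband_halfwidth <= 0 || stopband_halfwidth >= cc_band[1]) {
    stop("stopband_halfwidth must be in (0, cc_band lower edge)")
  }
  structure(list(power_threshold = power_threshold, cc_band = cc_band,
                 shockable_band = shockable_band,
                 low_fundamental_cut = low_fundamental_cut,
                 stopband_halfwidth = stopband_halfwidth,
                 power_band = power_band,
                 amplitude_normalization = amplitude_normalization,
                 welch_window_s = welch_window_s,
                 welch_overlap = welch_overlap,
                 peak_band = peak_band,
                 min_peak_separation = min_peak_separation,
                 harmonic_rel_tol = harmonic_rel_tol,
                 max_harmonic_order = max_harmonic_order,
                 strict_end_after_cond2 = strict_end_after_cond2,
                 recompute_peaks = recompute_peaks,
                 preprocess = preprocess),
            class = "filter_config")
}

#' Design a narrow stop-band filter
#'
#' Second-order Butterworth band-stop centred on the target frequency.
#' Applied forward-backward the attenuation at the centre exceeds 30 dB
#' while the gain stays within 1 dB outside three half-widths of the
#' centre. The cutoffs are not fixed: the condition-based algorithm
#' re-designs its stop-bands around the compression fundamental and
#' harmonics detected in each segment.
#'
#' @param center Centre frequency in Hz.
#' @param halfwidth Half-width in Hz (stop band is `center +/- halfwidth`).
#' @param fs Sampling rate in Hz.
#' @return A list with `b`, `a` coefficient vectors and the design
#'   parameters.
#' @export
design_stopband <- function(center, halfwidth, fs) {
  lo <- center - halfwidth
  hi <- center + halfwidth
  if (lo <= 0 || hi >= fs / 2) {
    stop(sprintf("stop band (%g, %g) Hz must lie strictly inside (0, %g) Hz",
                 lo, hi, fs / 2))
  }
  bt <- signal::butter(2, c(lo, hi) * 2 / fs, type = "stop")
  if (any(Mod(polyroot(rev(bt$a))) >= 1)) {
    stop("unstable stop-band design at center ", center, " Hz")
  }
  list(b = bt$b, a = bt$a, center = center, halfwidth = halfwidth, fs = fs)
}

apply_stopband <- function(x, sb) {
  signal::filtfilt(sb$b, sb$a, x)
}

# Pure decision logic of the three conditions (steps after the first
# stop-band). Inputs are the detected quantities; output says which of
# stop-bands 2 and 3 fire. Factored out so the 2^3 truth table can be
# checked directly.
condition_decision <- function(noise_comp1, noise_comp2, band_power_10_15,
                               cfg = filter_config()) {
  fire2 <- FALSE
  fire3 <- FALSE
  path <- character(0)
  above <- band_power_10_15 >= cfg$power_threshold
  if (!is.na(noise_comp2)) {
    in_shock <- noise_comp2 >= cfg$shockable_band[1] &&
      noise_comp2 <= cfg$shockable_band[2]
    fire2 <- !in_shock || above
    path <- c(path, sprintf(
      "condition2: noise_comp2=%.3g %s shockable band, band power %s threshold -> stop-band 2 %s",
      noise_comp2, if (in_shock) "inside" else "outside",
      if (above) ">=" else "<", if (fire2) "ON" else "off"))
    if (fire2 || cfg$strict_end_after_cond2) {
      return(list(fire2 = fire2, fire3 = FALSE, path = path))
    }
  } else {
    path <- c(path, "condition1: no remaining peak divisible by noise_comp1")
  }
  low <- noise_comp1 < cfg$low_fundamental_cut
  fire3 <- above || low
  path <- c(path, sprintf(
    "condition3: band power %s threshold, noise_comp1 %s %g Hz -> stop-band 3 %s",
    if (above) ">=" else "<", if (low) "<" else ">=",
    cfg$low_fundamental_cut, if (fire3) "ON" else "off"))
  list(fire2 = fire2, fire3 = fire3, path = path)
}

#' Suppress CPR chest-compression artifacts in an ECG segment
#'
#' The condition-based suppression algorithm. The segment is conditioned
#' ([preprocess_ecg()]), its Welch PSD is estimated and the three largest
#' peaks are located. A peak inside the 1-3 Hz band is taken as the
#' compression fundamental (Noise-comp1) and always removed with the
#' first stop-band. The 10-15 Hz band power of the filtered signal then
#' gates the removal of a harmonic: a remaining peak divisible by the
#' fundamental (Noise-comp2) is removed when it lies outside the 3-6 Hz
#' shockable band or when the band power clears the threshold (the
#' segment then behaves like a broadband non-shockable rhythm); otherwise
#' a third stop-band at twice the fundamental fires only when the band
#' power clears the threshold or the fundamental is below 1.5 Hz, so the
#' dynamics of shockable rhythms are never carved out.
#'
#' @param segment An [ecg_segment()] of at least 8 s, nominally sampled at
#'   125 Hz (resample first with [resample_ecg()] otherwise).
#' @param config A [filter_config()].
#' @return An object of class `cpr_suppress` with elements `input`,
#'   `preprocessed`, `filtered` (all [ecg_segment()]s), `trace` (a
#'   `condition_trace` recording Noise-comp1/2, the 10-15 Hz band power
#'   and which stop-bands fired), `peaks`, `psd_pre`, `psd_post` and
#'   `config`. Methods: [print()], [summary()], [plot()], [residuals()].
#' @examples
#' clean <- gen_rhythm("nsr", seed = 1)
#' art <- gen_cpr_artifact(fundamental_hz = 2.2, seed = 2)
#' fit <- suppress_cpr(mix_cpr(clean, art, snr_db = -3))
#' fit
#' @export
suppress_cpr <- function(segment, config = filter_config()) {
  stopifnot(is_ecg_segment(segment))
  if (duration(segment) < 8) {
    stop(sprintf("segment is %.2f s; at least 8 s are required", duration(segment)))
  }
  cfg <- config
  pre <- preprocess_ecg(segment, cfg$preprocess)
  s <- stats::sd(pre$samples)
  norm <- if (cfg$amplitude_normalization == "unit_std" && s > 0) 1 / s else 1
  xn <- pre$samples * norm

  empty_trace <- function(path, psd_pre = NULL, peaks = NULL) {
    trace <- structure(list(
      noise_comp1 = NA_real_, noise_comp2 = NA_real_,
      band_power_10_15 = NA_real_,
      stopband1_fired = FALSE, stopband2_fired = FALSE,
      stopband3_fired = FALSE, cutoffs = numeric(0),
      decision_path = path, threshold = cfg$power_threshold),
      class = "condition_trace")
    structure(list(input = segment, preprocessed = pre, filtered = pre,
                   trace = trace, peaks = peaks, psd_pre = psd_pre,
                   psd_post = NULL, config = cfg),
              class = "cpr_suppress")
  }

  flat_tol <- 1e-6 * (stats::sd(segment$samples) + mean(abs(segment$samples)))
  if (s == 0 || s < flat_tol) {
    return(empty_trace("flat segment: no spectral analysis possible"))
  }
  psd_pre <- welch_psd(set_samples(pre, xn), cfg$welch_window_s, cfg$welch_overlap)
  peaks <- top_peaks(psd_pre, k = 3, search_band = cfg$peak_band,
                     min_separation = cfg$min_peak_separation)
  nc1 <- find_fundamental(peaks, cfg$cc_band)
  if (is.na(nc1)) {
    return(empty_trace(
      sprintf("no PSD peak inside (%g-%g) Hz: no compression fundamental detected",
              cfg$cc_band[1], cfg$cc_band[2]),
      psd_pre = psd_pre, peaks = peaks))
  }
  path <- sprintf("noise_comp1 = %.3g Hz -> stop-band 1 ON", nc1)

  sb1 <- design_stopband(nc1, cfg$stopband_halfwidth, pre$fs)
  y <- apply_stopband(xn, sb1)
  cutoffs <- nc1

  psd_post <- welch_psd(ecg_segment(y, pre$fs), cfg$welch_window_s, cfg$welch_overlap)
  bp <- band_power(psd_post, cfg$power_band[1], cfg$power_band[2])

  # condition 1: remaining peaks divisible by the fundamental
  peak_set <- if (cfg$recompute_peaks) {
    top_peaks(psd_post, k = 3, search_band = cfg$peak_band,
              min_separation = cfg$min_peak_separation)
  } else peaks
  rem <- peak_set[abs(peak_set$freq - nc1) > 1e-9, , drop = FALSE]
  nc2 <- NA_real_
  if (nrow(rem)) {
    div <- vapply(rem$freq, function(f) {
      h <- is_harmonic(f, nc1, cfg$harmonic_rel_tol)
      h$harmonic && h$order <= cfg$max_harmonic_order
    }, logical(1))
    if (any(div)) {
      cand <- rem[div, , drop = FALSE]
      nc2 <- cand$freq[which.max(cand$density)]  # highest power when both divide
      path <- c(path, sprintf("condition1: noise_comp2 = %.3g Hz (harmonic of %.3g)",
                              nc2, nc1))
    }
  }

  dec <- condition_decision(nc1, nc2, bp, cfg)
  path <- c(path, dec$path)
  if (dec$fire2) {
    sb2 <- design_stopband(nc2, cfg$stopband_halfwidth, pre$fs)
    y <- apply_stopband(y, sb2)
    cutoffs <- c(cutoffs, nc2)
  }
  if (dec$fire3) {
    c3 <- 2 * nc1
    sb3 <- design_stopband(c3, cfg$stopband_halfwidth, pre$fs)
    y <- apply_stopband(y, sb3)
    cutoffs <- c(cutoffs, c3)
  }

  filtered <- set_samples(pre, y / norm)
  trace <- structure(list(
    noise_comp1 = nc1, noise_comp2 = nc2, band_power_10_15 = bp,
    stopband1_fired = TRUE, stopband2_fired = dec$fire2,
    stopband3_fired = dec$fire3, cutoffs = cutoffs,
    decision_path = path, threshold = cfg$power_threshold),
    class = "condition_trace")
  structure(list(input = segment, preprocessed = pre, filtered = filtered,
                 trace = trace, peaks = peaks, psd_pre = psd_pre,
                 psd_post = psd_post, config = cfg),
            class = "cpr_suppress")
}

#' Extract the condition trace of a suppression run
#' @param fit A `cpr_suppress` object.
#' @return The `condition_trace`.
#' @export
condition_trace <- function(fit) {
  stopifnot(inherits(fit, "cpr_suppress"))
  fit$trace
}

#' @export
print.condition_trace <- function(x, ...) {
  cat("<condition_trace>\n")
  cat(sprintf("  noise_comp1: %s Hz\n",
              if (is.na(x$noise_comp1)) "none" else format(x$noise_comp1, digits = 4)))
  cat(sprintf("  noise_comp2: %s Hz\n",
              if (is.na(x$noise_comp2)) "none" else format(x$noise_comp2, digits = 4)))
  cat(sprintf("  band power 10-15 Hz: %s (threshold %g)\n",
              if (is.na(x$band_power_10_15)) "n/a"
              else format(x$band_power_10_15, digits = 4), x$threshold))
  cat(sprintf("  stop-bands fired: %s\n",
              paste0(c("1", "2", "3")[c(x$stopband1_fired, x$stopband2_fired,
                                        x$stopband3_fired)], collapse = ", ")))
  if (length(x$cutoffs)) {
    cat(sprintf("  cutoffs: %s Hz\n", paste(format(x$cutoffs, digits = 4),
                                            collapse = ", ")))
  }
  invisible(x)
}

#' @export
print.cpr_suppress <- function(x, ...) {
  tr <- x$trace
  fired <- c("1", "2", "3")[c(tr$stopband1_fired, tr$stopband2_fired,
                              tr$stopband3_fired)]
  cat(sprintf("Condition-based CPR suppression of a %.1f s segment @ %g Hz\n",
              duration(x$input), x$input$fs))
  if (is.na(tr$noise_comp1)) {
    cat("  no compression fundamental detected; output = preprocessed input\n")
  } else {
    cat(sprintf("  compression fundamental: %.3g Hz; stop-bands fired: %s\n",
                tr$noise_comp1, paste(fired, collapse = ", ")))
  }
  invisible(x)
}

#' @export
summary.cpr_suppress <- function(object, ...) {
  print(object)
  cat("\nDetected peaks:\n")
  if (!is.null(object$peaks)) print(as.data.frame(object$peaks))
  cat("\nDecision path:\n")
  for (p in object$trace$decision_path) cat("  -", p, "\n")
  print(object$trace)
  invisible(object$trace)
}

#' @export
residuals.cpr_suppress <- function(object, ...) {
  object$preprocessed$samples - object$filtered$samples
}

#' Plot a suppression run
#'
#' Two panels: the preprocessed vs filtered time series, and the PSDs
#' before and after filtering with the fired stop-band centres marked.
#'
#' @param x A `cpr_suppress` object.
#' @param ... Unused.
#' @export
plot.cpr_suppress <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  t <- seq_along(x$preprocessed$samples) / x$preprocessed$fs
  graphics::plot(t, x$preprocessed$samples, type = "l", col = "grey50",
                 xlab = "time (s)", ylab = "amplitude",
                 main = "preprocessed (grey) vs filtered (black)")
  graphics::lines(t, x$filtered$samples, col = "black")
  if (!is.null(x$psd_pre)) {
    keep <- x$psd_pre$freqs <= 30
    graphics::plot(x$psd_pre$freqs[keep], x$psd_pre$density[keep], type = "l",
                   col = "grey50", xlab = "frequency (Hz)", ylab = "PSD",
                   main = "PSD before (grey) / after (black)")
    if (!is.null(x$psd_post)) {
      graphics::lines(x$psd_post$freqs[keep], x$psd_post$density[keep])
    }
    graphics::abline(v = x$trace$cutoffs, lty = 2, col = "red")
  }
  invisible(x)
}
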