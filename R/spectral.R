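#' Welch power spectral density estimate
#'
#' Averaged modified periodograms: the segment is split into
#' Hamming-windowed, overlapping blocks, each block is mean-removed,
#' windowed and Fourier transformed, and the one-sided periodograms are
#' averaged. The density normalization makes the integral of the PSD over
#' the frequency grid approximate the signal variance (Parseval).
#'
#' @param segment An [ecg_segment()].
#' @param window_s Welch block length in seconds (default 4, giving a
#'   0.25 Hz bin resolution).
#' @param overlap_frac Fractional overlap between blocks (default 0.5).
#' @return An object of class `psd_estimate`: list with `freqs` (Hz),
#'   `density` (power per Hz), `resolution` (Hz), `window_s`,
#'   `overlap_frac`, `fs`, `n_blocks`.
#' @export
welch_psd <- function(segment, window_s = 4, overlap_frac = 0.5) {
  stopifnot(is_ecg_segment(segment))
  fs <- segment$fs
  x <- segment$samples
  nper <- round(window_s * fs)
  if (nper > length(x)) stop("Welch window longer than the segment")
  if (overlap_frac < 0 || overlap_frac >= 1) stop("overlap_frac must be in [0, 1)")
  step <- max(1L, nper - floor(overlap_frac * nper))
  starts <- seq(1L, length(x) - nper + 1L, by = step)
  w <- hamming_window(nper)
  scale <- fs * sum(w^2)
  nfreq <- nper %/% 2L + 1L
  acc <- numeric(nfreq)
  for (s in starts) {
    blk <- x[s:(s + nper - 1L)]
    blk <- (blk - mean(blk)) * w
    p <- Mod(stats::fft(blk))^2 / scale
    p1 <- p[seq_len(nfreq)]
    # one-sided: double everything except DC (and Nyquist when nper even)
    dbl <- rep(2, nfreq); dbl[1] <- 1
    if (nper %% 2L == 0L) dbl[nfreq] <- 1
    acc <- acc + p1 * dbl
  }
  density <- acc / length(starts)
  freqs <- (seq_len(nfreq) - 1L) * fs / nper
  structure(list(freqs = freqs, density = density,
                 resolution = fs / nper, window_s = window_s,
                 overlap_frac = overlap_frac, fs = fs,
                 n_blocks = length(starts)),
            class = "psd_estimate")
}

# Symmetric Hamming window (MATLAB convention).
hamming_window <- function(n) {
  if (n == 1L) return(1)
  k <- 0:(n - 1L)
  0.54 - 0.46 * cos(2 * pi * k / (n - 1L))
}

#' @export
print.psd_estimate <- function(x, ...) {
  cat(sprintf("<psd_estimate> %d bins, 0-%g Hz, resolution %g Hz (%d blocks)\n",
              length(x$freqs), max(x$freqs), x$resolution, x$n_blocks))
  invisible(x)
}

#' Find the largest spectral peaks
#'
#' Locates local maxima of the PSD within a search band, enforces a
#' minimum peak separation, and returns up to `k` of them sorted by
#' descending density (ties broken toward the lower frequency). These are
#' the Peak1/Peak2/Peak3 with frequencies F1/F2/F3 used by the
#' condition-based filter.
#'
#' @param psd A `psd_estimate`.
#' @param k Maximum number of peaks to return (default 3).
#' @param search_band Length-2 Hz interval searched (default `c(0.5, 30)`).
#' @param min_separation Minimum spacing between returned peaks in Hz
#'   (default 0.5).
#' @param min_rel_density Candidates below this fraction of the strongest
#'   in-band density are discarded as numerical floor (default `1e-4`);
#'   genuine rhythm or artifact peaks sit far above it.
#' @return An object of class `spectral_peaks`: a data frame with columns
#'   `freq` and `density`, rows in descending density order.
#' @export
top_peaks <- function(psd, k = 3, search_band = c(0.5, 30),
                      min_separation = 0.5, min_rel_density = 1e-4) {
  stopifnot(inherits(psd, "psd_estimate"))
  f <- psd$freqs; d <- psd$density
  in_band <- which(f >= search_band[1] & f <= search_band[2])
  if (!length(in_band)) stop("search_band contains no PSD bins")
  in_band <- in_band[d[in_band] >= min_rel_density * max(d[in_band])]
  n <- length(d)
  is_max <- vapply(in_band, function(i) {
    left_ok <- i == 1L || d[i] > d[i - 1L]
    right_ok <- i == n || d[i] > d[i + 1L]
    left_ok && right_ok
  }, logical(1))
  cand <- in_band[is_max]
  # descending density, ties toward the lower frequency
  cand <- cand[order(-d[cand], f[cand])]
  sel <- integer(0)
  for (i in cand) {
    if (length(sel) >= k) break
    if (all(abs(f[i] - f[sel]) >= min_separation)) sel <- c(sel, i)
  }
  structure(data.frame(freq = f[sel], density = d[sel]),
            class = c("spectral_peaks", "data.frame"))
}

#' Locate the chest-compression fundamental among the top peaks
#'
#' The compression fundamental lies in the 1-3 Hz band. Among the
#' detected peak frequencies falling inside `cc_band`, the one with the
#' highest density is returned (the algorithm's Noise-comp1); `NA` when
#' no peak falls in the band.
#'
#' @param peaks A `spectral_peaks` object from [top_peaks()].
#' @param cc_band Length-2 Hz interval for the compression fundamental
#'   (default `c(1, 3)`, inclusive).
#' @return The fundamental frequency in Hz, or `NA_real_`.
#' @export
find_fundamental <- function(peaks, cc_band = c(1, 3)) {
  stopifnot(inherits(peaks, "spectral_peaks"))
  inb <- peaks$freq >= cc_band[1] & peaks$freq <= cc_band[2]
  if (!any(inb)) return(NA_real_)
  cand <- peaks[inb, , drop = FALSE]
  cand$freq[which.max(cand$density)]
}

#' Spectral power in a frequency band
#'
#' Trapezoidal integral of the PSD over `[lo, hi]`, with linear
#' interpolation of the density at band edges that fall between grid
#' points. The 10-15 Hz band power is the discriminant that separates
#' broadband non-shockable rhythms from shockable rhythms.
#'
#' @param psd A `psd_estimate`.
#' @param lo,hi Band edges in Hz (default 10 and 15).
#' @return Non-negative band power.
#' @export
band_power <- function(psd, lo = 10, hi = 15) {
  stopifnot(inherits(psd, "psd_estimate"))
  if (lo >= hi) stop("'lo' must be below 'hi'")
  f <- psd$freqs
  if (lo < min(f) || hi > max(f)) {
    stop(sprintf("band (%g, %g) Hz outside the PSD grid (%g-%g Hz)",
                 lo, hi, min(f), max(f)))
  }
  inner <- f[f > lo & f < hi]
  grid <- c(lo, inner, hi)
  dens <- stats::approx(f, psd$density, xout = grid)$y
  sum(diff(grid) * (utils::head(dens, -1) + utils::tail(dens, -1)) / 2)
}

#' Test whether a frequency is a harmonic of a fundamental
#'
#' A frequency `f` counts as "divisible" by the fundamental when the
#' ratio `f / fundamental` is within `rel_tol` (relative to the harmonic
#' order) of an integer of at least 2.
#'
#' @param f Candidate frequency in Hz.
#' @param fundamental Fundamental frequency in Hz (> 0).
#' @param rel_tol Relative tolerance on the ratio per unit order
#'   (default 0.08, about one 0.25 Hz bin at 3 Hz).
#' @return A list with `harmonic` (logical) and `order` (the rounded
#'   ratio; `NA` when not a harmonic).
#' @export
is_harmonic <- function(f, fundamental, rel_tol = 0.08) {
  if (!is.finite(fundamental) || fundamental <= 0) {
    stop("'fundamental' must be > 0")
  }
  ratio <- f / fundamental
  k <- round(ratio)
  ok <- k >= 2 & abs(ratio - k) <= rel_tol * k
  list(harmonic = isTRUE(ok), order = if (isTRUE(ok)) as.integer(k) else NA_integer_)
}
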