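# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: plain FFTs and explicit periodogram loops.

# One-sided signal power (variance contribution) in [lo, hi] Hz via a
# single raw FFT of the mean-removed signal.
fft_band_power <- function(x, fs, lo, hi) {
  n <- length(x)
  x <- x - mean(x)
  p2 <- Mod(stats::fft(x))^2 / n^2        # two-sided power per bin
  f <- (seq_len(n) - 1) * fs / n
  half <- f <= fs / 2
  p <- 2 * p2[half]
  p[1] <- p2[1]
  if (n %% 2 == 0) p[sum(half)] <- p2[sum(half)]
  sum(p[f[half] >= lo & f[half] <= hi])
}

# Frequency of the largest FFT magnitude (mean removed).
fft_peak_freq <- function(x, fs) {
  n <- length(x)
  m <- Mod(stats::fft(x - mean(x)))[seq_len(n %/% 2 + 1)]
  m[1] <- 0
  (which.max(m) - 1) * fs / n
}

# Brute-force Welch reference: explicitly compute each Hamming-windowed,
# mean-removed periodogram on the same segmentation and average them.
brute_force_welch <- function(x, fs, window_s, overlap_frac) {
  nper <- round(window_s * fs)
  step <- max(1, nper - floor(overlap_frac * nper))
  k <- 0:(nper - 1)
  w <- 0.54 - 0.46 * cos(2 * pi * k / (nper - 1))
  starts <- seq(1, length(x) - nper + 1, by = step)
  periodograms <- sapply(starts, function(s) {
    seg <- x[s:(s + nper - 1)]
    seg <- seg - sum(seg) / nper
    spec <- abs(stats::fft(seg * w))^2
    one <- spec[1:(nper %/% 2 + 1)] / (fs * sum(w * w))
    mult <- c(1, rep(2, nper %/% 2 - 1), if (nper %% 2 == 0) 1 else 2)
    one * mult
  })
  list(freqs = (0:(nper %/% 2)) * fs / nper,
       density = rowMeans(as.matrix(periodograms)))
}

# Construct a psd_estimate by hand (for peak-logic tests on exact grids).
fake_psd <- function(freqs, density) {
  structure(list(freqs = freqs, density = density,
                 resolution = freqs[2] - freqs[1], window_s = NA,
                 overlap_frac = NA, fs = 2 * max(freqs), n_blocks = 1),
            class = "psd_estimate")
}

# A deterministic multi-tone segment.
tone_segment <- function(freqs, amps, duration_s = 14, fs = 125) {
  t <- (seq_len(round(duration_s * fs)) - 1) / fs
  x <- numeric(length(t))
  for (i in seq_along(freqs)) x <- x + amps[i] * sin(2 * pi * freqs[i] * t)
  ecg_segment(x, fs = fs)
}

# Small seeded pools reused by heavier tests.
make_pools <- function(n_shock, n_nonshock, n_art, seed = 42,
                       duration_s = 14) {
  shock <- segment_collection(lapply(seq_len(n_shock), function(i) {
    if (i %% 3 == 0) {
      gen_rhythm("rapid_vt", duration_s = duration_s,
                 heart_rate_bpm = 180 + (i %% 4) * 20, seed = seed + i,
                 subject_id = sprintf("sh%03d", i))
    } else {
      gen_rhythm("vf", duration_s = duration_s,
                 vf_center_freq = 3.6 + (i %% 5) * 0.45, seed = seed + i,
                 subject_id = sprintf("sh%03d", i))
    }
  }))
  nonshock <- segment_collection(lapply(seq_len(n_nonshock), function(i) {
    gen_rhythm(if (i %% 2 == 0) "nsr" else "other_nonshockable",
               duration_s = duration_s, seed = seed + 1000 + i,
               subject_id = sprintf("ns%03d", i))
  }))
  arts <- segment_collection(lapply(seq_len(n_art), function(i) {
    gen_cpr_artifact(fundamental_hz = 1.4 + 1.5 * ((i - 1) %% 7) / 6,
                     duration_s = duration_s, seed = seed + 2000 + i,
                     artifact_id = sprintf("art%03d", i))
  }))
  list(shock = shock, nonshock = nonshock, arts = arts)
}
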