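# Seeded generators for the spectral regimes the condition-based filter
# assumes: broadband non-shockable rhythms with power above 10 Hz,
# shockable rhythms concentrated in 3-6 Hz, near-flat asystole, and
# quasi-periodic compression artifacts with a 1-3 Hz fundamental and
# decaying harmonics.

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

gaussian_pulse <- function(t, center, width, amp) {
  amp * exp(-0.5 * ((t - center) / width)^2)
}

#' Generate a synthetic ECG rhythm segment
#'
#' Emulates the spectral regimes the suppression algorithm relies on, not
#' physiologically detailed ECG:
#' \describe{
#'   \item{`nsr`}{P-QRS-T beats built from Gaussian pulses at the given
#'     heart rate with mild rate variability. The sharp QRS transients
#'     make the spectrum broadband, with measurable 10-15 Hz power.}
#'   \item{`other_nonshockable`}{Irregular (fibrillation-like) RR
#'     intervals, wider QRS, no P wave; still broadband.}
#'   \item{`vf`}{Amplitude- and frequency-modulated oscillation centred
#'     at `vf_center_freq`; power concentrated in 3-6 Hz.}
#'   \item{`rapid_vt`}{Near-monomorphic oscillation at
#'     `heart_rate_bpm / 60` Hz with weak harmonics.}
#'   \item{`asystole`}{Low-amplitude noise only.}
#' }
#'
#' @param rhythm One of `"nsr"`, `"other_nonshockable"`, `"vf"`,
#'   `"rapid_vt"`, `"asystole"`.
#' @param duration_s Segment length in seconds (default 14, minimum 8).
#' @param fs Sampling rate in Hz (default 125).
#' @param heart_rate_bpm Heart rate for `nsr` (default 75) and `rapid_vt`
#'   (default 210).
#' @param vf_center_freq Centre frequency for `vf`, in (3, 6) Hz
#'   (default 4.5).
#' @param noise_floor Relative standard deviation of additive noise
#'   (defaults: 0.03 for beats, 0.05 for vf/vt, 0.01 for asystole).
#' @param seed Integer seed; the same spec and seed give bitwise-identical
#'   segments.
#' @param subject_id Optional identifier stored on the segment.
#' @return An [ecg_segment()] with the rhythm label set.
#' @export
gen_rhythm <- function(rhythm = c("nsr", "other_nonshockable", "vf",
                                  "rapid_vt", "asystole"),
                       duration_s = 14, fs = 125,
                       heart_rate_bpm = NULL, vf_center_freq = 4.5,
                       noise_floor = NULL, seed = NULL,
                       subject_id = NULL) {
  rhythm <- match.arg(rhythm)
  if (duration_s < 8) stop("duration_s must be >= 8")
  if (rhythm == "vf" && (vf_center_freq <= 3 || vf_center_freq >= 6)) {
    stop("vf_center_freq must lie in (3, 6) Hz")
  }
  n <- round(duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  with_seed(seed, {
    x <- switch(rhythm,
      nsr = {
        hr <- if (is.null(heart_rate_bpm)) 75 else heart_rate_bpm
        nf <- if (is.null(noise_floor)) 0.03 else noise_floor
        beat_train(t, rr_mean = 60 / hr, rr_jitter = 0.04,
                   qrs_width = 0.012, p_wave = TRUE) +
          nf * stats::rnorm(n)
      },
      other_nonshockable = {
        hr <- if (is.null(heart_rate_bpm)) 90 else heart_rate_bpm
        nf <- if (is.null(noise_floor)) 0.05 else noise_floor
        beat_train(t, rr_mean = 60 / hr, rr_jitter = 0.25,
                   qrs_width = 0.018, p_wave = FALSE) +
          nf * stats::rnorm(n)
      },
      vf = {
        nf <- if (is.null(noise_floor)) 0.05 else noise_floor
        # smoothed random walks modulate frequency and amplitude
        fm <- smooth_noise(n, fs, cutoff = 0.4) * 0.5
        am <- 1 + 0.35 * smooth_noise(n, fs, cutoff = 0.5)
        phase <- 2 * pi * cumsum(vf_center_freq + fm) / fs
        am * sin(phase) + nf * stats::rnorm(n)
      },
      rapid_vt = {
        hr <- if (is.null(heart_rate_bpm)) 210 else heart_rate_bpm
        nf <- if (is.null(noise_floor)) 0.05 else noise_floor
        f0 <- hr / 60
        jit <- smooth_noise(n, fs, cutoff = 0.3) * 0.1
        phase <- 2 * pi * cumsum(f0 * (1 + jit)) / fs
        sin(phase) + 0.15 * sin(2 * phase) + nf * stats::rnorm(n)
      },
      asystole = {
        nf <- if (is.null(noise_floor)) 0.01 else noise_floor
        nf * stats::rnorm(n)
      }
    )
    ecg_segment(x, fs = fs, label = rhythm, subject_id = subject_id)
  })
}

# Gaussian-pulse P-QRS-T beat train with jittered RR intervals.
beat_train <- function(t, rr_mean, rr_jitter, qrs_width, p_wave) {
  dur <- max(t) + (t[2] - t[1])
  beats <- numeric(0)
  tt <- stats::runif(1, 0, rr_mean)
  while (tt < dur + rr_mean) {
    beats <- c(beats, tt)
    tt <- tt + rr_mean * max(0.3, 1 + rr_jitter * stats::rnorm(1))
  }
  x <- numeric(length(t))
  for (b in beats) {
    x <- x +
      gaussian_pulse(t, b - 0.025, qrs_width, -0.15) +       # Q
      gaussian_pulse(t, b, qrs_width, 1.0) +                 # R
      gaussian_pulse(t, b + 0.03, qrs_width * 1.2, -0.25) +  # S
      gaussian_pulse(t, b + 0.25, 0.05, 0.25)                # T
    if (p_wave) x <- x + gaussian_pulse(t, b - 0.15, 0.03, 0.12)
  }
  x
}

# Zero-mean unit-std noise lowpassed below `cutoff` Hz.
smooth_noise <- function(n, fs, cutoff) {
  e <- stats::rnorm(n)
  bt <- signal::butter(2, min(0.99, cutoff * 2 / fs), type = "low")
  y <- signal::filtfilt(bt$b, bt$a, e)
  s <- stats::sd(y)
  if (s > 0) y / s else y
}

#' Generate a synthetic CPR compression artifact
#'
#' Quasi-periodic compression waveform: each compression cycle carries a
#' sum of `n_harmonics` cosine components locked to the cycle phase with
#' geometrically decaying amplitudes, while the cycle period and depth
#' are jittered from cycle to cycle. With zero jitter the spectrum has
#' exact lines at the fundamental and its harmonics; with realistic
#' jitter the lines broaden as in recorded compression artifacts.
#'
#' @param fundamental_hz Compression fundamental in Hz, within `[1, 3]`
#'   (default 2, i.e. 120 compressions/min; guideline rates of
#'   100-120/min put it at 1.67-2 Hz, faster compressions up to 3 Hz).
#' @param n_harmonics Number of harmonic components including the
#'   fundamental (default 3).
#' @param harmonic_decay Amplitude ratio between consecutive harmonic
#'   orders (default 0.5).
#' @param rate_jitter Fractional cycle-period jitter (default 0.03).
#' @param depth_jitter Fractional cycle-amplitude jitter (default 0.1).
#' @param duration_s,fs Segment geometry (defaults 14 s, 125 Hz).
#' @param seed Integer seed.
#' @param artifact_id Optional identifier stored on the segment.
#' @return An [ecg_segment()] labelled `"cpr_artifact"`.
#' @export
gen_cpr_artifact <- function(fundamental_hz = 2, n_harmonics = 3,
                             harmonic_decay = 0.5, rate_jitter = 0.03,
                             depth_jitter = 0.1, duration_s = 14, fs = 125,
                             seed = NULL, artifact_id = NULL) {
  if (fundamental_hz < 1 || fundamental_hz > 3) {
    stop("fundamental_hz must lie within [1, 3] Hz")
  }
  if (n_harmonics < 1) stop("n_harmonics must be >= 1")
  n <- round(duration_s * fs)
  with_seed(seed, {
    # cycle boundaries with jittered periods
    periods <- numeric(0)
    total <- 0
    while (total < duration_s + 2 / fundamental_hz) {
      p <- (1 / fundamental_hz) * max(0.5, 1 + rate_jitter * stats::rnorm(1))
      periods <- c(periods, p)
      total <- total + p
    }
    amps <- pmax(0.2, 1 + depth_jitter * stats::rnorm(length(periods)))
    bounds <- c(0, cumsum(periods))
    t <- (seq_len(n) - 1) / fs
    cyc <- findInterval(t, bounds)
    phase <- (t - bounds[cyc]) / periods[cyc]       # in [0, 1)
    amp <- amps[cyc]
    x <- numeric(n)
    for (k in seq_len(n_harmonics)) {
      x <- x + harmonic_decay^(k - 1) * cos(2 * pi * k * phase)
    }
    ecg_segment(amp * x, fs = fs, label = "cpr_artifact",
                subject_id = artifact_id)
  })
}

#' Mix a CPR artifact into a clean ECG at a controlled SNR
#'
#' Additive corruption model: the artifact is scaled to unit standard
#' deviation, then to `std(clean) * 10^(-snr_db / 20)`, and added to the
#' clean signal, so that the added component satisfies
#' `20 * log10(std(clean) / std(added)) = snr_db` exactly. The model
#' assumes the artifact is additive and independent of the underlying
#' rhythm.
#'
#' @param clean Artifact-free [ecg_segment()].
#' @param artifact CPR-artifact [ecg_segment()] at the same sampling
#'   rate. A length mismatch is resolved by cropping or crossfade-tiling
#'   the artifact (with a message).
#' @param snr_db Requested signal-to-noise ratio in dB (the study's
#'   levels are 0, -3, -6, -9; the development setting is -3).
#' @return The corrupted [ecg_segment()] (label and subject of `clean`
#'   kept).
#' @export
mix_cpr <- function(clean, artifact, snr_db) {
  stopifnot(is_ecg_segment(clean), is_ecg_segment(artifact))
  if (!isTRUE(all.equal(clean$fs, artifact$fs))) {
    stop("clean and artifact must share a sampling rate")
  }
  if (!is.finite(snr_db)) stop("snr_db must be finite")
  sc <- stats::sd(clean$samples)
  sa <- stats::sd(artifact$samples)
  if (!is.finite(sc) || sc == 0) stop("clean segment has zero variance")
  if (!is.finite(sa) || sa == 0) stop("artifact segment has zero variance")
  a <- artifact$samples
  n <- length(clean$samples)
  if (length(a) != n) {
    message(sprintf("artifact length %d != clean length %d: %s",
                    length(a), n, if (length(a) > n) "cropping" else "tiling"))
    a <- tile_to_length(a, n, clean$fs)
    sa <- stats::sd(a)
    if (sa == 0) stop("artifact segment has zero variance after tiling")
  }
  mixed <- clean$samples + sc * 10^(-snr_db / 20) * a / sa
  ecg_segment(mixed, fs = clean$fs, label = clean$label,
              subject_id = clean$subject_id)
}

# Tile (with a 50 ms linear crossfade at the seams) or crop to length n.
tile_to_length <- function(a, n, fs) {
  if (length(a) >= n) return(a[seq_len(n)])
  xf <- max(1L, min(round(0.05 * fs), length(a) %/% 4L))
  out <- a
  while (length(out) < n) {
    ramp <- seq(0, 1, length.out = xf)
    head_new <- a[seq_len(xf)] * ramp + out[length(out) - xf + seq_len(xf)] * (1 - ramp)
    out <- c(out[seq_len(length(out) - xf)], head_new, a[-seq_len(xf)])
  }
  out[seq_len(n)]
}

#' Build a corrupted dataset as a full cross product
#'
#' Mixes every clean segment with every artifact at every SNR level via
#' [mix_cpr()], so the result has
#' `length(cleans) * length(artifacts) * length(snr_levels)` entries with
#' a manifest recording the provenance of each.
#'
#' @param cleans [segment_collection()] of artifact-free rhythms.
#' @param artifacts [segment_collection()] of CPR artifacts.
#' @param snr_levels Numeric vector of SNR levels in dB (default -3).
#' @return A [segment_collection()] of corrupted segments; the manifest
#'   gains `clean_index` and `artifact_index` columns.
#' @export
build_dataset <- function(cleans, artifacts, snr_levels = -3) {
  stopifnot(inherits(cleans, "segment_collection"),
            inherits(artifacts, "segment_collection"))
  if (!length(cleans) || !length(artifacts) || !length(snr_levels)) {
    stop("cleans, artifacts and snr_levels must be non-empty")
  }
  nt <- length(cleans) * length(artifacts) * length(snr_levels)
  segs <- vector("list", nt)
  man <- data.frame(subject_id = character(nt), artifact_id = character(nt),
                    snr_db = numeric(nt), label = character(nt),
                    clean_index = integer(nt), artifact_index = integer(nt),
                    stringsAsFactors = FALSE)
  k <- 0L
  for (ci in seq_len(length(cleans))) {
    for (ai in seq_len(length(artifacts))) {
      for (snr in snr_levels) {
        k <- k + 1L
        seg <- tryCatch(
          mix_cpr(cleans[[ci]], artifacts[[ai]], snr),
          error = function(e) {
            stop(sprintf("mix failed for clean %d x artifact %d @ %g dB: %s",
                         ci, ai, snr, conditionMessage(e)))
          })
        segs[[k]] <- seg
        man$subject_id[k] <- cleans$manifest$subject_id[ci]
        man$artifact_id[k] <- {
          aid <- artifacts$manifest$subject_id[ai]
          if (is.na(aid)) sprintf("art%03d", ai) else aid
        }
        man$snr_db[k] <- snr
        man$label[k] <- if (is.null(seg$label)) NA_character_ else seg$label
        man$clean_index[k] <- ci
        man$artifact_index[k] <- ai
      }
    }
  }
  segment_collection(segs, man)
}

#' Default synthetic rhythm and artifact pools
#'
#' Seeded pools whose sizes mirror the study design: a development pool
#' of 50 non-shockable and 45 shockable subjects, a validation pool of
#' 396 non-shockable and 72 shockable subjects, and 52 distinct
#' compression artifacts.
#'
#' @param which One of `"development"`, `"validation"`, `"artifacts"`.
#' @param seed Base seed (default 20211208); per-segment seeds are
#'   derived from it.
#' @param duration_s,fs Segment geometry.
#' @return For rhythm pools, a list with `shockable` and `nonshockable`
#'   [segment_collection()]s; for `"artifacts"`, a single collection.
#' @export
synthetic_pool <- function(which = c("development", "validation", "artifacts"),
                           seed = 20211208, duration_s = 14, fs = 125) {
  which <- match.arg(which)
  mk_rhythms <- function(n_nonshock, n_shock, base) {
    nonshock <- lapply(seq_len(n_nonshock), function(i) {
      rhythm <- if (i %% 2 == 0) "nsr" else "other_nonshockable"
      gen_rhythm(rhythm, duration_s = duration_s, fs = fs,
                 seed = base + i, subject_id = sprintf("ns%03d", i))
    })
    shock <- lapply(seq_len(n_shock), function(i) {
      if (i %% 3 == 0) {
        gen_rhythm("rapid_vt", duration_s = duration_s, fs = fs,
                   heart_rate_bpm = 180 + (i %% 5) * 15,
                   seed = base + 10000 + i, subject_id = sprintf("sh%03d", i))
      } else {
        gen_rhythm("vf", duration_s = duration_s, fs = fs,
                   vf_center_freq = 3.5 + (i %% 5) * 0.5,
                   seed = base + 10000 + i, subject_id = sprintf("sh%03d", i))
      }
    })
    list(shockable = segment_collection(shock),
         nonshockable = segment_collection(nonshock))
  }
  switch(which,
    development = mk_rhythms(50, 45, seed %% 100000),
    validation = mk_rhythms(396, 72, seed %% 100000 + 500),
    artifacts = {
      segs <- lapply(seq_len(52), function(i) {
        gen_cpr_artifact(
          fundamental_hz = 1.4 + 1.5 * ((i - 1) %% 13) / 12,
          harmonic_decay = 0.35 + 0.3 * ((i - 1) %% 4) / 3,
          duration_s = duration_s, fs = fs,
          seed = seed %% 100000 + 20000 + i,
          artifact_id = sprintf("cpr%02d", i))
      })
      segment_collection(segs)
    })
}
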