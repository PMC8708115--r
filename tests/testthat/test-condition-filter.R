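test_that("design_stopband notches its centre and leaves the passband intact", {
  fs <- 125
  t <- (0:1749) / fs
  sb <- design_stopband(2, 0.5, fs)
  expect_true(all(Mod(polyroot(rev(sb$a))) < 1))  # stable

  tone2 <- sin(2 * pi * 2 * t)
  out2 <- signal::filtfilt(sb$b, sb$a, tone2)
  atten_db <- 10 * log10(fft_band_power(out2, fs, 1.75, 2.25) /
                           fft_band_power(tone2, fs, 1.75, 2.25))
  expect_lt(atten_db, -30)

  tone5 <- sin(2 * pi * 5 * t)
  out5 <- signal::filtfilt(sb$b, sb$a, tone5)
  expect_lt(abs(sqrt(mean(out5^2)) / sqrt(mean(tone5^2)) - 1), 0.03)

  expect_error(design_stopband(0, 0.5, fs), "inside")
  expect_error(design_stopband(0.3, 0.5, fs), "inside")
  expect_error(design_stopband(62.4, 0.5, fs), "inside")
})

test_that("the three-condition decision logic matches the hand-enumerated truth table", {
  cfg <- filter_config()
  # columns: noise_comp2 (NA = absent), band power, noise_comp1,
  #          expected stop-band 2, expected stop-band 3
  cases <- list(
    # noise_comp2 present, inside the 3-6 Hz shockable band
    list(4.5, 0.20, 2.0, TRUE,  FALSE),  # band power above -> remove harmonic
    list(4.5, 0.20, 1.2, TRUE,  FALSE),
    list(4.5, 0.01, 2.0, FALSE, FALSE),  # shockable protection
    list(4.5, 0.01, 1.2, FALSE, TRUE),   # low fundamental: 2*f0 < 3 Hz is safe
    # noise_comp2 present, outside the shockable band
    list(7.5, 0.20, 2.0, TRUE,  FALSE),
    list(7.5, 0.20, 1.2, TRUE,  FALSE),
    list(7.5, 0.01, 2.0, TRUE,  FALSE),
    list(7.5, 0.01, 1.2, TRUE,  FALSE),
    # no divisible peak: only condition 3 remains
    list(NA,  0.20, 2.0, FALSE, TRUE),
    list(NA,  0.20, 1.2, FALSE, TRUE),
    list(NA,  0.01, 2.0, FALSE, FALSE),
    list(NA,  0.01, 1.2, FALSE, TRUE)
  )
  for (cs in cases) {
    dec <- cprsuppress:::condition_decision(cs[[3]], cs[[1]], cs[[2]], cfg)
    expect_equal(dec$fire2, cs[[4]],
                 info = sprintf("nc2=%s bp=%g nc1=%g", cs[[1]], cs[[2]], cs[[3]]))
    expect_equal(dec$fire3, cs[[5]],
                 info = sprintf("nc2=%s bp=%g nc1=%g", cs[[1]], cs[[2]], cs[[3]]))
    expect_false(dec$fire2 && dec$fire3)  # mutually exclusive branches
  }
  # strict variant: a declined second condition ends the run
  strict <- filter_config(strict_end_after_cond2 = TRUE)
  dec <- cprsuppress:::condition_decision(1.2, 4.5, 0.01, strict)
  expect_false(dec$fire2)
  expect_false(dec$fire3)
})

test_that("a broadband rhythm with a strong third harmonic fires stop-bands 1 and 2", {
  clean <- gen_rhythm("nsr", seed = 31)
  t <- (0:1749) / 125
  art <- ecg_segment(cos(2 * pi * 2.44 * t) + 0.6 * cos(2 * pi * 7.32 * t),
                     fs = 125, label = "cpr_artifact")
  mixed <- mix_cpr(clean, art, -3)
  cfg <- filter_config(power_threshold = 0.005)  # calibrated scale (unit-std)
  fit <- suppress_cpr(mixed, cfg)
  tr <- condition_trace(fit)
  res <- fit$psd_pre$resolution
  expect_true(tr$stopband1_fired)
  expect_lt(abs(tr$noise_comp1 - 2.44), res + 1e-9)
  expect_true(tr$stopband2_fired)
  expect_false(tr$stopband3_fired)
  expect_lt(abs(tr$noise_comp2 - 7.32), res + 1e-9)
  expect_equal(tr$cutoffs, c(tr$noise_comp1, tr$noise_comp2))
})

test_that("a shockable rhythm is protected from harmonic removal in 3-6 Hz", {
  clean <- gen_rhythm("vf", vf_center_freq = 5.2, seed = 37)
  t <- (0:1749) / 125
  art <- ecg_segment(cos(2 * pi * 1.7 * t) + 0.6 * cos(2 * pi * 3.4 * t),
                     fs = 125, label = "cpr_artifact")
  mixed <- mix_cpr(clean, art, -3)
  cfg <- filter_config(power_threshold = 0.005)
  fit <- suppress_cpr(mixed, cfg)
  tr <- condition_trace(fit)
  expect_true(tr$stopband1_fired)
  expect_lt(abs(tr$noise_comp1 - 1.7), fit$psd_pre$resolution + 1e-9)
  expect_false(is.na(tr$noise_comp2))         # the harmonic is detected...
  expect_lt(tr$band_power_10_15, cfg$power_threshold)
  expect_false(tr$stopband2_fired)            # ...but never removed
  expect_false(tr$stopband3_fired)
})

test_that("segments without a 1-3 Hz peak pass through unfiltered", {
  seg <- tone_segment(c(5, 11), c(1, 0.3))
  fit <- suppress_cpr(seg)
  tr <- condition_trace(fit)
  expect_false(tr$stopband1_fired || tr$stopband2_fired || tr$stopband3_fired)
  expect_true(is.na(tr$noise_comp1))
  expect_identical(fit$filtered$samples, fit$preprocessed$samples)
})

test_that("a low fundamental without harmonics triggers stop-band 3 at twice its frequency", {
  t <- (0:1749) / 125
  clean <- ecg_segment(sin(2 * pi * 5.6 * t) + 0.3 * sin(2 * pi * 11.2 * t) +
                         0.02 * sin(2 * pi * 17 * t), fs = 125, label = "unknown")
  art <- ecg_segment(cos(2 * pi * 1.2 * t), fs = 125, label = "cpr_artifact")
  mixed <- mix_cpr(clean, art, -3)
  fit <- suppress_cpr(mixed, filter_config(power_threshold = 0.005))
  tr <- condition_trace(fit)
  expect_true(tr$stopband1_fired)
  expect_lt(abs(tr$noise_comp1 - 1.2), fit$psd_pre$resolution + 1e-9)
  expect_false(tr$stopband2_fired)
  expect_true(tr$stopband3_fired)
  expect_equal(tr$cutoffs[length(tr$cutoffs)], 2 * tr$noise_comp1)
})

test_that("suppression is deterministic, rejects short input, and removes energy", {
  clean <- gen_rhythm("nsr", seed = 41)
  art <- gen_cpr_artifact(2.2, seed = 42)
  mixed <- mix_cpr(clean, art, -3)
  f1 <- suppress_cpr(mixed)
  f2 <- suppress_cpr(mixed)
  expect_identical(f1$filtered$samples, f2$filtered$samples)
  expect_identical(f1$trace$decision_path, f2$trace$decision_path)

  expect_error(suppress_cpr(ecg_segment(rnorm(500), 125)), "8 s")

  # energy removal whenever a stop-band fires
  expect_true(f1$trace$stopband1_fired)
  expect_lt(var(f1$filtered$samples), var(f1$preprocessed$samples))
  expect_equal(residuals(f1),
               f1$preprocessed$samples - f1$filtered$samples)
})

test_that("the flat-segment edge case yields an all-false trace", {
  fit <- suppress_cpr(ecg_segment(rep(1, 1750), 125) )
  tr <- condition_trace(fit)
  expect_false(tr$stopband1_fired)
  expect_true(is.na(tr$noise_comp1))
})

test_that("the fundamental of a mixed-in artifact is recovered within one bin", {
  f0s <- c(1.2, 1.8, 2.0, 2.4, 3.0)
  rhythms <- c("nsr", "other_nonshockable", "vf", "rapid_vt")
  n_trials <- 100
  hits <- 0L
  for (i in seq_len(n_trials)) {
    f0 <- f0s[((i - 1) %% length(f0s)) + 1]
    clean <- gen_rhythm(rhythms[((i - 1) %% length(rhythms)) + 1],
                        seed = 7000 + i)
    art <- gen_cpr_artifact(f0, seed = 9000 + i)
    fit <- suppress_cpr(mix_cpr(clean, art, -3))
    nc1 <- condition_trace(fit)$noise_comp1
    if (!is.na(nc1) && abs(nc1 - f0) <= fit$psd_pre$resolution + 1e-9) {
      hits <- hits + 1L
    }
  }
  expect_gte(hits / n_trials, 0.95)
})
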