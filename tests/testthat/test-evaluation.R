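test_that("component_snr recovers mixture levels and caps perfect recovery", {
  clean <- gen_rhythm("nsr", seed = 51)
  art <- gen_cpr_artifact(2.1, seed = 52)
  mixed <- mix_cpr(clean, art, -3)
  expect_equal(component_snr(clean, mixed), -3, tolerance = 1e-9)

  expect_equal(component_snr(clean, clean), 120)

  # residual with a tenth of the clean power -> exactly 10 dB
  set.seed(53)
  r <- rnorm(length(clean$samples))
  r <- (r - mean(r)) / sd(r) * sd(clean$samples) / sqrt(10)
  obs <- ecg_segment(clean$samples + r, clean$fs)
  expect_equal(component_snr(clean, obs), 10, tolerance = 1e-9)

  expect_error(component_snr(clean, ecg_segment(rnorm(100), 125)),
               "equal length")
  expect_error(component_snr(ecg_segment(rep(1, 1750), 125), mixed),
               "zero variance")
})

test_that("snr_improvement measures movement toward the clean reference", {
  clean <- gen_rhythm("nsr", seed = 54)
  art <- gen_cpr_artifact(2.1, seed = 55)
  corrupted <- mix_cpr(clean, art, -3)

  expect_equal(snr_improvement(clean, corrupted, corrupted), 0)
  expect_equal(snr_improvement(clean, corrupted, clean),
               120 - component_snr(clean, corrupted))

  # invariance under common amplitude scaling
  sc <- function(seg, a) ecg_segment(a * seg$samples, seg$fs)
  filt <- suppress_cpr(corrupted)$filtered
  clean_p <- preprocess_ecg(clean)
  corr_p <- preprocess_ecg(corrupted)
  base <- snr_improvement(clean_p, corr_p, filt)
  expect_equal(snr_improvement(sc(clean_p, 5), sc(corr_p, 5), sc(filt, 5)),
               base, tolerance = 1e-9)

  # ideal notch on a pure-tone artifact improves the SNR
  t <- (0:1749) / 125
  tone_art <- ecg_segment(cos(2 * pi * 2 * t), 125)
  corrupted2 <- mix_cpr(clean, tone_art, -3)
  sb <- design_stopband(2, 0.5, 125)
  ideal <- ecg_segment(signal::filtfilt(sb$b, sb$a, corrupted2$samples), 125)
  expect_gt(snr_improvement(clean, corrupted2, ideal), 0)
})

test_that("psd_correlation is affine-invariant, symmetric and discriminative", {
  seg <- gen_rhythm("nsr", seed = 56)
  a <- welch_psd(seg)
  expect_equal(psd_correlation(a, a), 1)

  b <- a
  b$density <- 2 * a$density + 3
  expect_equal(psd_correlation(a, b), 1, tolerance = 1e-12)

  other <- welch_psd(gen_rhythm("vf", seed = 57))
  expect_equal(psd_correlation(a, other), psd_correlation(other, a),
               tolerance = 1e-12)

  flat <- a
  flat$density <- rep(1, length(a$density))
  expect_error(psd_correlation(a, flat), "zero-variance")

  # independent white-noise PSDs decorrelate on average
  set.seed(58)
  rs <- replicate(100, {
    p1 <- welch_psd(ecg_segment(rnorm(1750), 125))
    p2 <- welch_psd(ecg_segment(rnorm(1750), 125))
    psd_correlation(p1, p2)
  })
  expect_lt(mean(abs(rs)), 0.3)
})

test_that("threshold calibration separates the rhythm classes", {
  pools <- make_pools(n_shock = 50, n_nonshock = 50, n_art = 1, seed = 59)
  rep <- calibrate_threshold(pools$shock, pools$nonshock)
  expect_s3_class(rep, "calibration_report")
  expect_gt(rep$recommended_threshold, rep$shockable_mean)
  expect_lt(rep$recommended_threshold, rep$nonshockable_mean)
  expect_true(rep$classes_separated)

  # degenerate whisker: identical band powers collapse to that value
  q <- quantile(rep$shockable_powers, c(0.25, 0.75), names = FALSE)
  expect_equal(rep$shockable_upper_whisker, q[2] + 1.5 * (q[2] - q[1]))

  small <- segment_collection(lapply(1:3, function(i)
    gen_rhythm("vf", seed = 60 + i, subject_id = paste0("v", i))))
  expect_error(calibrate_threshold(small, pools$nonshock), "at least 4")
})

test_that("a degenerate zero-spread class yields its common value as threshold", {
  # synthetic psd-level check through the public surface: four identical
  # segments give IQR 0, so the whisker equals the common band power
  seg <- gen_rhythm("vf", seed = 64)
  shock <- segment_collection(lapply(1:4, function(i) {
    s <- seg; s$subject_id <- paste0("s", i); s
  }))
  nonshock <- segment_collection(lapply(1:4, function(i)
    gen_rhythm("nsr", seed = 70 + i, subject_id = paste0("n", i))))
  rep <- calibrate_threshold(shock, nonshock)
  expect_equal(rep$shockable_upper_whisker, rep$shockable_mean,
               tolerance = 1e-12)
})

test_that("evaluate_dataset aggregates match hand-computed statistics", {
  pools <- make_pools(1, 2, 1, seed = 61)
  cleans <- segment_collection(list(pools$nonshock[[1]], pools$nonshock[[2]],
                                    pools$shock[[1]]))
  ds <- build_dataset(cleans, pools$arts, -3)
  cfg <- filter_config(power_threshold = 0.005)

  # identity "filter": conditioning only
  ident <- function(seg, cfg) preprocess_ecg(seg, cfg$preprocess)
  out <- evaluate_dataset(ds, cleans, cfg, filter_fun = ident)
  expect_equal(out$per_segment$snr_improvement_db, rep(0, 3), tolerance = 1e-9)
  expect_equal(out$per_segment$psd_corr_corrupted,
               out$per_segment$psd_corr_filtered, tolerance = 1e-12)
  expect_equal(out$per_segment$highly_correlated_before,
               out$per_segment$highly_correlated_after)

  # hand-computed per-class aggregates on the real filter
  out2 <- evaluate_dataset(ds, cleans, cfg)
  cls <- ifelse(out2$per_segment$label %in% c("vf", "rapid_vt"),
                "shockable", "non_shockable")
  for (cl in unique(cls)) {
    idx <- cls == cl
    row <- out2$summary[out2$summary$class == cl, ]
    expect_equal(row$mean_snr_improvement_db,
                 mean(out2$per_segment$snr_improvement_db[idx]))
    expect_equal(row$pct_high_corr_after,
                 100 * mean(out2$per_segment$highly_correlated_after[idx]))
    expect_equal(row$n, sum(idx))
  }

  # single-segment dataset: aggregates equal the single values
  one <- build_dataset(segment_collection(list(cleans[[1]])),
                       segment_collection(list(pools$arts[[1]])), -3)
  o1 <- evaluate_dataset(one, segment_collection(list(cleans[[1]])), cfg)
  expect_equal(o1$summary$mean_snr_improvement_db,
               o1$per_segment$snr_improvement_db)

  # unresolvable manifest entries are named
  bad <- ds
  bad$manifest$clean_index[2] <- 99L
  expect_error(evaluate_dataset(bad, cleans, cfg), "not resolvable")
})
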