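# Example run configuration for cpr-suppress / load_run_config().
# Unknown keys are rejected; omitted keys keep package defaults.
preprocess:
  notch_freq: 60        # Hz, powerline
  notch_q: 30
  wavelet_name: db6
  decomposition_levels: 10
  smoothing_window: 5   # samples, odd
filter:
  power_threshold: 0.07       # 10-15 Hz band power gate (unit-std scale)
  cc_band: [1, 3]             # compression fundamental search band, Hz
  shockable_band: [3, 6]      # protected band, Hz
  low_fundamental_cut: 1.5    # Hz
  stopband_halfwidth: 0.5     # Hz
  amplitude_normalization: unit_std
  strict_end_after_cond2: false
welch:
  window_s: 4
  overlap: 0.5
peaks:
  band: [0.5, 30]
  min_separation: 0.5
harmonic:
  rel_tol: 0.08
  max_order: 3
evaluation:
  corr_band: [0.5, 30]
seed: 1
log_level: info
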