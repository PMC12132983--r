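# Default severity bands and plausibility ranges for the pattern
# classifier. Excess bands are absolute percentage-point differences of
# fractions against the pooled all-facility reference; IQR shrinkage is
# relative to the facility's own IQR.
skipper_bands: {mild: 0.05, moderate: 0.10, severe: 0.30}
repeater_freq_bands: {mild: 0.05, moderate: 0.10, severe: 0.30}
iqr_shrink_bands: {mild: 0.25, moderate: 0.50, severe: 1.00}
wrong_z_bands: {mild: 0.05, moderate: 0.10, severe: 0.30}
plausible_ranges:
  temperature: [35.5, 38.0]
  muac: [11, 18]
  heart_rate: [80, 160]
  resp_rate: [20, 50]
  spo2: [92, 100]
excess_scale: absolute
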