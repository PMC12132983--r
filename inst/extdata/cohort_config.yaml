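# Demonstration cohort: 16 health centres, ~20,000 consultations, with a
# handful of facilities carrying injected measurement behaviours so the
# downstream pattern matrix is non-trivial. Seed is supplied at run time.
n_facilities: 16
n_per_facility: 1255
p_respiratory: 0.35
behaviors:
  - {hc: HC-02, sign: heart_rate, type: skipper, intensity: 0.22}
  - {hc: HC-02, sign: spo2, type: mono_repeater, intensity: 0.25, targets: [97]}
  - {hc: HC-03, sign: muac, type: skipper, intensity: 0.15}
  - {hc: HC-03, sign: resp_rate, type: multi_repeater, intensity: 0.35,
     targets: [34, 35, 36]}
  - {hc: HC-05, sign: height, type: skipper, intensity: 0.12}
  - {hc: HC-05, sign: weight, type: wrongly_evaluated, intensity: 0.25}
  - {hc: HC-10, sign: temperature, type: mono_repeater, intensity: 0.12,
     targets: [36.8]}
  - {hc: HC-15, sign: resp_rate, type: skipper, intensity: 0.40}
  - {hc: HC-15, sign: muac, type: wrongly_evaluated, intensity: 0.20}
  - {hc: HC-15, sign: heart_rate, type: mono_repeater, intensity: 0.20,
     targets: [120]}
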