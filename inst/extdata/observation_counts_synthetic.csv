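sign,n_total,n_skipped,n_sufficient,n_insufficient
temperature,188,14,48,126
muac,176,31,23,122
weight,188,25,31,132
height,188,39,48,101
heart_rate,89,33,29,27
spo2,82,27,28,27
resp_rate,136,58,47,31
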