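sign,method,n,n_sufficient
resp_rate,rrate,39,29
resp_rate,timer,39,18
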