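# Noise-free linear regime: the next-day target is an exact linear function
# of pm25(t), minat(t) and maxap(t); used for parameter-recovery checks.
n_days: 1000
phi: 0.6
beta_T: -0.5
beta_P: 0.4
c0: 23
noise_sd: 0
multiscale: false
seed: 1
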