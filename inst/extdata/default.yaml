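# Default synthetic study conditions: ~7 years of seasonal, AR(1) PM2.5
# coupled negatively to minimum temperature and positively to maximum
# pressure.
n_days: 2556
phi: 0.6
beta_T: -0.5
beta_P: 0.4
c0: 23
noise_sd: 6
multiscale: false
seed: 1
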