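# Adds a weekly oscillation to PM2.5 on top of the default regime: the
# setting in which wavelet detail components carry predictive signal.
n_days: 730
phi: 0.6
beta_T: -0.5
beta_P: 0.4
c0: 23
noise_sd: 6
multiscale: true
multiscale_amplitude: 8
multiscale_period: 7
seed: 1
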