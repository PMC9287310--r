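# Example borrowing-model configuration (see read_model_config()).
# Survival endpoint with the default half-Cauchy(0, 25) prior on the
# commensurability precision and production MCMC settings.
endpoint: pfs
tau_family: half_cauchy
tau_params: [0, 25]
effect_mean: 0
effect_sd: 1
shape_prior_rate: 10
chains: 3
burn_in: 1000
production: 20000
seed: 314
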