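# Shared fixtures: the published default parameter set and frozen oracle
# values computed independently with 40-digit arithmetic (mpmath) from the
# closed-form model definitions.

tf_params <- thermofruit_params()

oracle <- list(
  beta = 1.662087118478963,
  alpha = 0.2770145197464938,
  n_pollen_30 = 39691.44293556308,
  n_pollen_14 = 52110.32595813555,
  n_pollen_22 = 61322.57946083684,
  f_viable_30_4 = 0.08666666666666667,
  n_germ_control = 19261.54,
  n_seeds_control = 33.048464,
  mass_control = 4.637780192,
  mass_30_4 = 2.23394)

# small noise-free table reused across estimation tests
sim_noise_free <- function(seed = 1) {
  simulate_experiment(noise = zero_noise(), seed = seed)
}
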