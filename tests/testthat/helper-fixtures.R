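# Shared fixtures: small correlation models and surrogate draws.

modular_model <- function(sizes = c(3, 3), rho_within = 0.5,
                          rho_between = 0) {
  build_correlation(correlation_spec(sum(sizes), "modular",
                                     module_sizes = sizes,
                                     rho_within = rho_within,
                                     rho_between = rho_between))
}

random_model <- function(n = 5, n_factors = 2, seed = 11) {
  build_correlation(correlation_spec(n, "random_factor",
                                     n_factors = n_factors, seed = seed))
}

null_draw <- function(model, t_len, seed = 1) {
  sample_bold(surrogate_spec(model, t_len, seed = seed))
}

# z-scored surrogate draw
zdraw <- function(model, t_len, seed = 1) {
  zscore_bold(null_draw(model, t_len, seed))
}
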