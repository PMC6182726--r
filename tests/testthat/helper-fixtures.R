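# shared fixtures: small model configurations built in code

# one-pool parent (no metabolite conversion) for analytic oracles
collapse_model <- function(V = 40, CL = 8, ka = 0.24, t_lag = 1.33,
                           F = 0.459, fa_Fg = 0.832) {
  parent <- compound_params("AT", 277.4, 11.77, 0.0012,
                            CL_int_h = 0, CL_other = CL)
  build_pbpk_model(collapse_physiology(V),
                   parent, nortriptyline_params(),
                   absorption_params(ka, t_lag, F, fa_Fg))
}

full_model <- function(absorption = default_absorption()) {
  build_pbpk_model(default_physiology(), amitriptyline_params(),
                   nortriptyline_params(), absorption)
}

# closed-form single-dose one-compartment profile with first-order input
bateman_ngml <- function(t, dose, F, ka, ke, V, t_lag) {
  tt <- pmax(t - t_lag, 0)
  ifelse(t > t_lag,
         F * dose * ka / (V * (ka - ke)) * (exp(-ke * tt) - exp(-ka * tt)),
         0) * 1000
}

# short pacing protocol for unit tests (APD read after 12 beats)
fast_protocol <- function(cl_ms = 1000, ...) {
  pacing_protocol(cl_ms = cl_ms, n_beats = 12, ...)
}

example_blocks <- function() {
  load_channel_blocks(system.file("extdata",
                                  "channel_blocks_synthetic.yaml",
                                  package = "cardiopbpk"))
}
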