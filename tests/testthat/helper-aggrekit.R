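# Shared fixture builders (all generated in code; no stored data)

# noiseless normalized autocatalytic trace on an hourly grid
make_model_trace <- function(rho, k, t_grid = 0:36, replicate_id = "r1") {
  simulate_aggregation_trace(rho, k, t_grid = t_grid, noise_sd = 0,
                             replicate_id = replicate_id)
}

# noiseless titration from the static-quenching model
make_titration <- function(k_b, n = 1, temperature_c = 25, f0 = 1000,
                           q_grid = c(0, seq(2e-6, 20e-6, 2e-6))) {
  simulate_quench_titration(k_b, n = n, f0 = f0, q_grid = q_grid,
                            temperature_c = temperature_c, noise_sd = 0)
}

temp_csv <- function() tempfile(fileext = ".csv")
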