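# shared fixture builders (all synthetic, generated at test time)

make_disk <- function(dim, center_row, center_col, radius, value) {
  rows <- matrix(seq_len(dim[1]), dim[1], dim[2])
  cols <- matrix(seq_len(dim[2]), dim[1], dim[2], byrow = TRUE)
  value * ((rows - center_row)^2 + (cols - center_col)^2 <= radius^2)
}

# normalized FRAP trace group straight from the two-pool model
norm_group <- function(plateau, n, seed, noise_sd = 0.05,
                       fast_fraction = 0.4, half_fast = 60,
                       half_slow = 1200) {
  simulate_normalized_traces(
    recovery_model(plateau, fast_fraction, half_fast, half_slow),
    n_traces = n, noise_sd = noise_sd, seed = seed)
}

# normalized traces produced by the full raw-trace pipeline
pipeline_group <- function(plateau, n, seed, noise_sd = 0.05) {
  cfg <- frap_sim_config(
    recovery_model = recovery_model(plateau, 0.4, 60, 1200),
    noise_sd = noise_sd, n_boutons = n, seed = seed)
  lapply(simulate_frap_trace(cfg)$traces, normalize_trace)
}

# brute-force residual SS of the double-exponential model on (t, v)
biexp_ss_direct <- function(p, f, hf, hs, t, v) {
  r <- p * (f * (1 - 2^(-t / hf)) + (1 - f) * (1 - 2^(-t / hs)))
  sum((v - r)^2)
}
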