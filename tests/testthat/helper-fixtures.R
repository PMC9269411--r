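# Shared fixtures: a reference cell, quiet generator settings, and helpers
# used across test files. Everything is built in code at test time.

fix_rf <- function() rf_geometry(mdf_length = 2, mdf_width = 1,
                                 srf_extent = 5)

# near-noiseless, non-spiking parameter set for deterministic oracles
quiet_params <- function(...) {
  generator_params(noise_sigma = 1e-9, spike_threshold = 100, ...)
}

# conditioned, rest-subtracted trial matrix for a sequence
sim_matrix <- function(sq, rf, p, seeds, pad_ms = 300) {
  trs <- lapply(seeds, function(s) simulate_trial(sq, rf, p, seed = s,
                                                  pad_ms = pad_ms))
  cm <- condition_trials(trs, despike = FALSE)
  cm$vm <- cm$vm - p$v_rest
  cm
}

# blank-referenced isolated-ring trials of the radial protocol (SECTOR, ISO)
radial_isolated_trials <- function(proto, rf, p, n_trials, seed0,
                                   pad_ms = 600) {
  ct <- condition_table(proto)
  out <- list()
  for (k in seq_len(proto$rings)) {
    e <- ct$entry[ct$condition == paste0("GP-ISO-D", k) &
                    ct$configuration == "SECTOR"]
    cm <- sim_matrix(proto$condition_set[[e]], rf, p,
                     seeds = seed0 + 100 * k + seq_len(n_trials),
                     pad_ms = pad_ms)
    out[[paste0("D", k)]] <- list(time_ms = cm$time_ms, vm = cm$vm)
  }
  out
}

radial_entry <- function(proto, condition, configuration, trajectory) {
  ct <- condition_table(proto)
  e <- ct$entry[ct$condition == condition &
                  ct$configuration == configuration &
                  ct$trajectory == trajectory][1]
  proto$condition_set[[e]]
}
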