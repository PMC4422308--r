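# Shared fixtures, all generated in code.

# small noiseless simulation config for fast deterministic tests
quiet_config <- function(seed = 1, amp = rep(0.05, 24), sd = 0,
                         noise = noise_model(
                           white_sd = 0, drift_slope_sd = 0,
                           sinusoids = data.frame(freq = numeric(0),
                                                  amp = numeric(0)),
                           spike_rate_per_min = 0),
                         ...) {
  simulation_config(
    seed = seed,
    effects = list(case = group_effect_profile(amp, sd),
                   control = group_effect_profile(amp, sd)),
    noise = noise, ...)
}

# tiny recording: n_ch channels of supplied rows (or zeros)
make_recording <- function(mat, fs = 10, id = "s01", start_time = 0) {
  nirs_recording(id, list(oxy = mat, deoxy = -mat / 3),
                 sampling_rate = fs, unit = "hb_mM_mm",
                 start_time = start_time)
}

# per-channel statistic-level study draw at the reference effect profiles
draw_channel_stats <- function(profile_mean, profile_se, n = 10) {
  matrix(rnorm(n * length(profile_mean), rep(profile_mean, each = n),
               rep(profile_se * sqrt(10), each = n)),
         nrow = n)
}
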