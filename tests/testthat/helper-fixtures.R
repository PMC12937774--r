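# shared fixtures: tiny deterministic inputs built in code

fs_default <- 1000

unit_sine <- function(f, dur = 2, fs = fs_default, phase = 0) {
  sin(2 * pi * f * (0:(dur * fs - 1)) / fs + phase)
}

# a quiet profile: pure 1/f background only
background_profile <- function(chi = 1.5, offset = 0.5, noise_sd = 1e-4) {
  subject_profile("bg", "HC", aperiodic_exponent = chi,
                  aperiodic_offset = offset, beta_amp = 0, burst_rate = 0.1,
                  burst_mean_dur = 0.05, pac_depth = 0, shape_asym = 0,
                  noise_sd = noise_sd)
}

# reduced cohort for pipeline smoke tests: 2 HC + 2 PD, few trials
mini_config <- function(n_trials = 30L, master_seed = 77L) {
  cohort_config(n_hc = 2L, n_pd = 2L, n_trials = n_trials,
                master_seed = master_seed)
}

# single synthetic trial from a fixed profile
mini_trial <- function(seed = 11L, delta = 0, group = "PD",
                       channels = default_montage()) {
  prof <- subject_profile("t01", group, seed = 42L)
  spec <- stimulus_spec(5L, "sinusoid", list(carrier_hz = 10), 1, 2L, "sin")
  simulate_trial(prof, spec, delta, seed = seed, channels = channels)
}
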