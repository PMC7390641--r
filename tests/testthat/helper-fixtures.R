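# Shared fixtures: all synthetic, built in code at test time.

# Study-condition kinematics/geometry: motion from t = 10 s, ten 12-s cycles.
default_kin <- function(...) stimulus_kinematics(t_move_start = 10, ...)
default_geo <- function() eye_geometry()

# A short two-cycle stimulus for image-stack fixtures.
short_kin <- function(...) {
  stimulus_kinematics(n_cycles = 2, t_move_start = 2, dwell_per_cycle = 2,
                      ...)
}

# One synthetic trial under the study conditions.
quick_trial <- function(dd_true = 5, tau_decay = 0.7, amplitude = 0.2,
                        noise_sd = 0, seed = NULL, kin = default_kin(),
                        geo = default_geo(), latency = 0) {
  truth <- synthetic_truth(dd_true, kernel_params(0.05, tau_decay,
                                                  amplitude),
                           latency = latency, noise_sd = noise_sd)
  simulate_trial(truth, kin, geo, seed = seed)
}

# A bare trace holding a single analytic Gaussian-shaped peak.
gaussian_trace <- function(sigma = 0.4, center = 10, base = 100, amp = 20,
                           frame_period = 0.05, t_end = 20) {
  times <- seq(0, t_end, by = frame_period)
  fluorescence_trace(times, base + amp * exp(-(times - center)^2 /
                                               (2 * sigma^2)), frame_period)
}

expect_sorted <- function(x) expect_true(!is.unsorted(x))
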