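# Shared fixture builders (all generated in code, seeded).

# Epoch matrix of simulated LFP windows with configurable theta/gamma.
make_lfp_epochs <- function(n_epochs, window = c(-750, 50), buffer_ms = 0,
                            theta_amp = 1, gamma_amp = 0.25,
                            coupling_depth = 0, seed = 1, spacing_s = 1.2,
                            ...) {
  dur <- n_epochs * spacing_s + 2 * (buffer_ms / 1000 + 2.1)
  cfg <- sim_config(duration_s = dur, theta_amp = theta_amp,
                    gamma_amp = gamma_amp, coupling_depth = coupling_depth,
                    seed = seed, ...)
  sim <- simulate_lfp(cfg)
  margin <- 1000 * (buffer_ms / 1000 + 2)
  on <- seq(margin, dur * 1000 - margin, length.out = n_epochs)
  extract_epochs(sim$recording, on, window = window, buffer_ms = buffer_ms)
}

# Gaze record with scripted fixation positions/durations (no LFP needed).
make_scripted_gaze <- function(fix, duration_s = NULL, seed = 1) {
  if (is.null(duration_s)) {
    duration_s <- (max(fix$onset_ms + fix$duration_ms) + 500) / 1000
  }
  cfg <- sim_config(duration_s = duration_s, blink_rate = 0, seed = seed)
  simulate_gaze(cfg, fix)
}
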