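# Shared fixtures, built in code.

# Noise-free stage ground truth (means of the reference table).
stage_truth <- function(stage) sample_stage_parameters(stage, 1, sd_scale = 0)

# Free-decay trace for given modal parameters at a chosen sampling rate.
decay_trace <- function(f, xi, fs = 10000, duration = 2,
                        convention = "log-decrement-consistent") {
  gt <- data.frame(natural_frequency = f, damping_ratio = xi)
  generate_displacement(gt, excitation_config(
    forced_duration = 0, decay_duration = duration, sampling_rate = fs,
    envelope_convention = convention, noise_sd = 0))
}

# Single rendered frame of the default ellipse at a given sub-pixel shift.
render_shifted_frame <- function(shift, cfg = render_config()) {
  tr <- displacement_trace(c(0, 1e-3), c(0, shift), 1000)
  render_frames(tr, cfg)$frames[, , 2]
}

# Brute-force re-evaluation of the logarithmic decrement for one (i, j)
# pair, written independently of the package estimator.
brute_log_decrement <- function(amp, i, j) {
  log(amp[i] / amp[i + j]) / (2 * pi * j)
}

# Closed-form mean of a truncated normal (independent oracle for the
# stage samplers; the upper damping bound matters for the overripe stage).
trunc_norm_mean <- function(mu, sd, lower = -Inf, upper = Inf) {
  a <- (lower - mu) / sd; b <- (upper - mu) / sd
  mu + sd * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
}
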