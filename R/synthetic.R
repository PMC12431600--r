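# Synthetic vibrating-fruit cohorts, displacement signals and ground truth.

# Stage-level reference statistics for Hayward kiwifruit across ripening:
# firmness (MPa), natural frequency (Hz) and damping ratio, as mean +/- SD,
# together with plausible mass/diameter ranges for the cultivar.
.stage_table <- data.frame(
  stage            = c("unripe", "semi-ripe", "ripe", "overripe"),
  firmness_mean    = c(14.41, 10.37, 6.56, 2.51),
  firmness_sd      = c(0.8, 0.6, 0.5, 0.5),
  frequency_mean   = c(272, 244, 239, 223),
  frequency_sd     = c(0.9, 1.4, 1.3, 1.9),
  damping_mean     = c(0.394, 0.501, 0.631, 0.957),
  damping_sd       = c(0.09, 0.05, 0.06, 0.04),
  stringsAsFactors = FALSE
)

#' Reference ripening-stage statistics
#'
#' Mean and standard deviation of firmness (MPa), natural frequency (Hz) and
#' damping ratio for the four ripening stages (unripe, semi-ripe, ripe,
#' overripe) that the synthetic cohort generator emulates.
#'
#' @return A data frame with one row per ripening stage.
#' @export
stage_parameters <- function() .stage_table

.stage_row <- function(stage) {
  i <- match(stage, .stage_table$stage)
  if (is.na(i)) {
    stop("unknown stage label '", stage, "'; expected one of: ",
         paste(.stage_table$stage, collapse = ", "))
  }
  .stage_table[i, ]
}

# Correlated stage draws through a Gaussian copula.  `rho` couples the
# firmness deviate to the modal deviates (positive for frequency, negated
# for damping, which rises as tissue softens); marginals are exact
# truncated normals with the stage means and sd_scale * stage SDs.
.sample_stage <- function(stage, n, sd_scale = 1, rho = 0) {
  row <- .stage_row(stage)
  stopifnot(n >= 1, sd_scale >= 0, abs(rho) <= 1)
  z0 <- rnorm(n)
  zf <- rho * z0 + sqrt(1 - rho^2) * rnorm(n)
  zx <- -rho * z0 + sqrt(1 - rho^2) * rnorm(n)
  data.frame(
    stage = rep(stage, n),
    firmness = ztruncnorm(z0, row$firmness_mean,
                          sd_scale * row$firmness_sd, lower = 0),
    natural_frequency = ztruncnorm(zf, row$frequency_mean,
                                   sd_scale * row$frequency_sd, lower = 0),
    damping_ratio = ztruncnorm(zx, row$damping_mean,
                               sd_scale * row$damping_sd,
                               lower = 0, upper = 1),
    mass = rtruncnorm(n, 0.100, sd_scale * 0.010, lower = 0),
    diameter = rtruncnorm(n, 0.065, sd_scale * 0.004, lower = 0),
    stringsAsFactors = FALSE
  )
}

#' Sample per-fruit ground truth for one ripening stage
#'
#' Draws firmness (MPa), natural frequency (Hz) and damping ratio
#' independently from truncated normal distributions with the stage means
#' and `sd_scale` times the stage standard deviations
#' (see [stage_parameters()]). Damping is truncated to (0, 1), the other
#' quantities to the positive reals. `sd_scale = 0` returns the stage means
#' exactly. Mass (kg) and diameter (m) are drawn from cultivar-typical
#' distributions; they are recorded but unused downstream.
#'
#' @param stage One of `"unripe"`, `"semi-ripe"`, `"ripe"`, `"overripe"`.
#' @param n Number of fruits to draw.
#' @param sd_scale Non-negative multiplier on the stage standard deviations.
#' @param seed Integer seed; draws are reproducible given the seed.
#' @return A data frame with columns `fruit_id`, `stage`, `firmness`,
#'   `natural_frequency`, `damping_ratio`, `mass`, `diameter`.
#' @export
sample_stage_parameters <- function(stage, n, sd_scale = 1, seed = 1) {
  out <- withr::with_seed(seed, .sample_stage(stage, n, sd_scale, rho = 0))
  cbind(fruit_id = paste0(stage, "_", seq_len(n)), out,
        stringsAsFactors = FALSE)
}

#' Interpolate modal parameters from firmness
#'
#' Piecewise-linear monotone map through the four stage mean pairs
#' (firmness, natural frequency) and (firmness, damping ratio). Firmness
#' outside the anchored range (2.51 to 14.41 MPa) is clamped with a warning.
#' Natural frequency is non-decreasing and damping non-increasing in
#' firmness.
#'
#' @param firmness Positive firmness values in MPa.
#' @return A data frame with columns `natural_frequency` (Hz) and
#'   `damping_ratio`.
#' @export
firmness_to_modal <- function(firmness) {
  if (any(!is.finite(firmness)) || any(firmness <= 0)) {
    stop("firmness must be positive and finite")
  }
  tab <- .stage_table[order(.stage_table$firmness_mean), ]
  lo <- min(tab$firmness_mean); hi <- max(tab$firmness_mean)
  if (any(firmness < lo) || any(firmness > hi)) {
    warning(sprintf("firmness clamped to the anchored range [%.2f, %.2f] MPa",
                    lo, hi))
    firmness <- pmin(pmax(firmness, lo), hi)
  }
  data.frame(
    natural_frequency = stats::approx(tab$firmness_mean, tab$frequency_mean,
                                      xout = firmness)$y,
    damping_ratio = stats::approx(tab$firmness_mean, tab$damping_mean,
                                  xout = firmness)$y
  )
}

#' Excitation configuration for the signal simulator
#'
#' The simulated protocol is a forced steady sinusoid at the fruit's natural
#' frequency followed by free decay, 20 s in total by default, sampled at
#' 1000 samples per second.
#'
#' @param forced_duration Seconds of forced (steady-amplitude) excitation.
#' @param decay_duration Seconds of free decay after the excitation stops.
#' @param sampling_rate Samples per second.
#' @param forced_amplitude Steady-state displacement amplitude in px.
#' @param envelope_convention `"log-decrement-consistent"` (decay envelope
#'   `exp(-2 pi xi f t)` so successive displacement peaks have ratio
#'   `exp(2 pi xi)` and the logarithmic decrement recovers `xi` exactly) or
#'   `"physical-sdof"` (envelope `exp(-xi w_n t)` with ringing at the damped
#'   frequency `w_n sqrt(1 - xi^2)`).
#' @param noise_sd Additive Gaussian noise SD in px.
#' @param seed Integer seed for the noise draws.
#' @return An object of class `excitation_config`.
#' @export
excitation_config <- function(forced_duration = 18, decay_duration = 2,
                              sampling_rate = 1000, forced_amplitude = 1,
                              envelope_convention = c("log-decrement-consistent",
                                                      "physical-sdof"),
                              noise_sd = 0, seed = 1) {
  envelope_convention <- match.arg(envelope_convention)
  stopifnot(forced_duration >= 0, decay_duration > 0, sampling_rate > 0,
            forced_amplitude > 0, noise_sd >= 0)
  structure(list(forced_duration = forced_duration,
                 decay_duration = decay_duration,
                 sampling_rate = sampling_rate,
                 forced_amplitude = forced_amplitude,
                 envelope_convention = envelope_convention,
                 noise_sd = noise_sd, seed = seed),
            class = "excitation_config")
}

#' Simulate a surface-displacement signal for one fruit
#'
#' Generates a forced steady sinusoid at the fruit's natural frequency for
#' `forced_duration` seconds, then a free decay for `decay_duration`
#' seconds, phase-continuous at the switch. Under the
#' `log-decrement-consistent` convention the decay is
#' `A exp(-2 pi xi f (t - t0)) cos(2 pi f t)`; under `physical-sdof` it is
#' `A exp(-xi w_n (t - t0)) cos(w_d (t - t0) + phi0)` with
#' `w_d = w_n sqrt(1 - xi^2)`.
#'
#' @param gt A one-row data frame or list with `natural_frequency` (Hz) and
#'   `damping_ratio`, e.g. from [sample_stage_parameters()].
#' @param cfg An [excitation_config()].
#' @return A [displacement_trace()] with the forced/decay switch time
#'   recorded in its `forced_duration` field.
#' @export
generate_displacement <- function(gt, cfg = excitation_config()) {
  f <- gt$natural_frequency[1]
  xi <- gt$damping_ratio[1]
  stopifnot(is.finite(f), f > 0, is.finite(xi), xi >= 0, xi < 1)
  if (cfg$sampling_rate <= 2 * f) {
    stop("sampling_rate must exceed twice the natural frequency (Nyquist)")
  }
  fs <- cfg$sampling_rate
  n <- round((cfg$forced_duration + cfg$decay_duration) * fs)
  t <- (seq_len(n) - 1) / fs
  A <- cfg$forced_amplitude
  t0 <- cfg$forced_duration
  forced <- t < t0
  x <- numeric(n)
  x[forced] <- A * cos(2 * pi * f * t[forced])
  td <- t[!forced] - t0
  if (cfg$envelope_convention == "log-decrement-consistent") {
    # envelope chosen so the per-cycle peak ratio is exp(2 pi xi) exactly
    x[!forced] <- A * exp(-2 * pi * xi * f * td) * cos(2 * pi * f * t[!forced])
  } else {
    wn <- 2 * pi * f
    wd <- wn * sqrt(1 - xi^2)
    phi0 <- 2 * pi * f * t0   # phase continuity at the switch
    x[!forced] <- A * exp(-xi * wn * td) * cos(wd * td + phi0)
  }
  if (cfg$noise_sd > 0) {
    x <- x + withr::with_seed(cfg$seed, rnorm(n, 0, cfg$noise_sd))
  }
  displacement_trace(t, x, fs, forced_duration = t0, ground_truth = gt)
}

#' Generate a stage-stratified synthetic cohort
#'
#' Draws a cohort of fruits across the four ripening stages. Marginally,
#' firmness, natural frequency and damping ratio follow the stage truncated
#' normals of [stage_parameters()] scaled by `sd_scale`; within a stage the
#' modal parameters are coupled to firmness through a Gaussian copula with
#' correlation `modal_correlation` (positive with frequency, negative with
#' damping), reflecting that softer individuals within a stage vibrate at
#' lower frequency with higher damping.
#'
#' @param n Cohort size (default 120, at least 4).
#' @param stage_mix Proportions over the four stages (must sum to 1).
#' @param sd_scale Multiplier on the stage standard deviations.
#' @param modal_correlation Within-stage copula correlation in `[0, 1]`.
#' @param seed Integer seed.
#' @return A list with `ground_truth` (per-fruit data frame) and `features`
#'   (data frame `fruit_id`, `stage`, `damping_ratio`,
#'   `natural_frequency_hz`, `firmness_mpa`).
#' @export
generate_cohort <- function(n = 120, stage_mix = rep(0.25, 4), sd_scale = 1,
                            modal_correlation = 0.9, seed = 1) {
  stopifnot(n >= 4, length(stage_mix) == 4, all(stage_mix >= 0))
  if (abs(sum(stage_mix) - 1) > 1e-8) stop("stage_mix must sum to 1")
  counts <- floor(n * stage_mix)
  # distribute remaining fruits to the largest fractional parts
  rem <- n - sum(counts)
  if (rem > 0) {
    frac <- n * stage_mix - counts
    add <- order(frac, decreasing = TRUE)[seq_len(rem)]
    counts[add] <- counts[add] + 1
  }
  gt <- withr::with_seed(seed, {
    parts <- lapply(seq_along(counts), function(k) {
      if (counts[k] == 0) return(NULL)
      .sample_stage(.stage_table$stage[k], counts[k], sd_scale,
                    rho = modal_correlation)
    })
    do.call(rbind, parts)
  })
  gt <- cbind(fruit_id = sprintf("fruit_%03d", seq_len(nrow(gt))), gt,
              stringsAsFactors = FALSE)
  features <- data.frame(
    fruit_id = gt$fruit_id,
    stage = gt$stage,
    damping_ratio = gt$damping_ratio,
    natural_frequency_hz = gt$natural_frequency,
    firmness_mpa = gt$firmness,
    stringsAsFactors = FALSE
  )
  list(ground_truth = gt, features = features)
}
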