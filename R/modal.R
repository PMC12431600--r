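# Modal feature extraction: damping ratio via the logarithmic decrement and
# natural frequency via the FFT magnitude-spectrum peak.

#' Construct a displacement trace
#'
#' A uniformly sampled surface-displacement time series.
#'
#' @param time Times in seconds, uniformly spaced.
#' @param value Displacement values (px, or mm when a pixel scale is known).
#' @param sampling_rate Samples per second.
#' @param forced_duration Seconds of forced excitation preceding free decay,
#'   if known (`NA` when unknown; triggers auto-detection downstream).
#' @param ground_truth Optional generating parameters, kept for round-trip
#'   tests.
#' @return An object of class `displacement_trace`.
#' @export
displacement_trace <- function(time, value, sampling_rate,
                               forced_duration = NA_real_,
                               ground_truth = NULL) {
  stopifnot(length(time) == length(value), sampling_rate > 0)
  structure(list(time = as.numeric(time), value = as.numeric(value),
                 sampling_rate = sampling_rate,
                 forced_duration = forced_duration,
                 ground_truth = ground_truth),
            class = "displacement_trace")
}

#' @export
print.displacement_trace <- function(x, ...) {
  cat(sprintf("<displacement_trace> %d samples at %g Hz (%.3f s)\n",
              length(x$value), x$sampling_rate,
              length(x$value) / x$sampling_rate))
  invisible(x)
}

# 3-point parabolic refinement of a local maximum at index i.
# Returns c(time_offset_in_samples, refined_amplitude).
.parabolic_refine <- function(y, i) {
  if (i <= 1L || i >= length(y)) return(c(0, y[i]))
  a <- y[i - 1L]; b <- y[i]; c <- y[i + 1L]
  denom <- a - 2 * b + c
  if (denom >= 0) return(c(0, b))  # not locally concave; keep the sample
  d <- 0.5 * (a - c) / denom
  c(d, b - 0.25 * (a - c) * d)
}

#' Detect oscillation peaks in a displacement trace
#'
#' Finds successive positive interior local maxima, optionally refined by
#' three-point parabolic interpolation of both time and amplitude. Peaks
#' smaller than `min_peak_ratio` times the largest detected peak are
#' discarded (guards against numerically negligible late peaks of strongly
#' damped decays and against noise).
#'
#' @param trace A [displacement_trace()].
#' @param segment Optional `c(t_start, t_end)` in seconds restricting the
#'   search; default is the whole trace.
#' @param interpolate Refine peak time/amplitude parabolically
#'   (default `TRUE`).
#' @param detrend Subtract a least-squares line before peak picking
#'   (default `FALSE`; a fitted line perturbs the small late peaks of
#'   strongly damped decays).
#' @param min_peak_ratio Relative amplitude floor (default `1e-3`).
#' @return An object of class `peak_series`: list with `time` and
#'   `amplitude`, strictly increasing in time.
#' @export
detect_peaks <- function(trace, segment = NULL, interpolate = TRUE,
                         detrend = FALSE, min_peak_ratio = 1e-3) {
  stopifnot(inherits(trace, "displacement_trace"))
  t <- trace$time; x <- trace$value
  if (!is.null(segment)) {
    keep <- t >= segment[1] & t <= segment[2]
    if (!any(keep)) stop("segment outside trace support")
    t <- t[keep]; x <- x[keep]
  }
  if (detrend) x <- stats::lm.fit(cbind(1, t), x)$residuals
  pk <- pracma::findpeaks(x, nups = 1, ndowns = 1)
  if (is.null(pk) || nrow(pk) < 2) {
    stop("insufficient peaks: fewer than 2 oscillation maxima found")
  }
  idx <- sort(pk[, 2])
  amp <- x[idx]
  pos <- amp > 0
  idx <- idx[pos]; amp <- amp[pos]
  if (length(idx) >= 1) {
    keep <- amp >= min_peak_ratio * max(amp)
    idx <- idx[keep]; amp <- amp[keep]
  }
  if (length(idx) < 2) {
    stop("insufficient peaks: fewer than 2 positive maxima above the floor")
  }
  dt <- 1 / trace$sampling_rate
  if (interpolate) {
    ref <- vapply(idx, function(i) .parabolic_refine(x, i), numeric(2))
    times <- t[idx] + ref[1, ] * dt
    amps <- ref[2, ]
  } else {
    times <- t[idx]
    amps <- amp
  }
  structure(list(time = times, amplitude = amps), class = "peak_series")
}

#' Damping ratio by the logarithmic decrement
#'
#' Computes `xi = ln(x_i / x_{i+j}) / (2 pi j)` from oscillation-peak
#' amplitudes `j` cycles apart. With `i = NULL` (default) the estimate is
#' averaged over all valid starting peaks at the given `j`. The small-
#' damping form above is the default; `method = "exact-sdof"` applies the
#' exact single-degree-of-freedom conversion
#' `xi = delta / sqrt(4 pi^2 + delta^2)` to the per-cycle decrement
#' `delta`.
#'
#' @param peaks A `peak_series` from [detect_peaks()], or a numeric vector
#'   of positive peak amplitudes.
#' @param i Starting peak index (1-based), or `NULL` to average over all
#'   valid pairs.
#' @param j Cycle gap between the paired peaks (default 1).
#' @param method `"log-decrement"` (default) or `"exact-sdof"`.
#' @return The damping ratio estimate.
#' @export
damping_log_decrement <- function(peaks, i = NULL, j = 1,
                                  method = c("log-decrement", "exact-sdof")) {
  method <- match.arg(method)
  x <- if (inherits(peaks, "peak_series")) peaks$amplitude else as.numeric(peaks)
  n <- length(x)
  stopifnot(j >= 1, j == round(j))
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop("peak amplitudes must be positive and finite")
  }
  pair_xi <- function(i1) {
    if (i1 < 1 || i1 + j > n) stop("peak index out of range")
    delta <- log(x[i1] / x[i1 + j]) / j   # per-cycle decrement
    if (method == "log-decrement") delta / (2 * pi)
    else delta / sqrt(4 * pi^2 + delta^2)
  }
  if (!is.null(i)) return(pair_xi(i))
  if (n <= j) stop("need at least j + 1 peaks")
  mean(vapply(seq_len(n - j), pair_xi, numeric(1)))
}

#' FFT magnitude spectrum of a displacement trace
#'
#' Magnitude of the discrete Fourier transform of the mean-removed,
#' linearly detrended trace, zero-padded so the frequency grid has the
#' requested resolution, truncated at `min(f_max, Nyquist)`. No window is
#' applied by default (the forced tone dominates the record).
#'
#' @param trace A [displacement_trace()].
#' @param resolution Frequency-grid spacing in Hz (default 1).
#' @param f_max Upper frequency limit in Hz (default 2000).
#' @return An object of class `spectrum_mag`: list with `frequency`,
#'   `magnitude` and `resolution`.
#' @export
magnitude_spectrum <- function(trace, resolution = 1, f_max = 2000) {
  stopifnot(inherits(trace, "displacement_trace"))
  if (resolution <= 0) stop("resolution must be positive")
  x <- trace$value
  n <- length(x)
  fs <- trace$sampling_rate
  t <- trace$time
  # mean removal + linear detrend
  x <- stats::lm.fit(cbind(1, t), x)$residuals
  m <- fs / resolution                  # grid points per fs
  if (abs(m - round(m)) < 1e-8) {
    m <- round(m)
    nfft <- as.integer(ceiling(n / m) * m)
    stride <- nfft %/% m
  } else {
    nfft <- max(n, as.integer(ceiling(m)))
    stride <- 1L
  }
  xp <- c(x, numeric(nfft - n))
  mag <- Mod(fft(xp))
  half <- seq_len(nfft %/% 2 + 1L)
  freq <- (half - 1L) * fs / nfft
  pick <- seq(1L, length(half), by = stride)
  freq <- freq[pick]; mag <- mag[half][pick]
  lim <- min(f_max, fs / 2)
  keep <- freq <= lim + 1e-9
  structure(list(frequency = freq[keep], magnitude = mag[keep],
                 resolution = fs / nfft * stride),
            class = "spectrum_mag")
}

#' Natural frequency from a magnitude spectrum
#'
#' Default mode `"band-max"` returns the frequency of the largest magnitude
#' inside `band` (ties broken toward the lower frequency). Mode
#' `"first-peak"` returns the first local maximum in the band whose
#' magnitude reaches `prominence` times the in-band maximum.
#'
#' @param spec A `spectrum_mag` from [magnitude_spectrum()].
#' @param band Search band in Hz (default `c(200, 300)`).
#' @param mode `"band-max"` (default) or `"first-peak"`.
#' @param prominence Relative floor for `"first-peak"` (default 0.1).
#' @return A list with `natural_frequency` (Hz) and `peak_magnitude`.
#' @export
natural_frequency <- function(spec, band = c(200, 300),
                              mode = c("band-max", "first-peak"),
                              prominence = 0.1) {
  mode <- match.arg(mode)
  stopifnot(inherits(spec, "spectrum_mag"))
  keep <- spec$frequency >= band[1] & spec$frequency <= band[2]
  if (!any(keep)) stop("band does not intersect the spectrum grid")
  f <- spec$frequency[keep]; m <- spec$magnitude[keep]
  if (mode == "band-max") {
    i <- which.max(m)   # first maximum = lowest frequency on ties
  } else {
    loc <- which(diff(sign(diff(m))) < 0) + 1L
    loc <- loc[m[loc] >= prominence * max(m)]
    if (length(loc) == 0) i <- which.max(m) else i <- loc[1]
  }
  list(natural_frequency = f[i], peak_magnitude = m[i])
}

# Locate the start of free decay when the forced duration is unknown:
# last sample whose rolling RMS still reaches 90% of the plateau RMS.
.detect_decay_start <- function(trace, window_s = 0.05) {
  x <- trace$value
  n <- length(x)
  w <- max(8L, round(window_s * trace$sampling_rate))
  if (w >= n) return(trace$time[1])
  cs <- cumsum(c(0, x^2))
  rms <- sqrt((cs[(w + 1):(n + 1)] - cs[1:(n - w + 1)]) / w)
  ref <- max(rms)
  i <- max(which(rms >= 0.9 * ref))
  trace$time[min(n, i + w - 1L)]
}

#' Extract modal features from a displacement trace
#'
#' Natural frequency comes from the full-trace magnitude spectrum
#' ([magnitude_spectrum()] then [natural_frequency()]); damping comes from
#' the logarithmic decrement averaged over successive peak pairs (j = 1) in
#' the free-decay segment. The decay segment is taken from the trace's
#' recorded `forced_duration` when available and auto-detected from the
#' rolling RMS envelope otherwise. A median baseline is removed from the
#' decay segment before peak picking.
#'
#' @param trace A [displacement_trace()].
#' @param band Frequency search band in Hz (default `c(200, 300)`).
#' @param resolution Spectrum grid spacing in Hz; default 0.05 (zero-padded
#'   fine grid). Use 1 for the coarse reporting grid.
#' @param f_max Spectrum limit in Hz (default 2000).
#' @param j Cycle gap for the decrement (default 1).
#' @param min_peak_ratio Relative peak floor passed to [detect_peaks()].
#' @param method Decrement conversion passed to [damping_log_decrement()].
#' @return A list of class `modal_features` with `damping_ratio`,
#'   `natural_frequency`, `peak_magnitude` and `n_peaks_used`.
#' @export
extract_modal_features <- function(trace, band = c(200, 300),
                                   resolution = 0.05, f_max = 2000, j = 1,
                                   min_peak_ratio = 1e-3,
                                   method = "log-decrement") {
  stopifnot(inherits(trace, "displacement_trace"))
  spec <- magnitude_spectrum(trace, resolution = resolution, f_max = f_max)
  fn <- natural_frequency(spec, band = band)
  t0 <- trace$forced_duration
  if (is.na(t0)) t0 <- .detect_decay_start(trace)
  keep <- trace$time >= t0
  decay <- displacement_trace(trace$time[keep],
                              trace$value[keep] - median(trace$value[keep]),
                              trace$sampling_rate)
  xi <- 0; npk <- 0L
  res <- try(detect_peaks(decay, interpolate = TRUE,
                          min_peak_ratio = min_peak_ratio), silent = TRUE)
  if (inherits(res, "try-error")) {
    warning("insufficient decay oscillation; damping ratio reported as 0")
  } else {
    amp <- res$amplitude
    if (length(amp) > j && max(amp) > 0 &&
        abs(log(amp[1] / amp[min(length(amp), 1 + j)])) < 1e-12) {
      # undamped limit: equal peaks
      xi <- 0; npk <- length(amp)
    } else {
      xi <- damping_log_decrement(res, j = j, method = method)
      npk <- length(amp)
    }
  }
  structure(list(damping_ratio = xi,
                 natural_frequency = fn$natural_frequency,
                 peak_magnitude = fn$peak_magnitude,
                 n_peaks_used = npk),
            class = "modal_features")
}
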