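#' Single-channel EEG container
#'
#' @param samples numeric vector, microvolts.
#' @param fs_hz sampling rate in Hz (recordings of interest are acquired
#'   between 1 and 200 Hz, so fs >= 400 Hz is typical).
#' @param injection_time_s time of the convulsant injection, seconds from
#'   recording start; analysis is aligned to it.
#' @param artifact optional logical vector per sample; `TRUE` marks samples
#'   contaminated by movement/grooming, excluded from epoch power.
#' @return object of class `eeg_signal`.
#' @export
eeg_signal <- function(samples, fs_hz, injection_time_s = 0, artifact = NULL) {
  stopifnot(is.numeric(samples), fs_hz > 0, injection_time_s >= 0)
  if (!is.null(artifact)) stopifnot(length(artifact) == length(samples))
  structure(list(samples = as.numeric(samples), fs_hz = fs_hz,
                 injection_time_s = injection_time_s, artifact = artifact),
            class = "eeg_signal")
}

#' @export
print.eeg_signal <- function(x, ...) {
  cat(sprintf("<eeg_signal> %.1f s at %g Hz, injection at %.1f s\n",
              length(x$samples) / x$fs_hz, x$fs_hz, x$injection_time_s))
  invisible(x)
}

#' Parameters of the EEG simulator
#'
#' The simulated recording is a 1/f^a background plus band-limited
#' sinusoidal oscillations; an optional seizure segment multiplies the
#' signal by `seizure_gain` and superimposes a rhythmic train of sharp
#' biphasic spikes, emulating the high-amplitude electrographic discharge
#' that follows a kainic-acid challenge.
#'
#' @param fs_hz sampling rate (default 500 Hz).
#' @param duration_s recording duration, seconds.
#' @param band_components list of `c(center_hz, amplitude_uv)` pairs.
#' @param noise_exponent slope a of the 1/f^a background.
#' @param noise_sd RMS of the 1/f background in microvolts (0 disables it).
#' @param seizure_onset_s,seizure_offset_s seizure window, seconds from
#'   recording start; `NULL` for a seizure-free recording.
#' @param seizure_gain amplitude multiplier (>= 1) inside the window.
#' @param seizure_spike_rate_hz rate of the superimposed spike train.
#' @param injection_time_s stored in the returned signal.
#' @param seed RNG seed.
#' @return validated list of class `eeg_sim_params`.
#' @export
eeg_sim_params <- function(fs_hz = 500, duration_s = 600,
                           band_components = list(c(2, 20), c(6, 10)),
                           noise_exponent = 2, noise_sd = 15,
                           seizure_onset_s = NULL, seizure_offset_s = NULL,
                           seizure_gain = 3, seizure_spike_rate_hz = 8,
                           injection_time_s = 0, seed = 1L) {
  p <- as.list(environment())
  stopifnot(fs_hz > 0, duration_s > 0, noise_sd >= 0, seizure_gain >= 1)
  fmax <- if (length(band_components))
    max(vapply(band_components, `[`, 0, 1)) else 0
  if (fs_hz < 2 * fmax)
    stop("fs_hz must be at least twice the highest band component (aliasing)")
  if (!is.null(seizure_onset_s)) {
    if (is.null(seizure_offset_s) || seizure_onset_s >= seizure_offset_s ||
        seizure_offset_s > duration_s)
      stop("need seizure onset < offset <= duration")
  }
  class(p) <- "eeg_sim_params"
  p
}

# 1/f^a Gaussian-phase noise via spectral shaping, normalized to unit RMS.
# Power below f_min_hz is removed: the recordings emulated are acquired in
# a 1-200 Hz band, and an unbounded 1/f^2 process would otherwise drift.
one_over_f_noise <- function(n, exponent, fs, f_min_hz = 1) {
  nh <- floor((n - 1) / 2)                 # positive-freq bins excl. DC/Nyquist
  f <- seq_len(nh) * fs / n
  amp <- pmax(f, f_min_hz)^(-exponent / 2)
  amp[f < f_min_hz] <- 0
  phase <- runif(nh, 0, 2 * pi)
  spec <- complex(length.out = n)
  spec[2:(nh + 1)] <- amp * exp(1i * phase)
  if (n %% 2 == 0) spec[n / 2 + 1] <- (fs / 2)^(-exponent / 2)
  spec[n:(n - nh + 1)] <- Conj(spec[2:(nh + 1)])
  x <- Re(fft(spec, inverse = TRUE))
  x / sd(x)
}

#' Simulate an EEG recording with known seizure truth
#'
#' @param params an [eeg_sim_params()] object.
#' @return an [eeg_signal()] with attribute `truth`, a list holding
#'   `onset_s`/`offset_s` (or `NULL`) and the generating parameters.
#' @export
simulate_eeg <- function(params = eeg_sim_params()) {
  stopifnot(inherits(params, "eeg_sim_params"))
  p <- params
  set.seed(p$seed)
  n <- round(p$duration_s * p$fs_hz)
  t <- (seq_len(n) - 1) / p$fs_hz
  x <- numeric(n)
  if (p$noise_sd > 0)
    x <- x + p$noise_sd * one_over_f_noise(n, p$noise_exponent, p$fs_hz)
  for (bc in p$band_components)
    x <- x + bc[2] * sin(2 * pi * bc[1] * t + runif(1, 0, 2 * pi))

  truth <- list(onset_s = NULL, offset_s = NULL, params = p)
  if (!is.null(p$seizure_onset_s)) {
    win <- t >= p$seizure_onset_s & t < p$seizure_offset_s
    x[win] <- x[win] * p$seizure_gain
    # rhythmic sharp spikes: biphasic (Gaussian-derivative) wavelets
    base_rms <- max(p$noise_sd, 1)
    sp_t <- seq(p$seizure_onset_s, p$seizure_offset_s,
                by = 1 / p$seizure_spike_rate_hz)
    sp_t <- sp_t + rnorm(length(sp_t), 0, 0.01)
    width <- 0.02
    for (st in sp_t) {
      lo <- max(1L, ceiling((st - 4 * width) * p$fs_hz) + 1L)
      hi <- min(n, floor((st + 4 * width) * p$fs_hz) + 1L)
      if (lo > hi) next
      idx <- lo:hi
      u <- (t[idx] - st) / width
      x[idx] <- x[idx] - 4 * base_rms * p$seizure_gain * u * exp(-u^2 / 2)
    }
    truth$onset_s <- p$seizure_onset_s
    truth$offset_s <- p$seizure_offset_s
  }
  sig <- eeg_signal(x, p$fs_hz, injection_time_s = p$injection_time_s)
  attr(sig, "truth") <- truth
  sig
}
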