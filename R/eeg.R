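#' Conventional EEG frequency bands
#'
#' Half-open `[f_lo, f_hi)` intervals, non-overlapping and ordered: delta
#' 0.5-4, theta 4-8, alpha 8-12, sigma 12-16, beta 16-24, gamma 24-80 Hz.
#' Fully overridable wherever a `bands` argument is accepted.
#'
#' @return data.frame with columns `name`, `f_lo`, `f_hi`.
#' @export
default_bands <- function() {
  data.frame(name = c("delta", "theta", "alpha", "sigma", "beta", "gamma"),
             f_lo = c(0.5, 4, 8, 12, 16, 24),
             f_hi = c(4, 8, 12, 16, 24, 80))
}

validate_bands <- function(bands, fs) {
  stopifnot(all(c("name", "f_lo", "f_hi") %in% names(bands)),
            all(bands$f_lo < bands$f_hi))
  o <- order(bands$f_lo)
  bands <- bands[o, ]
  if (any(bands$f_lo[-1] < bands$f_hi[-nrow(bands)]))
    stop("bands must be non-overlapping")
  if (max(bands$f_hi) > fs / 2) stop("band above Nyquist")
  bands
}

#' Split an EEG recording into fixed-length epochs
#'
#' Consecutive non-overlapping epochs (default 10 s) starting at the
#' injection time; a trailing partial epoch is dropped. Epochs overlapping
#' the artifact mask (movement/grooming) are flagged excluded.
#'
#' @param sig an [eeg_signal()].
#' @param epoch_s epoch length in seconds.
#' @return list of epochs, each `list(index, start_s, samples, included)`;
#'   `start_s` is relative to recording start.
#' @export
epoch_signal <- function(sig, epoch_s = 10) {
  stopifnot(inherits(sig, "eeg_signal"), epoch_s > 0)
  fs <- sig$fs_hz
  i0 <- round(sig$injection_time_s * fs) + 1
  nrem <- length(sig$samples) - i0 + 1
  len <- round(epoch_s * fs)
  if (nrem < len) stop("recording shorter than one epoch after injection")
  n_ep <- nrem %/% len
  lapply(seq_len(n_ep), function(e) {
    idx <- i0 + (e - 1) * len + seq_len(len) - 1
    excl <- !is.null(sig$artifact) && any(sig$artifact[idx])
    list(index = e, start_s = (idx[1] - 1) / fs,
         samples = sig$samples[idx], included = !excl)
  })
}

# Hann-windowed one-sided periodogram, normalized so that the sum of
# returned powers over all bins equals the (window-weighted) mean square of
# the signal: a pure sinusoid of amplitude A contributes A^2/2 in total.
periodogram_power <- function(x, fs) {
  n <- length(x)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / n)
  V <- fft(x * w)
  p2 <- Mod(V)^2 / (n * sum(w^2))
  nh <- n %/% 2
  p <- p2[1:(nh + 1)]
  if (n %% 2 == 0) p[2:nh] <- p[2:nh] + rev(p2[(nh + 2):n])
  else p[2:(nh + 1)] <- p[2:(nh + 1)] + rev(p2[(nh + 2):n])
  list(freq = (0:nh) * fs / n, power = p)
}

#' FFT band power of one epoch
#'
#' Periodogram power (Hann window, one-sided, microvolts squared) summed
#' over each half-open band `[f_lo, f_hi)`. `total` is the power over the
#' union analysis range; `total_24_80` (the 24-80 Hz total that figure
#' captions also report) is emitted alongside.
#'
#' @param x numeric epoch samples.
#' @param fs sampling rate, Hz.
#' @param bands band definition data.frame (see [default_bands()]).
#' @return named numeric vector: one entry per band plus `total` and
#'   `total_24_80`.
#' @export
band_power <- function(x, fs, bands = default_bands()) {
  bands <- validate_bands(bands, fs)
  if (length(x) / fs < 2 / min(bands$f_lo))
    stop("epoch too short for the lowest band")
  pg <- periodogram_power(x, fs)
  pw <- vapply(seq_len(nrow(bands)), function(i) {
    sum(pg$power[pg$freq >= bands$f_lo[i] & pg$freq < bands$f_hi[i]])
  }, numeric(1))
  names(pw) <- bands$name
  rng <- pg$freq >= min(bands$f_lo) & pg$freq < max(bands$f_hi)
  c(pw, total = sum(pg$power[rng]),
    total_24_80 = sum(pg$power[pg$freq >= 24 & pg$freq < 80]))
}

#' Epoch-by-epoch band power table
#'
#' @param sig an [eeg_signal()].
#' @param bands band definition data.frame.
#' @param epoch_s epoch length in seconds (default 10 s).
#' @return data.frame: `epoch`, `start_s`, `included`, one column per band,
#'   `total`, `total_24_80`.
#' @export
epoch_band_power <- function(sig, bands = default_bands(), epoch_s = 10) {
  eps <- epoch_signal(sig, epoch_s)
  pw <- t(vapply(eps, function(e) band_power(e$samples, sig$fs_hz, bands),
                 band_power(eps[[1]]$samples, sig$fs_hz, bands)))
  cbind(data.frame(epoch = vapply(eps, `[[`, 0L, "index"),
                   start_s = vapply(eps, `[[`, 0, "start_s"),
                   included = vapply(eps, `[[`, TRUE, "included")),
        as.data.frame(pw))
}

#' Cumulative band power over an analysis period
#'
#' Sums included-epoch powers per band over the first `period_s` seconds
#' after injection (default 5400 s = the 90-min reporting period).
#'
#' @param table an [epoch_band_power()] data.frame.
#' @param period_s analysis period in seconds.
#' @param injection_time_s epoch times are measured from recording start;
#'   the period starts here (default: first epoch start).
#' @return named numeric vector of cumulative powers (bands + totals).
#' @export
cumulative_power <- function(table, period_s = 5400, injection_time_s = NULL) {
  t0 <- injection_time_s %||% min(table$start_s)
  keep <- table$included & table$start_s >= t0 &
    table$start_s < t0 + period_s
  cols <- setdiff(names(table), c("epoch", "start_s", "included"))
  colSums(table[keep, cols, drop = FALSE])
}

# RMS and median (50% spectral edge) frequency of a window over
# 1 Hz .. min(80, Nyquist). The median frequency is far more stable across
# noise realizations than higher spectral edges, so the twofold frequency
# criterion compares it.
window_features <- function(x, fs) {
  pg <- periodogram_power(x, fs)
  rng <- pg$freq >= 1 & pg$freq <= min(80, fs / 2)
  p <- pg$power[rng]; f <- pg$freq[rng]
  cs <- cumsum(p)
  sef <- if (cs[length(cs)] > 0) f[which(cs >= 0.5 * cs[length(cs)])[1]] else 0
  c(rms = sqrt(mean(x^2)), sef = sef)
}

#' Automated EEG seizure onset/duration call
#'
#' EEG-only implementation of the twofold criterion: seizure onset is the
#' start of the first sliding 10 s window whose RMS amplitude is at least
#' `factor` x baseline RMS *and* whose median frequency (50% spectral edge
#' over 1-80 Hz) is at least `factor` x the baseline median frequency,
#' sustained for at least `min_hold_s`. Offset is the first subsequent window with RMS below
#' 1.5 x baseline sustained for 30 s (an invented reporting convention,
#' flagged in the output). Behavioral (video) confirmation is out of scope,
#' so calls are labelled `"EEG-only"`.
#'
#' @param sig an [eeg_signal()].
#' @param baseline_window `c(t0, t1)` seconds from recording start used for
#'   baseline statistics; must precede the injection or be artifact-free.
#'   Default: the 60 s before injection (or the first 60 s).
#' @param factor the twofold criterion multiplier.
#' @param min_hold_s minimum time the onset criterion must hold.
#' @param window_s,step_s sliding window length and step.
#' @return `NULL` if no qualifying window, else a list of class
#'   `seizure_call`: `onset_s`, `offset_s`, `duration_s` (seconds after
#'   injection; offset may be `NA` if the criterion never releases),
#'   `baseline_rms`, `baseline_sef`, `criterion`.
#' @export
detect_onset <- function(sig, baseline_window = NULL, factor = 2,
                         min_hold_s = 10, window_s = 10, step_s = 1) {
  stopifnot(inherits(sig, "eeg_signal"))
  fs <- sig$fs_hz
  x <- sig$samples
  if (is.null(baseline_window)) {
    baseline_window <- if (sig$injection_time_s >= 60)
      c(sig$injection_time_s - 60, sig$injection_time_s) else c(0, 60)
  }
  bidx <- seq(round(baseline_window[1] * fs) + 1,
              min(length(x), round(baseline_window[2] * fs)))
  if (length(bidx) < window_s * fs) stop("baseline window too short")
  bstarts <- seq(1, length(bidx) - window_s * fs + 1, by = step_s * fs)
  bf <- t(vapply(bstarts, function(s)
    window_features(x[bidx[s + seq_len(window_s * fs) - 1]], fs), numeric(2)))
  base_rms <- median(bf[, 1]); base_sef <- median(bf[, 2])

  i0 <- round(sig$injection_time_s * fs) + 1
  wlen <- round(window_s * fs)
  starts <- seq(i0, length(x) - wlen + 1, by = round(step_s * fs))
  if (!length(starts)) return(NULL)
  feats <- t(vapply(starts, function(s)
    window_features(x[s + seq_len(wlen) - 1], fs), numeric(2)))
  hit <- feats[, 1] >= factor * base_rms & feats[, 2] >= factor * base_sef

  hold <- max(1L, ceiling(min_hold_s / step_s))
  run <- rle(hit)
  ends <- cumsum(run$lengths); begs <- ends - run$lengths + 1
  cand <- which(run$values & run$lengths >= hold)
  if (!length(cand)) return(NULL)
  oi <- begs[cand[1]]
  onset_s <- (starts[oi] - i0) / fs
  # refine within the first qualifying window: earliest 2 s sub-window whose
  # RMS alone crosses the criterion (removes the coarse-window lead bias)
  sub_len <- round(2 * fs)
  sub_starts <- seq(starts[oi], starts[oi] + wlen - sub_len,
                    by = round(0.5 * fs))
  sub_rms <- vapply(sub_starts, function(s)
    sqrt(mean(x[s + seq_len(sub_len) - 1]^2)), numeric(1))
  hit_sub <- which(sub_rms >= factor * base_rms)
  if (length(hit_sub)) onset_s <- (sub_starts[hit_sub[1]] - i0) / fs

  # offset: RMS back below 1.5 x baseline, sustained 30 s
  calm <- feats[, 1] < 1.5 * base_rms
  calm[seq_len(oi)] <- FALSE
  hold_off <- max(1L, ceiling(30 / step_s))
  run2 <- rle(calm)
  ends2 <- cumsum(run2$lengths); begs2 <- ends2 - run2$lengths + 1
  cand2 <- which(run2$values & run2$lengths >= hold_off)
  offset_s <- if (length(cand2)) (starts[begs2[cand2[1]]] - i0) / fs else NA_real_

  structure(list(onset_s = onset_s, offset_s = offset_s,
                 duration_s = offset_s - onset_s,
                 baseline_rms = base_rms, baseline_sef = base_sef,
                 criterion = "EEG-only twofold amplitude+frequency; offset 1.5x/30s (reporting convention)"),
            class = "seizure_call")
}

#' @export
print.seizure_call <- function(x, ...) {
  cat(sprintf("<seizure_call> onset %.1f s, offset %s, duration %s (%s)\n",
              x$onset_s,
              if (is.na(x$offset_s)) "NA" else sprintf("%.1f s", x$offset_s),
              if (is.na(x$duration_s)) "NA" else sprintf("%.1f s", x$duration_s),
              x$criterion))
  invisible(x)
}
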