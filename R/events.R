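#' Smooth a fluorescence trace (zero-phase low-pass)
#'
#' Removes high-frequency oscillations before the support-line fit while
#' preserving DC, using a zero-phase 2nd-order Butterworth low-pass
#' (forward-backward filtering). The slow photobleaching envelope must
#' survive smoothing, so no high-pass edge is applied.
#'
#' @param trace numeric fluorescence series.
#' @param cutoff_hz low-pass cutoff; must be below Nyquist.
#' @param frame_period_s frame period in seconds.
#' @return smoothed series, same length.
#' @export
smooth_trace <- function(trace, cutoff_hz = 0.5, frame_period_s = 0.328) {
  nyq <- 1 / (2 * frame_period_s)
  if (cutoff_hz >= nyq) stop("cutoff_hz must be below Nyquist (", nyq, " Hz)")
  stopifnot(all(is.finite(trace)))
  bf <- signal::butter(2, cutoff_hz / nyq, type = "low")
  n <- length(trace)
  # odd-reflection padding suppresses the start/end transients of the
  # forward-backward pass (they would otherwise anchor the support line)
  np <- min(n - 1, ceiling(3 / (cutoff_hz * frame_period_s)))
  if (np >= 1) {
    left <- 2 * trace[1] - trace[(np + 1):2]
    x <- c(left, trace, 2 * trace[n] - trace[(n - 1):(n - np)])
    y <- as.numeric(signal::filtfilt(bf, x))
    y[np + seq_len(n)]
  } else {
    as.numeric(signal::filtfilt(bf, trace))
  }
}

# Cubic basis over normalized time s in [-1, 1] (conditioning).
cubic_basis <- function(n, idx = seq_len(n)) {
  s <- 2 * (idx - 1) / (n - 1) - 1
  cbind(1, s, s^2, s^3)
}

# Convert coefficients in the normalized s-basis to the frame-index basis
# p(t) = r0 + r1*t + r2*t^2 + r3*t^3, t = 1..n (exact polynomial reparam).
coef_norm_to_raw <- function(cf, n) {
  a <- 2 / (n - 1); b <- -1 - a          # s = a*t + b
  r <- numeric(4)
  r[1] <- cf[1] + cf[2] * b + cf[3] * b^2 + cf[4] * b^3
  r[2] <- cf[2] * a + 2 * cf[3] * a * b + 3 * cf[4] * a * b^2
  r[3] <- cf[3] * a^2 + 3 * cf[4] * a^2 * b
  r[4] <- cf[4] * a^3
  r
}

#' Fit the cubic support line beneath a smoothed trace
#'
#' Finds the cubic p(t) lying entirely below the (smoothed) series whose
#' total distance from it, `sum over included frames of (y(t) - p(t))`, is
#' minimal -- the L1 lower envelope used to estimate the photobleaching
#' baseline. This is a linear program in the 4 cubic coefficients; it is
#' solved through its dual (4 equality constraints, one variable per frame)
#' with [boot::simplex()], recovering the primal cubic from the <= 4 active
#' frames at the optimum. A primal simplex fallback covers rank-deficient
#' active sets. The terminal KCl depolarization window is excluded from the
#' fit (pass it as `exclude`).
#'
#' @param smoothed numeric series (output of [smooth_trace()]).
#' @param exclude optional `c(first, last)` frame range excluded from the
#'   fit (typically the KCl window); p(t) is still evaluated there.
#' @return object of class `support_line`: `values` p(t) for every frame,
#'   `coef_norm` (basis over s in `[-1,1]`), `coef_raw` (frame-index basis),
#'   `objective` (total included gap), `active` (touching frames),
#'   `exclude`.
#' @export
fit_support_line <- function(smoothed, exclude = NULL) {
  n <- length(smoothed)
  stopifnot(all(is.finite(smoothed)))
  incl <- seq_len(n)
  if (!is.null(exclude)) {
    stopifnot(length(exclude) == 2, exclude[1] <= exclude[2])
    incl <- setdiff(incl, seq(max(1, exclude[1]), min(n, exclude[2])))
  }
  if (length(incl) < 8) stop("need >= 8 included frames to fit a support line")

  B <- cubic_basis(n, incl)
  y <- smoothed[incl]
  sc <- max(abs(y), 1)                       # scale for numerical tolerance
  sh <- min(y) - 1                           # shift so constraints are >= 1
  yy <- y - sh

  cf <- NULL
  fit <- tryCatch(
    boot::simplex(a = yy, A3 = t(B), b3 = colSums(B), maxi = FALSE),
    error = function(e) NULL)
  if (!is.null(fit) && fit$solved == 1) {
    act <- which(fit$soln > 1e-9)
    if (length(act) >= 1 && length(act) <= 4) {
      cf_try <- tryCatch(qr.solve(B[act, , drop = FALSE], yy[act]),
                         error = function(e) NULL)
      if (!is.null(cf_try) &&
          max(B %*% cf_try - yy) <= 1e-7 * sc) cf <- cf_try
    }
  }
  if (is.null(cf)) {                         # primal fallback (slower, robust)
    fit2 <- boot::simplex(a = c(colSums(B), -colSums(B)),
                          A1 = cbind(B, -B), b1 = yy, maxi = TRUE)
    if (fit2$solved != 1) stop("support-line LP failed to solve")
    cf <- fit2$soln[1:4] - fit2$soln[5:8]
  }
  cf[1] <- cf[1] + sh
  values <- as.numeric(cubic_basis(n) %*% cf)
  gaps <- smoothed[incl] - values[incl]
  structure(list(values = values,
                 coef_norm = as.numeric(cf),
                 coef_raw = coef_norm_to_raw(cf, n),
                 objective = sum(gaps),
                 active = incl[gaps <= 1e-7 * sc],
                 exclude = exclude,
                 n_frames = n),
            class = "support_line")
}

#' @export
print.support_line <- function(x, ...) {
  cat(sprintf("<support_line> %d frames, total gap %.4g, %d active frames\n",
              x$n_frames, x$objective, length(x$active)))
  invisible(x)
}

#' Detrend a trace with its support line
#'
#' The filtered series is the raw trace minus the support line. The support
#' line is a *lower* envelope touching only a few minima, so the filtered
#' series keeps a small, slowly varying positive offset; the baseline F0
#' level is therefore tracked as a running median (default 30 s window) of
#' the filtered series, and event detection measures exceedance above that
#' local level. The baseline fluorescence SD (SD of F0) is estimated as
#' 1.4826 x the median absolute *negative* deviation from the local level,
#' KCl window excluded: calcium transients deflect the trace only upward,
#' so the negative flank reflects pure baseline noise even when events
#' occupy a sizeable fraction of the frames.
#'
#' @param trace raw fluorescence series (same length as the fit).
#' @param sl a [fit_support_line()] result.
#' @param frame_period_s frame period, seconds.
#' @param level_window_s running-median window for the F0 level; long
#'   relative to any single transient (including slow glial waves), short
#'   relative to residual envelope misfit.
#' @return object of class `detrended_trace`: `filtered`, `baseline_sd`,
#'   `baseline_level` (per frame), `frame_period_s`, `exclude`.
#' @export
detrend_trace <- function(trace, sl, frame_period_s = 0.328,
                          level_window_s = 30) {
  stopifnot(inherits(sl, "support_line"), length(trace) == sl$n_frames)
  filtered <- trace - sl$values
  n <- length(filtered)
  incl <- seq_len(n)
  if (!is.null(sl$exclude))
    incl <- setdiff(incl, seq(sl$exclude[1], min(n, sl$exclude[2])))
  k <- min(round(level_window_s / frame_period_s), n)
  if (k %% 2 == 0) k <- k - 1
  if (k >= 3) {
    # keep the excluded (KCl) frames from leaking into the local level
    tmp <- filtered
    if (length(incl) < n) tmp[-incl] <- median(filtered[incl])
    lvl <- as.numeric(stats::runmed(tmp, k, endrule = "median"))
  } else lvl <- rep(median(filtered[incl]), n)
  neg <- (lvl - filtered)[incl]
  neg <- neg[neg >= 0]
  structure(list(filtered = filtered,
                 baseline_sd = 1.4826 * median(neg),
                 baseline_level = lvl,
                 frame_period_s = frame_period_s,
                 exclude = sl$exclude),
            class = "detrended_trace")
}

#' Detect calcium events by SD thresholding
#'
#' An event is a maximal run of frames where the detrended trace exceeds
#' its baseline level by at least the boundary threshold
#' `(k - boundary_sd_offset)` baseline SDs, containing at least one frame
#' that reaches the full `k`-SD threshold (default 3, the standard multiple
#' of the F0 SD) -- two-threshold (hysteresis) detection, which keeps the
#' k-SD existence criterion while measuring the transient's true extent.
#' Amplitudes are reported in baseline-SD units above baseline. The KCl
#' window is excluded from event calling. The event timestamp used by all
#' synchrony windows is the peak frame (earliest frame on ties).
#'
#' @param dt a [detrend_trace()] result.
#' @param k threshold in multiples of the baseline SD.
#' @param frame_period_s frame period (for durations).
#' @param merge_gap_frames runs separated by at most this many
#'   sub-threshold frames are one event (noise briefly interrupting a
#'   transient); 0 disables.
#' @param min_duration_frames discard events shorter than this many frames;
#'   the default 2 rejects single-frame noise excursions (a calcium
#'   transient at the 0.328 s frame period spans several frames).
#' @param boundary_sd_offset the boundary threshold sits this many SDs
#'   below `k` (floored at `k/2`); 0 reduces to plain `k`-SD run
#'   detection.
#' @return data.frame with columns `onset`, `peak`, `offset`,
#'   `amplitude_sd`, `duration_s` (zero rows if no events).
#' @export
detect_events <- function(dt, k = 3, frame_period_s = 0.328,
                          merge_gap_frames = 2, min_duration_frames = 2,
                          boundary_sd_offset = 1) {
  stopifnot(inherits(dt, "detrended_trace"), k > 0, boundary_sd_offset >= 0)
  x <- dt$filtered - (dt$baseline_level %||% 0)
  if (all(is.na(x))) stop("all-NaN trace")
  if (!is.finite(dt$baseline_sd) || dt$baseline_sd <= 0)
    stop("baseline_sd must be positive (constant trace?)")
  k_low <- max(k - boundary_sd_offset, k / 2)
  above <- x >= k_low * dt$baseline_sd
  if (!is.null(dt$exclude))
    above[seq(dt$exclude[1], min(length(x), dt$exclude[2]))] <- FALSE
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  on <- starts[r$values]; off <- ends[r$values]
  if (length(on) > 1 && merge_gap_frames > 0) {
    gap <- on[-1] - off[-length(off)] - 1L
    keep <- c(TRUE, gap > merge_gap_frames)
    grp <- cumsum(keep)
    on <- on[keep]
    off <- as.integer(tapply(off, grp, max))
  }
  if (length(on)) {
    keep <- (off - on + 1) >= min_duration_frames &
      mapply(function(a, b) max(x[a:b]) >= k * dt$baseline_sd, on, off)
    on <- on[keep]; off <- off[keep]
  }
  if (!length(on))
    return(data.frame(onset = integer(0), peak = integer(0),
                      offset = integer(0), amplitude_sd = numeric(0),
                      duration_s = numeric(0)))
  # split multi-modal runs (two transients bridged by gap closing):
  # consecutive supra-k maxima are distinct events only when the valley
  # between them falls back below the boundary threshold; wiggles riding a
  # sustained elevation (e.g. a slow glial wave) never split
  sdv <- dt$baseline_sd
  # 3-point weighted average stabilises peak localisation against
  # single-frame noise; thresholds and amplitudes still use the raw series
  xs <- x
  if (length(x) >= 3)
    xs[2:(length(x) - 1)] <- 0.25 * x[1:(length(x) - 2)] +
      0.50 * x[2:(length(x) - 1)] + 0.25 * x[3:length(x)]
  ev_on <- integer(0); ev_off <- integer(0); ev_peak <- integer(0)
  ev_amp <- numeric(0)
  for (r_ in seq_along(on)) {
    a <- on[r_]; b <- off[r_]
    seg <- x[a:b]; seg_s <- xs[a:b]
    m <- sort(unique(c(local_maxima(seg_s), which.max(seg_s))))
    m <- m[seg[m] >= k * sdv]
    if (!length(m)) m <- which.max(seg_s)
    if (length(m) > 1) {
      i <- 1L
      while (i < length(m)) {
        valley <- min(seg[m[i]:m[i + 1]])
        if (valley >= k_low * sdv) {
          m <- m[-(if (seg[m[i]] < seg[m[i + 1]]) i else i + 1L)]
        } else i <- i + 1L
      }
    }
    cuts <- if (length(m) > 1)
      vapply(seq_len(length(m) - 1), function(j)
        m[j] - 1L + which.min(seg[m[j]:m[j + 1]]), 0L) else integer(0)
    lo <- c(1L, cuts + 1L); hi <- c(cuts, length(seg))
    ev_on <- c(ev_on, a + lo - 1L)
    ev_off <- c(ev_off, a + hi - 1L)
    ev_peak <- c(ev_peak, a + m - 1L)
    ev_amp <- c(ev_amp, vapply(seq_along(lo), function(j)
      max(seg[lo[j]:hi[j]]), numeric(1)))
  }
  data.frame(onset = ev_on, peak = as.integer(ev_peak), offset = ev_off,
             amplitude_sd = ev_amp / sdv,
             duration_s = (ev_off - ev_on + 1) * frame_period_s)
}
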