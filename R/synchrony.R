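#' Synchrony analysis parameters
#'
#' @param participation_window_s half-width of the participation window
#'   around each SE peak, seconds. The default 0.984 s equals exactly 3
#'   frames at the 0.328 s frame period.
#' @param pc_candidates how many leading principal components are candidates
#'   to carry the synchronous events (typically the first or second).
#' @param se_threshold_sd SE peak threshold, multiples of the robust SD of
#'   the PC trace above its median.
#' @param burst_baseline_eps_sd tolerance above baseline (multiples of the
#'   robust SD) used by the burst "did not return to baseline" rule.
#' @param se_merge_drop_sd prominence rule for SE peaks: two consecutive
#'   supra-threshold maxima count as distinct SEs only if the PC trace
#'   between them drops at least this many robust SDs below the smaller
#'   peak; otherwise the smaller one is a shoulder (decay echo) of the same
#'   SE. Genuine burst members are far more prominent than this.
#' @param min_participation_frac peaks in which fewer than this fraction of
#'   retained cells participate are chance coincidences of asynchronous
#'   events, not population SEs, and are discarded.
#' @return validated list of class `synchrony_params`.
#' @export
synchrony_params <- function(participation_window_s = 0.984,
                             pc_candidates = 3,
                             se_threshold_sd = 3,
                             burst_baseline_eps_sd = 0.5,
                             se_merge_drop_sd = 2,
                             min_participation_frac = 0.1) {
  stopifnot(participation_window_s > 0, pc_candidates >= 1,
            se_threshold_sd > 0, burst_baseline_eps_sd >= 0,
            se_merge_drop_sd >= 0, min_participation_frac >= 0,
            min_participation_frac < 1)
  structure(as.list(environment()), class = "synchrony_params")
}

#' Event raster
#'
#' Boolean cells x frames matrix with `TRUE` at event peak frames, restricted
#' to retained (viable, non-glia) cells.
#'
#' @param events_per_cell list of [detect_events()] data.frames (already
#'   restricted to retained cells).
#' @param n_frames raster width in frames.
#' @param frame_period_s frame period, seconds.
#' @param cell_ids optional identifiers.
#' @return object of class `event_raster` (logical matrix with attributes
#'   `frame_period_s` and `cell_ids`).
#' @export
event_raster <- function(events_per_cell, n_frames, frame_period_s,
                         cell_ids = NULL) {
  n <- length(events_per_cell)
  m <- matrix(FALSE, n, n_frames)
  for (i in seq_len(n)) {
    pk <- events_per_cell[[i]]$peak
    m[i, pk[pk >= 1 & pk <= n_frames]] <- TRUE
  }
  structure(m, frame_period_s = frame_period_s,
            cell_ids = cell_ids %||% seq_len(n), class = "event_raster")
}

#' PCA of population activity
#'
#' Standard PCA of the detrended cells x frames matrix (cells centered).
#' Each component's time course is oriented so its skewness is
#' non-negative, making upward population transients positive deflections
#' regardless of the arbitrary PCA sign.
#'
#' @param detrended numeric matrix, cells x frames.
#' @return list of class `population_components` with `loadings`
#'   (cells x k, orthonormal), `timecourses` (k x frames), `var_frac`.
#' @export
population_pca <- function(detrended) {
  stopifnot(is.matrix(detrended), nrow(detrended) >= 2, ncol(detrended) >= 2)
  if (all(apply(detrended, 1, var) == 0)) stop("zero-variance matrix")
  pr <- prcomp(t(detrended), center = TRUE, scale. = FALSE)
  L <- pr$rotation
  Tc <- t(pr$x)
  flip <- apply(Tc, 1, skewness) < 0
  L[, flip] <- -L[, flip]
  Tc[flip, ] <- -Tc[flip, ]
  structure(list(loadings = L, timecourses = Tc,
                 var_frac = pr$sdev^2 / sum(pr$sdev^2)),
            class = "population_components")
}

#' Select the principal component carrying the synchronous events
#'
#' Among the first `n_candidates` components, returns the one whose time
#' course correlates best with the per-frame population event count --
#' the programmatic version of matching raster plots with the PC trace.
#' Because the PC time course is a calcium signal, the count series is
#' first convolved with a causal exponential of time constant
#' `kernel_decay_s` (the transient decay) so both carry the same temporal
#' signature. A correlation below `low_confidence_threshold` flags low
#' confidence (e.g. purely asynchronous activity): because both series are
#' smoothed by the same kernel, chance correlations sit well above zero,
#' and SE-carrying components score ~0.9, so the flag threshold is 0.5.
#'
#' @param pc a [population_pca()] result.
#' @param raster an [event_raster()].
#' @param n_candidates number of leading components considered.
#' @param kernel_decay_s decay constant of the matching kernel, seconds.
#' @param low_confidence_threshold correlation below which the selection is
#'   flagged unreliable.
#' @return list with `index` (1-based), `confidence` (the correlation) and
#'   `low_confidence` flag.
#' @export
select_se_component <- function(pc, raster, n_candidates = 3,
                                kernel_decay_s = 1,
                                low_confidence_threshold = 0.5) {
  stopifnot(inherits(pc, "population_components"))
  k <- min(n_candidates, nrow(pc$timecourses))
  fp <- attr(raster, "frame_period_s") %||% 0.328
  counts <- colSums(raster)
  a <- exp(-fp / kernel_decay_s)
  counts <- as.numeric(stats::filter(counts, a, method = "recursive"))
  cors <- vapply(seq_len(k), function(j) {
    tc <- pc$timecourses[j, ]
    if (sd(tc) == 0 || sd(counts) == 0) return(0)
    cor(tc, counts)
  }, numeric(1))
  best <- which.max(cors)
  list(index = best, confidence = cors[best],
       low_confidence = cors[best] < low_confidence_threshold)
}

# Local maxima of a series (plateau-aware; first frame of a plateau).
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  out <- integer(0)
  i <- 2L
  while (i < n) {
    if (x[i] > x[i - 1]) {
      j <- i
      while (j < n && x[j + 1] == x[j]) j <- j + 1L
      if (j < n && x[j + 1] < x[j]) out <- c(out, i)
      i <- j + 1L
    } else i <- i + 1L
  }
  out
}

#' Detect synchronous events on the PC trace
#'
#' SE peaks are local maxima of the selected PC time course at least
#' `se_threshold_sd` robust SDs above its median. Participants of each SE
#' are counted with [participation()].
#'
#' @param pc_trace selected component time course (frames).
#' @param raster an [event_raster()] of the retained cells.
#' @param params a [synchrony_params()].
#' @return data.frame of class `sync_events`: `peak_frame`,
#'   `n_participants`, `fraction`, `pc_amplitude`; participant cell indices
#'   in the list attribute `participants`.
#' @export
detect_ses <- function(pc_trace, raster, params = synchrony_params()) {
  stopifnot(length(pc_trace) == ncol(raster))
  rsd <- robust_sd(pc_trace)
  thr <- median(pc_trace) + params$se_threshold_sd * rsd
  peaks <- local_maxima(pc_trace)
  peaks <- peaks[pc_trace[peaks] >= thr]
  # prominence: drop shoulder maxima riding on another SE's flanks
  if (length(peaks) > 1 && params$se_merge_drop_sd > 0) {
    repeat {
      merged <- FALSE
      i <- 1L
      while (i < length(peaks)) {
        valley <- min(pc_trace[peaks[i]:peaks[i + 1]])
        lower <- min(pc_trace[peaks[i]], pc_trace[peaks[i + 1]])
        if (valley > lower - params$se_merge_drop_sd * rsd) {
          drop_i <- if (pc_trace[peaks[i]] < pc_trace[peaks[i + 1]]) i else i + 1L
          peaks <- peaks[-drop_i]
          merged <- TRUE
        } else i <- i + 1L
      }
      if (!merged) break
    }
  }
  parts <- lapply(peaks, function(p) participation(raster, p, params))
  if (params$min_participation_frac > 0 && length(peaks)) {
    keep <- vapply(parts, function(p) p$fraction, 0) >=
      params$min_participation_frac
    peaks <- peaks[keep]; parts <- parts[keep]
  }
  out <- data.frame(peak_frame = as.integer(peaks),
                    n_participants = vapply(parts, function(p) p$n, 0L),
                    fraction = vapply(parts, function(p) p$fraction, 0),
                    pc_amplitude = pc_trace[peaks])
  attr(out, "participants") <- lapply(parts, function(p) p$participants)
  class(out) <- c("sync_events", "data.frame")
  out
}

#' Participation of cells in a synchronous event
#'
#' A cell participates in an SE iff it has an event peak within
#' `round(participation_window_s / frame_period_s)` frames on either side
#' of the SE peak -- at the 0.328 s frame period the 984 ms window is
#' exactly +/-3 frames. The fraction uses the retained-cell denominator
#' (all rows of the raster).
#'
#' @param raster an [event_raster()].
#' @param se_peak SE peak frame.
#' @param params a [synchrony_params()].
#' @return list with `participants` (row indices), `n`, `fraction`,
#'   `window_frames`.
#' @export
participation <- function(raster, se_peak, params = synchrony_params()) {
  fp <- attr(raster, "frame_period_s")
  stopifnot(se_peak >= 1, se_peak <= ncol(raster))
  w <- round(params$participation_window_s / fp)
  win <- max(1, se_peak - w):min(ncol(raster), se_peak + w)
  hit <- rowSums(raster[, win, drop = FALSE]) > 0
  list(participants = which(hit), n = sum(hit),
       fraction = sum(hit) / nrow(raster), window_frames = w)
}

#' Split events into synchronous and asynchronous
#'
#' Every event peak is synchronous iff it falls inside the participation
#' window of some SE, else asynchronous; the two counts always sum to the
#' total number of retained events.
#'
#' @param event_peaks integer vector of all retained events' peak frames.
#' @param se_peaks integer vector of SE peak frames.
#' @param raster an [event_raster()] (supplies the frame period).
#' @param params a [synchrony_params()].
#' @return list with `n_sync`, `n_async` and logical `is_sync` per event.
#' @export
classify_async <- function(event_peaks, se_peaks, raster,
                           params = synchrony_params()) {
  w <- round(params$participation_window_s / attr(raster, "frame_period_s"))
  is_sync <- if (length(se_peaks))
    vapply(event_peaks, function(p) any(abs(p - se_peaks) <= w), logical(1))
  else rep(FALSE, length(event_peaks))
  list(n_sync = sum(is_sync), n_async = sum(!is_sync), is_sync = is_sync)
}

#' Detect bursts of synchronous events
#'
#' Consecutive SEs belong to the same burst when the PC trace between their
#' peaks does not return to baseline: the minimum between the peaks stays
#' above `baseline + burst_baseline_eps_sd x robust SD`, with baseline the
#' 10th percentile of the PC trace. Bursts are maximal chains of at least
#' two SEs.
#'
#' @param pc_trace selected component time course.
#' @param se_peaks SE peak frames (sorted).
#' @param params a [synchrony_params()].
#' @return list with `bursts` (data.frame `burst`, `first_se`, `last_se`,
#'   `n_se`, `start_frame`, `end_frame`), `se_burst_id` (NA = not in a
#'   burst) and `pct_se_in_bursts`.
#' @export
detect_bursts <- function(pc_trace, se_peaks, params = synchrony_params()) {
  n <- length(se_peaks)
  empty <- list(bursts = data.frame(burst = integer(0), first_se = integer(0),
                                    last_se = integer(0), n_se = integer(0),
                                    start_frame = integer(0),
                                    end_frame = integer(0)),
                se_burst_id = rep(NA_integer_, n), pct_se_in_bursts = 0)
  if (n < 2) return(empty)
  base <- quantile(pc_trace, 0.10, names = FALSE)
  eps <- params$burst_baseline_eps_sd * robust_sd(pc_trace)
  chained <- vapply(seq_len(n - 1), function(i) {
    min(pc_trace[se_peaks[i]:se_peaks[i + 1]]) > base + eps
  }, logical(1))
  id <- rep(NA_integer_, n)
  bid <- 0L; i <- 1L
  while (i < n) {
    if (chained[i]) {
      j <- i
      while (j < n && chained[j]) j <- j + 1L
      bid <- bid + 1L
      id[i:j] <- bid
      i <- j + 1L
    } else i <- i + 1L
  }
  if (bid == 0L) return(empty)
  bursts <- do.call(rbind, lapply(seq_len(bid), function(b) {
    m <- which(id == b)
    data.frame(burst = b, first_se = m[1], last_se = m[length(m)],
               n_se = length(m), start_frame = se_peaks[m[1]],
               end_frame = se_peaks[m[length(m)]])
  }))
  list(bursts = bursts, se_burst_id = id,
       pct_se_in_bursts = 100 * sum(!is.na(id)) / n)
}

#' Per-movie activity summary
#'
#' @param raster an [event_raster()] of retained cells.
#' @param ses a [detect_ses()] result.
#' @param bursts a [detect_bursts()] result (or `NULL` for no burst
#'   analysis; burst percentage is then 0).
#' @param duration_s analysed movie duration in seconds.
#' @return one-row data.frame: `n_se`, `se_per_min`, `total_events`,
#'   `n_async_events`, `pct_cells_per_se`, `pct_active_cells`,
#'   `pct_se_in_bursts`.
#' @export
summarize_movie <- function(raster, ses, bursts = NULL, duration_s) {
  if (duration_s <= 0) stop("duration must be positive")
  n_se <- nrow(ses)
  total <- sum(raster)
  peaks <- unlist(apply(raster, 1, which, simplify = FALSE), use.names = FALSE)
  cls <- classify_async(peaks, ses$peak_frame, raster)
  data.frame(
    n_se = n_se,
    se_per_min = n_se / (duration_s / 60),
    total_events = total,
    n_async_events = cls$n_async,
    pct_cells_per_se = if (n_se) 100 * mean(ses$fraction) else 0,
    pct_active_cells = 100 * mean(rowSums(raster) > 0),
    pct_se_in_bursts = if (is.null(bursts)) 0 else bursts$pct_se_in_bursts)
}
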