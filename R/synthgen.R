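#' Containers for cell traces and fluorescence movies
#'
#' `cell_traces()` wraps a cells x frames fluorescence matrix together with
#' the acquisition frame period; `fluorescence_movie()` wraps a
#' frames x height x width array. Both are plain S3 lists used throughout
#' the pipeline.
#'
#' @param traces numeric matrix, cells in rows, frames in columns.
#' @param frame_period_s frame period in seconds (0.328 s for the standard
#'   acquisition).
#' @param cell_ids optional character/integer cell identifiers.
#' @return an object of class `cell_traces`.
#' @export
cell_traces <- function(traces, frame_period_s, cell_ids = NULL) {
  traces <- as.matrix(traces)
  stopifnot(is.numeric(traces), all(is.finite(traces)), frame_period_s > 0)
  if (is.null(cell_ids)) cell_ids <- seq_len(nrow(traces))
  stopifnot(length(cell_ids) == nrow(traces))
  structure(list(traces = traces, frame_period_s = frame_period_s,
                 cell_ids = cell_ids),
            class = "cell_traces")
}

#' @export
print.cell_traces <- function(x, ...) {
  cat(sprintf("<cell_traces> %d cells x %d frames, %.3f s/frame (%.1f s)\n",
              nrow(x$traces), ncol(x$traces), x$frame_period_s,
              ncol(x$traces) * x$frame_period_s))
  invisible(x)
}

#' @param data numeric array frames x height x width, non-negative.
#' @rdname cell_traces
#' @export
fluorescence_movie <- function(data, frame_period_s) {
  stopifnot(length(dim(data)) == 3, dim(data)[1] >= 2,
            all(is.finite(data)), frame_period_s > 0)
  structure(list(data = data, frame_period_s = frame_period_s),
            class = "fluorescence_movie")
}

#' @export
print.fluorescence_movie <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<fluorescence_movie> %d frames of %dx%d px, %.3f s/frame\n",
              d[1], d[2], d[3], x$frame_period_s))
  invisible(x)
}

#' Parameters of the calcium-trace simulator
#'
#' Defaults describe the study conditions the generator emulates: ~5 min
#' movies at 0.328 s/frame, synchronous events (SEs) arriving as a Poisson
#' process at 2/min in which ~60% of viable cells participate, sparse
#' asynchronous per-cell events, a cubic photobleaching decline, i.i.d.
#' Gaussian noise, a terminal KCl depolarization answered by every viable
#' cell, and small fractions of non-viable (silent, KCl-unresponsive) and
#' glia-like cells (slow, large calcium waves only).
#'
#' Event amplitudes are expressed in multiples of `noise_sd`; when
#' `noise_sd = 0` the unit falls back to 1 raw fluorescence unit.
#'
#' @param n_cells number of cells.
#' @param n_frames number of frames.
#' @param frame_period_s frame period, seconds.
#' @param se_rate_per_min Poisson rate of SE seed events per minute.
#' @param participation_mean,participation_sd mean/SD of the fraction of
#'   eligible (viable, non-glia) cells participating in each SE.
#' @param burst_prob probability that an SE seed expands into a burst.
#' @param burst_size_mean mean number of SEs per burst (>= 2).
#' @param intra_burst_interval_s interval between SEs inside a burst; short
#'   enough that the population trace does not return to baseline, yet
#'   long enough (relative to the transient decay and the +/-1 frame spike
#'   jitter) that members remain distinct peaks.
#' @param async_rate_per_cell_per_min rate of asynchronous events per cell.
#' @param kernel_rise_s,kernel_decay_s calcium transient kernel time
#'   constants (difference of exponentials).
#' @param amp_mean_sd_units mean event amplitude, in units of `noise_sd`.
#' @param bleach_cubic_coeffs photobleaching baseline as cubic coefficients
#'   over normalized time s = (frame-1)/(n_frames-1): `NULL` for a random
#'   gentle decline per cell, a length-4 vector shared by all cells, or an
#'   `n_cells` x 4 matrix.
#' @param noise_sd SD of i.i.d. Gaussian frame noise (fluorescence units).
#' @param kcl_enabled add the terminal KCl depolarization?
#' @param kcl_onset_frame frame at which KCl reaches the slice.
#' @param kcl_amp_sd_units KCl response amplitude, units of `noise_sd`.
#' @param frac_nonviable,frac_glia fractions of non-viable and glia cells.
#' @param glia_event_duration_s decay constant of glial events (> 5 s, so
#'   the slow-event exclusion rule applies to them).
#' @param glia_amp_sd_units amplitude of glial events (units of `noise_sd`);
#'   large, as glial waves are, so their above-threshold time exceeds 5 s.
#' @param seed RNG seed; identical seeds give bit-identical output.
#' @return a validated parameter list of class `trace_sim_params`.
#' @export
trace_sim_params <- function(n_cells = 100,
                             n_frames = 975,
                             frame_period_s = 0.328,
                             se_rate_per_min = 2,
                             participation_mean = 0.6,
                             participation_sd = 0.1,
                             burst_prob = 0,
                             burst_size_mean = 3,
                             intra_burst_interval_s = 2.0,
                             async_rate_per_cell_per_min = 0.5,
                             kernel_rise_s = 0.05,
                             kernel_decay_s = 1.0,
                             amp_mean_sd_units = 6,
                             bleach_cubic_coeffs = NULL,
                             noise_sd = 1,
                             kcl_enabled = TRUE,
                             kcl_onset_frame = n_frames - round(15 / frame_period_s),
                             kcl_amp_sd_units = 20,
                             frac_nonviable = 0.1,
                             frac_glia = 0.05,
                             glia_event_duration_s = 6,
                             glia_amp_sd_units = 10,
                             seed = 1L) {
  p <- as.list(environment())
  fr <- c(participation_mean = participation_mean, burst_prob = burst_prob,
          frac_nonviable = frac_nonviable, frac_glia = frac_glia)
  if (any(fr < 0 | fr > 1))
    stop("fractions must lie in [0, 1]: ",
         paste(names(fr)[fr < 0 | fr > 1], collapse = ", "))
  rates <- c(se_rate_per_min, async_rate_per_cell_per_min)
  if (any(rates < 0)) stop("rates must be non-negative")
  if (n_cells < 1 || n_frames < 2) stop("need >= 1 cell and >= 2 frames")
  if (se_rate_per_min > 0 && n_frames * frame_period_s < 60)
    stop("movie must span >= 60 s when se_rate_per_min > 0")
  if (kcl_enabled && (kcl_onset_frame >= n_frames || kcl_onset_frame < 2))
    stop("kcl_onset_frame must lie inside the movie")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (glia_event_duration_s <= 5)
    stop("glia_event_duration_s must exceed 5 s")
  class(p) <- "trace_sim_params"
  p
}

# Calcium transient kernel, shifted so its continuous-time peak falls
# exactly on the spike frame (makes the true peak frame the discrete argmax).
transient_kernel <- function(t_rel, rise, decay) {
  t_peak <- rise * decay / (decay - rise) * log(decay / rise)
  tt <- t_rel + t_peak
  k <- ifelse(tt >= 0, exp(-tt / decay) - exp(-tt / rise), 0)
  k / (exp(-t_peak / decay) - exp(-t_peak / rise))
}

#' Simulate calcium traces with ground truth
#'
#' Generates a cells x frames fluorescence matrix as
#' `bleach(t) + sum of event transients + KCl response + Gaussian noise`,
#' together with a `ground_truth` list recording everything downstream
#' stages are supposed to recover: per-cell spike frames, SE frames and
#' participants, burst membership, bleaching polynomials, and the
#' viability/glia masks.
#'
#' SEs arrive as a Poisson process inside the analysis window (the movie up
#' to ~5 s before KCl). With probability `burst_prob` a seed expands into a
#' burst of geometrically distributed size at `intra_burst_interval_s`
#' spacing. Truth burst membership is defined as maximal chains of SEs with
#' inter-peak gaps <= 1.5 x `intra_burst_interval_s` (>= 2 members), which is
#' also what the chained seeds produce.
#'
#' @param params a [trace_sim_params()] object.
#' @return list with `traces` (a [cell_traces()]) and `truth` (class
#'   `ground_truth`): `spike_frames` (list per cell), `se_frames`,
#'   `se_participants` (list of cell indices), `burst_id` (NA = not in a
#'   burst), `bleach_poly` (n_cells x 4, normalized-time basis),
#'   `viable_mask`, `glia_mask`, `analysis_frames`, `kcl_window`.
#' @export
simulate_traces <- function(params = trace_sim_params()) {
  stopifnot(inherits(params, "trace_sim_params"))
  p <- params
  set.seed(p$seed)
  n <- p$n_cells; nf <- p$n_frames; fp <- p$frame_period_s
  scale <- if (p$noise_sd > 0) p$noise_sd else 1
  t_frames <- (seq_len(nf) - 1) * fp

  # cell classes: non-viable cells are silent and KCl-unresponsive; glia are
  # viable (they answer KCl) but carry only slow events
  n_nv <- round(p$frac_nonviable * n)
  n_gl <- round(p$frac_glia * n)
  perm <- sample.int(n)
  nonviable <- perm[seq_len(n_nv)]
  glia <- perm[n_nv + seq_len(n_gl)]
  viable_mask <- !(seq_len(n) %in% nonviable)
  glia_mask <- seq_len(n) %in% glia
  eligible <- which(viable_mask & !glia_mask)

  kcl_window <- if (p$kcl_enabled) c(p$kcl_onset_frame, nf) else NULL
  margin <- ceiling(5 / fp)
  last_active <- if (p$kcl_enabled) p$kcl_onset_frame - margin else nf - 2
  analysis_frames <- c(1L, as.integer(last_active))
  dur_min <- last_active * fp / 60

  # --- synchronous events ------------------------------------------------
  n_seed <- rpois(1, p$se_rate_per_min * dur_min)
  seed_t <- sort(runif(n_seed, 2, last_active * fp - 2))
  se_t <- numeric(0)
  for (st in seed_t) {
    memb <- st
    if (p$burst_prob > 0 && runif(1) < p$burst_prob) {
      extra <- if (p$burst_size_mean > 2)
        2 + rgeom(1, 1 / (p$burst_size_mean - 1)) else 2
      memb <- st + (seq_len(extra) - 1) * p$intra_burst_interval_s
      memb <- memb[memb < last_active * fp - 2]
    }
    se_t <- c(se_t, memb)
  }
  se_t <- sort(se_t)
  se_frames <- as.integer(round(se_t / fp) + 1)
  keep <- !duplicated(se_frames)
  se_frames <- se_frames[keep]; se_t <- se_t[keep]
  n_se <- length(se_frames)

  # truth burst membership: maximal chains with short inter-peak gaps
  burst_id <- rep(NA_integer_, n_se)
  if (n_se >= 2) {
    gap_ok <- diff(se_t) <= 1.5 * p$intra_burst_interval_s
    bid <- 0L; i <- 1L
    while (i < n_se) {
      if (gap_ok[i]) {
        j <- i
        while (j < n_se && gap_ok[j]) j <- j + 1L
        bid <- bid + 1L
        burst_id[i:j] <- bid
        i <- j + 1L
      } else i <- i + 1L
    }
  }

  # participants and their jittered spikes
  spike_frames <- vector("list", n)
  se_participants <- vector("list", n_se)
  for (s in seq_len(n_se)) {
    f <- min(1, max(0.05, rnorm(1, p$participation_mean, p$participation_sd)))
    k <- max(1L, round(f * length(eligible)))
    part <- sort(sample(eligible, k))
    se_participants[[s]] <- part
    jit <- sample(c(-1L, 0L, 1L), k, replace = TRUE, prob = c(.25, .5, .25))
    fr <- pmin(pmax(se_frames[s] + jit, 1L), last_active)
    for (i in seq_along(part))
      spike_frames[[part[i]]] <- c(spike_frames[[part[i]]], fr[i])
  }

  # asynchronous events (eligible cells) and slow glial events
  for (c_ in eligible) {
    n_as <- rpois(1, p$async_rate_per_cell_per_min * dur_min)
    if (n_as > 0) {
      fr <- as.integer(round(runif(n_as, 2, last_active - 1)))
      spike_frames[[c_]] <- c(spike_frames[[c_]], fr)
    }
  }
  # every glia cell carries at least one slow wave: a glia cell without
  # events would be indistinguishable from a neuron by the duration rule
  glia_spikes <- vector("list", n)
  for (c_ in glia) {
    n_g <- max(1L, rpois(1, p$async_rate_per_cell_per_min * dur_min))
    glia_spikes[[c_]] <- as.integer(round(runif(n_g, 2, last_active - margin)))
  }
  spike_frames <- lapply(spike_frames, function(v) sort(unique(v)))

  # --- bleaching baseline ------------------------------------------------
  s01 <- (seq_len(nf) - 1) / (nf - 1)
  B <- cbind(1, s01, s01^2, s01^3)
  if (is.null(p$bleach_cubic_coeffs)) {
    decl <- runif(n, 0.08, 0.25)          # total fractional decline
    w <- matrix(runif(3 * n), n, 3); w <- w / rowSums(w)
    bleach_poly <- cbind(100, -100 * decl * w)
  } else if (is.matrix(p$bleach_cubic_coeffs)) {
    stopifnot(dim(p$bleach_cubic_coeffs) == c(n, 4))
    bleach_poly <- p$bleach_cubic_coeffs
  } else {
    stopifnot(length(p$bleach_cubic_coeffs) == 4)
    bleach_poly <- matrix(p$bleach_cubic_coeffs, n, 4, byrow = TRUE)
  }
  traces <- bleach_poly %*% t(B)

  # --- add transients ----------------------------------------------------
  add_kernel <- function(row, frame, amp, rise, decay) {
    # transient support truncated at 8 decay constants
    span <- min(nf, frame + ceiling(8 * decay / fp))
    idx <- max(1L, frame - 2L):span
    row[idx] <- row[idx] +
      amp * transient_kernel(t_frames[idx] - t_frames[frame], rise, decay)
    row
  }
  for (c_ in seq_len(n)) {
    for (fr in spike_frames[[c_]]) {
      amp <- max(1, rnorm(1, p$amp_mean_sd_units, 0.1 * p$amp_mean_sd_units)) * scale
      traces[c_, ] <- add_kernel(traces[c_, ], fr, amp,
                                 p$kernel_rise_s, p$kernel_decay_s)
    }
    if (!is.null(glia_spikes[[c_]])) for (fr in glia_spikes[[c_]]) {
      amp <- max(1, rnorm(1, p$glia_amp_sd_units, 0.1 * p$glia_amp_sd_units)) * scale
      traces[c_, ] <- add_kernel(traces[c_, ], fr, amp,
                                 0.3, p$glia_event_duration_s)
    }
  }

  # --- KCl depolarization (viable cells only) ----------------------------
  if (p$kcl_enabled && p$kcl_amp_sd_units > 0) {
    tk <- t_frames - t_frames[p$kcl_onset_frame]
    resp <- ifelse(tk >= 0, (1 - exp(-pmax(tk, 0) / 1)) * exp(-pmax(tk, 0) / 60), 0)
    for (c_ in which(viable_mask))
      traces[c_, ] <- traces[c_, ] +
        p$kcl_amp_sd_units * scale * runif(1, 0.8, 1.2) * resp
  }

  if (p$noise_sd > 0)
    traces <- traces + matrix(rnorm(n * nf, 0, p$noise_sd), n, nf)

  truth <- structure(list(
    spike_frames = spike_frames,
    se_frames = se_frames,
    se_participants = se_participants,
    burst_id = burst_id,
    bleach_poly = bleach_poly,
    viable_mask = viable_mask,
    glia_mask = glia_mask,
    analysis_frames = analysis_frames,
    kcl_window = kcl_window,
    params = p), class = "ground_truth")

  list(traces = cell_traces(traces, fp), truth = truth)
}

#' Render traces into a synthetic fluorescence movie
#'
#' Places one disc-shaped ROI per cell on a grid (shuffled), sets the ROI
#' pixels of each frame to the cell's trace value, the remaining pixels to
#' `background`, and adds i.i.d. pixel noise. The mean over a true ROI's
#' pixels therefore reproduces the input trace up to pixel noise reduced by
#' averaging.
#'
#' @param traces a [cell_traces()] object.
#' @param h,w movie height and width in pixels.
#' @param roi_radius disc radius in pixels (0 = a single pixel).
#' @param background background fluorescence.
#' @param pixel_noise_sd SD of per-pixel Gaussian noise.
#' @param seed RNG seed (ROI placement and pixel noise).
#' @return list with `movie` (a [fluorescence_movie()]) and `rois`, a list of
#'   per-cell true pixel index vectors (linear indices into an h x w frame).
#' @export
render_movie <- function(traces, h, w, roi_radius = 3, background = 10,
                         pixel_noise_sd = 0, seed = 1L) {
  stopifnot(inherits(traces, "cell_traces"), roi_radius >= 0)
  n <- nrow(traces$traces); nf <- ncol(traces$traces)
  set.seed(seed)
  spacing <- 2 * roi_radius + 3
  if (w < 2 * roi_radius + 3 || h < 2 * roi_radius + 3)
    stop("cannot place ", n, " disjoint ROIs of radius ", roi_radius,
         " in a ", h, "x", w, " field")
  cx <- seq(roi_radius + 2, w - roi_radius - 1, by = spacing)
  cy <- seq(roi_radius + 2, h - roi_radius - 1, by = spacing)
  if (length(cx) * length(cy) < n)
    stop("cannot place ", n, " disjoint ROIs of radius ", roi_radius,
         " in a ", h, "x", w, " field")
  centers <- expand.grid(y = cy, x = cx)
  centers <- centers[sample.int(nrow(centers), n), , drop = FALSE]

  off <- expand.grid(dy = -roi_radius:roi_radius, dx = -roi_radius:roi_radius)
  off <- off[off$dy^2 + off$dx^2 <= roi_radius^2, , drop = FALSE]
  rois <- lapply(seq_len(n), function(i) {
    yy <- centers$y[i] + off$dy; xx <- centers$x[i] + off$dx
    sort(as.integer((xx - 1) * h + yy))      # linear index, column-major
  })

  data <- array(background, dim = c(nf, h, w))
  frame_mat <- matrix(background, h, w)
  for (t_ in seq_len(nf)) {
    fm <- frame_mat
    for (i in seq_len(n)) fm[rois[[i]]] <- traces$traces[i, t_]
    if (pixel_noise_sd > 0)
      fm <- fm + matrix(rnorm(h * w, 0, pixel_noise_sd), h, w)
    data[t_, , ] <- fm
  }
  data[data < 0] <- 0
  list(movie = fluorescence_movie(data, traces$frame_period_s), rois = rois)
}
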