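# Independent oracles and small fixtures used across the suite.

# Brute-force support line: enumerate every 4-subset of frames, interpolate
# a cubic through it, keep the feasible (everywhere-below) candidate with
# the smallest total gap. Independent of the LP implementation.
support_line_oracle <- function(y) {
  n <- length(y)
  s <- 2 * (seq_len(n) - 1) / (n - 1) - 1
  B <- cbind(1, s, s^2, s^3)
  combs <- utils::combn(n, 4)
  best <- Inf
  for (j in seq_len(ncol(combs))) {
    S <- combs[, j]
    cf <- tryCatch(solve(B[S, ], y[S]), error = function(e) NULL)
    if (is.null(cf)) next
    v <- B %*% cf
    if (max(v - y) <= 1e-9) best <- min(best, sum(y - v))
  }
  best
}

# Exhaustive frame-scan participation: which cells have a peak within +/-w
# frames of the SE peak, walking every cell x frame entry.
participation_oracle <- function(raster, se_peak, w) {
  hits <- integer(0)
  for (i in seq_len(nrow(raster))) {
    for (t_ in seq_len(ncol(raster))) {
      if (raster[i, t_] && abs(t_ - se_peak) <= w) {
        hits <- c(hits, i)
        break
      }
    }
  }
  hits
}

# Greedy peak matching with +/-tol frame tolerance; returns tp/fp/fn.
match_peaks <- function(detected, truth, tol = 1) {
  used <- rep(FALSE, length(detected))
  tp <- 0L
  for (tf in truth) {
    j <- which(!used & abs(detected - tf) <= tol)
    if (length(j)) { used[j[1]] <- TRUE; tp <- tp + 1L }
  }
  list(tp = tp, fp = sum(!used), fn = length(truth) - tp)
}

# A single clean trace with isolated transients of known peak frames and
# amplitude (in noise-SD units), riding on a cubic drift.
make_event_trace <- function(n_frames = 600, peaks = seq(30, 570, by = 30),
                             amp_sd = 6, noise_sd = 1, drift = c(100, -8, 3, -2),
                             seed = 1, fp = 0.328) {
  set.seed(seed)
  s01 <- (seq_len(n_frames) - 1) / (n_frames - 1)
  base <- drift[1] + drift[2] * s01 + drift[3] * s01^2 + drift[4] * s01^3
  tfr <- (seq_len(n_frames) - 1) * fp
  x <- base
  for (pk in peaks) {
    idx <- max(1, pk - 2):min(n_frames, pk + 40)
    x[idx] <- x[idx] + amp_sd * noise_sd *
      casync:::transient_kernel(tfr[idx] - tfr[pk], 0.05, 1)
  }
  x + rnorm(n_frames, 0, noise_sd)
}

# Two-group movies-within-animals design with known group difference.
sim_lmm_data <- function(delta = 1, n_animals = 10, n_movies = 4,
                         sd_animal = 0.5, sd_res = 0.5) {
  d <- expand.grid(animal = seq_len(2 * n_animals), movie = seq_len(n_movies))
  d$group <- ifelse(d$animal <= n_animals, "ctrl", "treat")
  a_eff <- rnorm(2 * n_animals, 0, sd_animal)
  d$value <- ifelse(d$group == "treat", delta, 0) + a_eff[d$animal] +
    rnorm(nrow(d), 0, sd_res)
  d
}

detrend_pipeline <- function(trace, fp = 0.328, exclude = NULL, cutoff = 0.5) {
  sm <- smooth_trace(trace, cutoff, fp)
  sl <- fit_support_line(sm, exclude = exclude)
  detrend_trace(trace, sl)
}
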