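test_that("trace generator is deterministic and validates parameters", {
  p <- trace_sim_params(n_cells = 20, n_frames = 400, seed = 11)
  a <- simulate_traces(p)
  b <- simulate_traces(p)
  expect_identical(a$traces$traces, b$traces$traces)
  expect_identical(a$truth$se_frames, b$truth$se_frames)
  expect_identical(a$truth$spike_frames, b$truth$spike_frames)

  expect_error(trace_sim_params(frac_glia = 1.2), "fractions")
  expect_error(trace_sim_params(se_rate_per_min = -1), "rates")
  expect_error(trace_sim_params(n_frames = 100, se_rate_per_min = 2), "60 s")
  expect_error(trace_sim_params(n_frames = 400, kcl_onset_frame = 500),
               "kcl_onset_frame")
})

test_that("degenerate generator settings give constant traces", {
  p <- trace_sim_params(n_cells = 4, n_frames = 300, se_rate_per_min = 0,
                        async_rate_per_cell_per_min = 0, noise_sd = 0,
                        bleach_cubic_coeffs = c(50, 0, 0, 0),
                        kcl_enabled = FALSE, frac_nonviable = 0,
                        frac_glia = 0, seed = 1)
  sim <- simulate_traces(p)
  expect_true(all(sim$traces$traces == 50))
})

test_that("SE counts are Poisson-consistent and participation matches", {
  rate <- 2
  counts <- vapply(1:100, function(s) {
    p <- trace_sim_params(n_cells = 2, n_frames = 975, se_rate_per_min = rate,
                          async_rate_per_cell_per_min = 0, frac_nonviable = 0,
                          frac_glia = 0, seed = s)
    length(simulate_traces(p)$truth$se_frames)
  }, numeric(1))
  sim_one <- simulate_traces(trace_sim_params(n_cells = 2, seed = 1))
  dur_min <- sim_one$truth$analysis_frames[2] * 0.328 / 60
  lambda <- rate * dur_min
  expect_lt(abs(mean(counts) - lambda), 3 * sqrt(lambda / 100))

  sim <- simulate_traces(trace_sim_params(n_cells = 150, seed = 5))
  n_elig <- sum(sim$truth$viable_mask & !sim$truth$glia_mask)
  mean_part <- mean(lengths(sim$truth$se_participants)) / n_elig
  expect_lt(abs(mean_part - 0.6), 0.05)
})

test_that("ground truth respects its own invariants", {
  for (s in 1:5) {
    sim <- simulate_traces(trace_sim_params(n_cells = 40, burst_prob = 0.4,
                                            seed = s))
    tr <- sim$truth
    eligible <- which(tr$viable_mask)
    for (part in tr$se_participants)
      expect_true(all(part %in% eligible))
    # burst members are consecutive SEs
    for (b in setdiff(unique(tr$burst_id), NA)) {
      m <- which(tr$burst_id == b)
      expect_identical(m, seq(min(m), max(m)))
      expect_gte(length(m), 2)
    }
    expect_true(all(diff(tr$se_frames) > 0))
  }
})

test_that("rendered movies reproduce their traces over true ROIs", {
  p <- trace_sim_params(n_cells = 5, n_frames = 120, se_rate_per_min = 0,
                        async_rate_per_cell_per_min = 3, kcl_enabled = FALSE,
                        frac_nonviable = 0, frac_glia = 0, noise_sd = 0.5,
                        seed = 2)
  sim <- simulate_traces(p)
  rm_ <- render_movie(sim$traces, h = 40, w = 40, roi_radius = 2,
                      background = 7, pixel_noise_sd = 0, seed = 2)
  for (i in 1:5) {
    px_mean <- apply(rm_$movie$data, 1,
                     function(fr) mean(fr[rm_$rois[[i]]]))
    expect_gt(cor(px_mean, sim$traces$traces[i, ]), 0.99)
  }
  # far-from-ROI pixels carry the background
  all_roi <- unlist(rm_$rois)
  far <- setdiff(seq_len(40 * 40), all_roi)[1]
  expect_equal(unique(rm_$movie$data[, , ][cbind(1:120,
    ((far - 1) %% 40) + 1, ((far - 1) %/% 40) + 1)]), 7)

  # radius 0: the single pixel IS the trace
  rm0 <- render_movie(sim$traces, h = 40, w = 40, roi_radius = 0,
                      background = 7, seed = 3)
  expect_equal(apply(rm0$movie$data, 1, function(fr) fr[rm0$rois[[1]]]),
               pmax(sim$traces$traces[1, ], 0))

  expect_error(render_movie(sim$traces, h = 8, w = 8, roi_radius = 3),
               "cannot place")
})

test_that("EEG generator honours component power, gain and determinism", {
  # single 6 Hz component, no noise: variance = A^2/2
  p <- eeg_sim_params(duration_s = 20, band_components = list(c(6, 10)),
                      noise_sd = 0, seed = 1)
  sig <- simulate_eeg(p)
  expect_equal(mean(sig$samples^2), 10^2 / 2, tolerance = 1e-3)
  expect_null(attr(sig, "truth")$onset_s)

  expect_identical(simulate_eeg(p)$samples, simulate_eeg(p)$samples)

  # seizure gain: RMS ratio close to the gain (spikes add a little more)
  ps <- eeg_sim_params(duration_s = 300, seizure_onset_s = 150,
                       seizure_offset_s = 250, seizure_gain = 3, seed = 4)
  xs <- simulate_eeg(ps)$samples
  fs <- ps$fs_hz
  rms <- function(i) sqrt(mean(xs[i]^2))
  ratio <- rms((150 * fs):(250 * fs)) / rms(1:(140 * fs))
  expect_gt(ratio, 3)
  expect_lt(ratio, 6)

  expect_error(eeg_sim_params(fs_hz = 100, band_components = list(c(80, 1))),
               "aliasing")
  expect_error(eeg_sim_params(seizure_onset_s = 100, seizure_offset_s = 50,
                              duration_s = 200), "onset < offset")
})
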