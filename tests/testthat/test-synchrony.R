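raster_from_peaks <- function(peak_list, n_frames, fp = 0.328) {
  evs <- lapply(peak_list, function(p)
    data.frame(peak = as.integer(p)))
  event_raster(evs, n_frames, fp)
}

test_that("population PCA is orthonormal, oriented, and catches shared activity", {
  set.seed(2)
  shared <- rep(0, 200); shared[c(50, 120)] <- 10
  shared <- stats::filter(shared, 0.7^(0:10), sides = 1)
  shared[is.na(shared)] <- 0
  D <- matrix(rep(shared, each = 12), 12, 200) + rnorm(12 * 200, 0, 0.01)
  pc <- population_pca(D)
  expect_gt(pc$var_frac[1], 0.99)
  expect_equal(crossprod(pc$loadings), diag(ncol(pc$loadings)),
               tolerance = 1e-8, ignore_attr = TRUE)
  # sign convention: negating the input leaves oriented time courses alone
  pc2 <- population_pca(-D)
  expect_equal(pc2$timecourses[1, ], pc$timecourses[1, ], tolerance = 1e-6)
  expect_gte(casync:::skewness(pc$timecourses[1, ]), 0)

  expect_error(population_pca(matrix(1, 5, 10)), "zero-variance")
})

test_that("SE component selection follows the event raster", {
  set.seed(3)
  sim <- simulate_traces(trace_sim_params(n_cells = 80, seed = 3))
  an <- analyze_traces(sim$traces, kcl_window = sim$truth$kcl_window)
  expect_lte(an$se_component$index, 2)
  expect_gt(an$se_component$confidence, 0.8)

  # purely asynchronous activity: no component tracks the raster well
  p0 <- trace_sim_params(n_cells = 60, se_rate_per_min = 0,
                         async_rate_per_cell_per_min = 4, seed = 9)
  sim0 <- simulate_traces(p0)
  an0 <- analyze_traces(sim0$traces, kcl_window = sim0$truth$kcl_window)
  expect_true(an0$se_component$low_confidence)
})

test_that("SE detection counts constructed supra-threshold peaks", {
  pcg <- rep(0, 300)
  for (f in c(60, 150, 240)) {
    idx <- f:(f + 12)
    pcg[idx] <- pcg[idx] + 30 * exp(-(idx - f) / 3)
  }
  pcg <- pcg + rnorm(300, 0, 0.5)
  raster <- raster_from_peaks(list(c(60, 150, 240)), 300)
  ses <- detect_ses(pcg, raster)
  expect_equal(nrow(ses), 3)
  expect_true(all(abs(ses$peak_frame - c(60, 150, 240)) <= 1))

  flat <- rnorm(300, 0, 0.3)
  expect_equal(nrow(detect_ses(flat, raster)), 0)
})

test_that("participation window is exactly +/-3 frames at 0.328 s", {
  raster <- raster_from_peaks(list(10, 13, 14, 7, 6), 20)
  p <- participation(raster, 10)
  expect_equal(p$window_frames, 3)
  expect_setequal(p$participants, c(1, 2, 4))  # peaks at 10, 13, 7 in window
  expect_equal(p$fraction, 3 / 5)

  # all cells at the peak frame -> fraction 1
  r2 <- raster_from_peaks(list(10, 10, 10), 20)
  expect_equal(participation(r2, 10)$fraction, 1)
})

test_that("participant sets equal the exhaustive frame scan", {
  set.seed(17)
  for (i in 1:20) {
    n_cells <- sample(3:8, 1)
    raster <- raster_from_peaks(
      lapply(seq_len(n_cells), function(j) sample(1:60, sample(0:6, 1))), 60)
    pk <- sample(4:57, 1)
    expect_setequal(participation(raster, pk)$participants,
                    participation_oracle(raster, pk, 3))
  }
})

test_that("every event is sync xor async and counts are conserved", {
  se_peaks <- c(20, 50)
  raster <- raster_from_peaks(list(c(20, 35), c(49, 10)), 60)
  cls <- classify_async(c(20, 35, 49, 10), se_peaks, raster)
  expect_identical(cls$is_sync, c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(cls$n_sync + cls$n_async, 4)

  set.seed(23)
  for (i in 1:15) {
    peaks <- sort(sample(1:200, 25))
    ses <- sort(sample(1:200, 4))
    cls <- classify_async(peaks, ses, raster_from_peaks(list(peaks), 200))
    brute <- vapply(peaks, function(p) any(abs(p - ses) <= 3), logical(1))
    expect_identical(cls$is_sync, brute)
    expect_equal(cls$n_sync + cls$n_async, length(peaks))
  }
})

test_that("burst chaining follows the baseline-return rule", {
  # two well-separated peaks returning to baseline: no burst
  pcg <- rep(0, 200)
  pcg[50:56] <- 20 * exp(-(0:6)); pcg[150:156] <- 20 * exp(-(0:6))
  b <- detect_bursts(pcg, c(50, 150))
  expect_equal(nrow(b$bursts), 0)
  expect_equal(b$pct_se_in_bursts, 0)

  # overlapping pair whose valley stays high: one burst of 2, pct 100
  pcg2 <- rep(0, 120)
  pcg2[40:70] <- 12
  pcg2[c(45, 60)] <- 20
  b2 <- detect_bursts(pcg2, c(45, 60))
  expect_equal(b2$pct_se_in_bursts, 100)
  expect_equal(b2$bursts$n_se, 2)

  # 5 SEs with exactly one merged pair -> 40%
  pcg3 <- rep(0, 400)
  for (f in c(50, 130, 210, 290, 350)) pcg3[f:(f + 8)] <- 15 * exp(-(0:8) / 2)
  pcg3[130:145] <- pmax(pcg3[130:145], 10)   # bridge 130 -> its pair at 141
  pcg3[141:149] <- pmax(pcg3[141:149], 15 * exp(-(0:8) / 2))
  b3 <- detect_bursts(pcg3, c(50, 130, 141, 210, 290))
  expect_equal(b3$pct_se_in_bursts, 40)
  expect_identical(b3$se_burst_id, c(NA_integer_, 1L, 1L, NA_integer_,
                                     NA_integer_))

  expect_equal(detect_bursts(pcg, c(50))$pct_se_in_bursts, 0)
})

test_that("movie summary fields are consistent and shift-invariant", {
  raster <- raster_from_peaks(list(c(20, 40), 21, integer(0)), 100)
  pc1 <- rep(0, 100); pc1[18:24] <- c(1, 4, 9, 4, 2, 1, 0)
  ses <- detect_ses(pc1, raster)
  s <- summarize_movie(raster, ses, NULL, duration_s = 180)
  expect_equal(s$n_se, 1)
  expect_equal(s$se_per_min, 1 / 3)
  expect_equal(s$total_events, 3)
  expect_equal(s$pct_active_cells, 100 * 2 / 3)
  expect_equal(s$n_se + 0, nrow(ses))

  # 6 SEs in a 3-minute movie: 2 per minute
  r6 <- raster_from_peaks(list(seq(30, 530, by = 100)), 549)
  pc6 <- rep(0, 549); pc6[seq(30, 530, by = 100)] <- 25
  for (f in seq(30, 530, by = 100)) pc6[f + 1:5] <- 25 * exp(-(1:5))
  s6 <- summarize_movie(r6, detect_ses(pc6, r6), NULL, duration_s = 180)
  expect_equal(s6$n_se, 6)
  expect_equal(s6$se_per_min, 2)

  # empty raster: all zero
  r0 <- raster_from_peaks(list(integer(0), integer(0)), 100)
  s0 <- summarize_movie(r0, detect_ses(rep(0, 100) + rnorm(100, 0, 1e-6), r0),
                        NULL, duration_s = 60)
  expect_equal(s0$total_events, 0)
  expect_equal(s0$pct_active_cells, 0)
  expect_equal(s0$pct_cells_per_se, 0)

  # shifting all events and peaks leaves the summary unchanged
  sh <- 7
  r_sh <- raster_from_peaks(list(c(20, 40) + sh, 21 + sh, integer(0)), 100)
  ses_sh <- ses; ses_sh$peak_frame <- ses$peak_frame + sh
  s_sh <- summarize_movie(r_sh, ses_sh, NULL, duration_s = 180)
  expect_equal(s_sh[, -1], s[, -1])

  expect_error(summarize_movie(raster, ses, NULL, duration_s = 0), "positive")
})

test_that("widening the participation window never loses participants", {
  set.seed(29)
  raster <- raster_from_peaks(
    lapply(1:6, function(j) sample(1:80, sample(1:5, 1))), 80)
  prev <- -1
  for (w_s in c(0.3, 0.984, 2, 4)) {
    p <- participation(raster, 40, synchrony_params(participation_window_s = w_s))
    expect_gte(p$n, prev)
    prev <- p$n
  }
})
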