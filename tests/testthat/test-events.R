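test_that("smoothing preserves DC and the passband, attenuates above cutoff", {
  fp <- 0.328
  expect_equal(smooth_trace(rep(3.7, 200), 0.5, fp), rep(3.7, 200),
               tolerance = 1e-5)

  t <- (0:799) * fp
  fast <- sin(2 * pi * 1.0 * t)            # 2 x cutoff
  out <- smooth_trace(fast, 0.5, fp)
  expect_lt(max(abs(out[100:700])), 0.1 * 1)

  slow <- sin(2 * pi * 0.02 * t)           # period 50 s >> 1/cutoff
  out2 <- smooth_trace(slow, 0.5, fp)
  expect_lt(max(abs(out2 - slow)[100:700]), 0.01)

  expect_error(smooth_trace(rnorm(10), 2, fp), "Nyquist")
})

test_that("support line reproduces trivial envelopes exactly", {
  expect_equal(fit_support_line(rep(5, 30))$values, rep(5, 30),
               tolerance = 1e-8)
  expect_equal(fit_support_line(rep(5, 30))$objective, 0, tolerance = 1e-9)

  s <- 2 * (0:29) / 29 - 1
  q <- 2 + 3 * s - s^2 + 0.5 * s^3
  sl <- fit_support_line(q)
  expect_equal(sl$values, q, tolerance = 1e-8)

  # positive bump on a line: the line is the optimum
  line <- 1 + 0.1 * (1:40)
  y <- line; y[18:22] <- y[18:22] + c(1, 3, 4, 3, 1)
  sl2 <- fit_support_line(y)
  expect_equal(sl2$values, line, tolerance = 1e-7)
  expect_equal(sl2$objective, 12, tolerance = 1e-7)
})

test_that("LP support line matches the vertex-enumeration oracle", {
  set.seed(31)
  for (i in 1:40) {
    n <- sample(8:16, 1)
    y <- rnorm(n) + cumsum(rnorm(n, 0, 0.3))
    sl <- fit_support_line(y)
    expect_lt(abs(sl$objective - support_line_oracle(y)), 1e-6)
    expect_lte(max(sl$values - y), 1e-9)
  }
})

test_that("support line is equivariant to adding a cubic", {
  set.seed(12)
  n <- 40
  t_ <- seq_len(n)
  for (i in 1:10) {
    y <- 10 + rnorm(n) + cumsum(rnorm(n, 0, 0.2))
    q <- c(rnorm(1, 0, 2), rnorm(1, 0, 0.1), rnorm(1, 0, 1e-3),
           rnorm(1, 0, 1e-5))
    qv <- q[1] + q[2] * t_ + q[3] * t_^2 + q[4] * t_^3
    a <- fit_support_line(y)
    b <- fit_support_line(y + qv)
    expect_equal(b$coef_raw, a$coef_raw + q, tolerance = 1e-8)
  }
})

test_that("support line respects the excluded window", {
  y <- rep(1, 60)
  y[45:60] <- 30                       # "KCl" rise: would drag a full fit up
  sl <- fit_support_line(y, exclude = c(45, 60))
  expect_equal(sl$values[1:44], rep(1, 44), tolerance = 1e-7)
  expect_error(fit_support_line(rep(1, 10), exclude = c(1, 8)), ">= 8")
})

test_that("detrending the support line itself yields zeros", {
  y <- 3 + 0.05 * (1:50)
  sl <- fit_support_line(y)
  dt <- detrend_trace(sl$values, sl)
  expect_equal(dt$filtered, rep(0, 50), tolerance = 1e-8)
})

test_that("event detection finds constructed transients at the right size", {
  n <- 400
  set.seed(5)
  noise <- rnorm(n, 0, 1)
  dt <- structure(list(filtered = noise, baseline_sd = 1, baseline_level = 0,
                       exclude = NULL), class = "detrended_trace")
  dt$filtered[200:203] <- c(3.5, 5, 3.5, 2.5)     # one clear transient
  ev <- detect_events(dt, k = 3)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$peak, 201)
  expect_equal(ev$amplitude_sd, 5)

  # a 2-SD bump is not an event at k = 3
  dt2 <- structure(list(filtered = rep(0, n), baseline_sd = 1,
                        baseline_level = 0, exclude = NULL),
                   class = "detrended_trace")
  dt2$filtered[100:102] <- 2
  expect_equal(nrow(detect_events(dt2, k = 3)), 0)

  expect_error(detect_events(structure(list(filtered = rep(NA_real_, 5),
                                            baseline_sd = 1),
                                       class = "detrended_trace")), "NaN")
})

test_that("raising k never increases the number of events", {
  set.seed(8)
  for (i in 1:5) {
    tr <- make_event_trace(seed = i)
    dt <- detrend_pipeline(tr)
    n_prev <- Inf
    for (k in c(2, 3, 4, 5, 6)) {
      n_k <- nrow(detect_events(dt, k = k))
      expect_lte(n_k, n_prev)
      n_prev <- n_k
    }
  }
})

test_that("event calling is invariant to cubic drift", {
  set.seed(21)
  for (i in 1:6) {
    tr <- make_event_trace(n_frames = 500, peaks = seq(40, 460, by = 42),
                           seed = 40 + i)
    t_ <- seq_len(500)
    drift <- 5 + 20 * (t_ / 500) - 15 * (t_ / 500)^2 + 30 * (t_ / 500)^3
    ev_a <- detect_events(detrend_pipeline(tr), k = 3)
    ev_b <- detect_events(detrend_pipeline(tr + drift), k = 3)
    expect_equal(nrow(ev_a), nrow(ev_b))
    expect_true(all(abs(sort(ev_a$peak) - sort(ev_b$peak)) <= 1))
  }
})

test_that("detection recovers planted 6-SD events with high precision/recall", {
  peaks <- seq(30, 570, by = 28)           # 20 isolated events
  res <- vapply(1:5, function(s) {
    tr <- make_event_trace(peaks = peaks, amp_sd = 6, seed = 100 + s)
    ev <- detect_events(detrend_pipeline(tr), k = 3)
    m <- match_peaks(ev$peak, peaks, tol = 1)
    c(m$tp / (m$tp + m$fp), m$tp / (m$tp + m$fn))
  }, numeric(2))
  expect_true(all(res[1, ] >= 0.9))        # precision
  expect_true(all(res[2, ] >= 0.9))        # recall
})
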