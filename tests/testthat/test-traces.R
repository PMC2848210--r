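damped_cosine <- function(t, period = 90, decay = 300) {
  exp(-t / decay) * cos(2 * pi * t / period)
}

test_that("normalisation is affine invariant and guards constants", {
  t <- seq(0, 200, by = 2)
  y <- damped_cosine(t)
  n1 <- normalize_trace(y, smooth_window = 1)
  n2 <- normalize_trace(7 * y + 123, smooth_window = 1)
  expect_equal(n1, n2, tolerance = 1e-12)
  expect_equal(range(n1), c(0, 1))
  # already [0,1] spanning the full range: unchanged without smoothing
  z <- c(0, 0.4, 1, 0.2)
  expect_equal(normalize_trace(z, smooth_window = 1), z)
  expect_error(normalize_trace(rep(3, 10)), "constant")
  expect_error(normalize_trace(1), "at least 2")
})

test_that("peaks of a damped cosine sit at the closed-form positions", {
  t <- seq(0, 400, by = 2)
  y <- normalize_trace(damped_cosine(t), smooth_window = 1)
  pk <- detect_peaks(y, t_min = t)
  # interior maxima near 90, 180, 270, 360 (t=0 is an endpoint, excluded);
  # the exponential envelope shifts each peak by atan(lambda/omega)/omega
  # ~= 0.7 min, within one 2-min frame
  expect_equal(length(pk$peak_times_min), 4)
  expect_true(all(abs(pk$peak_times_min - c(90, 180, 270, 360)) <= 2))
  expect_true(all(abs(pk$intervals_min - 90) <= 2))
})

test_that("monotone ramps have no peaks; endpoints never count", {
  expect_length(detect_peaks(seq(0, 1, length.out = 50))$peak_times_min, 0)
  y <- c(seq(0, 1, length.out = 25), seq(0.99, 0.5, length.out = 10))
  pk <- detect_peaks(y)
  expect_equal(length(pk$peak_times_min), 1) # interior max only
})

test_that("equal peaks closer than the separation keep the earlier one", {
  t <- c(0, 10, 20, 30, 40)
  y <- c(0, 1, 0.5, 1, 0)
  pk <- detect_peaks(y, t_min = t, min_separation_min = 25)
  expect_equal(pk$peak_times_min, 10)
  # far enough apart: both survive
  pk2 <- detect_peaks(y, t_min = t, min_separation_min = 15)
  expect_equal(pk2$peak_times_min, c(10, 30))
})

test_that("peak detection is shift invariant", {
  t <- seq(0, 400, by = 2)
  y <- normalize_trace(damped_cosine(t), smooth_window = 1)
  for (shift in c(14, 50, 126)) {
    pk0 <- detect_peaks(y, t_min = t)
    pk1 <- detect_peaks(y, t_min = t + shift)
    expect_equal(pk1$peak_times_min, pk0$peak_times_min + shift)
    expect_equal(pk1$intervals_min, pk0$intervals_min)
  }
})

test_that("intervals are robust to smoothing windows 1-5", {
  t <- seq(0, 400, by = 2)
  base <- damped_cosine(t)
  for (wdw in c(1, 3, 5)) {
    pk <- detect_peaks(normalize_trace(base, smooth_window = wdw), t_min = t)
    expect_true(all(abs(pk$intervals_min - 90) <= 2 + 2))
  }
})

test_that("first-peak alignment brings ensembles into register", {
  p <- oscillator_params()
  onsets <- c(0, 20, 40, 60)
  t <- seq(0, 400, by = 2)
  traces <- lapply(onsets, function(on)
    generate_trace(p, onset_min = on, noise_sd = 0, t_end_min = 400,
                   dt_min = 2)$value)
  norm <- lapply(traces, normalize_trace, smooth_window = 1)
  al <- align_first_peak(norm, t_min = t)
  expect_length(al$aligned, 4)
  # every aligned trace peaks at 0 within one frame
  for (d in al$aligned) {
    pk <- detect_peaks(d$value, t_min = d$t_min)
    expect_lte(abs(pk$peak_times_min[1]), 2)
  }
  # exactly shift-identical traces align to identical curves: a single
  # damped waveform translated in time, zero before onset, with its
  # extremes visible in every window so normalisation is shared
  g <- function(u) ifelse(u > 0, exp(-u / 150) * (1 - cos(2 * pi * u / 90))
                          / 2, 0)
  shifted <- lapply(onsets, function(on) g(t - on))
  al_g <- align_first_peak(shifted, t_min = t)
  common <- al_g$mean$t_min[al_g$mean$t_min >= 0 & al_g$mean$t_min <= 100]
  vals <- vapply(al_g$aligned, function(d)
    approx(d$t_min, d$value, xout = common)$y, numeric(length(common)))
  expect_lt(max(apply(vals, 1, function(r) diff(range(r)))), 1e-9)
  expect_equal(approx(al_g$mean$t_min, al_g$mean$value, xout = common)$y,
               vals[, 1], tolerance = 1e-9)
  # single trace: mean equals the trace
  one <- align_first_peak(norm[1], t_min = t)
  expect_equal(one$mean$value,
               one$aligned[[1]]$value[one$aligned[[1]]$t_min %in%
                                        one$mean$t_min])
  # peakless trace is excluded with a warning
  expect_warning(al2 <- align_first_peak(c(norm[1:2], list(rep(0, 201))),
                                         t_min = t),
                 "excluded")
  expect_equal(al2$excluded, 3L)
})

test_that("interval histogram counts and boundary conventions", {
  h <- interval_histogram(c(90, 95, 85, 45))
  expect_equal(unname(h$counts[["[40,60)"]]), 1)
  expect_equal(unname(h$counts[["[80,100)"]]), 3)
  expect_equal(unname(h$modal_bin), c(80, 100))
  expect_equal(sum(h$counts), 4)
  # boundary: exactly 100 falls in [100,120)
  h100 <- interval_histogram(rep(100, 5))
  expect_equal(unname(h100$counts[["[100,120)"]]), 5)
  # 140 is included in the closed top bin, 141 overflows to the guard
  h140 <- interval_histogram(c(140, 141, 30))
  expect_equal(unname(h140$counts[["[120,140]"]]), 1)
  expect_equal(unname(h140$counts[["over"]]), 1)
  expect_equal(unname(h140$counts[["under"]]), 1)
  expect_error(interval_histogram(numeric(0)), "non-empty")
})

test_that("histogram conservation holds for random inputs", {
  set.seed(2024)
  for (k in 1:20) {
    iv <- runif(sample(1:60, 1), 5, 220)
    h <- interval_histogram(iv)
    expect_equal(sum(h$counts), length(iv))
  }
})

test_that("generated traces obey onset, determinism and baseline", {
  p <- oscillator_params()
  tr <- generate_trace(p, onset_min = 30, noise_sd = 0, t_end_min = 200,
                       dt_min = 1)
  ss <- steady_state(p)
  expect_lt(max(abs(tr$value[tr$t_min < 30] - ss$n)), 1e-8)
  # zero-noise, zero-onset equals the oscillator solution
  tr0 <- generate_trace(p, onset_min = 0, noise_sd = 0, t_end_min = 200,
                        dt_min = 1)
  ref <- simulate_cell(p, stimulus_profile("sustained"), 200, 1)
  expect_equal(tr0$value, ref$n_p65, tolerance = 1e-12)
  # fixed seed, noisy: identical twice
  a <- generate_trace(p, 10, noise_sd = 0.05, t_end_min = 100, dt_min = 1,
                      seed = 99)
  b <- generate_trace(p, 10, noise_sd = 0.05, t_end_min = 100, dt_min = 1,
                      seed = 99)
  expect_identical(a$value, b$value)
  expect_error(generate_trace(p, onset_min = 50, t_end_min = 40), "exceed")
})
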