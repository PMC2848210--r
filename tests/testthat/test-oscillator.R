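test_that("nuclear fraction has the closed-form landmarks", {
  p <- oscillator_params()
  expect_equal(nuclear_fraction(0, p), 1)
  expect_equal(nuclear_fraction(p$K_i, p), 0.5)
  p4 <- oscillator_params(h = 4)
  expect_equal(nuclear_fraction(2 * p4$K_i, p4), 1 / 17)
  expect_error(nuclear_fraction(-1, p), "non-negative")
  # strictly decreasing
  x <- seq(0, 10, by = 0.1)
  expect_true(all(diff(nuclear_fraction(x, p)) < 0))
})

test_that("steady state solves the resting balance", {
  # linear case: k_syn = 0 collapses to k_basal/k_turn exactly
  p0 <- oscillator_params(k_syn = 1e-12, k_basal_syn = 0.05, k_turn = 0.02)
  expect_equal(steady_state(p0)$x, 2.5, tolerance = 1e-6)
  p <- oscillator_params()
  ss <- steady_state(p)
  residual <- p$k_basal_syn + p$k_syn * nuclear_fraction(ss$x, p) -
    p$k_turn * ss$x
  expect_lt(abs(residual), 1e-10)
  # grid-scan oracle: returned root minimises |residual| on a dense grid
  grid <- seq(0.01, 20, by = 0.001)
  res_grid <- abs(p$k_basal_syn + p$k_syn * nuclear_fraction(grid, p) -
                    p$k_turn * grid)
  expect_lt(abs(grid[which.min(res_grid)] - ss$x), 0.001)
})

test_that("no stimulus keeps the trace at equilibrium for 1000 min", {
  p <- oscillator_params()
  tr <- simulate_cell(p, stimulus_profile("none"), t_end_min = 1000,
                      dt_min = 1)
  ss <- steady_state(p)
  expect_lt(max(abs(tr$x_ikba - ss$x)), 1e-8)
  expect_lt(max(abs(tr$n_p65 - ss$n)), 1e-8)
})

test_that("sustained stimulus yields damped oscillations", {
  tr <- simulate_cell(oscillator_params(), stimulus_profile("sustained"),
                      t_end_min = 400, dt_min = 0.5)
  expect_true(all(tr$n_p65 >= 0 & tr$n_p65 <= 1))
  expect_true(all(tr$x_ikba >= 0))
  pk <- detect_peaks(tr$n_p65, t_min = tr$t_min)
  expect_gte(length(pk$peak_times_min), 2)
  h <- pk$peak_heights[1:min(3, length(pk$peak_heights))]
  expect_true(all(diff(h) < 0)) # strictly decreasing amplitude
})

test_that("a short pulse produces exactly one prominent peak", {
  tr <- simulate_cell(oscillator_params(),
                      stimulus_profile("pulse", duration_min = 5),
                      t_end_min = 300, dt_min = 0.5)
  pk <- detect_peaks(tr$n_p65 / max(tr$n_p65), t_min = tr$t_min)
  expect_equal(length(pk$peak_times_min), 1)
})

test_that("oscillation requires the delay", {
  p <- oscillator_params(tau = 2) # effectively no delay
  tr <- simulate_cell(p, stimulus_profile("sustained"), t_end_min = 400,
                      dt_min = 0.1)
  pk <- detect_peaks(tr$n_p65, t_min = tr$t_min)
  expect_lte(length(pk$peak_times_min), 1)
})

test_that("step halving converges and matches an independent integrator", {
  p <- oscillator_params()
  tr1 <- simulate_cell(p, stimulus_profile("sustained"), 400, 0.5)
  tr2 <- simulate_cell(p, stimulus_profile("sustained"), 400, 0.25)
  expect_lt(max(abs(tr1$x_ikba - tr2$x_ikba[seq(1, 1601, by = 2)])), 1e-4)
  # independent explicit-Euler reference; dt/100 keeps the first-order
  # oracle's own error inside the 1e-3 band (at dt/50 it is ~2e-3)
  ref <- euler_reference(p, "sustained", t_end = 400, dt = 0.005)
  idx <- seq(1, length(ref$t_min), by = 100)
  expect_lt(max(abs(tr1$x_ikba - ref$x_ikba[idx])), 1e-3)
  expect_lt(max(abs(tr1$n_p65 - ref$n_p65[idx])), 1e-3)
})

test_that("state bounds hold across random parameter sets", {
  set.seed(123)
  for (k in 1:8) {
    p <- oscillator_params(k_deg = runif(1, 0.05, 0.4),
                           k_syn = runif(1, 0.1, 1),
                           k_basal_syn = runif(1, 0.005, 0.1),
                           k_turn = runif(1, 0.005, 0.05),
                           tau = runif(1, 25, 60),
                           h = sample(1:4, 1))
    tr <- simulate_cell(p, stimulus_profile("sustained"), 300, 1)
    expect_true(all(tr$n_p65 >= 0 & tr$n_p65 <= 1))
    expect_true(all(tr$x_ikba >= 0))
  }
})

test_that("dt must resolve the delay", {
  expect_error(simulate_cell(oscillator_params(tau = 5),
                             stimulus_profile("sustained"), 100, 1),
               "tau/20")
})

test_that("dominant period recovers a cosine and rejects flat traces", {
  t <- seq(0, 400, by = 1)
  tr <- data.frame(t_min = t, n_p65 = 0.5 + 0.4 * cos(2 * pi * t / 90))
  expect_lt(abs(dominant_period(tr) - 90), 1 + 1e-9)
  flat <- data.frame(t_min = t, n_p65 = rep(0.2, length(t)))
  expect_true(is.na(dominant_period(flat)))
  # defaults land in the 80-100 min band
  tr_def <- simulate_cell(oscillator_params(), stimulus_profile("sustained"),
                          400, 0.5)
  per <- dominant_period(tr_def)
  expect_gte(per, 80)
  expect_lte(per, 100)
})
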