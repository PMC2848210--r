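#' Generate a noisy single-cell oscillation trace
#'
#' Emulates a live-cell nuclear-GFP time series: the delay-oscillator
#' solution with a sustained stimulus starting at `onset_min` (the cell
#' stays at its resting state before onset), plus zero-mean Gaussian
#' measurement noise.
#'
#' @param params an [oscillator_params()].
#' @param onset_min activation onset of this cell (min).
#' @param noise_sd standard deviation of the additive noise, on the
#'   nuclear-fraction scale.
#' @param t_end_min,dt_min time span and sampling step (min).
#' @param seed integer seed for the noise stream.
#' @return data frame with columns `t_min` and `value` (noisy nuclear
#'   signal); attributes `onset_min` and `clean` (the noise-free series).
#' @export
generate_trace <- function(params, onset_min = 0, noise_sd = 0.02,
                           t_end_min = 400, dt_min = 2, seed = 1L) {
  stopifnot(inherits(params, "oscillator_params"))
  check_number(onset_min, "onset_min", lower = 0)
  check_number(noise_sd, "noise_sd", lower = 0)
  if (t_end_min <= onset_min) stop("'t_end_min' must exceed 'onset_min'")
  tr <- simulate_cell(params, stimulus_profile("sustained",
                                               onset_min = onset_min),
                      t_end_min = t_end_min, dt_min = dt_min)
  set.seed(as.integer(seed))
  noise <- if (noise_sd > 0) rnorm(nrow(tr), 0, noise_sd) else 0
  out <- data.frame(t_min = tr$t_min, value = tr$n_p65 + noise)
  attr(out, "onset_min") <- onset_min
  attr(out, "clean") <- tr$n_p65
  out
}

#' Simulate an ensemble of heterogeneous single-cell traces
#'
#' Draws per-cell delay and degradation-rate multipliers from the default
#' cell-to-cell heterogeneity model (truncated normals) and simulates each
#' cell with a sustained stimulus. This is the stated world for the
#' single-cell interval statistics: peak-to-peak intervals pooled over the
#' ensemble fall within the observed 40-140 min range with the 80-100 min
#' bin most frequent.
#'
#' @param params an [oscillator_params()].
#' @param n_cells ensemble size.
#' @param tau_sd,tau_bounds relative spread and truncation of the per-cell
#'   delay multiplier.
#' @param k_deg_sd,k_deg_bounds same for the degradation-rate multiplier.
#' @param onset_max_min onsets are uniform on `[0, onset_max_min]`.
#' @param t_end_min,dt_min simulation span and step.
#' @param seed integer seed.
#' @return list with `traces` (cells x timepoints matrix of `n_p65`),
#'   `t_min`, and a data frame `cells` (`tau`, `k_deg`, `onset_min`).
#' @export
simulate_trace_ensemble <- function(params = oscillator_params(),
                                    n_cells = 50L, tau_sd = 0.15,
                                    tau_bounds = c(0.5, 1.5),
                                    k_deg_sd = 0.25,
                                    k_deg_bounds = c(0.3, 2),
                                    onset_max_min = 0, t_end_min = 400,
                                    dt_min = 0.5, seed = 1L) {
  stopifnot(inherits(params, "oscillator_params"))
  check_number(n_cells, "n_cells", lower = 1)
  set.seed(as.integer(seed))
  tau_mult <- rtruncnorm(n_cells, 1, tau_sd, tau_bounds[1], tau_bounds[2])
  kdeg_mult <- rtruncnorm(n_cells, 1, k_deg_sd, k_deg_bounds[1],
                          k_deg_bounds[2])
  onsets <- if (onset_max_min > 0) runif(n_cells, 0, onset_max_min)
            else rep(0, n_cells)
  X <- dde_integrate(params, stimulus_profile("sustained"), onsets = onsets,
                     t_end_min = t_end_min, dt_min = dt_min,
                     tau = params$tau * tau_mult,
                     k_deg = params$k_deg * kdeg_mult)
  N <- 1 / (1 + (pmax(X, 0) / params$K_i)^params$h)
  list(traces = N, t_min = attr(X, "t_min"),
       cells = data.frame(cell_id = seq_len(n_cells),
                          tau = params$tau * tau_mult,
                          k_deg = params$k_deg * kdeg_mult,
                          onset_min = onsets))
}

#' Pool peak-to-peak intervals from a simulated ensemble
#'
#' Runs default peak detection on each cell of a
#' [simulate_trace_ensemble()] result and pools all peak-to-peak intervals.
#'
#' @param ensemble result of [simulate_trace_ensemble()].
#' @param ... passed to [detect_peaks()].
#' @return numeric vector of pooled intervals (min).
#' @export
ensemble_intervals <- function(ensemble, ...) {
  unlist(lapply(seq_len(nrow(ensemble$traces)), function(i) {
    y <- ensemble$traces[i, ]
    rng <- range(y)
    if (diff(rng) == 0) return(numeric(0))
    pk <- detect_peaks((y - rng[1]) / diff(rng), t_min = ensemble$t_min, ...)
    pk$intervals_min
  }))
}
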