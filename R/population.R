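## MOI-dependent population simulation: asynchronous activation onsets,
## heterogeneous single-cell oscillators, thresholded percentage readout.

#' Population simulation configuration
#'
#' Activation onsets follow a memoryless single-hit contact process: the
#' per-cell first-contact time is exponential with hazard
#' `contact_rate_per_moi * moi`, and translocation starts a fixed lag
#' (default 20 min, the observed attachment-to-translocation delay) after
#' contact. At high MOI contacts are nearly synchronous; at low MOI they
#' spread over hours, which masks the oscillation in the population
#' percentage. The default hazard (0.01 per min and MOI unit) makes nearly
#' all cells activate within minutes of the lag at MOI 100, while at MOI 1
#' contact times average 100 min and spread over several hours, so that
#' activation saturates within a six-hour time course.
#'
#' @param n_cells cells per simulated population.
#' @param moi multiplicity of infection (bacteria per cell).
#' @param contact_rate_per_moi first-contact hazard per minute and MOI
#'   unit.
#' @param attach_to_transloc_lag_min lag between first contact and
#'   activation onset (min).
#' @param tau_sd,tau_bounds per-cell delay multiplier: truncated normal
#'   spread and hard bounds.
#' @param k_deg_sd,k_deg_bounds per-cell degradation-rate multiplier.
#' @param theta_nuc threshold on the nuclear fraction (as a fraction of
#'   the dynamic range above resting) for counting a cell as nuclear.
#' @param t_end_min simulated span (min).
#' @param sample_every_min readout grid spacing (min), as in fixed-cell
#'   time courses.
#' @param dt_min integration step (min).
#' @param seed integer seed.
#' @return object of class `population_config`.
#' @export
population_config <- function(n_cells = 500L, moi = 100,
                              contact_rate_per_moi = 0.01,
                              attach_to_transloc_lag_min = 20,
                              tau_sd = 0.15, tau_bounds = c(0.5, 1.5),
                              k_deg_sd = 0.25, k_deg_bounds = c(0.3, 2),
                              theta_nuc = 0.5, t_end_min = 360,
                              sample_every_min = 15, dt_min = 0.5,
                              seed = 1L) {
  check_number(n_cells, "n_cells", lower = 1)
  check_number(moi, "moi", lower = 0, strict_lower = TRUE)
  check_number(contact_rate_per_moi, "contact_rate_per_moi", lower = 0,
               strict_lower = TRUE)
  check_number(attach_to_transloc_lag_min, "attach_to_transloc_lag_min",
               lower = 0)
  check_number(tau_sd, "tau_sd", lower = 0)
  check_number(k_deg_sd, "k_deg_sd", lower = 0)
  if (tau_bounds[1] <= 0 || k_deg_bounds[1] <= 0)
    stop("heterogeneity truncation bounds must keep multipliers positive")
  check_number(theta_nuc, "theta_nuc", lower = 0, upper = 1,
               strict_lower = TRUE)
  check_number(t_end_min, "t_end_min", lower = 0, strict_lower = TRUE)
  check_number(sample_every_min, "sample_every_min", lower = 0,
               strict_lower = TRUE)
  check_number(dt_min, "dt_min", lower = 0, strict_lower = TRUE)
  structure(list(n_cells = as.integer(n_cells), moi = moi,
                 contact_rate_per_moi = contact_rate_per_moi,
                 attach_to_transloc_lag_min = attach_to_transloc_lag_min,
                 tau_sd = tau_sd, tau_bounds = tau_bounds,
                 k_deg_sd = k_deg_sd, k_deg_bounds = k_deg_bounds,
                 theta_nuc = theta_nuc, t_end_min = t_end_min,
                 sample_every_min = sample_every_min, dt_min = dt_min,
                 seed = as.integer(seed)),
            class = "population_config")
}

#' Sample per-cell activation onsets
#'
#' Inverse-transform exponential draws: `onset = lag - log(U) / rate` with
#' `rate = contact_rate_per_moi * moi`. Using the same seed across MOIs
#' reuses the same uniforms, so onsets are coupled monotonically in MOI.
#' Cells whose contact falls beyond `t_end_min` never activate (`Inf`).
#'
#' @param config a [population_config()].
#' @return numeric vector of onset times (min), `Inf` = never.
#' @export
sample_onsets <- function(config) {
  stopifnot(inherits(config, "population_config"))
  set.seed(seed_stream(config$seed, "onsets"))
  rate <- config$contact_rate_per_moi * config$moi
  onsets <- config$attach_to_transloc_lag_min - log(runif(config$n_cells)) /
    rate
  onsets[onsets > config$t_end_min] <- Inf
  onsets
}

#' Simulate an asynchronously activated population
#'
#' Draws onsets and per-cell heterogeneity, integrates all cells of the
#' delay oscillator under a sustained stimulus starting at each cell's
#' onset, and reports the percentage of cells whose nuclear-p65 fraction
#' exceeds the threshold on the sampling grid. The threshold is
#' `n* + theta_nuc * (1 - n*)` where `n*` is the resting nuclear fraction.
#' Cells that never activate stay at rest and count in the denominator.
#'
#' @param config a [population_config()].
#' @param params an [oscillator_params()].
#' @param keep_traces keep the full per-cell nuclear-fraction matrix.
#' @return object of class `population_result`: list with `t_min`,
#'   `pct_nuclear`, `n_activated` (cells with onset before each timepoint),
#'   `onsets`, `threshold`, and optionally `traces`.
#' @export
simulate_population <- function(config, params = oscillator_params(),
                                keep_traces = FALSE) {
  stopifnot(inherits(config, "population_config"),
            inherits(params, "oscillator_params"))
  onsets <- sample_onsets(config)
  set.seed(seed_stream(config$seed, "heterogeneity"))
  tau_mult <- rtruncnorm(config$n_cells, 1, config$tau_sd,
                         config$tau_bounds[1], config$tau_bounds[2])
  kdeg_mult <- rtruncnorm(config$n_cells, 1, config$k_deg_sd,
                          config$k_deg_bounds[1], config$k_deg_bounds[2])
  # never-activating cells sit at steady state; give them a finite onset
  # beyond the horizon so the integrator sees no stimulus
  sim_onsets <- ifelse(is.finite(onsets), onsets, 2 * config$t_end_min + 1)
  X <- dde_integrate(params, stimulus_profile("sustained"),
                     onsets = sim_onsets, t_end_min = config$t_end_min,
                     dt_min = config$dt_min,
                     tau = params$tau * tau_mult,
                     k_deg = params$k_deg * kdeg_mult)
  tgrid <- attr(X, "t_min")
  ss <- attr(X, "steady")
  N <- 1 / (1 + (pmax(X, 0) / params$K_i)^params$h)
  threshold <- ss$n + config$theta_nuc * (1 - ss$n)
  t_sample <- seq(0, config$t_end_min, by = config$sample_every_min)
  cols <- vapply(t_sample, function(tt) which.min(abs(tgrid - tt)),
                 integer(1))
  activated <- outer(onsets, t_sample, "<=")
  nuclear <- N[, cols, drop = FALSE] >= threshold & activated
  out <- list(t_min = t_sample,
              pct_nuclear = 100 * colMeans(nuclear),
              n_activated = colSums(activated),
              onsets = onsets, threshold = threshold,
              config = config)
  if (keep_traces) {
    out$traces <- N
    out$trace_t_min <- tgrid
  }
  class(out) <- "population_result"
  out
}

#' Oscillation visibility of a population percentage curve
#'
#' Quantifies how visible an oscillation is in a population readout. The
#' curve is min-max normalised and peaks are detected with a topographic
#' prominence filter ([detect_peaks()]), so slow activation trends and
#' counting noise do not register as oscillation. The score is the
#' amplitude (above the curve minimum) of the largest prominent peak
#' occurring after the global maximum, divided by the global maximum
#' amplitude: 0 for monotone or single-peaked curves, and the relative
#' second-peak height for synchronous damped oscillations.
#'
#' @param pct_trace percentage curve on a regular grid.
#' @param min_prominence prominence threshold as a fraction of the curve
#'   range, passed to [detect_peaks()].
#' @param min_tail minimum number of grid points required after the global
#'   maximum for the score to be defined.
#' @return score in `[0, 1]`.
#' @export
oscillation_visibility <- function(pct_trace, min_prominence = 0.2,
                                   min_tail = 5L) {
  y <- as.numeric(pct_trace)
  n <- length(y)
  if (n < 3L + min_tail) stop("trace too short")
  rng <- range(y)
  if (diff(rng) == 0) return(0)
  yn <- (y - rng[1]) / diff(rng)
  pk <- detect_peaks(yn, t_min = seq_len(n), min_prominence = min_prominence,
                     min_separation_min = 2)
  if (!length(pk$peak_times_min)) return(0)  # no oscillatory structure
  imax <- which.max(pk$peak_heights)
  if (n - pk$peak_times_min[imax] < min_tail)
    stop("need at least ", min_tail,
         " points after the dominant peak; extend the time course")
  later <- pk$peak_heights[seq_along(pk$peak_heights) > imax]
  if (!length(later)) return(0)
  max(later) / pk$peak_heights[imax]
}
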