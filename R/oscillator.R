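#' Parameters of the one-variable IkBa delay oscillator
#'
#' The model tracks a single state, the IkBa level \eqn{x(t)}, and derives
#' the nuclear-p65 fraction from it instantaneously. Three processes drive
#' the feedback loop: a stimulus accelerates IkBa degradation; IkBa
#' competitively inhibits p65-DNA binding, so the nuclear-p65 fraction is
#' \eqn{n(x) = 1 / (1 + (x/K_i)^h)}; and NF-kB-driven IkBa resynthesis acts
#' after a fixed transcription/translation delay \eqn{\tau}:
#' \deqn{dx/dt = -k_{deg} S(t) x - k_{turn} x + k_{basal}
#'   + k_{syn} n(x(t-\tau)).}
#'
#' Default values are calibrated (not measured): with a sustained stimulus
#' they produce damped oscillations of nuclear p65 with a dominant period
#' near 87 min, inside the 80-100 min band where observed single-cell
#' peak-to-peak intervals concentrate.
#'
#' @param k_deg stimulus-driven IkBa degradation rate (1/min).
#' @param k_syn maximal delayed, NF-kB-driven IkBa synthesis rate
#'   (conc/min).
#' @param k_basal_syn basal IkBa synthesis (conc/min).
#' @param k_turn basal IkBa turnover (1/min); gives the resting state a
#'   finite IkBa level.
#' @param tau transcription + translation delay (min).
#' @param K_i competitive-inhibition constant (conc units); IkBa level at
#'   which half of p65 is nuclear.
#' @param h Hill coefficient (>= 1) of the inhibition.
#' @param theta_nuc threshold on the nuclear-p65 fraction used for binary
#'   "nuclear" calls, expressed as a fraction of the dynamic range above the
#'   resting level.
#' @return object of class `oscillator_params`.
#' @export
oscillator_params <- function(k_deg = 0.2, k_syn = 0.6, k_basal_syn = 0.03,
                              k_turn = 0.01, tau = 40, K_i = 1, h = 2,
                              theta_nuc = 0.5) {
  for (nm in c("k_deg", "k_syn", "k_basal_syn", "k_turn", "tau", "K_i"))
    check_number(get(nm), nm, lower = 0, strict_lower = TRUE)
  check_number(h, "h", lower = 1)
  check_number(theta_nuc, "theta_nuc", lower = 0, upper = 1,
               strict_lower = TRUE)
  if (theta_nuc >= 1) stop("'theta_nuc' must be in (0, 1)")
  structure(list(k_deg = k_deg, k_syn = k_syn, k_basal_syn = k_basal_syn,
                 k_turn = k_turn, tau = tau, K_i = K_i, h = h,
                 theta_nuc = theta_nuc),
            class = "oscillator_params")
}

#' Stimulus time course
#'
#' @param kind `"sustained"` (stimulus stays on after onset, e.g. bacteria
#'   remaining attached), `"pulse"` (on for `duration_min`), or `"none"`.
#' @param onset_min time at which the stimulus switches on.
#' @param duration_min pulse length in minutes (pulse only).
#' @param amplitude relative stimulus strength in `[0, 1]`, scaling the
#'   induced degradation rate.
#' @return object of class `stimulus_profile`.
#' @export
stimulus_profile <- function(kind = c("sustained", "pulse", "none"),
                             onset_min = 0, duration_min = NULL,
                             amplitude = 1) {
  kind <- match.arg(kind)
  check_number(onset_min, "onset_min")
  check_number(amplitude, "amplitude", lower = 0, upper = 1)
  if (kind == "pulse") {
    if (is.null(duration_min))
      stop("'duration_min' is required for a pulse stimulus")
    check_number(duration_min, "duration_min", lower = 0,
                 strict_lower = TRUE)
  } else duration_min <- NA_real_
  structure(list(kind = kind, onset_min = onset_min,
                 duration_min = duration_min, amplitude = amplitude),
            class = "stimulus_profile")
}

#' Nuclear-p65 fraction as a function of IkBa
#'
#' Competitive inhibition of p65-DNA binding by IkBa:
#' `n(x) = 1 / (1 + (x / K_i)^h)`. Strictly decreasing, `n(0) = 1`,
#' `n(K_i) = 0.5` for any Hill coefficient.
#'
#' @param x_ikba IkBa level(s), >= 0.
#' @param params an [oscillator_params()].
#' @return nuclear fraction(s) in `[0, 1]`.
#' @export
nuclear_fraction <- function(x_ikba, params) {
  stopifnot(inherits(params, "oscillator_params"))
  if (any(!is.finite(x_ikba)) || any(x_ikba < 0))
    stop("'x_ikba' must be finite and non-negative")
  1 / (1 + (x_ikba / params$K_i)^params$h)
}

#' Pre-stimulus steady state
#'
#' Solves the resting balance
#' `k_basal_syn + k_syn * n(x) = k_turn * x` by bracketed root finding. The
#' left side is strictly decreasing in `x` and the right side strictly
#' increasing, so the root is unique; the bracket is widened automatically.
#'
#' @param params an [oscillator_params()].
#' @return list with elements `x` (IkBa level) and `n` (nuclear fraction).
#' @export
steady_state <- function(params) {
  stopifnot(inherits(params, "oscillator_params"))
  f <- function(x) params$k_basal_syn +
    params$k_syn * nuclear_fraction(x, params) - params$k_turn * x
  upper <- max(1, params$K_i)
  while (f(upper) > 0) {
    upper <- upper * 2
    if (upper > 1e6) stop("no steady state found below 1e6 conc units")
  }
  x <- uniroot(f, c(0, upper), tol = 1e-12)$root
  list(x = x, n = nuclear_fraction(x, params))
}

# Stimulus value S(t) for vectors of onsets; kind/duration/amplitude shared.
stimulus_value <- function(t, stim, onsets) {
  on <- switch(stim$kind,
    none = rep(FALSE, length(onsets)),
    sustained = t >= onsets,
    pulse = t >= onsets & t < onsets + stim$duration_min)
  stim$amplitude * as.numeric(on)
}

# Vectorised method-of-steps integrator: n_cells cells share the time grid
# but may have individual tau, k_deg and stimulus onset. Classical
# fixed-step 4th-order stepping; the delayed state is read from the stored
# solution with cubic Hermite interpolation (state + stored derivative at
# the bracketing grid points), which preserves 4th-order convergence.
# History is the resting steady state for t <= 0. Returns the IkBa matrix
# (cells x timepoints).
dde_integrate <- function(params, stim, onsets, t_end_min, dt_min,
                          tau = NULL, k_deg = NULL) {
  n_cells <- length(onsets)
  if (is.null(tau)) tau <- rep(params$tau, n_cells)
  if (is.null(k_deg)) k_deg <- rep(params$k_deg, n_cells)
  if (any(dt_min > tau / 20))
    stop("dt_min must not exceed tau/20 (delay must be resolved)")
  ss <- steady_state(params)
  nt <- floor(t_end_min / dt_min + 1e-9)
  tgrid <- seq(0, by = dt_min, length.out = nt + 1L)
  X <- matrix(ss$x, n_cells, nt + 1L)
  FD <- matrix(0, n_cells, nt + 1L) # stored derivatives for interpolation
  clipped <- 0L
  idx <- seq_len(n_cells)
  nfun <- function(x) 1 / (1 + (x / params$K_i)^params$h)
  delayed <- function(td) {
    # cubic Hermite interpolation of the stored solution; history is x*
    td <- pmax(td, 0)
    pos <- td / dt_min
    i0 <- pmin(floor(pos), nt - 1)
    th <- pos - i0
    x0 <- X[cbind(idx, i0 + 1L)]
    x1 <- X[cbind(idx, i0 + 2L)]
    f0 <- FD[cbind(idx, i0 + 1L)]
    f1 <- FD[cbind(idx, i0 + 2L)]
    h00 <- (1 + 2 * th) * (1 - th)^2
    h10 <- th * (1 - th)^2
    h01 <- th^2 * (3 - 2 * th)
    h11 <- th^2 * (th - 1)
    val <- h00 * x0 + h10 * dt_min * f0 + h01 * x1 + h11 * dt_min * f1
    # before each cell's stimulus onset the solution is exactly x*; this
    # also sidesteps the derivative corner at the onset
    if (stim$kind != "none") val[td <= onsets] <- ss$x
    val
  }
  rhs <- function(t, x) {
    s <- stimulus_value(t, stim, onsets)
    xd <- delayed(t - tau)
    -(k_deg * s + params$k_turn) * x + params$k_basal_syn +
      params$k_syn * nfun(xd)
  }
  FD[, 1L] <- rhs(0, X[, 1L])
  for (k in seq_len(nt)) {
    tk <- tgrid[k]
    xk <- X[, k]
    k1 <- FD[, k]
    k2 <- rhs(tk + dt_min / 2, xk + dt_min / 2 * k1)
    k3 <- rhs(tk + dt_min / 2, xk + dt_min / 2 * k2)
    k4 <- rhs(tk + dt_min, xk + dt_min * k3)
    xn <- xk + dt_min / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    neg <- xn < 0
    if (any(neg)) {
      clipped <- clipped + sum(neg)
      xn[neg] <- 0
    }
    X[, k + 1L] <- xn
    FD[, k + 1L] <- rhs(tgrid[k + 1L], xn)
  }
  if (clipped > 0L)
    warning(clipped, " negative IkBa step value(s) clipped to 0")
  structure(X, t_min = tgrid, steady = ss)
}

#' Simulate one cell of the delay oscillator
#'
#' Integrates the delay equation by the method of steps with fixed-step
#' classical 4th-order stepping and linear interpolation of the delayed
#' state; the pre-stimulus history is the resting steady state. `dt_min`
#' must resolve the delay (`dt_min <= tau / 20`).
#'
#' @param params an [oscillator_params()].
#' @param stimulus a [stimulus_profile()].
#' @param t_end_min simulated time span (min).
#' @param dt_min integration and output step (min).
#' @return data frame of class `nfkb_trace` with columns `t_min`, `x_ikba`,
#'   `n_p65`.
#' @export
simulate_cell <- function(params, stimulus = stimulus_profile("sustained"),
                          t_end_min = 400, dt_min = 0.5) {
  stopifnot(inherits(params, "oscillator_params"),
            inherits(stimulus, "stimulus_profile"))
  check_number(t_end_min, "t_end_min", lower = 0, strict_lower = TRUE)
  check_number(dt_min, "dt_min", lower = 0, strict_lower = TRUE)
  X <- dde_integrate(params, stimulus, onsets = stimulus$onset_min,
                     t_end_min = t_end_min, dt_min = dt_min)
  out <- data.frame(t_min = attr(X, "t_min"), x_ikba = X[1L, ],
                    n_p65 = nuclear_fraction(pmax(X[1L, ], 0), params))
  class(out) <- c("nfkb_trace", "data.frame")
  attr(out, "steady") <- attr(X, "steady")
  out
}

#' Dominant oscillation period of a trace
#'
#' Mean peak-to-peak interval of the nuclear-p65 signal, using the default
#' peak detection of [detect_peaks()].
#'
#' @param trace an `nfkb_trace` (or data frame with `t_min` and `n_p65`).
#' @param ... passed to [detect_peaks()].
#' @return period in minutes, or `NA_real_` when fewer than two peaks are
#'   detected.
#' @export
dominant_period <- function(trace, ...) {
  stopifnot(all(c("t_min", "n_p65") %in% names(trace)))
  rng <- range(trace$n_p65)
  if (diff(rng) == 0) return(NA_real_)
  norm <- (trace$n_p65 - rng[1]) / diff(rng)
  pk <- detect_peaks(norm, t_min = trace$t_min, ...)
  if (length(pk$peak_times_min) < 2L) return(NA_real_)
  mean(pk$intervals_min)
}
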