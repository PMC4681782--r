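#' Threshold power-law gain specification
#'
#' The neuronal transfer function is `g(x) = (x + theta)^gamma` for
#' `x + theta > 0` and 0 otherwise: a sublinear (gamma < 1) threshold
#' power law, continuous at the threshold.
#'
#' @param gamma Exponent in (0, 1].
#' @param theta Activation threshold, >= 0. `theta = 0` is allowed (the
#'   reference simulations use it), in which case `g(x) = x^gamma` for x > 0.
#' @return A list of class `gain_spec`.
#' @export
gain_spec <- function(gamma = 2 / 5, theta = 0) {
  if (gamma <= 0 || gamma > 1) {
    abort("`gamma` must be in (0, 1].", class = "recallnet_parameter_error")
  }
  if (theta < 0) {
    abort("`theta` must be >= 0.", class = "recallnet_parameter_error")
  }
  structure(list(gamma = gamma, theta = theta), class = "gain_spec")
}

#' Evaluate the gain function
#'
#' @param x Synaptic current (vectorised).
#' @param spec A `gain_spec`.
#' @return Firing rate(s), nonnegative.
#' @examples
#' gain(4, gain_spec(gamma = 1 / 2, theta = 0)) # 2
#' @export
gain <- function(x, spec = gain_spec()) {
  y <- x + spec$theta
  out <- numeric(length(y))
  pos <- is.finite(y) & y > 0
  out[pos] <- y[pos]^spec$gamma
  out[!is.finite(y)] <- NA_real_
  out
}

#' Inverse gain
#'
#' Current producing a given positive rate: `r^(1/gamma) - theta`.
#'
#' @param r Firing rate(s), >= 0.
#' @param spec A `gain_spec`.
#' @return Synaptic current(s).
#' @export
gain_inverse <- function(r, spec = gain_spec()) {
  ifelse(r > 0, r^(1 / spec$gamma) - spec$theta, -spec$theta)
}

#' Sinusoidal inhibition-oscillation schedule
#'
#' The relative inhibition strength phi is modulated as
#' `phi(t) = mean - amplitude * cos(2 pi (t/period) + phase0)` with
#' `mean = (phi_max + phi_min)/2` and `amplitude = (phi_max - phi_min)/2`.
#' With the default phase the oscillation starts at its trough
#' (`phi(0) = phi_min`), so an initialised memory sits inside the
#' single-attractor regime at t = 0. Setting `phi_min == phi_max` gives a
#' constant schedule.
#'
#' @param phi_min,phi_max Trough and peak inhibition values.
#' @param period Oscillation period tau_o (same time units as tau).
#' @param phase0 Initial phase offset in radians (0 = trough at t = 0).
#' @return A list of class `oscillation_schedule`.
#' @export
oscillation_schedule <- function(phi_min = 0.7, phi_max = 1.06,
                                 period = 1, phase0 = 0) {
  if (phi_min > phi_max) {
    abort("`phi_min` must be <= `phi_max`.",
          class = "recallnet_parameter_error")
  }
  if (period <= 0) {
    abort("`period` must be > 0.", class = "recallnet_parameter_error")
  }
  structure(list(phi_min = phi_min, phi_max = phi_max, period = period,
                 phase0 = phase0),
            class = "oscillation_schedule")
}

#' Instantaneous inhibition value
#'
#' @param t Time(s), >= 0.
#' @param schedule An `oscillation_schedule`.
#' @return phi(t), within `[phi_min, phi_max]`.
#' @examples
#' phi_schedule(0, oscillation_schedule())   # 0.7
#' phi_schedule(0.5, oscillation_schedule()) # 1.06
#' @export
phi_schedule <- function(t, schedule = oscillation_schedule()) {
  mid <- (schedule$phi_max + schedule$phi_min) / 2
  amp <- (schedule$phi_max - schedule$phi_min) / 2
  mid - amp * cos(2 * pi * t / schedule$period + schedule$phase0)
}

#' Neuronal noise specification
#'
#' Gaussian white noise driving the stochastic state transitions. In the
#' population-reduced dynamics every population unit receives independent
#' noise of amplitude (SD scale) `xi0` by default: the noise term of the
#' reduced equation keeps the single-unit amplitude rather than averaging
#' it away, which is what lets noise compete with the finite-size
#' heterogeneity of intersection sizes and randomise the selection of the
#' next recalled item. The mapping from a population's size to its noise SD
#' is exposed as a hook; [clt_noise_scaling()] provides the central-limit
#' alternative `xi0 / sqrt(S_v N)` (the average of `S_v N` independent
#' single-neuron noises), under which transitions become nearly
#' deterministic.
#'
#' @param xi0 Noise amplitude (SD scale), >= 0.
#' @param population_scaling Function `(xi0, fraction, n_neurons) -> SD`
#'   mapping population fractions to per-population noise SDs.
#' @return A list of class `noise_spec`.
#' @export
noise_spec <- function(xi0 = 65,
                       population_scaling = uniform_noise_scaling) {
  if (xi0 < 0) abort("`xi0` must be >= 0.",
                     class = "recallnet_parameter_error")
  structure(list(xi0 = xi0, population_scaling = population_scaling),
            class = "noise_spec")
}

#' Population noise-scaling rules
#'
#' `uniform_noise_scaling` (the default) gives every population unit the
#' full amplitude `xi0`. `clt_noise_scaling` treats the population noise as
#' the average of the `S_v N` members' independent noises,
#' `xi0 / sqrt(S_v N)`; it is provided for comparison — under it the
#' noise-driven transition mechanism largely degenerates to deterministic
#' largest-intersection selection.
#'
#' @param xi0 Noise amplitude.
#' @param fraction Population fractions S_v.
#' @param n_neurons Network size N.
#' @return Vector of per-population noise SDs.
#' @export
uniform_noise_scaling <- function(xi0, fraction, n_neurons) {
  rep(xi0, length(fraction))
}

#' @rdname uniform_noise_scaling
#' @export
clt_noise_scaling <- function(xi0, fraction, n_neurons) {
  if (xi0 == 0) {
    rep(0, length(fraction))
  } else {
    xi0 / sqrt(pmax(fraction * n_neurons, 1))
  }
}

#' Simulation configuration
#'
#' Euler--Maruyama integration settings for the rate dynamics
#' `tau dc/dt = -c + (recurrent drive) + noise`.
#'
#' @param tau Membrane/current decay time constant.
#' @param dt Integration step; must satisfy `dt <= tau / 5`.
#' @param t_total Simulated interval length T.
#' @param r_ini Initial firing rate of the populations of the cued memory.
#' @param r_thresh Recall threshold on a memory's mean firing rate.
#' @param seed Optional RNG seed applied just before integration.
#' @param record_dt Sampling interval for stored trajectory samples
#'   (rounded to a whole number of steps).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(tau = 0.01, dt = 0.001, t_total = 450,
                       r_ini = 1, r_thresh = 15, seed = NULL,
                       record_dt = 0.01) {
  if (dt <= 0 || dt > tau / 5) {
    abort("`dt` must be positive and <= tau/5 for a stable integration.",
          class = "recallnet_stability_error")
  }
  if (t_total <= 0) abort("`t_total` must be > 0.",
                          class = "recallnet_parameter_error")
  if (r_thresh <= 0) abort("`r_thresh` must be > 0.",
                           class = "recallnet_parameter_error")
  structure(list(tau = tau, dt = dt, t_total = t_total, r_ini = r_ini,
                 r_thresh = r_thresh, seed = seed, record_dt = record_dt),
            class = "sim_config")
}
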