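record_step_indices <- function(n_steps, dt, record_dt) {
  every <- max(1L, as.integer(round(record_dt / dt)))
  steps <- seq.int(0L, n_steps, by = every)
  if (steps[length(steps)] != n_steps) steps <- c(steps, n_steps)
  as.integer(steps)
}

new_trajectory <- function(core_out, n_memories, schedule, config,
                           initial_memory, kind) {
  structure(
    list(times = core_out$times, phi = core_out$phi, m0 = core_out$m0,
         memory_rates = core_out$memory_rates,
         overlaps = core_out$overlaps,
         pop_currents = core_out$pop_currents,
         currents = core_out$currents,
         final_currents = core_out$final_currents,
         n_memories = n_memories, schedule = schedule, config = config,
         initial_memory = initial_memory, kind = kind),
    class = "recall_trajectory"
  )
}

#' Simulate the population-reduced network dynamics
#'
#' Integrates the reduced stochastic rate dynamics over identical-code
#' populations,
#' `tau dc_v/dt = -c_v + sum_w Jt_vw S_w g(c_w) + noise_v`,
#' under the sinusoidal inhibition schedule. This is the workhorse used for
#' all recall experiments: it is an exact rewriting of the N-neuron system in
#' which only single-neuron (as opposed to population-mean) rates are lost.
#' The drive is evaluated through the low-rank overlap decomposition of the
#' coupling, so cost per step is O(V P) for V populations.
#'
#' Populations belonging to `initial_memory` start at rate `r_ini` (current
#' `gain_inverse(r_ini)`), all others at rate zero.
#'
#' @param partition A `population_partition`.
#' @param coupling A `coupling_params` (its `phi` is ignored in favour of the
#'   schedule).
#' @param gain A `gain_spec`.
#' @param schedule An `oscillation_schedule`; use `phi_min == phi_max` for
#'   constant inhibition.
#' @param noise A `noise_spec`.
#' @param config A `sim_config`.
#' @param initial_memory Index in 1..P of the cued memory.
#' @param record_pops Also store population currents at sample times
#'   (memory-hungry; for validation).
#' @return A `recall_trajectory`: sampled times, phi(t), per-memory mean
#'   rates (samples x P), overlaps m^mu, network activity m^0, and final
#'   currents.
#' @export
simulate_reduced <- function(partition, coupling, gain = gain_spec(),
                             schedule = oscillation_schedule(),
                             noise = noise_spec(), config = sim_config(),
                             initial_memory = 1L, record_pops = FALSE) {
  stopifnot(inherits(partition, "population_partition"),
            inherits(coupling, "coupling_params"))
  p <- partition$n_memories
  if (initial_memory < 1L || initial_memory > p) {
    abort("`initial_memory` must be in 1..P.",
          class = "recallnet_parameter_error")
  }
  n_steps <- as.integer(round(config$t_total / config$dt))
  rec <- record_step_indices(n_steps, config$dt, config$record_dt)
  sd_v <- noise$population_scaling(noise$xi0, partition$fractions,
                                   partition$n_neurons)
  c0 <- ifelse(partition$vectors[, initial_memory] > 0,
               gain_inverse(config$r_ini, gain), -gain$theta)
  if (!is.null(config$seed)) set.seed(config$seed)
  out <- reduced_core(
    partition$vectors, partition$fractions,
    partition$sparsity, coupling$kappa, coupling$j_plus, coupling$j_minus,
    (schedule$phi_max + schedule$phi_min) / 2,
    (schedule$phi_max - schedule$phi_min) / 2,
    schedule$period, schedule$phase0,
    gain$gamma, gain$theta,
    config$tau, config$dt, n_steps,
    as.numeric(sd_v), as.numeric(c0), rec, record_pops
  )
  new_trajectory(out, p, schedule, config, initial_memory, "reduced")
}

#' Simulate the full N-neuron network dynamics
#'
#' Integrates the single-neuron stochastic rate equations with the dense
#' connectivity matrix. Intended for validation at small N (guarded at
#' N <= 2000): the population-reduced simulator is the production path.
#' The contiguity terms use the `"per_neuron"` normalisation so that the
#' full system is the exact N-fold expansion of the reduced one.
#'
#' @inheritParams simulate_reduced
#' @param patterns A `pattern_set` with `n_neurons <= 2000`.
#' @param record_neurons Also store per-neuron currents at sample times.
#' @return A `recall_trajectory` (per-memory mean rates, overlaps, m^0).
#' @export
simulate_full <- function(patterns, coupling, gain = gain_spec(),
                          schedule = oscillation_schedule(),
                          noise = noise_spec(), config = sim_config(),
                          initial_memory = 1L, record_neurons = FALSE) {
  stopifnot(inherits(patterns, "pattern_set"))
  if (patterns$n_neurons > 2000L) {
    abort("full simulation is guarded at N <= 2000; use simulate_reduced().",
          class = "recallnet_size_error")
  }
  p <- patterns$n_memories
  if (initial_memory < 1L || initial_memory > p) {
    abort("`initial_memory` must be in 1..P.",
          class = "recallnet_parameter_error")
  }
  coupling0 <- coupling
  coupling0$phi <- 0
  j0 <- full_connectivity(patterns, coupling0, max_n = 2000L,
                          contiguity_norm = "per_neuron")
  n_steps <- as.integer(round(config$t_total / config$dt))
  rec <- record_step_indices(n_steps, config$dt, config$record_dt)
  c0 <- ifelse(patterns$eta[, initial_memory] > 0,
               gain_inverse(config$r_ini, gain), -gain$theta)
  if (!is.null(config$seed)) set.seed(config$seed)
  out <- full_core(
    t(j0), patterns$eta,
    patterns$sparsity, coupling$kappa,
    (schedule$phi_max + schedule$phi_min) / 2,
    (schedule$phi_max - schedule$phi_min) / 2,
    schedule$period, schedule$phase0,
    gain$gamma, gain$theta,
    config$tau, config$dt, n_steps,
    noise$xi0, as.numeric(c0), rec, record_neurons
  )
  new_trajectory(out, p, schedule, config, initial_memory, "full")
}

#' @export
print.recall_trajectory <- function(x, ...) {
  cat("<recall_trajectory> (", x$kind, ") ", length(x$times),
      " samples over t = [0, ", max(x$times), "], P = ", x$n_memories,
      "\n", sep = "")
  invisible(x)
}

#' Tidy a trajectory into one row per (time, memory)
#'
#' @param x A `recall_trajectory`.
#' @param ... Unused.
#' @return A tibble with columns `time`, `phi`, `memory`, `rate`, `overlap`,
#'   `m0`.
#' @method tidy recall_trajectory
#' @export
tidy.recall_trajectory <- function(x, ...) {
  p <- x$n_memories
  tibble(
    time = rep(x$times, times = p),
    phi = rep(x$phi, times = p),
    memory = rep(seq_len(p), each = length(x$times)),
    rate = as.vector(x$memory_rates),
    overlap = as.vector(x$overlaps),
    m0 = rep(x$m0, times = p)
  )
}

#' Per-memory mean firing rates of a trajectory
#'
#' Recomputes, for each memory mu, the mean firing rate of the neurons with
#' `eta_i^mu = 1` at every sample: the fraction-weighted mean of population
#' rates over populations belonging to mu, normalised by the total fraction
#' of mu-neurons. When the trajectory stores population (or neuron) currents
#' the rates are recomputed from them; otherwise the rates recorded during
#' integration are returned.
#'
#' @param trajectory A `recall_trajectory`.
#' @param partition The `population_partition` the trajectory was run with
#'   (required to recompute from stored population currents).
#' @param spec The `gain_spec` used in the simulation.
#' @return A numeric matrix, samples x P.
#' @export
memory_mean_rates <- function(trajectory, partition = NULL,
                              spec = gain_spec()) {
  stopifnot(inherits(trajectory, "recall_trajectory"))
  if (!is.null(trajectory$pop_currents) && !is.null(partition)) {
    v <- partition$vectors
    if (any(colSums(v * partition$fractions) == 0)) {
      abort("a memory has an empty representation in this partition.",
            class = "recallnet_degeneracy_error")
    }
    s <- partition$fractions
    rates <- gain(as.vector(trajectory$pop_currents), spec)
    dim(rates) <- dim(trajectory$pop_currents) # V x T
    num <- t(v * s) %*% rates                  # P x T
    den <- colSums(v * s)
    t(num / den)
  } else {
    trajectory$memory_rates
  }
}
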