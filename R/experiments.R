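#' Experiment configuration with reference defaults
#'
#' All network and dynamics parameters by name. The defaults are the
#' reference parameter set of the model: N = 1e5 neurons, P = 16 items,
#' f = 0.1, tau = 0.01, kappa = 13000, phi oscillating in [0.7, 1.06] with
#' period 1, gain exponent 2/5 with threshold 0, total time 450, dt = 0.001,
#' contiguity J+ = 1500 / J- = 400, noise scale 65, recall threshold 15,
#' 10000 trials, initial rate 1.
#'
#' @param n_neurons,n_memories,sparsity Pattern-code parameters N, P, f.
#' @param tau,dt,t_total,r_ini,r_thresh Integration / recall settings.
#' @param kappa,phi_max,phi_min Coupling and inhibition-oscillation range.
#' @param gamma,theta Gain function.
#' @param tau_osc Oscillation period.
#' @param j_plus,j_minus Contiguity couplings.
#' @param xi0 Noise scale.
#' @param n_trials Number of simulated networks.
#' @param record_dt Trajectory sampling interval.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(n_neurons = 1e5, n_memories = 16L,
                              sparsity = 0.1, tau = 0.01, kappa = 13000,
                              phi_max = 1.06, phi_min = 0.7, gamma = 2 / 5,
                              theta = 0, tau_osc = 1, t_total = 450,
                              dt = 0.001, j_plus = 1500, j_minus = 400,
                              xi0 = 65, r_thresh = 15, n_trials = 10000L,
                              r_ini = 1, record_dt = 0.01) {
  structure(
    list(n_neurons = n_neurons, n_memories = as.integer(n_memories),
         sparsity = sparsity, tau = tau, kappa = kappa, phi_max = phi_max,
         phi_min = phi_min, gamma = gamma, theta = theta,
         tau_osc = tau_osc, t_total = t_total, dt = dt, j_plus = j_plus,
         j_minus = j_minus, xi0 = xi0, r_thresh = r_thresh,
         n_trials = as.integer(n_trials), r_ini = r_ini,
         record_dt = record_dt),
    class = "experiment_config"
  )
}

#' Desk-scale experiment profile
#'
#' The reduced-cost profile used for the packaged experiments and tests:
#' N = 2e4 neurons, 50 trials, T = 100 oscillation cycles, dt = 2e-3.
#' Intensive statistics (transition-rank distribution, recall probability
#' versus size percentile) are stable under this down-scaling within
#' Monte-Carlo error.
#'
#' @param ... Overrides passed to [experiment_config()].
#' @return An `experiment_config`.
#' @export
scaled_config <- function(...) {
  defaults <- list(n_neurons = 2e4, n_trials = 50L, t_total = 100,
                   dt = 2e-3)
  overrides <- list(...)
  do.call(experiment_config, utils::modifyList(defaults, overrides))
}

config_pieces <- function(config, xi0 = config$xi0,
                          phi_min = config$phi_min,
                          phi_max = config$phi_max) {
  list(
    coupling = coupling_params(kappa = config$kappa, phi = phi_min,
                               j_plus = config$j_plus,
                               j_minus = config$j_minus),
    gain = gain_spec(gamma = config$gamma, theta = config$theta),
    schedule = oscillation_schedule(phi_min = phi_min, phi_max = phi_max,
                                    period = config$tau_osc),
    noise = noise_spec(xi0 = xi0),
    sim = sim_config(tau = config$tau, dt = config$dt,
                     t_total = config$t_total, r_ini = config$r_ini,
                     r_thresh = config$r_thresh,
                     record_dt = config$record_dt)
  )
}

trial_seeds <- function(master_seed, n) {
  set.seed(master_seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Run a multi-trial recall ensemble
#'
#' Each trial draws a fresh pattern set (a new random word list), runs the
#' population-reduced simulator under oscillating inhibition, and extracts
#' the recall log. Per-trial seeds are derived deterministically from
#' `master_seed`.
#'
#' @param config An `experiment_config`.
#' @param master_seed Integer master seed.
#' @param init Initial-memory assignment: `"stratified"` cycles through
#'   random permutations of 1..P (marginally uniform, balanced across the
#'   ensemble), `"uniform"` draws each start independently.
#' @param n_trials Override of `config$n_trials`.
#' @return A list of class `recall_ensemble`: `logs` (tibble with `trial`
#'   column), `sizes` (tibble trial/item/size), `similarity` (list of P x P
#'   intersection matrices), `init_items`, `n_recalled` (distinct items per
#'   trial), `seeds`, `config`.
#' @export
run_trials <- function(config = scaled_config(), master_seed = 1L,
                       init = c("stratified", "uniform"),
                       n_trials = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  init <- match.arg(init)
  n_trials <- if (is.null(n_trials)) config$n_trials else as.integer(n_trials)
  p <- config$n_memories
  seeds <- trial_seeds(master_seed, n_trials + 1L)
  set.seed(seeds[n_trials + 1L])
  init_items <- if (init == "stratified") {
    as.vector(replicate(ceiling(n_trials / p), sample.int(p)))[
      seq_len(n_trials)]
  } else {
    sample.int(p, n_trials, replace = TRUE)
  }
  pieces <- config_pieces(config)
  logs <- vector("list", n_trials)
  sims <- vector("list", n_trials)
  sizes <- matrix(NA_integer_, n_trials, p)
  n_recalled <- integer(n_trials)
  for (tr in seq_len(n_trials)) {
    set.seed(seeds[tr])
    ps <- generate_patterns(config$n_neurons, p, config$sparsity)
    part <- partition_populations(ps)
    traj <- simulate_reduced(part, pieces$coupling, pieces$gain,
                             pieces$schedule, pieces$noise, pieces$sim,
                             initial_memory = init_items[tr])
    log <- detect_recalls(traj)
    log$trial <- tr
    logs[[tr]] <- log
    sims[[tr]] <- intersection_matrix(ps)
    sizes[tr, ] <- ps$sizes
    n_recalled[tr] <- sum(log$first_time)
  }
  structure(
    list(logs = dplyr::bind_rows(logs), sizes = sizes_to_tibble(sizes),
         similarity = sims, init_items = init_items,
         n_recalled = n_recalled, seeds = seeds[seq_len(n_trials)],
         config = config),
    class = "recall_ensemble"
  )
}

#' @export
print.recall_ensemble <- function(x, ...) {
  cat("<recall_ensemble>", length(x$n_recalled), "trials, mean",
      round(mean(x$n_recalled), 2), "distinct items recalled\n")
  invisible(x)
}

#' Recall performance as a function of a model parameter
#'
#' Sweeps either the forward-contiguity coupling `j_plus` (with `j_minus`
#' held at its reference value) or the noise scale `xi0`, running an
#' independent ensemble per value and reporting the mean number of distinct
#' items retrieved within the simulation window.
#'
#' @param parameter `"j_plus"` or `"xi0"`.
#' @param values Numeric vector of parameter values (nonempty).
#' @param config Base `experiment_config`.
#' @param n_trials Trials per value.
#' @param master_seed Integer; per-value ensembles get derived seeds.
#' @return A tibble of class `performance_sweep` with `parameter`, `value`,
#'   `mean_recalled`, `se`, `n_trials`.
#' @export
performance_sweep <- function(parameter = c("j_plus", "xi0"), values,
                              config = scaled_config(), n_trials = 20L,
                              master_seed = 1L) {
  parameter <- match.arg(parameter)
  if (length(values) == 0L) {
    abort("`values` must be nonempty.", class = "recallnet_parameter_error")
  }
  sweep_seeds <- trial_seeds(master_seed, length(values))
  rows <- purrr::map2_dfr(values, sweep_seeds, function(val, sd_i) {
    cfg <- config
    cfg[[parameter]] <- val
    ens <- tryCatch(
      run_trials(cfg, master_seed = sd_i, n_trials = n_trials),
      error = function(e) {
        abort(paste0("simulation failed at ", parameter, " = ", val, ": ",
                     conditionMessage(e)),
              class = "recallnet_sweep_error")
      }
    )
    tibble(parameter = parameter, value = val,
           mean_recalled = mean(ens$n_recalled),
           se = sd(ens$n_recalled) / sqrt(length(ens$n_recalled)),
           n_trials = length(ens$n_recalled))
  })
  class(rows) <- c("performance_sweep", class(rows))
  rows
}

#' Compare full and reduced simulators on one instance
#'
#' Runs the N-neuron and the population-reduced simulators on the same
#' pattern realisation without noise and reports the sup-norm deviation of
#' the population-mean currents over the whole trajectory. The reduction is
#' an exact rewriting of the dynamics, so the deviation is at numerical
#' round-off for any step size.
#'
#' @param n_neurons Network size (<= 500).
#' @param config An `experiment_config` (xi0 must be 0).
#' @param n_memories Optional override of `config$n_memories` (small P keeps
#'   the dense run cheap).
#' @param master_seed Seed for the pattern draw.
#' @param tolerance Pass threshold on the sup-norm deviation.
#' @return A list with `max_deviation`, `pass`, `tolerance`, `n_populations`.
#' @export
validate_reduction <- function(n_neurons = 200L, config = scaled_config(),
                               n_memories = 4L, master_seed = 1L,
                               tolerance = 1e-6) {
  if (n_neurons > 500L) {
    abort("`n_neurons` must be <= 500 for the validation run.",
          class = "recallnet_size_error")
  }
  if (config$xi0 != 0) {
    abort(paste("validate_reduction requires xi0 = 0: stochastic paths are",
                "not comparable pathwise; compare moments instead."),
          class = "recallnet_parameter_error")
  }
  cfg <- config
  cfg$n_neurons <- n_neurons
  cfg$n_memories <- as.integer(n_memories)
  pieces <- config_pieces(cfg)
  pieces$noise <- noise_spec(0)
  set.seed(master_seed)
  ps <- generate_patterns(n_neurons, cfg$n_memories, cfg$sparsity)
  part <- partition_populations(ps)
  full <- simulate_full(ps, pieces$coupling, pieces$gain, pieces$schedule,
                        pieces$noise, pieces$sim, initial_memory = 1L,
                        record_neurons = TRUE)
  red <- simulate_reduced(part, pieces$coupling, pieces$gain,
                          pieces$schedule, pieces$noise, pieces$sim,
                          initial_memory = 1L, record_pops = TRUE)
  # population means of the full currents, per sample
  pop_mean_full <- apply(full$currents, 2L, function(cc) {
    tapply(cc, part$population_index, mean)
  })
  ord <- sort(unique(part$population_index))
  dev <- max(abs(pop_mean_full[as.character(ord), , drop = FALSE] -
                   red$pop_currents))
  list(max_deviation = dev, pass = dev <= tolerance,
       tolerance = tolerance, n_populations = nrow(part$vectors))
}
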