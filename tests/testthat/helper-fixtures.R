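# shared small fixtures; everything is generated in code at test time

small_instance <- function(n = 200L, p = 4L, f = 0.1, seed = 42L) {
  ps <- generate_patterns(n, p, f, seed = seed)
  list(patterns = ps, partition = partition_populations(ps))
}

quick_sim <- function(t_total = 2, dt = 1e-3, r_thresh = 15,
                      record_dt = 0.01) {
  sim_config(tau = 0.01, dt = dt, t_total = t_total, r_ini = 1,
             r_thresh = r_thresh, record_dt = record_dt)
}

constant_phi <- function(phi) {
  oscillation_schedule(phi_min = phi, phi_max = phi, period = 1)
}

# build a hand-made trajectory carrying given memory-rate traces
fake_trajectory <- function(times, rates, period = 1, r_thresh = 15) {
  structure(
    list(times = times, phi = rep(0.7, length(times)),
         m0 = rowMeans(rates), memory_rates = rates,
         overlaps = rates - rowMeans(rates),
         n_memories = ncol(rates),
         schedule = oscillation_schedule(period = period),
         config = quick_sim(t_total = max(times), r_thresh = r_thresh),
         initial_memory = 1L, kind = "reduced"),
    class = "recall_trajectory"
  )
}
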