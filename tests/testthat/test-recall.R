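test_that("threshold crossings are detected with interpolated times", {
  times <- seq(0, 4, by = 0.1)
  rates <- matrix(0, length(times), 4)
  # memory 3 ramps through the threshold between t = 2.2 and 2.4,
  # crossing 15 exactly at t = 2.30
  ramp <- 15 + (times - 2.3) * 50
  rates[, 3] <- pmax(0, pmin(ramp, 40))
  traj <- fake_trajectory(times, rates)
  log <- detect_recalls(traj)
  expect_equal(nrow(log), 1L)
  expect_equal(log$item, 3L)
  expect_equal(log$time, 2.30, tolerance = 1e-9)
  expect_equal(log$cycle, 2L)
  expect_true(log$first_time)
  # a trace that never crosses gives an empty log
  empty <- detect_recalls(fake_trajectory(times, rates * 0))
  expect_equal(nrow(empty), 0L)
})

test_that("repeated crossings merge within a cycle but not across cycles", {
  times <- seq(0, 3, by = 0.05)
  rates <- matrix(0, length(times), 2)
  # two bumps of memory 1 inside cycle 0, another in cycle 2
  bump <- function(t0) 20 * exp(-((times - t0) / 0.08)^2)
  rates[, 1] <- bump(0.3) + bump(0.6) + bump(2.5)
  log <- detect_recalls(fake_trajectory(times, rates))
  expect_equal(nrow(log), 2L)
  expect_equal(log$cycle, c(0L, 2L))
  expect_equal(log$first_time, c(TRUE, FALSE))
})

test_that("simultaneously suprathreshold memories raise a calibration error", {
  times <- seq(0, 1, by = 0.1)
  rates <- matrix(0, length(times), 3)
  rates[6, 1] <- 20
  rates[6, 2] <- 22
  expect_error(detect_recalls(fake_trajectory(times, rates)),
               class = "recallnet_simultaneity_error")
})

test_that("detected events match a per-cycle argmax oracle on a real run", {
  set.seed(23)
  ps <- generate_patterns(1e4, 16, 0.1)
  part <- partition_populations(ps)
  cfg <- quick_sim(t_total = 15, dt = 2e-3)
  traj <- simulate_reduced(part, coupling_params(kappa = 13000),
                           gain_spec(2 / 5, 0), oscillation_schedule(),
                           noise_spec(65), cfg, initial_memory = 4L)
  log <- detect_recalls(traj)
  # independent brute-force pass: track each memory's above/below state
  # sample by sample, record upward crossings, merge within cycles
  ev <- list()
  for (mu in 1:16) {
    r <- traj$memory_rates[, mu]
    above <- r[1] >= 15
    if (above) ev[[length(ev) + 1L]] <- c(traj$times[1], mu)
    for (k in 2:length(r)) {
      if (!above && r[k] >= 15) {
        tc <- traj$times[k - 1] + (15 - r[k - 1]) / (r[k] - r[k - 1]) *
          (traj$times[k] - traj$times[k - 1])
        ev[[length(ev) + 1L]] <- c(tc, mu)
      }
      above <- r[k] >= 15
    }
  }
  ev <- do.call(rbind, ev)
  ev <- ev[order(ev[, 1]), , drop = FALSE]
  keep <- logical(nrow(ev))
  last <- NULL
  for (i in seq_len(nrow(ev))) {
    key <- c(ev[i, 2], floor(ev[i, 1]))
    if (is.null(last) || any(key != last)) {
      keep[i] <- TRUE
      last <- key
    }
  }
  ev <- ev[keep, , drop = FALSE]
  expect_equal(log$item, as.integer(ev[, 2]))
  expect_equal(log$time, ev[, 1], tolerance = 1e-12)
  # every detected item's within-cycle peak clears the threshold
  cyc <- floor(traj$times / 1)
  for (i in seq_len(nrow(log))) {
    expect_gte(max(traj$memory_rates[cyc == log$cycle[i], log$item[i]]), 15)
  }
})

test_that("transitions and first-time IRTs follow their definitions", {
  logs <- tibble::tibble(
    trial = 1L, event = 1:5, time = c(0, 1, 3, 5, 7),
    cycle = c(0L, 1L, 3L, 5L, 7L), item = c(2L, 2L, 5L, 2L, 7L),
    first_time = c(TRUE, FALSE, TRUE, FALSE, TRUE)
  )
  # reported-protocol view: successive new items, revisits absorbed into
  # the inter-retrieval times
  tr <- recall_transitions(logs)
  expect_equal(tr$from, c(2L, 5L))
  expect_equal(tr$to, c(5L, 7L))
  expect_equal(tr$irt, c(3, 4))
  # event-level view: repeats of the current item are not transitions
  tr_ev <- recall_transitions(logs, convention = "distinct_events")
  expect_equal(tr_ev$from, c(2L, 5L, 2L))
  expect_equal(tr_ev$to, c(5L, 2L, 7L))
  expect_equal(tr_ev$irt, c(2, 2, 2))
  # first-time IRTs for a 0,1,3,7 retrieval schedule are 1, 2, 4
  logs2 <- tibble::tibble(trial = 1L, event = 1:4, time = c(0, 1, 3, 7),
                          cycle = 0:3, item = 1:4,
                          first_time = rep(TRUE, 4))
  st <- irt_statistics(logs2)
  expect_equal(st$irts$irt, c(1, 2, 4))
  # without repeated items, transitions = events - trials
  expect_equal(nrow(recall_transitions(logs2)), nrow(logs2) - 1L)
})

test_that("conditional IRT curves collapse when all trials are identical", {
  one <- tibble::tibble(trial = 1L, event = 1:3, time = c(0, 2, 5),
                        cycle = c(0L, 2L, 5L), item = 1:3,
                        first_time = rep(TRUE, 3))
  logs <- dplyr::bind_rows(lapply(1:4, function(tr) {
    x <- one
    x$trial <- tr
    x
  }))
  st <- irt_statistics(logs)
  expect_equal(unique(st$conditional$total_recalled), 3L)
  expect_equal(st$conditional$n_trials, c(4L, 4L))
})

test_that("accumulation curves are step functions of first retrievals", {
  logs <- tibble::tibble(trial = 1L, event = 1:3, time = c(1, 2, 3),
                         cycle = 1:3, item = 1:3,
                         first_time = rep(TRUE, 3))
  curve <- accumulation_curve(logs, time_grid = c(0, 1, 1.5, 2, 3, 4))
  expect_equal(curve$mean_recalled, c(0, 1, 1, 2, 3, 3))
  expect_true(all(diff(curve$mean_recalled) >= 0))
  # a trial with no events drags the mean down
  curve2 <- accumulation_curve(logs, time_grid = c(4), n_trials = 2L)
  expect_equal(curve2$mean_recalled, 1.5)
  expect_error(accumulation_curve(logs[0, ]),
               class = "recallnet_input_error")
})

test_that("transition ranks put deterministic mass on the most similar item", {
  p <- 6L
  sim <- matrix(0, p, p)
  sim[1, 2] <- sim[2, 1] <- 10 # most similar partner of 1 is 2
  sim[1, 3] <- sim[3, 1] <- 5
  logs <- tibble::tibble(trial = 1L, event = 1:2, time = c(0, 1),
                         cycle = 0:1, item = c(1L, 2L),
                         first_time = c(TRUE, TRUE))
  rd <- transition_rank_distribution(logs, sim)
  expect_equal(sum(rd$probability), 1)
  expect_equal(rd$probability[p - 1L], 1) # rank P-1 = most similar
  # ties split their mass evenly: constant similarity spreads uniformly
  rd_tie <- transition_rank_distribution(logs, matrix(1, p, p))
  expect_equal(rd_tie$probability, rep(1 / (p - 1L), p - 1L))
  expect_error(transition_rank_distribution(logs, matrix(1, p, p - 1L)),
               class = "recallnet_input_error")
  asym <- matrix(runif(p * p), p, p)
  expect_error(transition_rank_distribution(logs, asym),
               class = "recallnet_input_error")
})

test_that("uniformly random transitions give a flat rank distribution", {
  set.seed(77)
  p <- 16L
  sim <- matrix(rnorm(p * p), p, p)
  sim <- sim + t(sim)
  diag(sim) <- 0
  n_ev <- 3000L
  items <- integer(n_ev)
  items[1] <- 1L
  for (i in 2:n_ev) {
    items[i] <- sample(setdiff(1:p, items[i - 1]), 1L)
  }
  logs <- tibble::tibble(trial = 1L, event = seq_len(n_ev),
                         time = as.numeric(seq_len(n_ev)),
                         cycle = seq_len(n_ev), item = items,
                         first_time = !duplicated(items))
  rd <- transition_rank_distribution(logs, sim, convention = "distinct_events")
  # multinomial SE per rank ~ sqrt(p(1-p)/n)
  se <- sqrt((1 / 15) * (14 / 15) / (n_ev - 1))
  expect_true(all(abs(rd$probability - 1 / 15) < 5 * se))
})

test_that("IRT-versus-similarity bins average the right transitions", {
  p <- 4L
  sim <- matrix(c(0, 3, 1, 1,
                  3, 0, 1, 1,
                  1, 1, 0, 1,
                  1, 1, 1, 0), p, p)
  logs <- tibble::tibble(trial = 1L, event = 1:2, time = c(0, 2.5),
                         cycle = 0:1, item = c(1L, 2L),
                         first_time = c(TRUE, TRUE))
  out <- irt_vs_similarity(logs, sim)
  expect_equal(nrow(out), 1L)
  expect_equal(out$mean_irt, 2.5)
  # constant similarity: a single bin holding the mean of all IRTs
  logs3 <- tibble::tibble(trial = 1L, event = 1:3, time = c(0, 1, 4),
                          cycle = 0:2, item = c(1L, 2L, 3L),
                          first_time = rep(TRUE, 3))
  out3 <- irt_vs_similarity(logs3, matrix(1, p, p))
  expect_equal(nrow(out3), 1L)
  expect_equal(out3$mean_irt, 2)
})

test_that("recall probability by size handles saturated and binary cases", {
  sizes <- tibble::tibble(trial = rep(1:2, each = 4L),
                          item = rep(1:4, 2L),
                          size = c(10, 20, 30, 40, 12, 22, 32, 42))
  all_logs <- tibble::tibble(trial = rep(1:2, each = 4L), event = rep(1:4, 2),
                             time = rep(1:4, 2), cycle = rep(1:4, 2),
                             item = rep(1:4, 2), first_time = TRUE)
  curve <- recall_probability_by_size(all_logs, sizes, n_bins = 2)
  expect_true(all(curve$p_recall == 1))
  # single trial: probabilities are 0 or 1
  one <- all_logs[all_logs$trial == 1 & all_logs$item <= 2, ]
  curve1 <- recall_probability_by_size(one, sizes[sizes$trial == 1, ],
                                       n_bins = 4)
  expect_true(all(curve1$p_recall %in% c(0, 1)))
})
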