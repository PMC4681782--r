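#' Extract recall events from a trajectory
#'
#' A memory is recalled when its mean firing rate crosses the recall
#' threshold from below; the crossing time is linearly interpolated between
#' trajectory samples. Repeated crossings of the same item within one
#' oscillation cycle are merged into a single event. If two memories are
#' above threshold at the same sample, the threshold is miscalibrated for
#' this parameter set and an error is raised.
#'
#' @param trajectory A `recall_trajectory`.
#' @param r_thresh Recall threshold; defaults to the trajectory's config.
#' @param period Oscillation period used for cycle indexing; defaults to the
#'   trajectory's schedule.
#' @return A tibble (the recall log) with columns `event`, `time`, `cycle`,
#'   `item`, `first_time`.
#' @export
detect_recalls <- function(trajectory, r_thresh = NULL, period = NULL) {
  stopifnot(inherits(trajectory, "recall_trajectory"))
  rates <- trajectory$memory_rates
  times <- trajectory$times
  if (is.null(rates) || length(times) == 0L) {
    abort("trajectory carries no samples.", class = "recallnet_input_error")
  }
  if (is.null(r_thresh)) r_thresh <- trajectory$config$r_thresh
  if (is.null(period)) period <- trajectory$schedule$period
  above <- rates > r_thresh
  multi <- rowSums(above) > 1L
  if (any(multi)) {
    k <- which(multi)[1L]
    abort(paste0("memories ", paste(which(above[k, ]), collapse = ", "),
                 " are simultaneously above threshold at t = ", times[k],
                 "; r_thresh is miscalibrated."),
          class = "recallnet_simultaneity_error")
  }
  ev_time <- numeric(0)
  ev_item <- integer(0)
  for (mu in seq_len(ncol(rates))) {
    r <- rates[, mu]
    up <- which(r[-1L] >= r_thresh & r[-length(r)] < r_thresh)
    if (r[1L] >= r_thresh) {
      ev_time <- c(ev_time, times[1L])
      ev_item <- c(ev_item, mu)
    }
    if (length(up)) {
      tcross <- times[up] + (r_thresh - r[up]) / (r[up + 1L] - r[up]) *
        (times[up + 1L] - times[up])
      ev_time <- c(ev_time, tcross)
      ev_item <- c(ev_item, rep(mu, length(up)))
    }
  }
  if (length(ev_time) == 0L) {
    return(tibble(event = integer(), time = numeric(), cycle = integer(),
                  item = integer(), first_time = logical()))
  }
  ord <- order(ev_time)
  ev_time <- ev_time[ord]
  ev_item <- ev_item[ord]
  cycle <- as.integer(floor(ev_time / period))
  keep <- rep(TRUE, length(ev_time))
  last_kept <- 1L
  for (i in seq_along(ev_time)[-1L]) {
    if (ev_item[i] == ev_item[last_kept] && cycle[i] == cycle[last_kept]) {
      keep[i] <- FALSE
    } else {
      last_kept <- i
    }
  }
  ev_time <- ev_time[keep]
  ev_item <- ev_item[keep]
  cycle <- cycle[keep]
  tibble(
    event = seq_along(ev_time), time = ev_time, cycle = cycle,
    item = ev_item, first_time = !duplicated(ev_item)
  )
}

#' Transitions between recalled items
#'
#' Two conventions are supported. `"first_retrieval"` (the default for the
#' similarity statistics) treats the sequence of *reported* items — the
#' first retrieval of each distinct item — as the recall protocol, matching
#' the assumption that repeated reactivations of an already-recalled item
#' are not reported again; a transition is a pair of successive new items
#' and its inter-retrieval time spans everything in between, including
#' revisits. `"distinct_events"` pairs consecutive recall events with
#' different items (repeats of the current item are not transitions); this
#' is the event-level view of the network state sequence.
#'
#' @param logs A recall-log tibble (optionally with a `trial` column).
#' @param convention `"first_retrieval"` or `"distinct_events"`.
#' @return A tibble with `trial`, `transition`, `from`, `to`, `time_from`,
#'   `time_to`, `irt`.
#' @export
recall_transitions <- function(logs,
                               convention = c("first_retrieval",
                                              "distinct_events")) {
  convention <- match.arg(convention)
  logs <- ensure_trial(logs)
  if (convention == "first_retrieval") {
    logs <- dplyr::filter(logs, .data$first_time)
  }
  out <- logs |>
    dplyr::arrange(.data$trial, .data$time) |>
    dplyr::group_by(.data$trial) |>
    dplyr::mutate(next_item = dplyr::lead(.data$item),
                  next_time = dplyr::lead(.data$time)) |>
    dplyr::filter(!is.na(.data$next_item),
                  .data$next_item != .data$item) |>
    dplyr::transmute(transition = dplyr::row_number(),
                     from = .data$item, to = .data$next_item,
                     time_from = .data$time, time_to = .data$next_time,
                     irt = .data$next_time - .data$time) |>
    dplyr::ungroup()
  out
}

ensure_trial <- function(logs) {
  logs <- as_tibble(logs)
  if (!"trial" %in% names(logs)) logs$trial <- 1L
  logs
}

#' Mean cumulative number of distinct items recalled
#'
#' For each grid time, the mean (over trials) count of distinct items
#' retrieved by that time. Trials present in `n_trials` but absent from the
#' logs (no recalls) contribute zero counts.
#'
#' @param logs Recall-log tibble with a `trial` column.
#' @param time_grid Numeric grid; defaults to 200 points spanning the logs.
#' @param n_trials Number of trials in the ensemble; defaults to the number
#'   of distinct trials present in `logs`.
#' @return A tibble with `time`, `mean_recalled`, `se`.
#' @export
accumulation_curve <- function(logs, time_grid = NULL, n_trials = NULL) {
  logs <- ensure_trial(logs)
  if (nrow(logs) == 0L) {
    abort("need at least one recall event.",
          class = "recallnet_input_error")
  }
  if (is.null(n_trials)) n_trials <- dplyr::n_distinct(logs$trial)
  if (is.null(time_grid)) {
    time_grid <- seq(0, max(logs$time), length.out = 200L)
  }
  firsts <- logs[logs$first_time, c("trial", "time")]
  counts <- vapply(time_grid, function(tg) {
    per_trial <- table(factor(firsts$trial[firsts$time <= tg],
                              levels = unique(firsts$trial)))
    tot <- sum(firsts$time <= tg)
    c(mean = tot / n_trials,
      se = if (n_trials > 1L) {
        cnt <- as.numeric(per_trial)
        cnt <- c(cnt, rep(0, n_trials - length(cnt)))
        sd(cnt) / sqrt(n_trials)
      } else NA_real_)
  }, numeric(2))
  tibble(time = time_grid,
         mean_recalled = as.numeric(counts["mean", ]),
         se = as.numeric(counts["se", ]))
}

#' Inter-retrieval time statistics
#'
#' IRTs are the waiting times between the retrieval of successive *new*
#' items within a trial. Returns the pooled per-trial IRT sequences and the
#' Murdock--Okada style conditional curves: mean IRT at each transition
#' index, one curve per total number of items recalled in the trial.
#'
#' @param logs Recall-log tibble with `trial` and `first_time` columns.
#' @return A list with tibbles `irts` (`trial`, `transition`, `irt`,
#'   `total_recalled`) and `conditional` (`total_recalled`, `transition`,
#'   `mean_irt`, `n_trials`).
#' @export
irt_statistics <- function(logs) {
  logs <- ensure_trial(logs)
  firsts <- logs |>
    dplyr::filter(.data$first_time) |>
    dplyr::arrange(.data$trial, .data$time)
  irts <- firsts |>
    dplyr::group_by(.data$trial) |>
    dplyr::filter(dplyr::n() >= 2L) |>
    dplyr::mutate(irt = .data$time - dplyr::lag(.data$time),
                  total_recalled = dplyr::n()) |>
    dplyr::filter(!is.na(.data$irt)) |>
    dplyr::transmute(transition = dplyr::row_number(), irt = .data$irt,
                     total_recalled = .data$total_recalled) |>
    dplyr::ungroup()
  conditional <- irts |>
    dplyr::group_by(.data$total_recalled, .data$transition) |>
    dplyr::summarise(mean_irt = mean(.data$irt),
                     n_trials = dplyr::n(), .groups = "drop")
  list(irts = irts, conditional = conditional)
}

sizes_to_tibble <- function(sizes) {
  if (inherits(sizes, "pattern_set")) {
    return(tibble(trial = 1L, item = seq_along(sizes$sizes),
                  size = sizes$sizes))
  }
  if (is.matrix(sizes)) {
    return(tibble(trial = rep(seq_len(nrow(sizes)), ncol(sizes)),
                  item = rep(seq_len(ncol(sizes)), each = nrow(sizes)),
                  size = as.vector(sizes)))
  }
  stopifnot(all(c("trial", "item", "size") %in% names(sizes)))
  as_tibble(sizes)
}

#' Recall probability versus representation size
#'
#' Pools (trial, item) pairs across the ensemble, marks each as recalled or
#' not, and bins items by representation size into equal-count bins
#' (quantile bins of the pooled size distribution).
#'
#' @param logs Recall-log tibble with a `trial` column.
#' @param sizes Representation sizes: a tibble (`trial`, `item`, `size`), a
#'   trials x P matrix, or a single `pattern_set`.
#' @param n_bins Number of equal-count bins.
#' @return A tibble with `bin`, `size_mean`, `p_recall`, `n`, `se`.
#' @export
recall_probability_by_size <- function(logs, sizes, n_bins = 10) {
  logs <- ensure_trial(logs)
  items <- sizes_to_tibble(sizes)
  recalled <- logs |>
    dplyr::filter(.data$first_time) |>
    dplyr::distinct(.data$trial, .data$item) |>
    dplyr::mutate(recalled = TRUE)
  items <- items |>
    dplyr::left_join(recalled, by = c("trial", "item")) |>
    dplyr::mutate(recalled = !is.na(.data$recalled))
  brk <- unique(quantile(items$size, probs = seq(0, 1, length.out =
                                                   n_bins + 1L)))
  if (length(brk) < 2L) brk <- c(brk - 0.5, brk + 0.5)
  items$bin <- cut(items$size, breaks = brk, include.lowest = TRUE)
  empty <- setdiff(levels(items$bin), unique(as.character(items$bin)))
  if (length(empty)) {
    warn(paste("dropping empty size bins:", paste(empty, collapse = ", ")))
  }
  items |>
    dplyr::filter(!is.na(.data$bin)) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(size_mean = mean(.data$size),
                     p_recall = mean(.data$recalled),
                     n = dplyr::n(),
                     se = sqrt(.data$p_recall * (1 - .data$p_recall) /
                                 dplyr::n()),
                     .groups = "drop") |>
    dplyr::arrange(.data$size_mean)
}

similarity_for_trial <- function(similarity, trial) {
  m <- if (is.list(similarity) && !is.matrix(similarity)) {
    similarity[[trial]]
  } else {
    similarity
  }
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    abort("`similarity` must be a square matrix (or list of them, one per trial).",
          class = "recallnet_input_error")
  }
  if (!isTRUE(all.equal(unname(m), unname(t(m))))) {
    abort("`similarity` must be symmetric.",
          class = "recallnet_input_error")
  }
  m
}

#' Per-transition similarity and similarity rank
#'
#' For each transition a -> b, ranks the similarity of the pair among the
#' similarities of `a` with every other list item, ascending: with P items
#' the most similar partner has rank P - 1. Ties receive the mean fractional
#' rank.
#'
#' @param logs Recall-log tibble with a `trial` column.
#' @param similarity Symmetric P x P similarity matrix (e.g. the
#'   representation intersection sizes), or a list of one matrix per trial.
#' @param convention Transition convention, see [recall_transitions()].
#' @return A tibble: `trial`, `from`, `to`, `similarity`, `rank`, `irt`.
#' @export
transition_ranks <- function(logs, similarity,
                             convention = c("first_retrieval",
                                            "distinct_events")) {
  trans <- recall_transitions(logs, convention)
  if (nrow(trans) == 0L) {
    return(tibble(trial = integer(), from = integer(), to = integer(),
                  similarity = numeric(), rank = numeric(),
                  irt = numeric()))
  }
  res <- purrr::pmap_dfr(
    trans[c("trial", "from", "to", "irt")],
    function(trial, from, to, irt) {
      m <- similarity_for_trial(similarity, trial)
      vals <- m[from, -from]
      others <- setdiff(seq_len(nrow(m)), from)
      v0 <- m[from, to]
      n_less <- sum(vals < v0)
      n_tie <- sum(vals == v0)
      tibble(trial = trial, from = from, to = to, similarity = v0,
             rank = n_less + (n_tie + 1) / 2, irt = irt,
             n_less = n_less, n_tie = n_tie)
    }
  )
  res
}

#' Distribution of transition similarity ranks
#'
#' Probability that a recall transition lands on the k-th most similar item
#' (rank P - 1 = most similar). Tied similarities split their mass evenly
#' over the tied ranks, so the distribution stays normalised.
#'
#' @inheritParams transition_ranks
#' @return A tibble with `rank` (1..P-1) and `probability`.
#' @export
transition_rank_distribution <- function(logs, similarity,
                                         convention = c("first_retrieval",
                                                        "distinct_events")) {
  tr <- transition_ranks(logs, similarity, convention)
  m1 <- similarity_for_trial(similarity, if (nrow(tr)) tr$trial[1L] else 1L)
  p <- nrow(m1)
  mass <- numeric(p - 1L)
  for (i in seq_len(nrow(tr))) {
    ranks <- tr$n_less[i] + seq_len(tr$n_tie[i])
    mass[ranks] <- mass[ranks] + 1 / tr$n_tie[i]
  }
  tibble(rank = seq_len(p - 1L),
         probability = if (nrow(tr)) mass / nrow(tr) else mass)
}

#' Mean inter-retrieval time versus similarity
#'
#' Bins transitions by the similarity of the pair (raw values, equal-width
#' bins unless `breaks` is supplied) and reports the mean IRT per bin.
#'
#' @inheritParams transition_ranks
#' @param n_bins Number of equal-width similarity bins.
#' @param breaks Optional explicit bin breaks.
#' @return A tibble with `bin`, `similarity_mean`, `mean_irt`, `n`.
#' @export
irt_vs_similarity <- function(logs, similarity, n_bins = 8, breaks = NULL,
                              convention = c("first_retrieval",
                                             "distinct_events")) {
  tr <- transition_ranks(logs, similarity, convention)
  if (nrow(tr) == 0L) {
    return(tibble(bin = factor(), similarity_mean = numeric(),
                  mean_irt = numeric(), n = integer()))
  }
  if (is.null(breaks)) {
    rng <- range(tr$similarity)
    if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
    breaks <- seq(rng[1L], rng[2L], length.out = n_bins + 1L)
  }
  tr$bin <- cut(tr$similarity, breaks = breaks, include.lowest = TRUE)
  tr |>
    dplyr::filter(!is.na(.data$bin)) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(similarity_mean = mean(.data$similarity),
                     mean_irt = mean(.data$irt), n = dplyr::n(),
                     .groups = "drop")
}
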