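#' Read and write recall logs, similarity matrices and trajectories
#'
#' Plain tab-separated text with a header row; memory indices are 1-based.
#'
#' @param logs Recall-log tibble.
#' @param path File path.
#' @return `read_recall_log` returns a tibble; the writers return the path
#'   invisibly.
#' @name recallnet-io
NULL

#' @rdname recallnet-io
#' @export
write_recall_log <- function(logs, path) {
  logs <- ensure_trial(logs)
  cols <- c("trial", "event", "time", "cycle", "item", "first_time")
  utils::write.table(logs[intersect(cols, names(logs))], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname recallnet-io
#' @export
read_recall_log <- function(path) {
  as_tibble(utils::read.table(path, header = TRUE, sep = "\t"))
}

#' @rdname recallnet-io
#' @param similarity Square symmetric matrix.
#' @export
write_similarity <- function(similarity, path) {
  colnames(similarity) <- paste0("item_", seq_len(ncol(similarity)))
  utils::write.table(similarity, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname recallnet-io
#' @export
read_similarity <- function(path) {
  m <- as.matrix(utils::read.table(path, header = TRUE, sep = "\t"))
  dimnames(m) <- NULL
  m
}

#' @rdname recallnet-io
#' @param trajectory A `recall_trajectory`.
#' @export
write_trajectory <- function(trajectory, path) {
  rates <- trajectory$memory_rates
  colnames(rates) <- paste0("rate_", seq_len(ncol(rates)))
  df <- data.frame(time = trajectory$times, phi = trajectory$phi,
                   m0 = trajectory$m0, rates)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read or write an experiment configuration as YAML
#'
#' Field names mirror the reference parameter table of the model
#' (`n_neurons`, `kappa`, `phi_max`, ...).
#'
#' @param config An `experiment_config`.
#' @param path File path.
#' @return `read_config` returns an `experiment_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "experiment_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(experiment_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    abort(paste("unknown config fields:", paste(unknown, collapse = ", ")),
          class = "recallnet_input_error")
  }
  do.call(experiment_config, vals)
}

#' Serialise pattern sets and partitions to plain-text arrays
#'
#' The pattern matrix is written as a compact text table (one row per
#' neuron, 0/1 columns per memory) with a one-line header carrying N, P, f.
#'
#' @param patterns A `pattern_set`.
#' @param path File path.
#' @export
write_patterns <- function(patterns, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n_neurons=%d n_memories=%d sparsity=%g",
                     patterns$n_neurons, patterns$n_memories,
                     patterns$sparsity), con)
  utils::write.table(patterns$eta, con, sep = "", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_patterns
#' @export
read_patterns <- function(path) {
  header <- readLines(path, n = 1L)
  m <- sub("^=", "", regmatches(header, gregexpr("=[0-9.eE+-]+",
                                                 header))[[1L]])
  lines <- readLines(path)[-1L]
  eta <- do.call(rbind, lapply(strsplit(lines, ""), as.integer))
  structure(
    list(eta = eta, n_neurons = as.integer(m[1L]),
         n_memories = as.integer(m[2L]), sparsity = as.numeric(m[3L]),
         seed = NULL, sizes = as.integer(colSums(eta))),
    class = "pattern_set"
  )
}
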