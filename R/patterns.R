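#' Generate sparse random memory patterns
#'
#' Draws the binary memory code of the network: an `n_neurons` x `n_memories`
#' matrix whose entries are i.i.d. Bernoulli(`sparsity`). Column mu is the
#' ensemble of neurons representing memory item mu; neurons shared by two
#' columns form the intersection of the two representations, the quantity
#' that governs transitions during recall.
#'
#' Any memory that happens to come out with an empty representation is
#' redrawn (up to `max_retries` times), so every stored item is represented
#' by at least one neuron.
#'
#' @param n_neurons Number of neurons N (>= 1).
#' @param n_memories Number of stored items P (>= 1).
#' @param sparsity Coding level f in (0,1): probability that a neuron takes
#'   part in a given memory.
#' @param seed Optional integer seed; when supplied the draw is reproducible.
#' @param max_retries Maximum redraws for an all-zero memory column.
#' @return An object of class `pattern_set`: list with `eta` (N x P integer
#'   0/1 matrix), `n_neurons`, `n_memories`, `sparsity`, `seed`, and `sizes`
#'   (per-memory representation sizes, i.e. column sums).
#' @examples
#' ps <- generate_patterns(500, 8, 0.1, seed = 1)
#' ps$sizes
#' @export
generate_patterns <- function(n_neurons, n_memories, sparsity,
                              seed = NULL, max_retries = 100L) {
  if (!is.numeric(sparsity) || length(sparsity) != 1L ||
      sparsity <= 0 || sparsity >= 1) {
    abort("`sparsity` must be a single number in (0, 1).",
          class = "recallnet_parameter_error")
  }
  n_neurons <- as.integer(n_neurons)
  n_memories <- as.integer(n_memories)
  if (n_neurons < 1L || n_memories < 1L) {
    abort("`n_neurons` and `n_memories` must be >= 1.",
          class = "recallnet_parameter_error")
  }
  if (!is.null(seed)) set.seed(seed)
  eta <- matrix(rbinom(n_neurons * n_memories, 1L, sparsity),
                nrow = n_neurons, ncol = n_memories)
  sizes <- colSums(eta)
  tries <- 0L
  while (any(sizes == 0L)) {
    tries <- tries + 1L
    if (tries > max_retries) {
      abort(paste0("could not obtain non-empty representations for all ",
                   "memories after ", max_retries, " retries ",
                   "(N*f is too small)."),
            class = "recallnet_degeneracy_error")
    }
    empty <- which(sizes == 0L)
    eta[, empty] <- rbinom(n_neurons * length(empty), 1L, sparsity)
    sizes <- colSums(eta)
  }
  structure(
    list(eta = eta, n_neurons = n_neurons, n_memories = n_memories,
         sparsity = sparsity, seed = seed, sizes = as.integer(sizes)),
    class = "pattern_set"
  )
}

#' @export
print.pattern_set <- function(x, ...) {
  cat("<pattern_set> N =", x$n_neurons, " P =", x$n_memories,
      " f =", x$sparsity, "\n")
  cat("  representation sizes:", paste(utils::head(x$sizes, 8L),
                                       collapse = " "),
      if (x$n_memories > 8L) "..." else "", "\n")
  invisible(x)
}

#' @method tidy pattern_set
#' @export
tidy.pattern_set <- function(x, ...) {
  tibble(memory = seq_len(x$n_memories), size = x$sizes,
         expected_size = x$n_neurons * x$sparsity)
}

#' Partition neurons into identical-code populations
#'
#' Neurons whose membership vector across all P memories is identical receive
#' identical recurrent input and are statistically interchangeable, so the
#' N-neuron dynamics collapses exactly onto one rate unit per distinct
#' membership vector v. This function performs that grouping and records the
#' empirical population fractions S_v = (neurons with code v) / N, which
#' converge to (1-f)^(P-|v|) f^|v| as N grows.
#'
#' @param patterns A `pattern_set`.
#' @return An object of class `population_partition`: list with `vectors`
#'   (V x P 0/1 matrix of distinct codes), `counts`, `fractions`,
#'   `population_index` (length-N map from neuron to population row),
#'   `n_neurons`, `n_memories`, `sparsity`.
#' @examples
#' ps <- generate_patterns(200, 4, 0.1, seed = 1)
#' pp <- partition_populations(ps)
#' sum(pp$fractions) # exactly 1
#' @export
partition_populations <- function(patterns) {
  stopifnot(inherits(patterns, "pattern_set"))
  eta <- patterns$eta
  p <- patterns$n_memories
  if (p <= 30L) {
    key <- as.vector(eta %*% 2^(seq_len(p) - 1L))
  } else {
    key <- apply(eta, 1L, paste0, collapse = "")
  }
  fac <- factor(key, levels = unique(key))
  idx <- as.integer(fac)
  first_row <- match(levels(fac), key)
  vectors <- eta[first_row, , drop = FALSE]
  storage.mode(vectors) <- "double"
  counts <- tabulate(idx, nbins = nrow(vectors))
  structure(
    list(vectors = vectors, counts = as.integer(counts),
         fractions = counts / patterns$n_neurons,
         population_index = idx,
         n_neurons = patterns$n_neurons, n_memories = p,
         sparsity = patterns$sparsity),
    class = "population_partition"
  )
}

#' @export
print.population_partition <- function(x, ...) {
  cat("<population_partition>", nrow(x$vectors), "populations from N =",
      x$n_neurons, "neurons, P =", x$n_memories, "\n")
  invisible(x)
}

#' @method tidy population_partition
#' @export
tidy.population_partition <- function(x, ...) {
  card <- rowSums(x$vectors)
  tibble(population = seq_along(x$counts), cardinality = card,
         count = x$counts, fraction = x$fractions,
         expected_fraction = population_probability(card, x$n_memories,
                                                    x$sparsity))
}

#' Limit population probability
#'
#' Probability S_v that a random membership vector equals a given v of
#' cardinality `cardinality`, i.e. `f^|v| (1-f)^(P-|v|)`.
#'
#' @param cardinality Number of memories the population belongs to, |v|.
#' @param n_memories P.
#' @param sparsity f.
#' @return Numeric vector of probabilities.
#' @export
population_probability <- function(cardinality, n_memories, sparsity) {
  sparsity^cardinality * (1 - sparsity)^(n_memories - cardinality)
}

#' Pairwise intersection sizes of memory representations
#'
#' Returns the P x P matrix whose (mu, nu) entry counts neurons encoding both
#' items; the diagonal holds representation sizes. Intersection size is the
#' model's analogue of semantic similarity between two items.
#'
#' @param patterns A `pattern_set`.
#' @return Symmetric integer P x P matrix.
#' @export
intersection_matrix <- function(patterns) {
  stopifnot(inherits(patterns, "pattern_set"))
  m <- crossprod(patterns$eta)
  storage.mode(m) <- "integer"
  dimnames(m) <- NULL
  m
}
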