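#' Coupling parameters of the memory network
#'
#' Bundles the recurrent-coupling parameters: Hebbian excitation strength
#' `kappa`, relative feedback-inhibition strength `phi` (the baseline value;
#' during simulation the instantaneous value comes from the oscillation
#' schedule), and the temporal-contiguity couplings `j_plus` / `j_minus`
#' linking each item to its list neighbours.
#'
#' @param kappa Excitation strength, > 0.
#' @param phi Relative inhibition strength (baseline).
#' @param j_plus,j_minus Contiguity couplings, >= 0.
#' @return A list of class `coupling_params`.
#' @export
coupling_params <- function(kappa = 13000, phi = 0.7,
                            j_plus = 0, j_minus = 0) {
  if (kappa <= 0) abort("`kappa` must be > 0.",
                        class = "recallnet_parameter_error")
  if (j_plus < 0 || j_minus < 0) {
    abort("`j_plus` and `j_minus` must be >= 0.",
          class = "recallnet_parameter_error")
  }
  structure(list(kappa = kappa, phi = phi,
                 j_plus = j_plus, j_minus = j_minus),
            class = "coupling_params")
}

#' Full N x N Hebbian connectivity matrix
#'
#' Materialises the covariance-rule connectivity
#' \deqn{J_{ij} = (\kappa/N)\left(\sum_\mu (\eta_i^\mu - f)(\eta_j^\mu - f)
#'   - \phi\right)}
#' plus, when contiguity couplings are nonzero, the asymmetric chaining terms
#' `j_plus * sum_mu eta_i^mu eta_j^(mu+1)` and
#' `j_minus * sum_mu eta_i^mu eta_j^(mu-1)` (presentation order 1..P, open
#' boundaries). Intended for validation at small N; the experiments use the
#' population-reduced coupling instead.
#'
#' Two normalisations of the contiguity terms are supported. `"pairwise"`
#' applies `j_plus`/`j_minus` per synapse as written above. `"per_neuron"`
#' divides them by N, which makes the full network the exact N-fold expansion
#' of the population-reduced system with the same coupling values; use it
#' when comparing the two simulators with contiguity switched on.
#'
#' @param patterns A `pattern_set`.
#' @param coupling A `coupling_params`.
#' @param max_n Guard on N (the matrix is dense); raise deliberately to
#'   override.
#' @param contiguity_norm `"pairwise"` (default) or `"per_neuron"`.
#' @return A dense N x N numeric matrix.
#' @export
full_connectivity <- function(patterns, coupling, max_n = 2000L,
                              contiguity_norm = c("pairwise", "per_neuron")) {
  stopifnot(inherits(patterns, "pattern_set"),
            inherits(coupling, "coupling_params"))
  contiguity_norm <- match.arg(contiguity_norm)
  n <- patterns$n_neurons
  if (n > max_n) {
    abort(paste0("N = ", n, " exceeds the dense-matrix guard (", max_n,
                 "); use the population-reduced coupling, or raise `max_n`."),
          class = "recallnet_size_error")
  }
  f <- patterns$sparsity
  p <- patterns$n_memories
  etac <- patterns$eta - f
  j <- (coupling$kappa / n) * (tcrossprod(etac) - coupling$phi)
  if (coupling$j_plus > 0 || coupling$j_minus > 0) {
    scale <- if (contiguity_norm == "per_neuron") 1 / n else 1
    eta <- patterns$eta
    if (p >= 2L) {
      fwd <- tcrossprod(eta[, 1:(p - 1L), drop = FALSE],
                        eta[, 2:p, drop = FALSE])
      bwd <- tcrossprod(eta[, 2:p, drop = FALSE],
                        eta[, 1:(p - 1L), drop = FALSE])
      j <- j + scale * (coupling$j_plus * fwd + coupling$j_minus * bwd)
    }
  }
  j
}

#' Population-reduced coupling matrix
#'
#' Coupling between identical-code populations v and w:
#' \deqn{\tilde J_{vw} = \kappa\left(\sum_\mu (v^\mu - f)(w^\mu - f) -
#'   \phi\right) + J_+ \sum_{\mu \le P-1} v^\mu w^{\mu+1} +
#'   J_- \sum_{\mu \ge 2} v^\mu w^{\mu-1}.}
#' The population drive is then `sum_w Jt_vw S_w g(c_w)`, which reproduces
#' the full network's population-averaged input field exactly (the 1/N of the
#' synaptic rule is absorbed by the fractions S_w, and inhibition phi is
#' subtracted once per weight).
#'
#' @param partition A `population_partition`.
#' @param coupling A `coupling_params`.
#' @return A dense V x V numeric matrix over populations.
#' @export
reduced_coupling <- function(partition, coupling) {
  stopifnot(inherits(partition, "population_partition"),
            inherits(coupling, "coupling_params"))
  v <- partition$vectors
  f <- partition$sparsity
  p <- partition$n_memories
  vc <- v - f
  j <- coupling$kappa * (tcrossprod(vc) - coupling$phi)
  if ((coupling$j_plus > 0 || coupling$j_minus > 0) && p >= 2L) {
    fwd <- tcrossprod(v[, 1:(p - 1L), drop = FALSE],
                      v[, 2:p, drop = FALSE])
    bwd <- tcrossprod(v[, 2:p, drop = FALSE],
                      v[, 1:(p - 1L), drop = FALSE])
    j <- j + coupling$j_plus * fwd + coupling$j_minus * bwd
  }
  j
}
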