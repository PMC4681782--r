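all_population_vectors <- function(p) {
  if (p > 20L) {
    abort("exact enumeration over 2^P population vectors is limited to P <= 20.",
          class = "recallnet_size_error")
  }
  idx <- 0:(2^p - 1)
  vapply(seq_len(p), function(b) as.numeric(bitwAnd(idx, 2^(b - 1)) > 0),
         numeric(length(idx)))
}

#' Mean-field fixed-point residual
#'
#' Evaluates `m - F(m)` for the overlap self-consistency map of the network
#' in the N -> infinity limit, by exact enumeration over all 2^P population
#' vectors weighted by their limit probabilities
#' `S_v = f^|v| (1-f)^(P-|v|)`. The map computes the population currents
#' `c_v = kappa (sum_nu (v^nu - f) m^nu - phi m^0)`, applies the gain, and
#' re-projects: `m^mu = sum_v (v^mu - f) S_v g(c_v)`,
#' `m^0 = sum_v S_v g(c_v)`. Zeros of the residual are the mean-field fixed
#' points.
#'
#' @param overlaps Numeric vector `(m^1, ..., m^P, m^0)`.
#' @param n_memories P (<= 20 for exact enumeration).
#' @param sparsity f.
#' @param coupling A `coupling_params` (kappa and phi are used).
#' @param gain A `gain_spec`.
#' @return Residual vector of length P + 1.
#' @export
fixed_point_residual <- function(overlaps, n_memories, sparsity, coupling,
                                 gain = gain_spec(gamma = 1 / 2)) {
  p <- as.integer(n_memories)
  stopifnot(length(overlaps) == p + 1L)
  v <- all_population_vectors(p)
  m <- overlaps[seq_len(p)]
  m0 <- overlaps[p + 1L]
  sv <- population_probability(rowSums(v), p, sparsity)
  cv <- coupling$kappa *
    (as.vector(v %*% m) - sparsity * sum(m) - coupling$phi * m0)
  y <- cv + gain$theta
  r <- ifelse(y > 0, y^gain$gamma, 0)
  sr <- sv * r
  m_new <- as.vector(crossprod(v, sr)) - sparsity * sum(sr)
  m0_new <- sum(sr)
  c(m - m_new, m0 - m0_new)
}

#' Closed-form intersection-attractor solution
#'
#' Under the ansatz that exactly Q memories are co-active with a common
#' overlap (only populations inside all Q active memories fire), the
#' mean-field equations collapse to a scalar self-consistency for the rate
#' of the active populations. Writing `Delta = Q (1-f)^2 - phi`, the network
#' activity solves `m0^2 = f^(2Q) (kappa Delta m0 + theta)` for the
#' square-root gain (gamma = 1/2), giving
#' \deqn{m^0 = \tfrac12\left(f^{2Q}\kappa\Delta +
#'   \sqrt{f^{4Q}\kappa^2\Delta^2 + 4 f^{2Q}\theta}\right),\qquad
#'   m^{active} = (1-f)\,m^0,\qquad m^{inactive} = 0.}
#' For theta = 0 the solution exists iff `phi < Q (1-f)^2`. For a general
#' exponent gamma and theta = 0 the closed form
#' `r = (kappa f^Q Delta)^(gamma/(1-gamma))`, `m0 = f^Q r` is used; with
#' theta > 0 the scalar equation is solved by damped fixed-point iteration
#' initialised from the gamma = 1/2 form.
#'
#' @param q_active Number of co-active memories Q >= 1.
#' @param f Sparsity.
#' @param kappa Excitation strength.
#' @param phi Relative inhibition.
#' @param theta Gain threshold (>= 0).
#' @param gamma Gain exponent (default 1/2, the analytic case).
#' @param tol,max_iter Iteration controls for the general case.
#' @return A `meanfield_solution`: list with `q_active`, `m0`, `m_active`,
#'   `m_inactive = 0`, `r_active` (firing rate of active populations),
#'   `exists`, plus the parameters.
#' @export
closed_form_solution <- function(q_active, f, kappa, phi, theta = 0,
                                 gamma = 1 / 2, tol = 1e-10,
                                 max_iter = 1e5) {
  if (q_active < 1) {
    abort("`q_active` must be >= 1.", class = "recallnet_parameter_error")
  }
  q <- as.integer(q_active)
  delta <- q * (1 - f)^2 - phi
  fq <- f^q
  if (abs(gamma - 0.5) < 1e-12) {
    m0 <- (fq^2 * kappa * delta +
             sqrt(fq^4 * kappa^2 * delta^2 + 4 * fq^2 * theta)) / 2
  } else if (theta == 0) {
    m0 <- if (delta > 0) fq * (kappa * fq * delta)^(gamma / (1 - gamma)) else 0
  } else {
    # damped iteration on r = (kappa Delta f^Q r + theta)^gamma
    r <- {
      m_half <- (fq^2 * kappa * delta +
                   sqrt(fq^4 * kappa^2 * delta^2 + 4 * fq^2 * theta)) / 2
      max(m_half / fq, theta^gamma)
    }
    damp <- 0.5
    for (i in seq_len(max_iter)) {
      y <- kappa * delta * fq * r + theta
      r_new <- if (y > 0) y^gamma else 0
      if (abs(r_new - r) < tol) {
        r <- r_new
        break
      }
      r <- damp * r + (1 - damp) * r_new
    }
    m0 <- fq * r
  }
  exists <- is.finite(m0) && m0 > 0
  if (!exists) m0 <- 0
  structure(
    list(q_active = q, m0 = m0, m_active = (1 - f) * m0, m_inactive = 0,
         r_active = if (exists) m0 / fq else 0,
         exists = exists, ansatz_ok = NA,
         f = f, kappa = kappa, phi = phi, theta = theta, gamma = gamma),
    class = "meanfield_solution"
  )
}

#' @export
print.meanfield_solution <- function(x, ...) {
  cat("<meanfield_solution> Q =", x$q_active,
      if (x$exists) "" else "(does not exist)", "\n")
  cat("  m0 =", x$m0, " m_active =", x$m_active,
      " r_active =", x$r_active, "\n")
  invisible(x)
}

#' @method tidy meanfield_solution
#' @export
tidy.meanfield_solution <- function(x, ...) {
  tibble(q_active = x$q_active, m0 = x$m0, m_active = x$m_active,
         m_inactive = 0, r_active = x$r_active, exists = x$exists,
         ansatz_ok = x$ansatz_ok, f = x$f, kappa = x$kappa, phi = x$phi,
         theta = x$theta, gamma = x$gamma)
}

#' @method glance meanfield_solution
#' @export
glance.meanfield_solution <- function(x, ...) {
  va <- verify_ansatz(x)
  tibble(q_active = x$q_active, exists = x$exists, ansatz_ok = va$ok,
         margin = va$margin, m0 = x$m0)
}

#' Verify the current-sign ansatz of an intersection solution
#'
#' A Q-intersection solution assumes that populations inside all Q active
#' memories receive suprathreshold current while every other population is
#' subthreshold. Since a population's current depends only on how many of
#' the active memories it belongs to (a = 0..Q),
#' `c_a = kappa m0 ((1-f)(a - Q f) - phi)`, the check enumerates these Q + 1
#' current classes and reports the minimal signed margin.
#'
#' @param solution An existing `meanfield_solution`.
#' @return List with `ok` (logical), `margin` (smallest signed margin;
#'   positive iff the ansatz holds), and a tibble `currents` of the classes.
#' @export
verify_ansatz <- function(solution) {
  stopifnot(inherits(solution, "meanfield_solution"))
  if (!solution$exists) {
    return(list(ok = FALSE, margin = NA_real_,
                currents = tibble(a = integer(), current = numeric(),
                                  required = character())))
  }
  q <- solution$q_active
  a <- 0:q
  cur <- solution$kappa * solution$m0 *
    ((1 - solution$f) * (a - q * solution$f) - solution$phi)
  need_pos <- a == q
  margin_each <- ifelse(need_pos, cur + solution$theta,
                        -(cur + solution$theta))
  list(ok = all(margin_each > 0), margin = min(margin_each),
       currents = tibble(a = a, current = cur,
                         required = ifelse(need_pos, "above threshold",
                                           "below threshold")))
}

#' Scan the (kappa, phi) mean-field phase diagram
#'
#' For every grid cell, evaluates the closed-form Q-intersection solutions
#' for Q = 1..`q_max` together with their current-sign ansatz and assigns a
#' composite phase label recording which state types exist there.
#'
#' @param kappa_range Numeric vector of kappa values.
#' @param phi_range Numeric vector of phi values.
#' @param f Sparsity.
#' @param theta Gain threshold.
#' @param q_max Largest intersection order scanned.
#' @param gamma Gain exponent.
#' @return A tibble of class `phase_diagram` with columns `kappa`, `phi`,
#'   one logical column `q<k>` per order, and `label` ("none", "single",
#'   "single+pair", ...).
#' @export
phase_diagram_scan <- function(kappa_range, phi_range, f = 0.1, theta = 0,
                               q_max = 3, gamma = 1 / 2) {
  if (length(kappa_range) == 0L || length(phi_range) == 0L) {
    abort("grids must be nonempty.", class = "recallnet_parameter_error")
  }
  grid <- tidyr::expand_grid(kappa = kappa_range, phi = phi_range)
  qcols <- purrr::map(seq_len(q_max), function(q) {
    purrr::map2_lgl(grid$kappa, grid$phi, function(k, ph) {
      sol <- closed_form_solution(q, f, k, ph, theta, gamma)
      sol$exists && verify_ansatz(sol)$ok
    })
  })
  names(qcols) <- paste0("q", seq_len(q_max))
  grid <- dplyr::bind_cols(grid, tibble::as_tibble(qcols))
  part_names <- c("single", "pair", if (q_max >= 3)
    paste0("q", 3:q_max))
  grid$label <- purrr::pmap_chr(grid[paste0("q", seq_len(q_max))],
    function(...) {
      ok <- c(...)
      if (!any(ok)) "none" else paste(part_names[ok], collapse = "+")
    })
  class(grid) <- c("phase_diagram", class(grid))
  grid
}

#' @method autoplot phase_diagram
#' @export
autoplot.phase_diagram <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$kappa, y = .data$phi,
                               fill = .data$label)) +
    ggplot2::geom_tile() +
    ggplot2::labs(x = expression(kappa), y = expression(phi),
                  fill = "states") +
    ggplot2::theme_minimal()
}
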