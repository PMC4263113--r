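#' Kinetics matrix A of the graph of complexes
#'
#' For each reaction from complex j to complex k with rate constant
#' \eqn{k_{jk}}, the n x n matrix A gains \eqn{A[k,j] += k_{jk}} and
#' \eqn{A[j,j] -= k_{jk}}, so every column sums to zero and the balance
#' equations read \eqn{\dot c = Y A \psi(c)}.
#'
#' @param net a [reaction_network()].
#' @param k named rate vector (or `NULL` to use the values stored in `net`).
#' @return n x n numeric matrix.
#' @export
kinetics_matrix <- function(net, k = NULL) {
  kv <- rate_vector(net, k)
  n <- length(net$complexes)
  A <- matrix(0, n, n)
  for (i in seq_len(nrow(net$reactions))) {
    fr <- net$reactions$from[i]; to <- net$reactions$to[i]
    A[to, fr] <- A[to, fr] + kv[i]
    A[fr, fr] <- A[fr, fr] - kv[i]
  }
  A
}

#' Mass-action monomials of every complex
#'
#' \eqn{\psi_j(c) = \prod_i c_i^{y_{ij}}}; the zero complex contributes the
#' empty product 1.  Concentrations must be strictly positive (the
#' logarithmic derivation of the equilibrium manifold requires it).
#'
#' @param net a [reaction_network()].
#' @param conc positive concentration vector in species order.
#' @return numeric vector of length n.
#' @export
mass_action_monomials <- function(net, conc) {
  if (length(conc) != length(net$species)) stop("concentration length mismatch")
  if (any(conc <= 0)) stop("concentrations must be strictly positive")
  vapply(net$complexes, function(cx) {
    if (length(cx) == 0L) return(1)
    prod(conc[match(names(cx), net$species)]^cx)
  }, 0)
}

#' Right-hand side of the mass-action balance equations
#'
#' Evaluates \eqn{\dot c = Y A \psi(c)}.  The identical value is obtained as
#' \eqn{N v(c)} with \eqn{v_{jk} = k_{jk}\psi_j}; see [reaction_rates()].
#'
#' @inheritParams kinetics_matrix
#' @param conc positive concentration vector.
#' @export
ode_rhs <- function(net, k = NULL, conc) {
  Y <- structural_Y(net)
  A <- kinetics_matrix(net, k)
  drop(Y %*% (A %*% mass_action_monomials(net, conc)))
}

#' Reaction rate vector \eqn{v_{jk} = k_{jk} \psi_j(c)}
#' @inheritParams ode_rhs
#' @export
reaction_rates <- function(net, k = NULL, conc) {
  kv <- rate_vector(net, k)
  psi <- mass_action_monomials(net, conc)
  stats::setNames(kv * psi[net$reactions$from], net$reactions$label)
}

#' @noRd
structural_Y <- function(net) {
  m <- length(net$species); n <- length(net$complexes)
  Y <- matrix(0, m, n, dimnames = list(net$species, NULL))
  for (j in seq_len(n)) {
    cx <- net$complexes[[j]]
    if (length(cx)) Y[names(cx), j] <- cx
  }
  Y
}

#' Integrate the mass-action ODE system
#'
#' Thin wrapper around [deSolve::lsoda()] used for steady-state relaxation
#' (continuation seeding) and as an independent oracle in tests.
#'
#' @inheritParams ode_rhs
#' @param c0 positive initial concentrations.
#' @param times output times.
#' @param ... passed to [deSolve::lsoda()].
#' @return deSolve output matrix (time in column 1).
#' @export
simulate_network <- function(net, k = NULL, c0, times, ...) {
  kv <- rate_vector(net, k)
  Y <- structural_Y(net)
  A <- kinetics_matrix(net, kv)
  YA <- Y %*% A
  f <- function(t, y, parms) {
    y <- pmax(y, 1e-300)
    list(drop(YA %*% mass_action_monomials(net, y)))
  }
  deSolve::lsoda(y = c0, times = times, func = f, parms = NULL,
                 rtol = 1e-10, atol = 1e-12, ...)
}

#' Relax to a steady state by long ODE integration
#'
#' Integrates until the right-hand side is small relative to the state or a
#' time horizon is exhausted.  Used to seed equilibrium continuation.
#'
#' @inheritParams simulate_network
#' @param t_max total integration horizon.
#' @param tol relative residual tolerance.
#' @return list with `conc` (steady state) and `residual`.
#' @export
relax_to_steady_state <- function(net, k = NULL, c0, t_max = 1e6, tol = 1e-10) {
  kv <- rate_vector(net, k)
  t_cur <- 1
  cc <- c0
  repeat {
    out <- simulate_network(net, kv, cc, c(0, t_cur))
    cc <- pmax(as.numeric(out[nrow(out), -1]), 1e-12)
    res <- max(abs(ode_rhs(net, kv, cc))) / max(max(cc), 1e-12)
    if (res < tol || t_cur >= t_max) break
    t_cur <- t_cur * 10
  }
  list(conc = cc, residual = res)
}
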