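#' Equilibrium-manifold system
#'
#' On the equilibrium locus the complex-space flux satisfies
#' \eqn{A\psi(c) = \sum_i \alpha_i \omega_i}, with \eqn{\omega_1..\omega_\delta}
#' spanning the deficiency subspace and \eqn{\alpha} the deficiency
#' parameters.  Projecting the residual \eqn{A\psi(c) - \omega\alpha} onto an
#' orthonormal basis \eqn{U} of \eqn{Im(A)} yields exactly \eqn{n - l}
#' independent equations \eqn{H_s(c, \alpha; k) = 0} whose zero set is the
#' equilibrium manifold of dimension \eqn{\lambda = m - s}.  Because
#' \eqn{Im(A)} equals the span of the incidence vectors of the graph of
#' complexes for t = l networks, \eqn{U} does not depend on the rate
#' constants and is computed once per network.  Any other choice of n - l
#' independent rows has the same zero set; the projection merely fixes a
#' numerically convenient representative.
#'
#' @param summary a [structural_summary()] (or a `reaction_network`, which is
#'   summarized first).
#' @return An object of class `manifold_system` with the projector `U`
#'   ((n-l) x n, orthonormal rows), the deficiency basis `omega` and the
#'   underlying summary (plus precomputed index tables used by the fast
#'   internal evaluators).
#' @export
manifold_system <- function(summary) {
  if (inherits(summary, "reaction_network")) summary <- structural_summary(summary)
  stopifnot(inherits(summary, "structural_summary"))
  U <- t(range_space(summary$incidence))
  if (nrow(U) != summary$n - summary$ell) {
    stop("incidence span dimension disagrees with n - l")
  }
  net <- summary$network
  cx_idx <- lapply(net$complexes, function(cx) match(names(cx), net$species))
  cx_exp <- lapply(net$complexes, as.numeric)
  from <- net$reactions$from
  structure(list(summary = summary, U = U,
                 omega = summary$omega,
                 from = from,
                 to = net$reactions$to,
                 Y = summary$Y,
                 incidence = summary$incidence,
                 cx_idx = cx_idx, cx_exp = cx_exp,
                 n_cx = summary$n, m = summary$m, r = summary$r,
                 Yt_from = t(summary$Y)[from, , drop = FALSE],
                 Bt = t(summary$B)),
            class = "manifold_system")
}

# ---- fast internal evaluators (k as a plain vector in reaction order) ----

#' @noRd
ms_psi <- function(ms, cc) {
  psi <- rep(1, ms$n_cx)
  idx <- ms$cx_idx; expv <- ms$cx_exp
  for (j in seq_len(ms$n_cx)) {
    ij <- idx[[j]]
    if (length(ij)) psi[j] <- prod(cc[ij]^expv[[j]])
  }
  psi
}

#' @noRd
ms_residual <- function(ms, cc, alpha, kvec, psi = NULL) {
  if (is.null(psi)) psi <- ms_psi(ms, cc)
  z <- drop(ms$incidence %*% (kvec * psi[ms$from]))
  if (length(alpha)) z <- z - drop(ms$omega %*% alpha)
  drop(ms$U %*% z)
}

#' @noRd
ms_jac <- function(ms, cc, kvec, psi = NULL) {
  if (is.null(psi)) psi <- ms_psi(ms, cc)
  v <- kvec * psi[ms$from]
  Dr <- (v * ms$Yt_from) / rep(cc, each = ms$r)
  D_c <- ms$U %*% (ms$incidence %*% Dr)
  D_alpha <- -ms$U %*% ms$omega
  list(D_c = D_c, D_alpha = D_alpha)
}

# typical magnitude of the complex flux, for relative residual tests
#' @noRd
ms_scale <- function(ms, kvec, psi) max(abs(kvec * psi[ms$from]))

#' Equilibrium-manifold residual \eqn{H_s(c, \alpha; k)}
#'
#' @param ms a [manifold_system()].
#' @param conc strictly positive concentration vector (length m).
#' @param alpha deficiency parameter vector (length \eqn{\delta}; may be
#'   empty for deficiency-zero networks).
#' @param k named rate vector.
#' @return numeric vector of length n - l; zero exactly on the manifold.
#' @export
manifold_residual <- function(ms, conc, alpha, k = NULL) {
  if (any(conc <= 0)) stop("concentrations must be strictly positive")
  kvec <- rate_vector(ms$summary$network, k)
  ms_residual(ms, conc, alpha, kvec)
}

#' Solve the manifold equations for the concentrations
#'
#' Damped Newton iteration on \eqn{H_s(\cdot, \alpha; k) = 0} with step
#' halving until all concentrations stay positive.  For \eqn{\delta = \lambda}
#' the system is square in c; for \eqn{\lambda > \delta} the surplus
#' \eqn{\lambda - \delta} concentration coordinates must be pinned to given
#' values via `pinned`.
#'
#' Non-convergence is reported through the `converged` flag, not an error,
#' so optimization loops can penalize and move on.  A Jacobian with
#' reciprocal condition number below 1e-12 is treated as singular and also
#' flagged.
#'
#' @param ms a [manifold_system()].
#' @param k named rate vector.
#' @param alpha deficiency parameters.
#' @param c_guess positive starting concentrations.
#' @param pinned optional named numeric vector of species pinned to values.
#' @param max_iter,tol Newton controls (residual max-norm tolerance,
#'   relative to the complex-flux scale when that exceeds one).
#' @return list with `conc`, `alpha`, `k`, `converged`, `residual`,
#'   `iterations`; class `equilibrium_point`.
#' @export
solve_manifold_point <- function(ms, k = NULL, alpha = numeric(0), c_guess,
                                 pinned = NULL, max_iter = 100, tol = 1e-10) {
  net <- ms$summary$network
  kvec <- unname(rate_vector(net, k))
  m <- ms$m
  free <- seq_len(m)
  cc <- unname(c_guess)
  if (!is.null(pinned)) {
    idx <- match(names(pinned), net$species)
    if (anyNA(idx)) stop("pinned species not found")
    cc[idx] <- pinned
    free <- setdiff(free, idx)
  }
  neq <- ms$summary$n - ms$summary$ell
  if (length(free) != neq) {
    stop(sprintf("manifold solve needs %d free concentrations, got %d",
                 neq, length(free)))
  }
  if (any(cc <= 0)) stop("c_guess must be strictly positive")
  psi <- ms_psi(ms, cc)
  res <- ms_residual(ms, cc, alpha, kvec, psi)
  it <- 0L
  ok <- FALSE
  while (it < max_iter) {
    sc <- max(1, ms_scale(ms, kvec, psi))
    if (max(abs(res)) < tol * sc) { ok <- TRUE; break }
    J <- ms_jac(ms, cc, kvec, psi)$D_c[, free, drop = FALSE]
    rc <- tryCatch(rcond(J), error = function(e) 0)
    if (!is.finite(rc) || rc < 1e-12) break
    step <- tryCatch(solve(J, -res), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) break
    lam <- 1
    improved <- FALSE
    for (h in 1:30) {
      trial <- cc
      trial[free] <- cc[free] + lam * step
      if (all(trial > 0)) {
        psi2 <- ms_psi(ms, trial)
        r2 <- ms_residual(ms, trial, alpha, kvec, psi2)
        if (all(is.finite(r2)) &&
            (sum(r2^2) < sum(res^2) || max(abs(r2)) < tol * sc)) {
          cc <- trial; res <- r2; psi <- psi2; improved <- TRUE; break
        }
      }
      lam <- lam / 2
    }
    if (!improved) break
    it <- it + 1L
  }
  if (!ok) ok <- max(abs(res)) < tol * max(1, ms_scale(ms, kvec, psi))
  structure(list(conc = stats::setNames(cc, net$species), alpha = alpha,
                 k = stats::setNames(kvec, net$reactions$label),
                 converged = ok, residual = max(abs(res)),
                 iterations = it),
            class = "equilibrium_point")
}

# kept as an internal alias for modules that already hold a resolved kvec
#' @noRd
res_scale <- function(ms, conc, kvec) ms_scale(ms, kvec, ms_psi(ms, conc))

#' @noRd
manifold_jacobians <- function(ms, conc, alpha, kvec) {
  J <- ms_jac(ms, conc, unname(kvec))
  J$residual <- ms_residual(ms, conc, alpha, unname(kvec))
  J
}

#' Manifold tangent \eqn{dc/d\alpha = -D_c H_s^{-1} D_\alpha H_s}
#'
#' Requires \eqn{\delta = \lambda} so that \eqn{D_c H_s} is square.  The
#' linear system is solved directly (no explicit inverse).
#'
#' @param ms a [manifold_system()].
#' @param pt an `equilibrium_point` from [solve_manifold_point()].
#' @return m x delta matrix.
#' @export
dc_dalpha <- function(ms, pt) {
  if (ms$summary$delta == 0L) {
    stop("deficiency-zero network: no deficiency parameters to differentiate by")
  }
  if (ms$summary$delta != ms$summary$lambda) {
    stop("dc_dalpha requires delta = lambda (square D_c H_s)")
  }
  J <- ms_jac(ms, unname(pt$conc), unname(pt$k))
  rc <- tryCatch(rcond(J$D_c), error = function(e) 0)
  if (!is.finite(rc) || rc < 1e-14) {
    stop("D_c H_s is singular at this point (degenerate equilibrium)")
  }
  solve(J$D_c, -J$D_alpha)
}

#' Tangency matrix G and its determinant
#'
#' Assembles the square matrix
#' \deqn{G = [[D_c H_s, D_\alpha H_s], [B^T, 0]]}
#' of size \eqn{(n-l) + (m-s) = m + \delta}.  The equilibrium manifold and
#' the stoichiometric compatibility class through the point are tangent --
#' i.e. a saddle-node (limit point) bifurcation occurs -- exactly when
#' \eqn{det(G) = 0}.  The determinant is evaluated after row/column max-norm
#' equilibration so the value is insensitive to concentration units, and a
#' reciprocal condition estimate is reported so callers can distinguish a
#' genuine tangency from mere bad scaling.
#'
#' @param ms a [manifold_system()].
#' @param pt an `equilibrium_point`; must satisfy the manifold equations.
#' @param check if `TRUE` (default) refuse points off the manifold.
#' @return list of class `tangency_report`: `G`, `det` (equilibrated),
#'   `rcond`, `size`.
#' @export
tangency_matrix <- function(ms, pt, check = TRUE) {
  if (check && !isTRUE(pt$converged)) stop("point is not on the manifold")
  J <- ms_jac(ms, unname(pt$conc), unname(pt$k))
  G <- rbind(cbind(J$D_c, J$D_alpha),
             cbind(ms$Bt, matrix(0, nrow(ms$Bt), ms$summary$delta)))
  stopifnot(nrow(G) == ms$summary$m + ms$summary$delta, nrow(G) == ncol(G))
  e <- equilibrated_det(G)
  structure(list(G = G, det = e$det, rcond = e$rcond, size = nrow(G)),
            class = "tangency_report")
}

# det only, for hot loops
#' @noRd
ms_det <- function(ms, cc, kvec) {
  J <- ms_jac(ms, cc, kvec)
  G <- rbind(cbind(J$D_c, J$D_alpha),
             cbind(ms$Bt, matrix(0, nrow(ms$Bt), ms$summary$delta)))
  r <- apply(abs(G), 1, max); r[r == 0] <- 1
  Gs <- G / r
  cs <- apply(abs(Gs), 2, max); cs[cs == 0] <- 1
  det(sweep(Gs, 2, cs, "/"))
}

#' Reaction-polyhedron residual \eqn{B^T c - b}
#'
#' The stoichiometric compatibility class (reaction polyhedron) through a
#' reference state is the affine slice on which the conservation quantities
#' equal `b`.
#'
#' @param summary a [structural_summary()].
#' @param conc concentration vector.
#' @param b conservation constants (length m - s).
#' @export
polyhedron_residual <- function(summary, conc, b) {
  if (length(b) != ncol(summary$B)) {
    stop(sprintf("b must have %d entries (one per conservation law)",
                 ncol(summary$B)))
  }
  drop(t(summary$B) %*% conc) - b
}

#' Least-squares deficiency coordinates of a state
#'
#' For a steady state of the ODE system the complex flux \eqn{A\psi(c)} lies
#' in the deficiency subspace; its coordinates in the \eqn{\omega} basis are
#' recovered by least squares.  Off equilibrium the residual of this fit is
#' nonzero and is returned alongside.
#'
#' @param ms a [manifold_system()].
#' @param conc positive concentration vector.
#' @param k named rate vector.
#' @return list with `alpha` and `residual` (max-norm of the unexplained
#'   part of \eqn{A\psi}).
#' @export
alpha_from_state <- function(ms, conc, k = NULL) {
  kvec <- unname(rate_vector(ms$summary$network, k))
  psi <- ms_psi(ms, unname(conc))
  z <- drop(ms$incidence %*% (kvec * psi[ms$from]))
  if (ncol(ms$omega) == 0L) {
    return(list(alpha = numeric(0), residual = max(abs(z))))
  }
  alpha <- drop(qr.solve(ms$omega, z))
  list(alpha = alpha, residual = max(abs(z - drop(ms$omega %*% alpha))))
}
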