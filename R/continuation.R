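#' Trace an equilibrium branch against a stimulus
#'
#' Computes the locus of equilibria of a bistable network as one stimulus is
#' varied: either a conservation-law constant (total amount of a conserved
#' moiety, e.g. total enzyme) or a rate constant (e.g. a degradation rate).
#' In a typical bistable system the branch is S-shaped: the stimulus
#' direction reverses at two saddle-node (limit) points which enclose the
#' bistable interval.
#'
#' Two strategies are used.  For a conservation-constant stimulus on a
#' \eqn{\delta = \lambda = 1} network the branch is followed natively in the
#' deficiency parameter \eqn{\alpha} (the manifold's own coordinate), mapping
#' each point to \eqn{b = B^T c}; no arclength machinery is needed because
#' \eqn{\alpha} stays monotone through the folds.  In every other case
#' (rate-constant stimuli, or \eqn{\delta = \lambda = 2}) a standard
#' pseudo-arclength predictor--corrector is run on the stacked system
#' \eqn{[H_s; B^T c - b]} with the stimulus appended as an unknown.
#'
#' @param ms a [manifold_system()].
#' @param k named rate vector (the stimulus label, if any, may be left unset).
#' @param stimulus list: `list(kind = "conservation", index = i)` or
#'   `list(kind = "rate", label = "k7_13")`.
#' @param range numeric `c(lo, hi)`: the stimulus interval to cover.
#' @param c_seed optional positive equilibrium (or near-equilibrium) state at
#'   the start of the range; when absent a state is obtained by ODE
#'   relaxation inside the starting compatibility class.
#' @param b_fixed conservation constants held fixed: all of them for a rate
#'   stimulus; all but `index` for a conservation stimulus (the value at
#'   `index` is taken as the range start).
#' @param n_min minimum number of recorded points across the range (controls
#'   the target stimulus resolution, `range/200` by default near folds).
#' @param max_steps hard cap on continuation steps.
#' @return An object of class `equilibrium_branch`: `points` (matrix with
#'   columns `stimulus`, the m concentrations, the \eqn{\delta} alphas and
#'   `det`), plus the context needed to refine limit points.
#' @export
trace_branch <- function(ms, k = NULL, stimulus, range, c_seed = NULL,
                         b_fixed = NULL, n_min = 200, max_steps = 5000) {
  sm <- ms$summary
  net <- sm$network
  lo <- min(range); hi <- max(range)
  nlaws <- ncol(sm$B)

  if (stimulus$kind == "conservation") {
    kvec <- rate_vector(net, k)
    i_st <- stimulus$index
    b0 <- numeric(nlaws)
    if (!is.null(b_fixed)) b0[] <- b_fixed
    b0[i_st] <- lo
  } else if (stimulus$kind == "rate") {
    kv0 <- k %||% numeric(0)
    kv0[stimulus$label] <- lo
    kvec <- rate_vector(net, kv0)
    i_rxn <- match(stimulus$label, net$reactions$label)
    if (is.na(i_rxn)) stop("unknown stimulus rate label")
    b0 <- b_fixed
    if (is.null(b0) || length(b0) != nlaws) {
      stop("rate-stimulus continuation needs b_fixed (all conservation constants)")
    }
  } else stop("stimulus$kind must be 'conservation' or 'rate'")

  # seed equilibrium at the range start
  if (is.null(c_seed)) c_seed <- complete_class_state(sm, b0)
  rel <- relax_to_steady_state(net, kvec, c_seed, t_max = 1e8, tol = 1e-9)
  cc <- rel$conc
  if (rel$residual > 1e-6) stop("no equilibrium found at the range start (seeding error)")
  al <- alpha_from_state(ms, cc, kvec)$alpha

  if (stimulus$kind == "conservation" && sm$delta == 1L && sm$lambda == 1L) {
    pts <- trace_natural_alpha(ms, kvec, i_st, lo, hi, cc, al, n_min, max_steps)
  } else {
    pts <- trace_arclength(ms, kvec, stimulus, lo, hi, cc, al, b0, n_min, max_steps)
  }
  structure(list(points = pts, stimulus = stimulus, k = kvec,
                 b_fixed = b0, ms = ms),
            class = "equilibrium_branch")
}

# a positive state lying exactly in the compatibility class B^T c = b: all
# species start tiny, then the first species of each conservation law
# absorbs the remainder of its total
#' @noRd
complete_class_state <- function(sm, b) {
  m <- sm$m
  B <- sm$B
  eps <- min(1e-6, 1e-3 * min(abs(b[b != 0]), 1))
  cc <- rep(eps, m)
  for (j in seq_len(ncol(B))) {
    idx <- which(abs(B[, j]) > 1e-9)
    lead <- idx[1]
    rest <- sum(B[idx[-1], j] * cc[idx[-1]])
    cc[lead] <- (b[j] - rest) / B[lead, j]
    if (cc[lead] <= 0) cc[lead] <- eps
  }
  cc
}

#' @noRd
branch_row <- function(ms, stim_value, pt) {
  tr <- tangency_matrix(ms, pt, check = FALSE)
  c(stim_value, pt$conc, pt$alpha, tr$det)
}

# natural continuation in alpha (delta = lambda = 1, conservation stimulus)
#' @noRd
trace_natural_alpha <- function(ms, kvec, i_st, lo, hi, cc, al, n_min, max_steps) {
  sm <- ms$summary
  Bi <- sm$B[, i_st]
  width <- hi - lo
  target_db <- width / max(n_min, 200)
  margin <- 0.05 * width
  # initial direction: db/dalpha sign so that b increases
  pt <- solve_manifold_point(ms, kvec, al, cc)
  dbda <- drop(Bi %*% dc_dalpha(ms, pt))
  dir <- if (dbda >= 0) 1 else -1
  da <- max(abs(al), 0.1) / 200
  rows <- list(branch_row(ms, drop(Bi %*% cc), pt))
  b_cur <- drop(Bi %*% cc)
  streak <- 0L
  for (step in seq_len(max_steps)) {
    ok <- FALSE
    while (da > 1e-12 * max(abs(al), 1)) {
      al_try <- al + dir * da
      ptt <- solve_manifold_point(ms, kvec, al_try, cc, max_iter = 40)
      if (ptt$converged && all(ptt$conc > 0)) { ok <- TRUE; break }
      da <- da / 2; streak <- 0L
    }
    if (!ok) break
    b_new <- drop(Bi %*% ptt$conc)
    # keep stimulus resolution near target; refine if we moved too far
    if (abs(b_new - b_cur) > 2 * target_db && da > 1e-11) {
      da <- da / 2; streak <- 0L; next
    }
    al <- al + dir * da; cc <- ptt$conc
    rows[[length(rows) + 1L]] <- branch_row(ms, b_new, ptt)
    b_cur <- b_new
    streak <- streak + 1L
    if (streak >= 3L) { da <- da * 1.3; streak <- 0L }
    if (b_cur > hi + margin || b_cur < lo - margin) break
  }
  pts <- do.call(rbind, rows)
  colnames(pts) <- c("stimulus", sm$network$species,
                     alpha_names(sm$delta), "det")
  pts
}

#' @noRd
alpha_names <- function(delta) {
  if (delta == 0L) return(character(0))
  paste0("alpha", seq_len(delta))
}

# pseudo-arclength continuation on [H_s; B^T c - b] with the stimulus as an
# extra unknown.  x = (c, alpha, theta).
#' @noRd
trace_arclength <- function(ms, kvec, stimulus, lo, hi, cc, al, b0, n_min,
                            max_steps) {
  sm <- ms$summary
  net <- sm$network
  m <- sm$m; delta <- sm$delta
  nlaws <- ncol(sm$B)
  is_rate <- stimulus$kind == "rate"
  i_rxn <- if (is_rate) match(stimulus$label, net$reactions$label) else NA
  i_st <- if (!is_rate) stimulus$index else NA
  width <- hi - lo
  margin <- 0.05 * width

  kv_at <- function(theta) {
    kk <- kvec
    if (is_rate) kk[i_rxn] <- theta
    kk
  }
  b_at <- function(theta) {
    bb <- b0
    if (!is_rate) bb[i_st] <- theta
    bb
  }
  Ffun <- function(x) {
    ccx <- x[1:m]; alx <- if (delta) x[m + seq_len(delta)] else numeric(0)
    th <- x[m + delta + 1L]
    c(manifold_residual(ms, ccx, alx, kv_at(th)),
      drop(t(sm$B) %*% ccx) - b_at(th))
  }
  Jfun <- function(x) {
    ccx <- x[1:m]; alx <- if (delta) x[m + seq_len(delta)] else numeric(0)
    th <- x[m + delta + 1L]
    kk <- kv_at(th)
    J <- manifold_jacobians(ms, ccx, alx, kk)
    psi <- mass_action_monomials(net, ccx)
    dH_dth <- if (is_rate) {
      drop(ms$U %*% ms$incidence[, i_rxn]) * psi[net$reactions$from[i_rxn]]
    } else rep(0, nrow(ms$U))
    db_dth <- rep(0, nlaws)
    if (!is_rate) db_dth[i_st] <- -1
    rbind(cbind(J$D_c, J$D_alpha, dH_dth),
          cbind(t(sm$B), matrix(0, nlaws, delta), db_dth))
  }
  # state scaling for the arclength metric: concentrations can span decades
  # along a branch, so the metric is rescaled to the current point
  x <- c(cc, al, lo)
  scal <- pmax(abs(x), 1e-3)
  theta_i <- m + delta + 1L

  tangent <- function(x, t_prev) {
    J <- Jfun(x)
    Ab <- rbind(J, t_prev)
    tv <- tryCatch(solve(Ab, c(rep(0, nrow(J)), 1)), error = function(e) NULL)
    if (is.null(tv) || any(!is.finite(tv))) return(NULL)
    tv / sqrt(sum((tv / scal)^2))
  }
  corrector <- function(x_pred, tv, max_iter = 25) {
    xx <- x_pred
    for (it in seq_len(max_iter)) {
      if (any(xx[1:m] <= 0)) return(NULL)
      Fv <- c(Ffun(xx), sum(tv * (xx - x_pred) / scal^2))
      if (max(abs(Fv)) < 1e-10 * max(1, res_scale(ms, xx[1:m], kv_at(xx[theta_i]))))
        return(xx)
      J <- rbind(Jfun(xx), tv / scal^2)
      st <- tryCatch(solve(J, -Fv), error = function(e) NULL)
      if (is.null(st) || any(!is.finite(st))) return(NULL)
      lam <- 1
      repeat {
        trial <- xx + lam * st
        if (all(trial[1:m] > 0)) break
        lam <- lam / 2
        if (lam < 1e-6) return(NULL)
      }
      xx <- xx + lam * st
    }
    NULL
  }

  # sharpen the relaxed seed onto [H_s; B^T c - b] at fixed stimulus
  fix_theta <- rep(0, theta_i); fix_theta[theta_i] <- 1
  x_sharp <- corrector(x, fix_theta)
  if (!is.null(x_sharp)) x <- x_sharp

  t_prev <- fix_theta
  tv <- tangent(x, t_prev)
  if (is.null(tv)) stop("singular Jacobian at the branch seed")
  if (tv[theta_i] < 0) tv <- -tv

  h <- 0.02
  h_min <- 1e-10
  h_max <- 0.2
  res_coarse <- width / max(60, n_min / 4)   # global stimulus resolution
  res_fold <- width / max(200, n_min)        # resolution across a fold
  rows <- list(branch_row_x(ms, x, m, delta, kv_at))
  streak <- 0L
  for (step in seq_len(max_steps)) {
    ok <- FALSE
    while (h >= h_min) {
      x_pred <- x + h * tv
      xx <- corrector(x_pred, tv)
      if (!is.null(xx)) {
        dth <- abs(xx[theta_i] - x[theta_i])
        tv_new <- tangent(xx, tv / scal^2)
        if (!is.null(tv_new)) {
          if (sum(tv_new * tv / scal^2) < 0) tv_new <- -tv_new
          crossing <- tv_new[theta_i] * tv[theta_i] < 0
          need <- if (crossing) res_fold else res_coarse
          if (dth <= need || h <= 4 * h_min) { ok <- TRUE; break }
        }
      }
      h <- h / 2; streak <- 0L
    }
    if (!ok) break
    x <- xx
    scal <- pmax(abs(x), 1e-3)
    tv <- tv_new / sqrt(sum((tv_new / scal)^2))
    rows[[length(rows) + 1L]] <- branch_row_x(ms, x, m, delta, kv_at)
    streak <- streak + 1L
    if (streak >= 2L) { h <- min(h * 1.4, h_max); streak <- 0L }
    th <- x[theta_i]
    if (th > hi + margin || th < lo - margin) break
  }
  pts <- do.call(rbind, rows)
  colnames(pts) <- c("stimulus", net$species, alpha_names(delta), "det")
  pts
}

#' @noRd
branch_row_x <- function(ms, x, m, delta, kv_at) {
  th <- x[m + delta + 1L]
  pt <- structure(list(conc = x[1:m],
                       alpha = if (delta) x[m + seq_len(delta)] else numeric(0),
                       k = kv_at(th), converged = TRUE),
                  class = "equilibrium_point")
  branch_row(ms, th, pt)
}

#' Detect and refine limit points on a branch
#'
#' Folds are bracketed by a sign change of the stimulus increment along the
#' branch and refined by bisection on the equilibrated determinant of the
#' tangency matrix G, which changes sign across each fold.  Each refined
#' point satisfies \eqn{|det(G)| < 10^{-6}} (equilibrated scale).
#'
#' @param branch an `equilibrium_branch`.
#' @return list of `limit_point` objects: `stimulus`, `conc`, `alpha`,
#'   `det`, `side` (`"lower"`/`"upper"` by stimulus value).
#' @export
detect_limit_points <- function(branch) {
  pts <- branch$points
  if (nrow(pts) < 3L) return(list())
  th <- pts[, "stimulus"]
  dth <- diff(th)
  rev_idx <- which(dth[-1] * dth[-length(dth)] < 0) + 1L
  lps <- lapply(rev_idx, function(i) refine_fold(branch, i))
  lps <- Filter(Negate(is.null), lps)
  if (length(lps) == 0L) return(lps)
  ord <- order(vapply(lps, function(l) l$stimulus, 0))
  lps <- lps[ord]
  for (i in seq_along(lps)) {
    lps[[i]]$side <- if (length(lps) == 2L && i == 1L) "lower" else
      if (length(lps) == 2L) "upper" else "fold"
  }
  lps
}

# bisection on det(G) between branch points (i-1, i+1), re-correcting onto
# the branch at each midpoint
#' @noRd
refine_fold <- function(branch, i) {
  ms <- branch$ms
  sm <- ms$summary
  pts <- branch$points
  m <- sm$m; delta <- sm$delta
  get_x <- function(j) unname(pts[j, 2:(1 + m + delta)])
  get_det <- function(j) pts[j, "det"]
  ia <- max(i - 1L, 1L); ib <- min(i + 1L, nrow(pts))
  da <- get_det(ia); db <- get_det(ib)
  if (da * db > 0) {  # widen until the determinant brackets zero
    ia <- max(i - 2L, 1L); ib <- min(i + 2L, nrow(pts))
    da <- get_det(ia); db <- get_det(ib)
    if (da * db > 0) return(NULL)
  }
  xa <- c(get_x(ia), pts[ia, "stimulus"])
  xb <- c(get_x(ib), pts[ib, "stimulus"])
  eval_mid <- function(xm_pred, normal) {
    correct_onto_branch(branch, xm_pred, normal)
  }
  for (iter in 1:60) {
    normal <- (xb - xa)
    nn <- sqrt(sum(normal^2)); if (nn == 0) break
    normal <- normal / nn
    xm <- eval_mid((xa + xb) / 2, normal)
    if (is.null(xm)) break
    dm <- xm$det
    if (abs(dm) < 1e-12 || nn < 1e-12) { xa <- c(xm$x); da <- dm; break }
    if (da * dm <= 0) { xb <- xm$x; db <- dm } else { xa <- xm$x; da <- dm }
  }
  x_fin <- xa
  pt <- structure(list(conc = stats::setNames(x_fin[1:m], sm$network$species),
                       alpha = if (delta) x_fin[m + seq_len(delta)] else numeric(0),
                       k = branch_k_at(branch, x_fin[m + delta + 1L]),
                       converged = TRUE),
                  class = "equilibrium_point")
  tr <- tangency_matrix(ms, pt, check = FALSE)
  structure(list(stimulus = unname(x_fin[m + delta + 1L]), conc = pt$conc,
                 alpha = unname(pt$alpha), det = tr$det, side = "fold"),
            class = "limit_point")
}

#' @noRd
branch_k_at <- function(branch, theta) {
  kk <- branch$k
  if (branch$stimulus$kind == "rate") {
    i <- match(branch$stimulus$label, branch$ms$summary$network$reactions$label)
    kk[i] <- theta
  }
  kk
}

# Newton-correct a predicted state onto the branch within the hyperplane
# through the prediction with the given normal; returns the corrected state
# and det(G) there.
#' @noRd
correct_onto_branch <- function(branch, x_pred, normal) {
  ms <- branch$ms
  sm <- ms$summary
  net <- sm$network
  m <- sm$m; delta <- sm$delta
  is_rate <- branch$stimulus$kind == "rate"
  i_st <- if (!is_rate) branch$stimulus$index else NA
  xx <- x_pred
  for (it in 1:30) {
    if (any(xx[1:m] <= 0)) return(NULL)
    th <- xx[m + delta + 1L]
    kk <- branch_k_at(branch, th)
    bb <- branch$b_fixed
    if (!is_rate) bb[i_st] <- th
    al <- if (delta) xx[m + seq_len(delta)] else numeric(0)
    Fv <- c(manifold_residual(ms, xx[1:m], al, kk),
            drop(t(sm$B) %*% xx[1:m]) - bb,
            sum(normal * (xx - x_pred)))
    if (max(abs(Fv)) < 1e-11 * max(1, res_scale(ms, xx[1:m], kk))) break
    J <- manifold_jacobians(ms, xx[1:m], al, kk)
    psi <- mass_action_monomials(net, xx[1:m])
    dH_dth <- if (is_rate) {
      i_rxn <- match(branch$stimulus$label, net$reactions$label)
      drop(ms$U %*% ms$incidence[, i_rxn]) * psi[net$reactions$from[i_rxn]]
    } else rep(0, nrow(ms$U))
    db_dth <- rep(0, ncol(sm$B))
    if (!is_rate) db_dth[i_st] <- -1
    Jx <- rbind(cbind(J$D_c, J$D_alpha, dH_dth),
                cbind(t(sm$B), matrix(0, ncol(sm$B), delta), db_dth),
                normal)
    st <- tryCatch(solve(Jx, -Fv), error = function(e) NULL)
    if (is.null(st) || any(!is.finite(st))) return(NULL)
    lam <- 1
    repeat {
      if (all((xx + lam * st)[1:m] > 0)) break
      lam <- lam / 2
      if (lam < 1e-8) return(NULL)
    }
    xx <- xx + lam * st
  }
  th <- xx[m + delta + 1L]
  pt <- structure(list(conc = xx[1:m],
                       alpha = if (delta) xx[m + seq_len(delta)] else numeric(0),
                       k = branch_k_at(branch, th), converged = TRUE),
                  class = "equilibrium_point")
  list(x = xx, det = tangency_matrix(ms, pt, check = FALSE)$det)
}

#' Synthesize a forward or backward dose-response curve
#'
#' For a branch with two limit points the stable outer segments are combined
#' with the hysteretic jump: increasing the stimulus (forward) the response
#' follows the first outer segment and jumps at the upper limit point;
#' decreasing it (backward) the response follows the other outer segment and
#' jumps at the lower limit point.  With no fold the branch itself is
#' returned for both directions.
#'
#' @param branch an `equilibrium_branch`.
#' @param observable numeric vector of length m (a row of the observable map
#'   Q), or a species name.
#' @param direction `"forward"` or `"backward"`.
#' @return data frame with columns `stimulus`, `response` and `segment`;
#'   attribute `jump_at` holds the jump stimulus (or `NA`).
#' @export
dose_response <- function(branch, observable, direction = c("forward", "backward")) {
  direction <- match.arg(direction)
  sm <- branch$ms$summary
  if (is.character(observable)) {
    qv <- as.numeric(sm$network$species == observable)
  } else qv <- observable
  pts <- branch$points
  conc <- pts[, 1 + seq_len(sm$m), drop = FALSE]
  resp <- drop(conc %*% qv)
  th <- pts[, "stimulus"]
  lps <- detect_limit_points(branch)
  if (length(lps) == 0L) {
    out <- data.frame(stimulus = th, response = resp, segment = 1L)
    attr(out, "jump_at") <- NA_real_
    return(out)
  }
  if (length(lps) != 2L) stop("branches with more than two limit points are not supported")
  th_l <- lps[[1]]$stimulus; th_u <- lps[[2]]$stimulus
  dth <- diff(th)
  rev_idx <- which(dth[-1] * dth[-length(dth)] < 0) + 1L
  seg <- cut(seq_along(th), breaks = c(0, rev_idx, length(th)), labels = FALSE)
  first <- seg == 1L
  last <- seg == max(seg)
  if (direction == "forward") {
    keep1 <- first & th <= th_u
    keep2 <- last & th >= th_u
    out <- data.frame(stimulus = c(th[keep1], th[keep2]),
                      response = c(resp[keep1], resp[keep2]),
                      segment = rep(1:2, c(sum(keep1), sum(keep2))))
    attr(out, "jump_at") <- th_u
  } else {
    keep1 <- last & th >= th_l
    keep2 <- first & th <= th_l
    out <- data.frame(stimulus = c(rev(th[keep1]), rev(th[keep2])),
                      response = c(rev(resp[keep1]), rev(resp[keep2])),
                      segment = rep(1:2, c(sum(keep1), sum(keep2))))
    attr(out, "jump_at") <- th_l
  }
  out
}
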