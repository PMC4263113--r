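#' Normalized constraint-satisfaction cost of a decision vector
#'
#' The error-free constraints are folded into one scalar: the squared
#' equilibrated tangency determinants at the two candidate points plus the
#' squared observation residuals scaled by the observed values.  Viability
#' thresholds refer to this cost.
#'
#' @param problem an [inverse_problem()].
#' @param p decision vector.
#' @export
viability_cost <- function(problem, p) {
  ev <- eval_decision(problem, p)
  if (!ev$ok) return(ev$penalty)
  bt <- b_targets(problem)
  sig_q <- pmax(abs(problem$obs$q), 1e-6)
  sig_b <- pmax(abs(bt), 1e-6)
  ev$l$det^2 + ev$u$det^2 +
    sum((ev$l$q_res / sig_q[1, ])^2) + sum((ev$u$q_res / sig_q[2, ])^2) +
    sum((ev$l$b_res / sig_b[1, ])^2) + sum((ev$u$b_res / sig_b[2, ])^2)
}

#' Find an initial viable point
#'
#' Runs the error-free solve with the determinant objective \eqn{J_1},
#' providing the seed required by [explore_viable_region()].
#'
#' @param problem an [inverse_problem()].
#' @param ... passed to [solve_error_free()].
#' @export
find_initial_viable_point <- function(problem, ...) {
  solve_error_free(problem, objective = "J1", ...)
}

#' Explore the viable region by adaptive sampling
#'
#' Characterizes the subsets of the decision space whose cost (see
#' [viability_cost()]) stays below a decreasing ladder of thresholds, using
#' a two-phase sampler: a local random walk with adaptively scaled
#' proposals around the current point, interleaved with global Metropolis
#' jumps that restart the walk from a random earlier acceptance (so poorly
#' connected viable pockets remain reachable).  Acceptance is a flat test
#' `cost < threshold`, giving approximately uniform coverage of each
#' sublevel set; a pairwise-distance statistic against a uniform box sample
#' is reported as a uniformity diagnostic.
#'
#' @param problem an [inverse_problem()].
#' @param seed_point a `bif_estimate` (or bare decision vector) viable at
#'   the loosest threshold.
#' @param thresholds decreasing cost ladder.
#' @param n_target accepted samples wanted per threshold.
#' @param rng_seed seed.
#' @param max_proposals proposal budget per threshold; aborts when the
#'   acceptance rate stays below 0.1% over the budget.
#' @param cost_fn optional replacement cost function of the decision vector
#'   (defaults to [viability_cost()] on `problem`); used mainly to verify
#'   the sampler against analytically known viable sets.
#' @return object of class `viable_sample_set`: per threshold a matrix of
#'   accepted decision vectors, acceptance statistics and the uniformity
#'   diagnostic.
#' @export
explore_viable_region <- function(problem, seed_point,
                                  thresholds = c(1e-2, 1e-4, 1e-6),
                                  n_target = 200, rng_seed = 1L,
                                  max_proposals = 1e5, cost_fn = NULL) {
  p0 <- if (inherits(seed_point, "bif_estimate")) unname(seed_point$p) else
    as.numeric(seed_point)
  cost_fn <- cost_fn %||% function(p) viability_cost(problem, p)
  thresholds <- sort(thresholds, decreasing = TRUE)
  c0 <- cost_fn(p0)
  if (!(c0 < thresholds[1])) {
    stop(sprintf("seed point is not viable at the loosest threshold (cost %g)", c0))
  }
  d <- length(p0)
  sets <- list()
  stats_out <- list()
  cur <- p0
  for (th in thresholds) {
    if (!(cost_fn(cur) < th)) cur <- p0
    if (!(cost_fn(cur) < th)) {
      stats_out[[as.character(th)]] <- list(skipped = TRUE)
      break
    }
    acc <- with_seed(derive_seed(rng_seed, paste0("vr", th)), {
      sample_sublevel(problem, cur, th, n_target, d, max_proposals, cost_fn)
    })
    sets[[as.character(th)]] <- acc$samples
    stats_out[[as.character(th)]] <- acc$stats
    if (nrow(acc$samples)) cur <- acc$samples[nrow(acc$samples), ]
  }
  structure(list(samples = sets, stats = stats_out, thresholds = thresholds,
                 problem = problem, rng_seed = rng_seed),
            class = "viable_sample_set")
}

#' @noRd
sample_sublevel <- function(problem, p_start, th, n_target, d, max_proposals,
                            cost_fn) {
  step <- rep(0.05, d)
  kept <- matrix(p_start, nrow = 1)
  cur <- p_start
  n_prop <- 0L; n_acc <- 0L
  emp_cov <- NULL
  while (nrow(kept) < n_target + 1 && n_prop < max_proposals) {
    n_prop <- n_prop + 1L
    global <- nrow(kept) > 10 && stats::runif(1) < 0.10
    if (global) {
      base <- kept[sample.int(nrow(kept), 1), ]
    } else base <- cur
    if (!is.null(emp_cov) && stats::runif(1) < 0.5) {
      prop <- drop(base + MASS::mvrnorm(1, rep(0, d), emp_cov))
    } else {
      prop <- base + stats::rnorm(d) * step
    }
    if (cost_fn(prop) < th) {
      n_acc <- n_acc + 1L
      kept <- rbind(kept, prop)
      cur <- prop
      step <- step * 1.05
      if (nrow(kept) %% 50 == 0 && nrow(kept) > d + 2) {
        emp_cov <- 2.4^2 / d * stats::cov(kept) +
          diag(1e-8, d)
      }
    } else {
      step <- step * 0.985
    }
    if (n_prop >= 1e5 && n_acc / n_prop < 1e-3) {
      stop(sprintf("viable-region exploration aborted: acceptance %.2e over %d proposals",
                   n_acc / n_prop, n_prop))
    }
  }
  samples <- kept[-1, , drop = FALSE]
  colnames(samples) <- if (!is.null(problem$p_names) &&
                           length(problem$p_names) == d) problem$p_names else
    paste0("p", seq_len(d))
  # uniformity diagnostic: mean pairwise distance relative to a uniform draw
  # over the samples' bounding box
  diag_ratio <- NA_real_
  if (nrow(samples) > 10) {
    sub <- samples[sample.int(nrow(samples), min(200, nrow(samples))), ]
    dp <- stats::dist(sub)
    lo <- apply(sub, 2, min); hi <- apply(sub, 2, max)
    unif <- matrix(stats::runif(length(sub), lo, hi), nrow(sub), ncol(sub),
                   byrow = TRUE)
    diag_ratio <- mean(dp) / mean(stats::dist(unif))
  }
  list(samples = samples,
       stats = list(proposals = n_prop, accepted = n_acc,
                    acceptance = n_acc / max(n_prop, 1),
                    uniformity = diag_ratio))
}

#' Viable ranges of parameter combinations
#'
#' Per-combination min/max over the accepted samples at the tightest
#' threshold reached (ranges are nested across the ladder by construction:
#' a tighter sublevel set is contained in a looser one).
#'
#' @param samples a `viable_sample_set` (or bare sample matrix).
#' @param combinations list of combination specs: each a list with `name`
#'   and either `k_exponents` (named integer vector over rate labels; the
#'   combination is the monomial \eqn{\prod k^e}) or `alpha = list(point,
#'   index)`.
#' @param threshold which threshold's samples to use (default: tightest
#'   with any samples).
#' @return data frame with `name`, `lower`, `upper`.
#' @export
viable_ranges <- function(samples, combinations, threshold = NULL) {
  if (inherits(samples, "viable_sample_set")) {
    sets <- samples$samples
    have <- names(sets)[vapply(sets, nrow, 0L) > 0]
    key <- threshold %||% have[length(have)]
    mat <- sets[[as.character(key)]]
    problem <- samples$problem
  } else {
    mat <- samples
    problem <- attr(samples, "problem")
  }
  if (is.null(mat) || nrow(mat) == 0L) stop("no viable samples")
  vals <- vapply(combinations, function(combo) {
    v <- combination_values_matrix(combo, mat, problem)
    range(v)
  }, c(0, 0))
  data.frame(name = vapply(combinations, `[[`, "", "name"),
             lower = vals[1, ], upper = vals[2, ])
}

#' @noRd
combination_values_matrix <- function(combo, mat, problem) {
  if (!is.null(combo$alpha)) {
    col <- sprintf("alpha_%s%d", combo$alpha$point, combo$alpha$index)
    return(mat[, col])
  }
  ex <- combo$k_exponents
  out <- rep(0, nrow(mat))
  for (lab in names(ex)) {
    if (lab %in% names(problem$fixed_k)) {
      out <- out + ex[[lab]] * log10(problem$fixed_k[[lab]])
    } else {
      out <- out + ex[[lab]] * mat[, paste0("log10_", lab)]
    }
  }
  10^out
}

#' Propose identifiable parameter combinations from viable samples
#'
#' Principal-component analysis of the accepted samples (free rate
#' constants in log10, deficiency parameters linear): directions whose
#' variance falls below a relative threshold are constrained by the data
#' and hence locally identifiable.  Loadings within 0.05 of a sparse
#' integer pattern are snapped to exponent vectors (e.g. a log-ratio
#' k_a/k_b); others are reported as raw directions.  The procedure is a
#' local, heuristic screen, and is flagged as such in the output.
#'
#' @param samples a `viable_sample_set` or sample matrix (>= 100 rows).
#' @param rel_var_tol relative variance threshold (default 0.01 of total).
#' @param threshold ladder threshold to use (default tightest).
#' @return list of combination specs (as in [viable_ranges()]) with
#'   `loading`, `interval`, `snapped`; attribute `heuristic = TRUE`.
#' @export
propose_identifiable_combinations <- function(samples, rel_var_tol = 0.01,
                                              threshold = NULL) {
  if (inherits(samples, "viable_sample_set")) {
    sets <- samples$samples
    have <- names(sets)[vapply(sets, nrow, 0L) > 0]
    key <- threshold %||% have[length(have)]
    mat <- sets[[as.character(key)]]
  } else mat <- samples
  if (is.null(mat) || nrow(mat) < 100L) {
    stop("need at least 100 viable samples for the identifiability screen")
  }
  pc <- stats::prcomp(mat, center = TRUE, scale. = FALSE)
  tot <- sum(pc$sdev^2)
  small <- which(pc$sdev^2 < rel_var_tol * tot)
  out <- list()
  for (j in small) {
    v <- pc$rotation[, j]
    nz <- abs(v) > 0.1 * max(abs(v))
    w <- v / min(abs(v[nz]))
    snapped <- all(abs(w[nz] - round(w[nz])) < 0.05 * pmax(1, abs(round(w[nz])))) &&
      all(abs(w[!nz]) < 0.05)
    expv <- if (snapped) {
      e <- round(w); e[!nz] <- 0
      if (e[which(e != 0)[1]] < 0) e <- -e
      stats::setNames(e, colnames(mat))
    } else NULL
    proj <- drop(scale(mat, center = FALSE, scale = FALSE) %*%
                   (if (snapped) {
                     ee <- expv / sqrt(sum(expv^2)); ee
                   } else v))
    out[[length(out) + 1L]] <- list(
      name = paste0("rho", length(out) + 1L),
      loading = v, snapped = snapped,
      exponents = expv,
      interval = range(proj),
      variance_fraction = pc$sdev[j]^2 / tot)
  }
  attr(out, "heuristic") <- TRUE
  out
}
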