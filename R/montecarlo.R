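#' Fit observation distributions to replicate measurements
#'
#' For each bifurcation point a multivariate normal distribution is fitted
#' by maximum likelihood to the replicate table (mean vector and ML
#' covariance across the observables measured there).  With `per_pair =
#' TRUE` the covariance is reduced to the pairing structure of the
#' experiment -- each concentration observable is measured jointly with the
#' stimulus, so stimulus--observable covariances are kept and
#' observable--observable covariances are zeroed (the default mirrors how
#' dose-response replicates are actually acquired); `per_pair = FALSE`
#' keeps the full joint covariance.
#'
#' @param table a `replicate_table` from [generate_noisy_data()] (columns
#'   `point`, `observable`, `replicate`, `value`).
#' @param per_pair reduce covariance to stimulus--observable pairs.
#' @param ridge relative ridge added when the ML covariance is singular.
#' @return list of class `observation_distribution`: per point (`l`, `u`)
#'   a list with `mean`, `cov`, `n`; attribute `degenerate` flags zero
#'   covariance.
#' @export
fit_observation_distribution <- function(table, per_pair = TRUE,
                                         ridge = 1e-10) {
  out <- list()
  degenerate <- FALSE
  for (point in c("l", "u")) {
    tb <- table[table$point == point, c("replicate", "observable", "value")]
    if (nrow(tb) == 0L) next
    wide <- stats::reshape(as.data.frame(tb), idvar = "replicate",
                           timevar = "observable", direction = "wide")
    X <- as.matrix(wide[, -1, drop = FALSE])
    colnames(X) <- sub("^value\\.", "", colnames(X))
    if (nrow(X) < 3L) stop("need at least 3 replicates per point")
    mu <- colMeans(X)
    S <- stats::cov(X) * (nrow(X) - 1) / nrow(X)   # ML covariance
    if (per_pair && "stimulus" %in% colnames(X)) {
      keep <- outer(colnames(X) == "stimulus", colnames(X) == "stimulus", "|")
      diag(keep) <- TRUE
      S[!keep] <- 0
    }
    if (all(abs(S) < 1e-300)) degenerate <- TRUE
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < ridge * max(abs(ev), 1e-12)) {
      warning("singular replicate covariance; ridge-regularized")
      S <- S + diag(ridge * max(diag(S), 1e-12), nrow(S))
    }
    out[[point]] <- list(mean = mu, cov = S, n = nrow(X))
  }
  structure(out, class = "observation_distribution", degenerate = degenerate)
}

#' Sample observation vectors from fitted distributions
#'
#' Draws `M` joint replicates of the bifurcation-point observables from the
#' fitted normals; draws containing a nonpositive concentration are
#' rejected and redrawn (the count is reported), failing if more than half
#' of all draws are rejected.
#'
#' @param dist an `observation_distribution`.
#' @param M number of samples.
#' @param rng_seed seed (fixed seed gives identical samples).
#' @return list with `samples` (list of M lists, each with per-point named
#'   vectors) and `rejected` (redraw count).
#' @export
sample_observations <- function(dist, M, rng_seed = 1L) {
  stopifnot(M >= 1)
  rejected <- 0L
  samples <- with_seed(rng_seed, {
    lapply(seq_len(M), function(i) {
      draw <- list()
      for (point in names(dist)) {
        d <- dist[[point]]
        for (tries in 1:200) {
          x <- drop(MASS::mvrnorm(1, d$mean, d$cov))
          if (all(x > 0)) break
          rejected <<- rejected + 1L
        }
        if (any(x <= 0)) stop("distribution-misfit: persistent nonpositive draws")
        draw[[point]] <- x
      }
      draw
    })
  })
  if (rejected > M * length(dist) / 2) {
    stop("distribution-misfit: more than half of the draws were rejected")
  }
  list(samples = samples, rejected = rejected)
}

# translate one sampled draw into the (q, b) layout used by solve_noisy
#' @noRd
draw_to_observations <- function(problem, draw) {
  obs <- problem$obs
  q <- obs$q
  bt <- b_targets(problem)
  for (i in 1:2) {
    point <- c("l", "u")[i]
    x <- draw[[point]]
    nm <- intersect(names(x), colnames(q))
    q[i, nm] <- x[nm]
    if ("stimulus" %in% names(x) && obs$stimulus$kind == "conservation") {
      bt[i, obs$stimulus$index] <- x[["stimulus"]]
    }
  }
  list(q = q, b = bt)
}

#' Monte Carlo uncertainty propagation to the parameter estimates
#'
#' Re-estimates the parameters for each sampled observation vector (problem
#' (w1 J1 + w2 J2) solved warm-started from the error-free estimate),
#' excludes failed fits, and summarizes the per-parameter sample
#' distributions with percentile confidence intervals and a correlation
#' matrix.
#'
#' @param problem an [inverse_problem()].
#' @param samples output of [sample_observations()] (or a bare list of
#'   draws).
#' @param warm_start a `bif_estimate` from [solve_error_free()].
#' @param combinations optional list of parameter combinations to track
#'   (see [viable_ranges()]); defaults to every free rate constant and the
#'   alpha components.
#' @param level confidence level (default 0.95).
#' @return object of class `mc_result`: `M`, `samples` (matrix of
#'   per-sample combination values), `ci` (2 x n matrix), `correlation`,
#'   `failed`, `estimates` (list of `bif_estimate`).
#' @export
estimate_distribution <- function(problem, samples, warm_start,
                                  combinations = NULL, level = 0.95) {
  draws <- samples$samples %||% samples
  combinations <- combinations %||% default_combinations(problem)
  ests <- vector("list", length(draws))
  vals <- matrix(NA_real_, length(draws), length(combinations),
                 dimnames = list(NULL, vapply(combinations, `[[`, "", "name")))
  failed <- 0L
  prev <- warm_start
  for (i in seq_along(draws)) {
    oo <- draw_to_observations(problem, draws[[i]])
    est <- solve_noisy(problem, oo, warm_start)
    if (!isTRUE(est$converged)) {
      # one retry from the previous successful sample's estimate
      est2 <- solve_noisy(problem, oo, prev)
      if (isTRUE(est2$converged)) est <- est2
    }
    ests[[i]] <- est
    if (isTRUE(est$converged)) {
      vals[i, ] <- vapply(combinations, combination_value, 0, est = est)
      prev <- est
    } else failed <- failed + 1L
  }
  keep <- stats::complete.cases(vals)
  vv <- vals[keep, , drop = FALSE]
  alp <- (1 - level) / 2
  ci <- apply(vv, 2, stats::quantile, probs = c(alp, 1 - alp), names = FALSE)
  rownames(ci) <- c("lower", "upper")
  corr <- if (nrow(vv) > 2) {
    sds <- apply(vv, 2, stats::sd)
    ok <- sds > 0
    cm <- diag(1, ncol(vv)); dimnames(cm) <- list(colnames(vv), colnames(vv))
    if (sum(ok) > 1) cm[ok, ok] <- stats::cor(vv[, ok, drop = FALSE])
    cm
  } else NULL
  structure(list(M = length(draws), samples = vv, ci = ci,
                 correlation = corr, failed = failed, level = level,
                 estimates = ests,
                 unreliable = failed > 0.2 * length(draws)),
            class = "mc_result")
}

#' @noRd
default_combinations <- function(problem) {
  combos <- lapply(problem$free_labels, function(lab) {
    list(name = lab, k_exponents = stats::setNames(1, lab))
  })
  da <- problem$d_alpha
  if (da) {
    for (point in c("l", "u")) for (j in seq_len(da)) {
      combos[[length(combos) + 1L]] <-
        list(name = sprintf("alpha_%s%d", point, j), alpha = list(point = point, index = j))
    }
  }
  combos
}

# value of a tracked combination at an estimate
#' @noRd
combination_value <- function(combo, est) {
  if (!is.null(combo$alpha)) {
    a <- if (combo$alpha$point == "l") est$alpha_l else est$alpha_u
    return(a[combo$alpha$index])
  }
  ex <- combo$k_exponents
  prod(est$k[names(ex)]^ex)
}

#' @export
print.mc_result <- function(x, ...) {
  cat(sprintf("Monte Carlo result: M = %d (%d failed fits)%s\n", x$M, x$failed,
              if (isTRUE(x$unreliable)) " [flagged unreliable]" else ""))
  cat(sprintf("%d%% percentile confidence intervals:\n", round(100 * x$level)))
  print(signif(t(x$ci), 5))
  invisible(x)
}
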