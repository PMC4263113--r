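# Seeded differential-evolution global optimizer (DE/rand/1/bin with bound
# reflection).  The inverse-bifurcation objectives are nonconvex and
# multimodal, so the box-constrained global phase is run with a
# population-based search before local refinement; the implementation is
# deliberately small and fully deterministic under a seed.

#' Differential-evolution global minimization
#'
#' @param fn objective, taking a numeric vector.
#' @param lower,upper box bounds.
#' @param seed integer seed (all randomness is local to the call).
#' @param np population size (default `10 * d`, capped at 60).
#' @param maxiter generations.
#' @param F,CR mutation and crossover rates.
#' @param init optional matrix of initial members (rows), recycled into the
#'   population after clipping to the bounds.
#' @param tol stop early when the population's best improves by less than
#'   `tol` over `patience` generations.
#' @param patience generations without improvement before stopping.
#' @return list with `par`, `value`, `population`, `values`, `iterations`.
#' @export
de_optimize <- function(fn, lower, upper, seed = 1, np = NULL, maxiter = 200,
                        F = 0.7, CR = 0.9, init = NULL, tol = 1e-12,
                        patience = 40) {
  d <- length(lower)
  stopifnot(length(upper) == d, all(upper > lower))
  np <- np %||% min(10 * d, 60)
  np <- max(np, 8)
  with_seed(seed, {
    pop <- matrix(stats::runif(np * d, lower, upper), np, d, byrow = TRUE)
    if (!is.null(init)) {
      init <- as.matrix(init)
      ni <- min(nrow(init), np)
      for (i in seq_len(ni)) {
        pop[i, ] <- pmin(pmax(init[i, ], lower), upper)
      }
    }
    vals <- apply(pop, 1, fn)
    best_i <- which.min(vals)
    best_v <- vals[best_i]
    stall <- 0L
    iter <- 0L
    for (g in seq_len(maxiter)) {
      iter <- g
      for (i in seq_len(np)) {
        idx <- sample.int(np, 3)
        while (any(idx == i)) idx <- sample.int(np, 3)
        trial <- pop[idx[1], ] + F * (pop[idx[2], ] - pop[idx[3], ])
        # reflect at bounds
        below <- trial < lower; trial[below] <- 2 * lower[below] - trial[below]
        above <- trial > upper; trial[above] <- 2 * upper[above] - trial[above]
        trial <- pmin(pmax(trial, lower), upper)
        cross <- stats::runif(d) < CR
        cross[sample.int(d, 1)] <- TRUE
        cand <- pop[i, ]
        cand[cross] <- trial[cross]
        v <- fn(cand)
        if (is.finite(v) && v <= vals[i]) {
          pop[i, ] <- cand
          vals[i] <- v
        }
      }
      new_best <- min(vals)
      if (best_v - new_best > tol * max(1, abs(best_v))) {
        stall <- 0L
      } else stall <- stall + 1L
      best_v <- new_best
      if (stall >= patience) break
    }
    best_i <- which.min(vals)
    list(par = pop[best_i, ], value = vals[best_i], population = pop,
         values = vals, iterations = iter)
  })
}
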