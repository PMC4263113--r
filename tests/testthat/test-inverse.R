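synthetic_case <- function() memo("synthetic_case", {
  fx <- synthetic_bistable_fixture(rng_seed = 3)
  problem <- fixture_problem(fx, seed = 5)
  base <- protein_fx()
  est <- polish_estimate(problem, initial_decision(problem, base$reference_k))
  list(fx = fx, problem = problem, est = est)
})

test_that("objective identities: J0/J1 nonnegative, J2 quadratic in the data", {
  sc <- synthetic_case()
  problem <- sc$problem
  p <- unname(sc$est$p)
  expect_gte(objective_J0(problem, p), 0)
  expect_gte(objective_J1(problem, p), 0)
  # at the solved estimate of exactly consistent data, J2 vanishes
  expect_lt(objective_J2(problem, p), 1e-12)
  # perturbing one observable by eps raises J2 by eps^2 (exactly, up to the
  # cross term with the ~1e-8 residual of the estimate itself)
  for (eps in c(0.01, 0.3)) {
    oo <- list(q = problem$obs$q, b = NULL)
    oo$q[1, 1] <- oo$q[1, 1] + eps
    expect_equal(objective_J2(problem, p, oo), objective_J2(problem, p) + eps^2,
                 tolerance = 1e-4)
  }
  # duplicated deficiency coordinates double the single-point tangency cost
  nf <- problem$n_free
  p_dup <- p; p_dup[nf + 2] <- p_dup[nf + 1]
  ev_sym <- objective_J1(problem, p_dup)
  p_half <- p_dup
  one <- local({
    ev <- invbif:::eval_decision(problem, p_half)
    ev$l$det^2
  })
  expect_equal(ev_sym, 2 * one, tolerance = 1e-6)
  # random infeasible decision vectors score positive
  set.seed(11)
  vals <- replicate(5, objective_J1(problem, p + stats::rnorm(length(p), 0, 0.3)))
  expect_true(all(vals > 0))
})

test_that("identifiable combinations are recovered to <1% from noise-free data", {
  sc <- synthetic_case()
  truth <- sc$fx$truth_k
  est <- sc$est
  expect_true(est$converged)
  expect_lt(est$feasibility, 1e-7)
  expect_lt(est$J1, 1e-10)
  for (lab in c("k5_7", "k7_3", "k1_8", "k4_1")) {
    expect_lt(abs(est$k[[lab]] / truth[[lab]] - 1), 0.01)
  }
  expect_lt(abs((est$k[["k2_6"]] / est$k[["k6_2"]]) /
                  (truth[["k2_6"]] / truth[["k6_2"]]) - 1), 0.01)
})

test_that("estimates are self-consistent: continuation reproduces the folds", {
  sc <- synthetic_case()
  lps <- estimate_limit_points(sc$fx, sc$est)
  expect_length(lps, 2)
  found <- sort(vapply(lps, function(l) l$stimulus, 0))
  target <- sc$fx$observations$stimulus$values
  expect_lt(max(abs(found - target) / target), 1e-3)
})

test_that("zero-noise samples collapse onto the error-free estimate", {
  sc <- synthetic_case()
  oo <- list(q = sc$problem$obs$q, b = NULL)
  est2 <- solve_noisy(sc$problem, oo, sc$est)
  expect_true(est2$converged)
  expect_lt(max(abs(unname(est2$p) - unname(sc$est$p))), 1e-4)
  # optimality: the refit cannot be worse than the start on its own data
  expect_lte(est2$J2, sc$est$J2 + 1e-10)
})

test_that("decision-vector layout matches r_free + 2 lambda", {
  pr <- fixture_problem(protein_fx())
  expect_length(pr$p_names, 6 + 2 * 1)
  pt <- fixture_problem(toggle_fx())
  # 8 free rates (k1_8 fixed, k7_13 is the stimulus) + 2 * delta alphas
  expect_length(pt$p_names, 8 + 2 * 2)
})

test_that("lambda > delta networks demand pinned concentrations", {
  net <- ab_network()  # delta 0, lambda 1
  obs <- observation_set(
    stimulus = list(kind = "conservation", index = 1, values = c(1, 2)),
    Q = matrix(c(0, 1), 1, 2, dimnames = list("B", c("A", "B"))),
    q = rbind(l = 0.5, u = 1.2))
  expect_error(inverse_problem(manifold_system(net), obs), "pin")
  pr <- inverse_problem(manifold_system(net), obs, pin_species = "A")
  expect_true(any(grepl("pin_l_A", pr$p_names)))
})
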