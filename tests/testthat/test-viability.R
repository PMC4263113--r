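# the sampler can be verified against an analytically known viable set by
# swapping in a synthetic cost whose sublevel set is a box
box_cost <- function(p) sum(pmax(abs(p) - 1, 0)^2)

test_that("the explorer covers an analytically known viable box", {
  vs <- explore_viable_region(problem = NULL, seed_point = rep(0, 3),
                              thresholds = 1e-4, n_target = 600,
                              rng_seed = 2, cost_fn = box_cost)
  mat <- vs$samples[[1]]
  expect_gte(nrow(mat), 600)
  # componentwise coverage of [-1, 1]^3: at least 95% of each side
  lo <- apply(mat, 2, min); hi <- apply(mat, 2, max)
  expect_true(all(hi - lo > 1.9))
  # volume via the bounding box of samples against the true box
  expect_gte(prod(pmin(hi, 1) - pmax(lo, -1)) / 8, 0.95)
  expect_false(is.na(vs$stats[[1]]$uniformity))
})

test_that("tightening the threshold never widens a viable range", {
  # cost with nested sublevel sets: ellipsoidal in 2-D
  cost <- function(p) p[1]^2 + 4 * p[2]^2
  vs <- explore_viable_region(problem = NULL, seed_point = c(0, 0),
                              thresholds = c(1, 0.1), n_target = 400,
                              rng_seed = 4, cost_fn = cost)
  loose <- vs$samples[["1"]]
  tight <- vs$samples[["0.1"]]
  for (j in 1:2) {
    expect_gte(min(tight[, j]), min(loose[, j]))
    expect_lte(max(tight[, j]), max(loose[, j]))
  }
})

test_that("infeasible seeds are refused", {
  expect_error(
    explore_viable_region(problem = NULL, seed_point = c(5, 5),
                          thresholds = 1e-2, cost_fn = box_cost),
    "not viable")
})

test_that("identifiability screen recovers a constrained ratio", {
  set.seed(9)
  n <- 400
  # only log(k1) - log(k2) is pinned; the sum is free
  s <- stats::runif(n, -2, 2)
  dratio <- stats::rnorm(n, 0, 0.005)
  mat <- cbind(log10_k1 = (s + dratio) / 2, log10_k2 = (s - dratio) / 2)
  combos <- propose_identifiable_combinations(mat)
  expect_length(combos, 1)
  expect_true(combos[[1]]$snapped)
  ex <- combos[[1]]$exponents
  expect_equal(unname(ex[order(names(ex))]), c(1, -1) * sign(ex[["log10_k1"]]))

  # isotropic samples expose no constrained direction
  iso <- matrix(stats::rnorm(2 * n), ncol = 2,
                dimnames = list(NULL, c("log10_k1", "log10_k2")))
  expect_length(propose_identifiable_combinations(iso), 0)
  # degenerate single sample: zero-width ranges
  one <- mat[1, , drop = FALSE]
  attr(one, "problem") <- list(fixed_k = numeric(0))
  rng <- viable_ranges(one, list(list(name = "k1", k_exponents = c(k1 = 1))))
  expect_equal(rng$lower, rng$upper)
})

test_that("viable exploration around the protein estimate stays tangency-true", {
  est <- protein_ef()
  problem <- fixture_problem(protein_fx(), seed = 7)
  c0 <- viability_cost(problem, unname(est$p))
  th <- max(10 * c0, 1e-3)
  vs <- explore_viable_region(problem, est, thresholds = th,
                              n_target = 120, rng_seed = 6)
  mat <- vs$samples[[1]]
  expect_gte(nrow(mat), 120)
  # every stored sample re-verifies its cost below the threshold from scratch
  problem2 <- fixture_problem(protein_fx(), seed = 99)
  recheck <- apply(mat[seq(1, nrow(mat), length.out = 20), ], 1,
                   function(p) viability_cost(problem2, p))
  expect_true(all(recheck < th))
  combos <- list(
    list(name = "k5_7", k_exponents = c(k5_7 = 1)),
    list(name = "k3_7/k7_3", k_exponents = c(k3_7 = 1, k7_3 = -1)))
  rng <- viable_ranges(vs, combos)
  # the degradation/formation structure pins both combinations tightly
  expect_lt(rng$upper[1] / rng$lower[1], 1.5)
  expect_true(rng$lower[2] < 1 / 15 && 1 / 15 < rng$upper[2])
})
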