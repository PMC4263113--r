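test_that("shipped reference parameters reproduce the noise-free limit points", {
  fx <- protein_fx()
  lps <- estimate_limit_points(fx, fx$reference_k)
  expect_length(lps, 2)
  found <- sort(vapply(lps, function(l) l$stimulus, 0))
  expect_equal(found, fx$observations$stimulus$values, tolerance = 1e-3)

  fy <- toggle_fx()
  lps_y <- estimate_limit_points(fy, fy$reference_k)
  expect_length(lps_y, 2)
  found_y <- sort(vapply(lps_y, function(l) l$stimulus, 0))
  expect_equal(found_y, fy$observations$stimulus$values, tolerance = 5e-3)
})

test_that("fixture rate labels and observables match the documented structure", {
  fx <- protein_fx()
  expect_setequal(names(fx$reference_k),
                  c("k1_4", "k4_1", "k1_8", "k2_6", "k6_2", "k3_7", "k7_3", "k5_7"))
  expect_equal(rownames(fx$Q), c("S", "ESS", "P"))
  expect_equal(fx$fixed_k, c(k1_4 = 1, k3_7 = 0.01))
  fy <- toggle_fx()
  expect_equal(rownames(fy$Q), c("P1", "G2P1", "P2"))
  expect_equal(fy$fixed_k, c(k1_8 = 100))
  expect_equal(fy$observations$stimulus$label, "k7_13")
})

test_that("re-deriving reference parameters closes the loop on consistent data", {
  fx <- synthetic_bistable_fixture(rng_seed = 8)
  ref <- derive_reference_parameters(
    fx, budget = list(np = 20, maxiter = 30, restarts = 1), seed = 4)
  expect_length(ref$limit_points, 2)
  expect_lt(ref$max_rel_error, 1e-3)
})

test_that("the viability seeding solve returns a usable estimate object", {
  fx <- synthetic_bistable_fixture(rng_seed = 8)
  problem <- fixture_problem(fx, seed = 4)
  est <- find_initial_viable_point(
    problem, budget = list(np = 16, maxiter = 20, restarts = 0))
  expect_s3_class(est, "bif_estimate")
  expect_gte(est$J1, 0)
  expect_true(is.finite(viability_cost(problem, unname(est$p))))
})
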