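test_that("proportional noise generation has the nominal CV and is seeded", {
  fx <- protein_fx()
  tab <- generate_noisy_data(fx, noise_model(0.10), n_replicates = 1000,
                             rng_seed = 21)
  for (nm in c("S", "P")) {
    v <- tab$value[tab$observable == nm & tab$point == "l"]
    cv <- stats::sd(v) / mean(v)
    expect_gt(cv, 0.08); expect_lt(cv, 0.12)
    # sample mean within 3 standard errors of the noise-free value
    mu <- fx$observations$q["l", nm]
    expect_lt(abs(mean(v) - mu), 3 * stats::sd(v) / sqrt(length(v)))
  }
  tab2 <- generate_noisy_data(fx, noise_model(0.10), n_replicates = 1000,
                              rng_seed = 21)
  expect_identical(tab$value, tab2$value)
  # CV = 0 reproduces the noise-free values exactly
  tab0 <- generate_noisy_data(fx, noise_model(0), n_replicates = 3,
                              rng_seed = 1)
  expect_equal(unique(tab0$value[tab0$observable == "S" & tab0$point == "l"]),
               fx$observations$q["l", "S"])
})

test_that("distribution fitting recovers means and flags degeneracy", {
  fx <- protein_fx()
  tab <- generate_noisy_data(fx, noise_model(0.10), n_replicates = 500,
                             rng_seed = 22)
  dist <- fit_observation_distribution(tab)
  mu_hat <- dist$l$mean["S"]
  se <- sqrt(dist$l$cov["S", "S"] / dist$l$n)
  expect_lt(abs(mu_hat - fx$observations$q["l", "S"]), 3 * se)
  # identical replicates give a degenerate (zero-covariance) fit
  tab0 <- generate_noisy_data(fx, noise_model(0), n_replicates = 4,
                              rng_seed = 1)
  w <- testthat::capture_warnings(d0 <- fit_observation_distribution(tab0))
  expect_true(all(grepl("singular", w)) && length(w) >= 1)
  expect_true(attr(d0, "degenerate"))
  ss0 <- sample_observations(d0, 5, rng_seed = 3)
  vals <- vapply(ss0$samples, function(s) s$l[["S"]], 0)
  expect_lt(stats::sd(vals), 1e-6)
})

test_that("observation sampling is reproducible and respects positivity", {
  fx <- protein_fx()
  tab <- generate_noisy_data(fx, noise_model(0.10), n_replicates = 50,
                             rng_seed = 23)
  dist <- fit_observation_distribution(tab)
  s1 <- sample_observations(dist, 200, rng_seed = 7)
  s2 <- sample_observations(dist, 200, rng_seed = 7)
  expect_identical(s1$samples, s2$samples)
  all_vals <- unlist(s1$samples)
  expect_true(all(all_vals > 0))
  # empirical mean close to the fitted mean (3 SE at M = 200)
  sv <- vapply(s1$samples, function(s) s$l[["S"]], 0)
  se <- sqrt(dist$l$cov["S", "S"] / 200)
  expect_lt(abs(mean(sv) - dist$l$mean[["S"]]), 4 * se)
})

test_that("Monte Carlo re-estimation yields calibrated-looking intervals", {
  sc_fx <- synthetic_bistable_fixture(rng_seed = 3)
  problem <- fixture_problem(sc_fx, seed = 5)
  est <- polish_estimate(problem, initial_decision(problem,
                                                   protein_fx()$reference_k))
  expect_true(est$converged)
  tab <- generate_noisy_data(sc_fx, noise_model(0.10), n_replicates = 12,
                             rng_seed = 31)
  dist <- fit_observation_distribution(tab)
  ss <- sample_observations(dist, 24, rng_seed = 32)
  mc <- estimate_distribution(problem, ss, est)
  expect_lte(mc$failed, 0.2 * mc$M)
  expect_false(mc$unreliable)
  ci <- mc$ci
  expect_true(all(ci["lower", ] < ci["upper", ]))
  # correlation matrix: symmetric, unit diagonal, positive semidefinite
  cm <- mc$correlation
  expect_equal(cm, t(cm))
  expect_equal(unname(diag(cm)), rep(1, ncol(cm)))
  expect_gte(min(eigen(cm, symmetric = TRUE, only.values = TRUE)$values), -1e-8)

  # smaller measurement error gives narrower intervals
  tab5 <- generate_noisy_data(sc_fx, noise_model(0.05), n_replicates = 12,
                              rng_seed = 31)
  ss5 <- sample_observations(fit_observation_distribution(tab5), 24,
                             rng_seed = 32)
  mc5 <- estimate_distribution(problem, ss5, est)
  w10 <- ci["upper", "k5_7"] - ci["lower", "k5_7"]
  w5 <- mc5$ci["upper", "k5_7"] - mc5$ci["lower", "k5_7"]
  expect_lt(w5, w10)
})
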