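test_that("deficiency-zero isomerization: manifold zeros are the balance line", {
  net <- ab_network()
  ms <- manifold_system(net)
  k <- c(k1_2 = 2, k2_1 = 3)
  # on the detailed-balance line k12 cA = k21 cB
  expect_lt(max(abs(manifold_residual(ms, c(3, 2), numeric(0), k))), 1e-12)
  expect_gt(max(abs(manifold_residual(ms, c(1, 2), numeric(0), k))), 0.1)
  # pinning c_A leaves the square 1x1 system: c_B = k12/k21 * c_A
  pt <- solve_manifold_point(ms, k, numeric(0), c(1, 5), pinned = c(A = 1))
  expect_true(pt$converged)
  expect_equal(unname(pt$conc[["B"]]), 2 / 3, tolerance = 1e-9)
})

test_that("ODE steady states lie on the manifold and vice versa", {
  fx <- protein_fx()
  ms <- fx$ms
  set.seed(2)
  for (i in 1:8) {
    k <- fx$reference_k * exp(stats::rnorm(8, 0, 0.1))
    k[c("k1_4", "k3_7")] <- fx$reference_k[c("k1_4", "k3_7")]
    c0 <- c(E = 0.01 * stats::runif(1, 0.5, 2), S = stats::runif(1, 0.5, 5),
            ES = 1e-4, ESS = 1e-4, P = stats::runif(1, 0.5, 5))
    ss <- relax_to_steady_state(fx$network, k, c0, tol = 1e-11)
    af <- alpha_from_state(ms, ss$conc, k)
    # the steady state maps to manifold coordinates with tiny residual
    expect_lt(max(abs(manifold_residual(ms, ss$conc, af$alpha, k))), 1e-8)
    expect_lt(max(abs(ode_rhs(fx$network, k, ss$conc))), 1e-8)
  }
  # a state off equilibrium is not explained by any alpha
  cc <- c(E = 0.01, S = 1, ES = 0.001, ESS = 0.001, P = 1)
  af <- alpha_from_state(ms, cc, fx$reference_k)
  expect_gt(af$residual, 1e-6)
})

test_that("manifold solve reports failure (not an error) from hopeless starts", {
  fx <- protein_fx()
  pt <- solve_manifold_point(fx$ms, fx$reference_k, alpha = 50,
                             c_guess = rep(1e-6, 5), max_iter = 15)
  expect_false(pt$converged)
})

test_that("analytic dc/dalpha matches central finite differences", {
  fx <- protein_fx()
  ms <- fx$ms
  al <- -0.1
  base <- solve_manifold_point(ms, fx$reference_k, al,
                               c(0.003, 3, 0.003, 0.005, 10))
  expect_true(base$converged)
  dd <- dc_dalpha(ms, base)
  h <- 1e-6
  up <- solve_manifold_point(ms, fx$reference_k, al + h, base$conc)
  dn <- solve_manifold_point(ms, fx$reference_k, al - h, base$conc)
  fd <- (up$conc - dn$conc) / (2 * h)
  expect_lt(max(abs(dd - fd)) / max(abs(fd)), 1e-5)
})

test_that("dc/dalpha is guarded for deficiency-zero networks", {
  ms <- manifold_system(ab_network())
  pt <- solve_manifold_point(ms, c(k1_2 = 2, k2_1 = 3), numeric(0), c(1, 1),
                             pinned = c(A = 1))
  expect_error(dc_dalpha(ms, pt), "deficiency-zero")
})

test_that("tangency matrix is square of size m + delta and detects folds", {
  fx <- protein_fx()
  ms <- fx$ms
  # deficiency zero: G for the isomerization never vanishes (fold-free)
  ms0 <- manifold_system(ab_network())
  for (k12 in c(0.5, 1, 2)) {
    pt0 <- solve_manifold_point(ms0, c(k1_2 = k12, k2_1 = 1), numeric(0),
                                c(1, k12), pinned = c(A = 1))
    tr0 <- tangency_matrix(ms0, pt0)
    expect_equal(tr0$size, 2L)
    expect_gt(abs(tr0$det), 0.1)
  }
  # protein fixture: |det| tiny at a continuation-detected fold, large away
  br <- memo("protein_branch", {
    trace_branch(ms, fx$reference_k, list(kind = "conservation", index = 1),
                 range = c(0.004, 0.015))
  })
  lps <- detect_limit_points(br)
  expect_length(lps, 2)
  for (lp in lps) expect_lt(abs(lp$det), 1e-6)
  mid <- solve_manifold_point(ms, fx$reference_k, -0.11,
                              c(0.003, 3, 0.003, 0.005, 10))
  trm <- tangency_matrix(ms, mid)
  expect_equal(trm$size, 6L)
  expect_gt(abs(trm$det), 1e-5)
})

test_that("polyhedron residual is B^T c - b", {
  fx <- protein_fx()
  sm <- fx$summary
  set.seed(3)
  cc <- exp(stats::rnorm(5))
  b <- drop(t(sm$B) %*% cc)
  expect_equal(polyhedron_residual(sm, cc, b), 0)
  expect_error(polyhedron_residual(sm, cc, c(1, 2)), "entries")
})
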