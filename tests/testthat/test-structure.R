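test_that("two-species isomerization has the textbook decomposition", {
  sm <- structural_summary(ab_network())
  expect_equal(sm$n, 2L)
  expect_equal(sm$ell, 1L)
  expect_equal(sm$t, 1L)
  expect_equal(sm$s, 1L)
  expect_equal(sm$delta, 0L)
  expect_equal(sm$lambda, 1L)
  # conservation of A + B (integerized basis, proportional to (1, 1))
  expect_equal(abs(sm$B[, 1] / max(abs(sm$B[, 1]))), c(A = 1, B = 1))
})

test_that("protein activation fixture has deficiency one and lambda one", {
  sm <- protein_fx()$summary
  expect_equal(sm$n, 8L)
  expect_equal(sm$ell, 3L)
  expect_equal(sm$t, 3L)
  expect_equal(sm$s, 4L)
  expect_equal(sm$delta, 1L)
  expect_equal(sm$lambda, 1L)
  expect_equal(sm$conservation_laws, "E + ES + ESS")
  # decision dimension r + 2 lambda = 10
  expect_equal(sm$r + 2 * sm$lambda, 10L)
  expect_setequal(sm$network$reactions$label,
                  c("k1_4", "k4_1", "k1_8", "k2_6", "k6_2", "k3_7", "k7_3", "k5_7"))
})

test_that("toggle switch fixture has deficiency two and two conservation laws", {
  sm <- toggle_fx()$summary
  expect_equal(sm$n, 13L)
  expect_equal(sm$ell, 6L)
  expect_equal(sm$t, 6L)
  expect_equal(sm$s, 5L)
  expect_equal(sm$delta, 2L)
  expect_equal(sm$lambda, 2L)
  expect_setequal(sm$conservation_laws,
                  c("G1 + G1P2", "G2 + G2P1 + G2P1P1"))
  expect_equal(sm$r + 2 * sm$lambda, 14L)
})

test_that("networks with t > l are refused", {
  # one linkage class, two terminal strong linkage classes: B <- A -> C
  net <- parse_network_text(c("A -> B ; k1", "A -> C ; k2"))
  expect_error(structural_summary(net), "t > ell|unsuited")
})

test_that("structural identities hold on random reversible networks", {
  for (seed in 1:30) {
    net <- random_reversible_network(seed)
    sm <- structural_summary(net)
    expect_identical(sm$t, sm$ell)
    expect_equal(sm$delta, sm$n - sm$ell - sm$s)
    expect_gte(sm$delta, 0L)
    if (sm$delta > 0) {
      expect_lt(max(abs(sm$Y %*% sm$omega)), 1e-9)
      expect_lt(max(abs(t(sm$Lambda) %*% sm$omega)), 1e-9)
    }
    if (ncol(sm$B) > 0) {
      expect_lt(max(abs(t(sm$B) %*% sm$N)), 1e-10)
    }
  }
})

test_that("ODE trajectories conserve B^T c and deficiency-zero relaxes uniquely", {
  net <- ab_network()
  sm <- structural_summary(net)
  out <- simulate_network(net, NULL, c(A = 2, B = 1), times = seq(0, 10, 1))
  bvals <- as.matrix(out[, -1]) %*% sm$B
  expect_lt(max(abs(bvals - bvals[1])) / abs(bvals[1]), 1e-6)
  # same compatibility class, different initial splits -> same steady state
  s1 <- relax_to_steady_state(net, NULL, c(A = 3, B = 0.001))$conc
  s2 <- relax_to_steady_state(net, NULL, c(A = 0.001, B = 3))$conc
  expect_lt(max(abs(s1 - s2)) / max(s1), 1e-6)
  # conservation on the protein fixture as well
  fx <- protein_fx()
  out2 <- simulate_network(fx$network, fx$reference_k,
                           c(E = 0.005, S = 2, ES = 0.001, ESS = 0.001, P = 2),
                           times = c(0, 50, 100))
  b2 <- as.matrix(out2[, -1]) %*% fx$summary$B
  expect_lt(max(abs(b2 - b2[1])) / abs(b2[1]), 1e-6)
})
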