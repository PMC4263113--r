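test_that("kinetics matrix matches its definition and spectral structure", {
  net <- ab_network()
  A <- kinetics_matrix(net, c(k1_2 = 2, k2_1 = 3))
  expect_equal(A, matrix(c(-2, 2, 3, -3), 2, 2))
  # column sums are exactly zero, i.e. ones is a left null vector
  expect_equal(colSums(A), c(0, 0))

  fx <- protein_fx()
  Ap <- kinetics_matrix(fx$network, fx$reference_k)
  expect_equal(colSums(Ap), rep(0, 8))
  # rank(A) = n - t
  d <- svd(Ap, nu = 0, nv = 0)$d
  expect_equal(sum(d > 1e-10 * d[1]), 8L - 3L)
})

test_that("mass-action monomials follow the molecularity exponents", {
  net <- parse_network_text(c("A + B -> C ; k1", "2 S -> A ; k2", "0 -> S ; k3"))
  ord <- vapply(seq_along(net$complexes), function(j) complex_label(net, j), "")
  cc <- stats::setNames(c(2, 3, 1, 3), net$species)  # A, B, C, S (order of appearance)
  psi <- mass_action_monomials(net, cc)
  expect_equal(unname(psi[match("A + B", ord)]), 6)
  expect_equal(unname(psi[match("2 S", ord)]), 9)
  expect_equal(unname(psi[match("0", ord)]), 1)
  expect_error(mass_action_monomials(net, c(2, 3, 0, 3)), "positive")
})

test_that("graph and stoichiometric formulations of the balance agree", {
  fx <- protein_fx()
  sm <- fx$summary
  set.seed(1)
  for (i in 1:10) {
    cc <- exp(stats::rnorm(5))
    lhs <- ode_rhs(fx$network, fx$reference_k, cc)
    v <- reaction_rates(fx$network, fx$reference_k, cc)
    rhs <- drop(sm$N %*% v)
    expect_lt(max(abs(lhs - rhs)) / max(abs(lhs), 1e-12), 1e-12)
    # conservation-law projection of the balance vanishes identically
    expect_lt(max(abs(t(sm$B) %*% lhs)), 1e-10 * max(abs(lhs), 1))
  }
})

test_that("detailed-balance states of the isomerization are equilibria", {
  net <- ab_network()
  rhs <- ode_rhs(net, c(k1_2 = 2, k2_1 = 3), c(A = 3, B = 2))  # 2*3 = 3*2
  expect_equal(rhs, c(A = 0, B = 0))
})
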