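test_that("text dialect parses reversible reactions and the zero complex", {
  net <- parse_network_text(c("A <-> B ; k1_2, k2_1"))
  expect_length(net$species, 2)
  expect_length(net$complexes, 2)
  expect_equal(nrow(net$reactions), 2)

  net0 <- parse_network_text(c("S -> 0 ; kd", "0 -> S ; kf"))
  zero <- which(vapply(net0$complexes, length, 0L) == 0L)
  expect_length(zero, 1)
  expect_equal(unname(mass_action_monomials(net0, c(S = 5))[zero]), 1)
})

test_that("JSON schema round-trips bit-identically and reconstructs the fixture", {
  path <- system.file("extdata", "protein_activation.json", package = "invbif")
  net <- parse_network(path)
  expect_length(net$species, 5)
  expect_length(net$complexes, 8)
  expect_equal(nrow(net$reactions), 8)
  txt <- write_network(net)
  net2 <- parse_network(txt)
  expect_identical(write_network(net2), txt)
  expect_identical(paste(readLines(path), collapse = "\n"), txt)
})

test_that("schema violations are rejected with informative errors", {
  expect_error(
    reaction_network(c("A"), list(c(A = 1), c(A = 1)),
                     data.frame(from = 1, to = 2, label = "k")),
    "duplicated complex")
  expect_error(
    reaction_network(c("A"), list(c(A = 1), c(B = 1)),
                     data.frame(from = 1, to = 2, label = "k")),
    "unknown species")
  expect_error(
    reaction_network(c("A", "B"), list(c(A = 1), c(B = 1)),
                     data.frame(from = 1, to = 2, label = "k"),
                     rate_values = c(k = -1)),
    "nonpositive|positive")
  expect_error(
    reaction_network(c("A", "B"), list(c(A = 1), c(B = 1)),
                     data.frame(from = 1, to = 1, label = "k")),
    "self-loop")
  expect_error(
    reaction_network(c("A", "B", "C"), list(c(A = 1), c(B = 1)),
                     data.frame(from = 1, to = 2, label = "k")),
    "no complex")
})

test_that("rate vectors require every label and strict positivity", {
  net <- parse_network_text("A <-> B ; k1_2, k2_1")
  expect_error(rate_vector(net), "unset rate value")
  kv <- rate_vector(net, c(k1_2 = 1, k2_1 = 2))
  expect_named(kv, c("k1_2", "k2_1"))
  expect_error(set_rates(net, c(k1_2 = 0)), "positive")
})
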