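test_that("monotone branch of the isomerization has no folds", {
  net <- ab_network()
  ms <- manifold_system(net)
  br <- trace_branch(ms, NULL, list(kind = "conservation", index = 1),
                     range = c(0.5, 3), c_seed = c(A = 0.3, B = 0.2))
  expect_gt(nrow(br$points), 10)
  expect_length(detect_limit_points(br), 0)
  fwd <- dose_response(br, "B", "forward")
  bwd <- dose_response(br, "B", "backward")
  expect_true(is.na(attr(fwd, "jump_at")))
  expect_equal(sort(fwd$response), sort(bwd$response))
})

test_that("protein branch is S-shaped with folds at the closed-form extrema", {
  fx <- protein_fx()
  k <- fx$reference_k
  br <- memo("protein_branch", {
    trace_branch(fx$ms, k, list(kind = "conservation", index = 1),
                 range = c(0.004, 0.015))
  })
  lps <- detect_limit_points(br)
  expect_length(lps, 2)
  found <- vapply(lps, function(l) l$stimulus, 0)

  # independent oracle: along the reduced steady-state family, S determines
  # every other concentration in closed form; the folds are the interior
  # extrema of E_T(S), located here by direct 1-D optimization
  k37 <- k[["k3_7"]]; k57 <- k[["k5_7"]]; k73 <- k[["k7_3"]]
  rho1 <- k[["k1_4"]] / k[["k4_1"]]; rho3 <- k[["k2_6"]] / k[["k6_2"]]
  k18 <- k[["k1_8"]]
  ET <- function(S) {
    P <- (k73 - k37 * S) / k57
    E <- k57 * P / (k18 * S)
    E * (1 + rho1 * S + rho1 * rho3 * S^2)
  }
  # E_T(S) diverges as S -> 0 and vanishes as P -> 0: the folds are the
  # interior local minimum (low-S side) and local maximum (high-S side)
  lo_fold <- stats::optimize(ET, c(0.2, 3), maximum = FALSE)
  hi_fold <- stats::optimize(ET, c(3, 12), maximum = TRUE)
  oracle <- sort(c(lo_fold$objective, hi_fold$objective))
  expect_equal(found, oracle, tolerance = 1e-6)

  # every recorded branch point re-verifies the steady-state equations
  m <- fx$summary$m
  for (i in seq(1, nrow(br$points), length.out = 25)) {
    row <- br$points[round(i), ]
    cc <- row[1 + seq_len(m)]
    expect_lt(max(abs(ode_rhs(fx$network, k, cc))), 1e-8)
  }
})

test_that("fold locations are stable under step halving", {
  fx <- protein_fx()
  br1 <- memo("protein_branch", {
    trace_branch(fx$ms, fx$reference_k, list(kind = "conservation", index = 1),
                 range = c(0.004, 0.015))
  })
  br2 <- trace_branch(fx$ms, fx$reference_k,
                      list(kind = "conservation", index = 1),
                      range = c(0.004, 0.015), n_min = 400)
  f1 <- sort(vapply(detect_limit_points(br1), function(l) l$stimulus, 0))
  f2 <- sort(vapply(detect_limit_points(br2), function(l) l$stimulus, 0))
  expect_equal(f1, f2, tolerance = 1e-6)
})

test_that("det(G) changes sign exactly once per fold along the branch", {
  fx <- protein_fx()
  br <- memo("protein_branch", {
    trace_branch(fx$ms, fx$reference_k, list(kind = "conservation", index = 1),
                 range = c(0.004, 0.015))
  })
  dets <- br$points[, "det"]
  sign_changes <- sum(diff(sign(dets)) != 0)
  expect_equal(sign_changes, length(detect_limit_points(br)))
})

test_that("rate-constant continuation of the toggle finds both folds", {
  fx <- toggle_fx()
  br <- memo("toggle_branch", {
    trace_branch(fx$ms, fx$reference_k, list(kind = "rate", label = "k7_13"),
                 range = c(0.3, 5), b_fixed = fx$b)
  })
  lps <- detect_limit_points(br)
  expect_length(lps, 2)
  folds <- sort(vapply(lps, function(l) l$stimulus, 0))
  expect_equal(folds, c(0.86, 2.96), tolerance = 5e-3)
  # branch points satisfy both the balance and the conservation constraints
  m <- fx$summary$m
  for (i in seq(1, nrow(br$points), length.out = 20)) {
    row <- br$points[round(i), ]
    cc <- row[1 + seq_len(m)]
    kk <- fx$reference_k
    kk["k7_13"] <- row[["stimulus"]]
    expect_lt(max(abs(ode_rhs(fx$network, kk, cc))), 1e-8)
    expect_lt(max(abs(drop(t(fx$summary$B) %*% cc) - fx$b)), 1e-9)
  }
})

test_that("hysteretic dose-response curves jump at the correct limit points", {
  fx <- protein_fx()
  br <- memo("protein_branch", {
    trace_branch(fx$ms, fx$reference_k, list(kind = "conservation", index = 1),
                 range = c(0.004, 0.015))
  })
  lps <- detect_limit_points(br)
  th_l <- lps[[1]]$stimulus; th_u <- lps[[2]]$stimulus
  expect_lt(th_l, th_u)
  fwd <- dose_response(br, "P", "forward")
  bwd <- dose_response(br, "P", "backward")
  expect_equal(attr(fwd, "jump_at"), th_u)
  expect_equal(attr(bwd, "jump_at"), th_l)
  # hysteresis width is the distance between the folds
  expect_equal(attr(fwd, "jump_at") - attr(bwd, "jump_at"), th_u - th_l)
  # the forward curve is single-valued: at most one point per stimulus side
  expect_lte(max(table(fwd$segment)), nrow(br$points))
})
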