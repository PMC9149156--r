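test_that("interior closed forms match the reference parameter set", {
  p <- fig4_params()
  st <- interior_of(p, "static")
  expect_equal(unname(st$point), c(0.5, 5 / 12))

  dp <- interior_of(p, "dynamic_penalty")
  expect_equal(unname(dp$point), c(1 / 3, 5 / 9))

  dr <- interior_of(p, "dynamic_reward")
  expect_equal(unname(dr$point), c(2 - sqrt(2), 10 / (12 + 6 * sqrt(2))))

  db <- interior_of(p, "dynamic_both")
  expect_equal(unname(db$point), c((7 - sqrt(17)) / 8, 10 / (3 + 3 * sqrt(17))))
})

test_that("every returned interior point zeroes the right-hand side", {
  set.seed(31)
  for (i in 1:40) {
    p <- draw_params()
    for (m in mechanisms()) {
      r <- interior_of(p, m)
      if (is.null(r)) next
      rhs <- replicator_rhs(r$point[["x"]], r$point[["y"]], p, m)
      expect_lt(max(abs(rhs)), 1e-10 * max(1, p$P, p$S, p$C + p$dL))
    }
  }
})

test_that("closed-form interior equilibria agree with the grid+Newton oracle", {
  set.seed(32)
  for (m in mechanisms()) {
    found <- 0
    while (found < 25) {
      p <- draw_params()
      r <- interior_of(p, m)
      if (is.null(r)) next
      o <- oracle_interior(p, m)
      expect_false(is.null(o))
      expect_equal(unname(r$point), o, tolerance = 1e-8)
      found <- found + 1
    }
  }
})

test_that("analytic Jacobians match finite differences of the printed systems", {
  set.seed(33)
  for (i in 1:25) {
    p <- draw_params()
    x <- runif(1); y <- runif(1)
    for (m in mechanisms()) {
      J <- jacobian_at(x, y, p, m)
      Jfd <- fd_jacobian(x, y, p, m)
      expect_lt(max(abs(J - Jfd)), 1e-6 * max(1, max(abs(J))))
    }
  }
})

test_that("static Jacobian has the published off-diagonal structure", {
  set.seed(34)
  for (i in 1:10) {
    p <- draw_params()
    x <- runif(1); y <- runif(1)
    J <- jacobian_at(x, y, p, "static")
    expect_equal(J[1, 2], x * (1 - x) * (p$S + p$P))
    expect_equal(J[2, 1], -y * (1 - y) * (p$S + p$P))
  }
})

test_that("dynamic-penalty Jacobian at the interior point matches the hand derivation", {
  J <- jacobian_at(1 / 3, 5 / 9, fig4_params(), "dynamic_penalty")
  expect_equal(J, matrix(c(-10 / 9, 2, -300 / 81, 0), 2, byrow = TRUE))
})

test_that("Jacobian at a corner is diagonal for every mechanism", {
  set.seed(35)
  p <- draw_params()
  for (m in mechanisms()) {
    J <- jacobian_at(0, 0, p, m)
    expect_equal(J[1, 2], 0)
    expect_equal(J[2, 1], 0)
  }
})

test_that("corner det J / tr J match the published formulas", {
  set.seed(36)
  for (i in 1:20) {
    p <- draw_params()
    S <- p$S; P <- p$P; I <- p$I; CD <- p$C + p$dL

    eq_static <- enumerate_equilibria(p, "static")
    want_static <- list(
      `0,0` = c((-CD) * (P - I), -CD + P - I),
      `1,0` = c(CD * (-S - I), CD - S - I),
      `0,1` = c((S + P - CD) * (I - P), S - CD + I),
      `1,1` = c((-S - P + CD) * (I + S), -P + CD + I)
    )
    for (r in eq_static) {
      if (r$kind != "corner") next
      key <- paste0(r$point[["x"]], ",", r$point[["y"]])
      expect_equal(c(r$detJ, r$trJ), unname(want_static[[key]]))
    }

    eq_dp <- enumerate_equilibria(p, "dynamic_penalty")
    want_dp <- list(
      `0,0` = c((-CD) * (P - I), -CD + P - I),
      `1,0` = c(CD * (-I - S), CD - I - S),
      `0,1` = c((P + S - CD) * (I - P), S - CD + I),
      `1,1` = c((-S + CD) * (I + S), CD + I)
    )
    for (r in eq_dp) {
      if (r$kind != "corner") next
      key <- paste0(r$point[["x"]], ",", r$point[["y"]])
      expect_equal(c(r$detJ, r$trJ), unname(want_dp[[key]]))
    }
  }
})

test_that("stability classification follows the trace-determinant rule", {
  # sink at the origin when the penalty does not cover the supervision cost
  r00 <- classify_equilibrium(c(0, 0), fig1_params(), "static")
  expect_equal(r00$detJ, 2.5)
  expect_equal(r00$trJ, -5.5)
  expect_equal(r00$stability, "ESS_sink")

  # interior center of the static reference set
  ctr <- interior_of(fig4_params(), "static")
  expect_equal(ctr$stability, "center")
  expect_equal(ctr$trJ, 0, tolerance = 1e-12)
  expect_gt(ctr$detJ, 0)

  # dynamic-penalty interior point: stable spiral with Re(lambda) = -5/9
  dp <- interior_of(fig4_params(), "dynamic_penalty")
  expect_equal(dp$stability, "ESS_sink")
  expect_equal(Re(dp$eigenvalues), c(-5 / 9, -5 / 9), tolerance = 1e-12)
  expect_true(all(Im(dp$eigenvalues) != 0))

  expect_error(
    classify_equilibrium(c(0.37, 0.9), fig4_params(), "static"),
    "not an equilibrium"
  )
})

test_that("interior point is absent outside its existence region and the registry of corners is complete", {
  # static: P < I puts the closed form outside (0,1)
  eq <- enumerate_equilibria(fig1_params(), "static")
  expect_length(eq, 4)
  expect_true(all(vapply(eq, function(r) r$kind == "corner", logical(1))))

  # degenerate dynamic-penalty closed form (P = 0) falls back cleanly
  p0 <- game_params(S = 2, P = 0, I = 1, C = 1, dL = 1)
  eq0 <- enumerate_equilibria(p0, "dynamic_penalty")
  expect_length(eq0, 4)
})

test_that("static regime classification reproduces the three published conditions", {
  expect_equal(classify_static_regime(fig1_params()), "ESS_00")
  expect_equal(classify_static_regime(fig2_params()), "ESS_01")
  cs <- case_study_params(8000, 150, 105, 120, 10000, 700000)
  expect_equal(classify_static_regime(cs$params), "CENTER")
  expect_equal(classify_static_regime(fig4_params()), "CENTER")
  # tie lands on the boundary class
  expect_equal(
    classify_static_regime(game_params(S = 1, P = 2, I = 2, C = 1, dL = 4)),
    "BOUNDARY"
  )
})
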