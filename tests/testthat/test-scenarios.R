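test_that("the scenario registry carries the published parameterizations", {
  s1 <- builtin_scenario("sim1")
  expect_equal(
    unclass(s1$params)[c("S", "P", "I", "C", "dL")],
    list(S = 1, P = 1.5, I = 2, C = 1, dL = 4)
  )
  expect_equal(s1$mechanism, "static")

  s4 <- builtin_scenario("fig4")
  expect_equal(
    unclass(s4$params)[c("S", "P", "I", "C", "dL")],
    list(S = 3, P = 9, I = 3, C = 1, dL = 4)
  )
  expect_setequal(
    s4$mechanism, c("dynamic_penalty", "dynamic_reward", "dynamic_both")
  )

  cs <- builtin_scenario("case_study")
  expect_equal(cs$params$S, 1200000)
  expect_equal(cs$params$P, 700000)

  expect_error(builtin_scenario("nope"), "valid names")
})

test_that("case-study aggregation multiplies per-person quantities by the client count", {
  cs <- case_study_params(8000, 150, 105, 120, 10000, 700000)
  expect_identical(cs$params$S, 1200000)
  expect_identical(cs$params$C, 840000)
  expect_identical(cs$params$dL, 960000)
  expect_identical(cs$params$I, 10000)
  expect_identical(cs$params$P, 700000)
  expect_identical(cs$threshold, 600000)

  one <- case_study_params(1, 150, 105, 120, 10000, 700000)
  expect_equal(
    c(one$params$S, one$params$C, one$params$dL), c(150, 105, 120)
  )

  dbl <- case_study_params(16000, 150, 105, 120, 10000, 700000)
  expect_equal(dbl$params$S, 2 * cs$params$S)
  expect_equal(dbl$params$C, 2 * cs$params$C)
  expect_equal(dbl$params$dL, 2 * cs$params$dL)
  expect_equal(dbl$params$I, cs$params$I)
  expect_equal(dbl$params$P, cs$params$P)

  expect_error(case_study_params(8000, -1, 105, 120, 1, 1), "positive")
  expect_error(case_study_params(10.5, 150, 105, 120, 1, 1), "integer")
})

test_that("random scenarios are deterministic in the seed and honor regime requests", {
  a <- random_scenario(99)
  b <- random_scenario(99)
  expect_identical(unclass(a$params), unclass(b$params))

  for (sd in 1:5) {
    pc <- random_scenario(sd, regime = "CENTER")$params
    expect_equal(classify_static_regime(pc), "CENTER")
    expect_gt(pc$P, max(pc$I, pc$C + pc$dL - pc$S))

    pd <- random_scenario(sd, regime = "dynamic_interior")$params
    for (m in c("dynamic_penalty", "dynamic_reward", "dynamic_both")) {
      expect_false(is.null(interior_of(pd, m)))
    }
  }

  p00 <- random_scenario(3, regime = "ESS_00")$params
  tr <- integrate_trajectory(p00, "static", c(0.5, 0.5), 500)
  n <- nrow(tr)
  expect_lt(abs(tr$x[n]), 1e-3)
  expect_lt(abs(tr$y[n]), 1e-3)

  expect_error(
    random_scenario(1, regime = "CENTER", max_tries = 0),
    "budget exhausted"
  )
})

test_that("random draws do not disturb the caller's RNG stream", {
  set.seed(123)
  u1 <- runif(1)
  set.seed(123)
  invisible(random_scenario(5))
  u2 <- runif(1)
  expect_identical(u1, u2)
})

test_that("scenario configs round-trip bit-identically", {
  for (nm in c("sim1", "sim2", "case_study", "fig4")) {
    scn <- builtin_scenario(nm)
    path <- withr::local_tempfile(fileext = ".cfg")
    write_scenario_config(scn, path)
    back <- read_scenario_config(path)
    expect_identical(unclass(back$params), unclass(scn$params))
    expect_identical(back$mechanism, scn$mechanism[1])
    expect_identical(unname(back$init), unname(scn$init))
  }
})

test_that("config parsing rejects unknown or malformed keys", {
  path <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("S = 1", "P = 2", "I = 1", "C = 1", "dL = 1", "foo = 9"), path)
  expect_error(read_scenario_config(path), "unknown config key")
  writeLines(c("S = 1", "P = 2", "I = 1", "C = 1", "dL = 1", "s = 9"), path)
  expect_error(read_scenario_config(path), "unknown config key")
  writeLines(c("S = 1", "S = 2", "P = 2", "I = 1", "C = 1", "dL = 1"), path)
  expect_error(read_scenario_config(path), "duplicate")
})

test_that("scenario reports bundle regime, limits and mechanism comparison", {
  rep1 <- run_report(builtin_scenario("sim1"))
  expect_equal(rep1$schema, 1)
  expect_equal(rep1$regime, "ESS_00")
  expect_true(rep1$mechanisms$static$trajectory$converged)
  expect_equal(
    unname(rep1$mechanisms$static$trajectory$limit), c(0, 0),
    tolerance = 1e-3
  )

  repc <- run_report(builtin_scenario("case_study"))
  expect_equal(repc$regime, "CENTER")
  expect_true(repc$oscillation$is_closed)
  expect_true(repc$mechanisms$static$trajectory$oscillatory)
  expect_lt(repc$oscillation$H_drift_max, 1e-6)

  rep4 <- run_report(builtin_scenario("fig4"), compare = TRUE)
  expect_equal(
    rep4$ordering, c("dynamic_reward", "dynamic_both", "dynamic_penalty")
  )
  for (m in names(rep4$mechanisms)) {
    expect_true(rep4$mechanisms[[m]]$trajectory$converged)
  }

  json <- withr::local_tempfile(fileext = ".json")
  write_report_json(rep4, json)
  parsed <- jsonlite::read_json(json)
  expect_equal(parsed$schema, 1)
  expect_equal(parsed$regime, "CENTER")
  expect_equal(unlist(parsed$ordering)[1], "dynamic_reward")

  csv <- withr::local_tempfile(fileext = ".csv")
  rep_csv <- run_report(builtin_scenario("sim2"), trajectory_csv = csv)
  expect_true(file.exists(csv))
  expect_identical(readLines(csv)[1], "t,x,y")
})
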