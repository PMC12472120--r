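# Numerical integration with events and discontinuity handling.

test_that("exponential decay matches its closed form", {
  sys <- decay_system(k = 1, S0 = 1)
  tr <- simulate(sys, sim_settings(0, 1, 10, "S"))
  expect_equal(unname(tr$values[11, "S"]), exp(-1), tolerance = 1e-6)
  expect_equal(unname(tr$values[11, "S"]), 0.3678794, tolerance = 1e-6 / 0.36)
})

test_that("zero rate constant keeps the state flat", {
  sys <- decay_system(k = 0, S0 = 1)
  tr <- simulate(sys, sim_settings(0, 10, 20, "S"))
  expect_true(all(tr$values[, "S"] == 1))
})

test_that("the output grid is constructed, not accumulated", {
  settings <- sim_settings(0, 7, 13, "S")
  tr <- simulate(decay_system(), settings)
  expect_identical(tr$times, 0 + (0:13) * (7 / 13))
})

test_that("a rate-switching event reproduces its piecewise closed form", {
  # dS/dt = -kdeg * S with kdeg = 0 until t >= 5, then kdeg = 1;
  # S(10) = exp(-5)
  fx <- generate_fixture("event_dosing",
                         parameters = list(k1 = 0, k2 = 1, T = 5, S0 = 1))
  sys <- build_ode_system(parse_sbml(fx$sbml))
  tr <- simulate(sys, sim_settings(0, 10, 50, "S"))
  expect_equal(unname(tr$values[51, "S"]), 6.7379e-3, tolerance = 1e-6 / 6e-3)
  expect_equal(unname(tr$values[51, "S"]), exp(-5), tolerance = 1e-6)
  # before the switch nothing decays
  expect_equal(unname(tr$values[26, "S"]), 1, tolerance = 1e-9)
})

test_that("events fire immediately when the initial trigger value is false", {
  fx <- generate_fixture("event_dosing",
                         parameters = list(k1 = 0, k2 = 1, T = 0, S0 = 1))
  txt <- sub('initialValue="true"', 'initialValue="false"', fx$sbml)
  sys <- build_ode_system(parse_sbml(txt))
  tr <- simulate(sys, sim_settings(0, 1, 10, "S"))
  expect_equal(unname(tr$values[11, "S"]), exp(-1), tolerance = 1e-6)
})

test_that("piecewise time inputs integrate through the breakpoint", {
  fx <- generate_fixture("piecewise_input")
  sys <- build_ode_system(parse_sbml(fx$sbml))
  settings <- read_settings(fx$settings)
  tr <- simulate(sys, settings)
  expected <- read_trajectory_csv(fx$results)
  cmp <- compare_trajectories(tr, expected, atol = 1e-6, rtol = 0)
  expect_true(cmp$pass)
})

test_that("derived quantities are reported alongside states", {
  fx <- generate_fixture("assignment_rule_derived")
  sys <- build_ode_system(parse_sbml(fx$sbml))
  tr <- simulate(sys, sim_settings(0, 2, 10, c("S", "E")))
  expect_equal(tr$values[, "E"],
               fx$parameters$alpha * tr$values[, "S"], tolerance = 1e-12)
})

test_that("the adaptive solver agrees with the fixed-step RK4 oracle", {
  grid <- 0 + (0:20) * (2 / 20)
  for (fam in event_free_families()) {
    sys <- build_ode_system(parse_sbml(generate_fixture(fam)$sbml))
    adaptive <- simulate(sys, sim_settings(0, 2, 20, sys$state_ids))
    oracle <- rk4_trajectory(sys, grid, h = 1e-4)
    dev <- max(abs(adaptive$values - oracle$values[, adaptive$columns]))
    expect_lt(dev, 1e-6)
  }
})

test_that("conserved linear combinations drift below 1e-8", {
  fx <- generate_fixture("reversible_binding")
  sys <- build_ode_system(parse_sbml(fx$sbml))
  settings <- read_settings(fx$settings)
  tr <- simulate(sys, settings)
  tot_a <- tr$values[, "A"] + tr$values[, "C"]
  tot_b <- tr$values[, "B"] + tr$values[, "C"]
  expect_lt(max(abs(tot_a - tot_a[1])), 1e-8)
  expect_lt(max(abs(tot_b - tot_b[1])), 1e-8)
})

test_that("tightening solver tolerances tenfold moves nothing past 1e-5", {
  for (fam in translatable_families()) {
    fx <- generate_fixture(fam)
    sys <- build_ode_system(parse_sbml(fx$sbml))
    settings <- read_settings(fx$settings)
    a <- simulate(sys, settings, rtol = 1e-8, atol = 1e-10)
    b <- simulate(sys, settings, rtol = 1e-9, atol = 1e-11)
    expect_lt(max(abs(a$values - b$values)), 1e-5)
  }
})

test_that("finite-time blow-up reports the last good time", {
  # dS/dt = S^2 escapes at t = 1/S0
  txt <- sub("<apply><times/><ci>k</ci><ci>S</ci></apply>",
             "<apply><power/><ci>S</ci><cn>2</cn></apply>",
             sub("<listOfReactants>", "<listOfProducts>",
                 sub("</listOfReactants>", "</listOfProducts>",
                     generate_fixture("decay")$sbml)))
  sys <- build_ode_system(parse_sbml(txt))
  expect_error(simulate(sys, sim_settings(0, 5, 10, "S")),
               class = "sbml_numeric_error")
})

test_that("trajectory CSV round-trips at full precision", {
  sys <- decay_system()
  tr <- simulate(sys, sim_settings(0, 3, 6, "S"))
  back <- read_trajectory_csv(write_trajectory_csv(tr))
  expect_identical(back$times, tr$times)
  expect_identical(unname(back$values), unname(tr$values))
})
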