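# Model -> ODE system compilation.

test_that("user functions inline by capture-free substitution", {
  f <- list(id = "f", arg_names = "x",
            body = e_call("times", e_num(2), e_sym("x")))
  g <- list(id = "g", arg_names = c("a", "b"),
            body = e_call("divide", e_sym("a"), e_sym("b")))
  out <- inline_functions(e_call("f", e_sym("S")), list(f))
  expect_identical(render_prefix(out), "(times 2 S)")
  out <- inline_functions(e_call("g", e_sym("k1"), e_sym("k2")), list(f, g))
  expect_identical(render_prefix(out), "(divide k1 k2)")
  # nested: g(f(S), 2)
  out <- inline_functions(e_call("g", e_call("f", e_sym("S")), e_num(2)),
                          list(f, g))
  expect_identical(render_prefix(out), "(divide (times 2 S) 2)")
})

test_that("recursion, unknown functions and arity mismatches error", {
  rec <- list(id = "f", arg_names = "x",
              body = e_call("plus", e_call("f", e_sym("x")), e_num(1)))
  expect_error(inline_functions(e_call("f", e_num(1)), list(rec)),
               "recursive")
  expect_error(inline_functions(e_call("h", e_num(1)), list(rec)),
               "unknown function")
  f <- list(id = "f", arg_names = "x", body = e_sym("x"))
  expect_error(inline_functions(e_call("f", e_num(1), e_num(2)), list(f)),
               "argument")
})

test_that("assignment rules order topologically with document-order ties", {
  rules <- list(list(variable = "a", math = e_call("times", e_num(2),
                                                   e_sym("b"))),
                list(variable = "b", math = e_num(3)))
  out <- order_assignments(rules)
  expect_identical(vapply(out, `[[`, character(1), "id"), c("b", "a"))
  single <- order_assignments(list(list(variable = "p",
                                        math = e_call("times", e_sym("k"),
                                                      e_time()))))
  expect_identical(single[[1]]$id, "p")
  cyc <- list(list(variable = "a", math = e_sym("b")),
              list(variable = "b", math = e_sym("a")))
  expect_error(order_assignments(cyc), "cycle.*a.*b")
})

test_that("the decay model compiles to -(k*S) with S as the only state", {
  sys <- decay_system()
  expect_identical(sys$state_ids, "S")
  expect_identical(render_prefix(sys$derivatives$S), "(minus (times k S))")
  expect_identical(sort(names(sys$constants)), c("cell", "k"))
  expect_equal(initial_state_values(sys)[["S"]], 1)
})

test_that("stoichiometry bookkeeping: A + B -> C", {
  sys <- build_ode_system(parse_sbml(generate_fixture("reversible_binding")$sbml))
  expect_identical(sys$state_ids, c("A", "B", "C"))
  env <- list(A = 2, B = 3, C = 1, kf = 1, kr = 0.5)
  # dA = dB = -kf*A*B + kr*C ; dC = +kf*A*B - kr*C
  expect_equal(evaluate(sys$derivatives$A, env), -2 * 3 + 0.5)
  expect_equal(evaluate(sys$derivatives$B, env), -2 * 3 + 0.5)
  expect_equal(evaluate(sys$derivatives$C, env), 2 * 3 - 0.5)
})

test_that("boundary species stay out of the state vector but feed rates", {
  sys <- build_ode_system(parse_sbml(generate_fixture("boundary_feed")$sbml))
  expect_false("B" %in% sys$state_ids)
  expect_true("B" %in% names(sys$constants))
  expect_true("B" %in% expr_symbols(sys$derivatives$S))
})

test_that("rate rules drive parameters as states; event targets get promoted", {
  sys <- build_ode_system(parse_sbml(generate_fixture("rate_rule_param")$sbml))
  expect_identical(sys$state_ids, c("S", "p_deg"))
  expect_identical(render_prefix(sys$derivatives$p_deg), "a")

  sys2 <- build_ode_system(parse_sbml(generate_fixture("event_dosing")$sbml))
  expect_true("kdeg" %in% sys2$state_ids)
  expect_false("kdeg" %in% names(sys2$constants))
  expect_identical(render_prefix(sys2$derivatives$kdeg), "0")
  expect_equal(initial_state_values(sys2)[["kdeg"]], 0.2)
})

test_that("compilation refuses models with findings or missing initials", {
  m <- parse_sbml(generate_fixture("unsupported_compartment")$sbml)
  expect_error(build_ode_system(m), class = "sbml_compile_error")
  noinit <- sub(' initialAmount="1"', "", generate_fixture("decay")$sbml)
  expect_error(build_ode_system(parse_sbml(noinit)),
               class = "sbml_compile_error")
})

test_that("compiled systems satisfy symbol closure on every fixture", {
  for (fam in translatable_families()) {
    sys <- build_ode_system(parse_sbml(generate_fixture(fam)$sbml))
    expect_silent(validate_ode_system(sys))
  }
})

test_that("left null vectors of the stoichiometric matrix annihilate the rates", {
  # closed mass-action network A + B <-> C: conservation of A+C and B+C
  fx <- generate_fixture("reversible_binding")
  sys <- build_ode_system(parse_sbml(fx$sbml))
  w <- list(c(A = 1, B = 0, C = 1), c(A = 0, B = 1, C = 1))
  set.seed(7)
  for (i in 1:100) {
    env <- list(A = runif(1, 0, 5), B = runif(1, 0, 5), C = runif(1, 0, 5),
                kf = fx$parameters$kf, kr = fx$parameters$kr)
    dx <- vapply(sys$state_ids, function(s) evaluate(sys$derivatives[[s]], env),
                 numeric(1))
    for (wv in w) {
      expect_lt(abs(sum(wv[sys$state_ids] * dx)), 1e-12)
    }
  }
})

test_that("compiling twice yields identical structures including order", {
  txt <- generate_fixture("event_dosing")$sbml
  s1 <- build_ode_system(parse_sbml(txt))
  s2 <- build_ode_system(parse_sbml(txt))
  expect_identical(s1, s2)
})

test_that("function definitions are inlined through the whole pipeline", {
  sys <- build_ode_system(parse_sbml(sbml_with_function_def()))
  # k * f(S) with f(x) = 2x  ->  deriv(S) = -(k * (2 * S))
  expect_equal(evaluate(sys$derivatives$S, list(k = 0.5, S = 3)), -3)
})
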