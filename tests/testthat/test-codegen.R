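# Equation-text rendering and compiled-model JSON.

test_that("the decay system renders the expected equation lines", {
  txt <- render_equations(decay_system())
  lines <- strsplit(txt, "\n")[[1]]
  expect_true("deriv(S) = -(k * S)" %in% lines)
  expect_true("init S = 1" %in% lines)
  expect_true("const k = 1" %in% lines)
})

test_that("derived quantities render before the derivatives that use them", {
  sys <- build_ode_system(parse_sbml(
    generate_fixture("assignment_rule_derived")$sbml))
  lines <- strsplit(render_equations(sys), "\n")[[1]]
  let_line <- grep("^let E = ", lines)
  deriv_lines <- grep("^deriv\\(", lines)
  expect_length(let_line, 1)
  expect_true(all(let_line < deriv_lines))
  expect_identical(lines[let_line], "let E = alpha * S")
})

test_that("rendering is byte-deterministic", {
  for (fam in c("decay", "event_dosing", "piecewise_input")) {
    sys <- build_ode_system(parse_sbml(generate_fixture(fam)$sbml))
    expect_identical(render_equations(sys), render_equations(sys))
    expect_identical(export_compiled_json(sys), export_compiled_json(sys))
  }
})

test_that("infix rendering uses minimal parentheses", {
  expect_identical(
    render_infix(e_call("plus", e_sym("a"),
                        e_call("times", e_sym("b"), e_sym("c")))),
    "a + b * c")
  expect_identical(
    render_infix(e_call("times", e_call("plus", e_sym("a"), e_sym("b")),
                        e_sym("c"))),
    "(a + b) * c")
  expect_identical(
    render_infix(e_call("power", e_sym("a"),
                        e_call("power", e_sym("b"), e_sym("c")))),
    "a ^ b ^ c")
  expect_identical(
    render_infix(e_call("minus", e_sym("a"),
                        e_call("minus", e_sym("b"), e_sym("c")))),
    "a - (b - c)")
})

test_that("compiled JSON matches the schema contract", {
  sys <- decay_system()
  doc <- jsonlite::fromJSON(export_compiled_json(sys), simplifyVector = FALSE)
  expect_length(doc$states, 1)
  expect_identical(doc$states[[1]]$id, "S")
  expect_true("S" %in% names(doc$derivatives))
  expect_identical(doc$derivatives$S$kind, "call")
  # empty events serialize as an empty array, not as absent
  expect_true("events" %in% names(doc))
  expect_length(doc$events, 0)
})

test_that("JSON export -> import -> export is the byte identity", {
  for (fam in c("decay", "event_dosing", "assignment_rule_derived",
                "piecewise_input")) {
    sys <- build_ode_system(parse_sbml(generate_fixture(fam)$sbml))
    json1 <- export_compiled_json(sys)
    json2 <- export_compiled_json(import_compiled_json(json1))
    expect_identical(json2, json1)
  }
})

test_that("an independent JSON interpreter reproduces the derivatives", {
  set.seed(11)
  for (fam in translatable_families()) {
    fx <- generate_fixture(fam)
    sys <- build_ode_system(parse_sbml(fx$sbml))
    doc <- jsonlite::fromJSON(export_compiled_json(sys),
                              simplifyVector = FALSE)
    consts <- lapply(doc$constants, function(v) if (is.null(v)) NA_real_ else v)
    for (rep in 1:50) {
      env <- consts
      for (s in doc$states) env[[s$id]] <- runif(1, 0.05, 5)
      t <- runif(1, 0, 10)
      # derived quantities first, in document order
      for (d in doc$derived) env[[d$id]] <- json_eval(d$expr, env, t)
      for (sid in names(doc$derivatives)) {
        ref <- evaluate(sys$derivatives[[sid]], env, t)
        got <- json_eval(doc$derivatives[[sid]], env, t)
        expect_equal(got, ref, tolerance = 1e-12)
      }
    }
  }
})
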