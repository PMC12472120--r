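# SBML document parsing into the intermediate representation.

test_that("a minimal decay document parses with the right element counts", {
  m <- parse_sbml(generate_fixture("decay")$sbml)
  expect_s3_class(m, "sbml_model")
  expect_length(m$compartments, 1)
  expect_length(m$species, 1)
  expect_length(m$parameters, 1)
  expect_length(m$reactions, 1)
  expect_identical(m$level, 2L)
  # SBML defaults applied
  expect_false(m$species[[1]]$boundary_condition)
  expect_false(m$species[[1]]$constant)
  expect_identical(m$species[[1]]$initial_kind, "amount")
})

test_that("function definitions parse as lambdas", {
  m <- parse_sbml(sbml_with_function_def())
  expect_length(m$function_defs, 1)
  fd <- m$function_defs[[1]]
  expect_identical(fd$id, "f")
  expect_identical(fd$arg_names, "x")
  expect_identical(render_prefix(fd$body), "(times 2 x)")
})

test_that("malformed and unsupported documents are rejected", {
  expect_error(parse_sbml("not xml"), class = "sbml_parse_error")
  expect_error(parse_sbml("<notsbml/>"), class = "sbml_parse_error")
  l1 <- sub('level="2"', 'level="1"',
            sub("level2/version4", "level1", generate_fixture("decay")$sbml))
  expect_error(parse_sbml(l1), class = "sbml_unsupported_document")
  # a required package gates the document
  pkg <- sub("<sbml ",
             '<sbml xmlns:comp="http://www.sbml.org/sbml/level3/version1/comp/version1" comp:required="true" ',
             generate_fixture("event_dosing")$sbml)
  expect_error(parse_sbml(pkg), class = "sbml_unsupported_document")
})

test_that("duplicate identifiers are a validation error", {
  dup <- sub('<parameter id="k" value="1"/>',
             '<parameter id="k" value="1"/><parameter id="S" value="1"/>',
             generate_fixture("decay")$sbml)
  expect_error(parse_sbml(dup), class = "sbml_validation_error")
})

test_that("cross-references must resolve", {
  bad <- sub('compartment="cell"', 'compartment="nucleus"',
             generate_fixture("decay")$sbml)
  expect_error(parse_sbml(bad), class = "sbml_validation_error")
})

test_that("kinetic-law local parameters are namespaced into the flat table", {
  txt <- sub("<kineticLaw>",
             paste0("<kineticLaw><listOfParameters>",
                    '<parameter id="k_local" value="2"/>',
                    "</listOfParameters>"),
             sub("<ci>k</ci>", "<ci>k_local</ci>",
                 generate_fixture("decay")$sbml))
  m <- parse_sbml(txt)
  lp <- m$reactions[[1]]$local_parameters
  expect_length(lp, 1)
  expect_identical(lp[[1]]$id, "degradation__k_local")
  expect_true("degradation__k_local" %in%
                expr_symbols(m$reactions[[1]]$kinetic_law))
})

test_that("both emitted dialects parse to equivalent models", {
  for (fam in c("decay", "event_dosing", "rate_rule_param")) {
    m2 <- parse_sbml(generate_fixture(fam, level_version = c(2, 4))$sbml)
    m3 <- parse_sbml(generate_fixture(fam, level_version = c(3, 2))$sbml)
    expect_identical(length(m2$species), length(m3$species))
    expect_identical(length(m2$reactions), length(m3$reactions))
    expect_identical(length(m2$events), length(m3$events))
  }
})

test_that("unsupported MathML is recorded, not fatal", {
  txt <- sub("<apply><times/><ci>k</ci><ci>S</ci></apply>",
             "<apply><factorial/><ci>S</ci></apply>",
             generate_fixture("decay")$sbml)
  m <- parse_sbml(txt)
  expect_length(m$unsupported_math, 1)
  expect_identical(m$unsupported_math[[1]]$element_id, "degradation")
})
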