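# Unsupported-feature detection.

test_that("a compartment of size two is flagged", {
  m <- parse_sbml(generate_fixture("unsupported_compartment")$sbml)
  rep <- detect_unsupported(m)
  expect_false(report_is_clean(rep))
  expect_true("compartment_size_ne_1" %in% report_tags(rep))
})

test_that("algebraic rules are flagged", {
  txt <- sub("</listOfSpecies>",
             paste0("</listOfSpecies><listOfRules><algebraicRule>",
                    '<math xmlns="http://www.w3.org/1998/Math/MathML">',
                    "<apply><minus/><ci>S</ci><ci>k</ci></apply></math>",
                    "</algebraicRule></listOfRules>"),
             generate_fixture("decay")$sbml)
  rep <- detect_unsupported(parse_sbml(txt))
  expect_true("algebraic_rule" %in% report_tags(rep))
})

test_that("assignment rules for non-boundary species are flagged", {
  txt <- sub('<assignmentRule variable="E">',
             '<assignmentRule variable="S">',
             generate_fixture("assignment_rule_derived")$sbml)
  rep <- detect_unsupported(parse_sbml(txt))
  expect_true("assignment_rule_nonboundary_species" %in% report_tags(rep))
})

test_that("events touching species are refused; parameter events are fine", {
  base <- generate_fixture("event_dosing")$sbml
  expect_true(report_is_clean(detect_unsupported(parse_sbml(base))))
  tospecies <- sub('<eventAssignment variable="kdeg">',
                   '<eventAssignment variable="S">', base)
  rep <- detect_unsupported(parse_sbml(tospecies))
  expect_true("event_targets_species" %in% report_tags(rep))
})

test_that("self-referencing event assignments are flagged", {
  selfref <- sub(
    '<eventAssignment variable="kdeg"><math xmlns="http://www.w3.org/1998/Math/MathML"><ci>k_late</ci></math>',
    paste0('<eventAssignment variable="kdeg">',
           '<math xmlns="http://www.w3.org/1998/Math/MathML">',
           '<apply><plus/><ci>kdeg</ci><ci>k_late</ci></apply></math>'),
    generate_fixture("event_dosing")$sbml, fixed = TRUE)
  rep <- detect_unsupported(parse_sbml(selfref))
  expect_true("event_self_reference" %in% report_tags(rep))
})

test_that("delayed events, fast reactions and conversion factors are flagged", {
  base <- generate_fixture("event_dosing")$sbml
  delayed <- sub("<listOfEventAssignments>",
                 paste0("<delay><math xmlns=\"http://www.w3.org/1998/Math/MathML\">",
                        "<cn>1</cn></math></delay><listOfEventAssignments>"),
                 base)
  expect_true("delayed_event" %in%
                report_tags(detect_unsupported(parse_sbml(delayed))))
  fast <- sub('<reaction id="degradation" reversible="false">',
              '<reaction id="degradation" reversible="false" fast="true">',
              generate_fixture("decay")$sbml)
  expect_true("fast_reaction" %in%
                report_tags(detect_unsupported(parse_sbml(fast))))
  cf <- sub('<model id="event_dosing">',
            '<model id="event_dosing" conversionFactor="k_late">', base)
  expect_true("conversion_factor" %in%
                report_tags(detect_unsupported(parse_sbml(cf))))
})

test_that("unparsable MathML surfaces as an unsupported_mathml finding", {
  txt <- sub("<apply><times/><ci>k</ci><ci>S</ci></apply>",
             "<apply><factorial/><ci>S</ci></apply>",
             generate_fixture("decay")$sbml)
  rep <- detect_unsupported(parse_sbml(txt))
  expect_true("unsupported_mathml" %in% report_tags(rep))
})

test_that("species-referencing triggers warn but do not gate", {
  trig <- sub("<ci>t_switch</ci></apply>", "<ci>S</ci></apply>",
              sub("<csymbol encoding=\"text\" definitionURL=\"http://www.sbml.org/sbml/symbols/time\">t</csymbol>",
                  "<cn>1</cn>", generate_fixture("event_dosing")$sbml))
  rep <- detect_unsupported(parse_sbml(trig))
  expect_true(report_is_clean(rep))
  expect_length(rep$warnings, 1)
})

test_that("detection is pure: repeated calls give identical reports", {
  m <- parse_sbml(generate_fixture("unsupported_compartment")$sbml)
  expect_identical(detect_unsupported(m), detect_unsupported(m))
  m2 <- parse_sbml(generate_fixture("decay")$sbml)
  expect_true(report_is_clean(detect_unsupported(m2)))
  expect_identical(detect_unsupported(m2), detect_unsupported(m2))
})
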