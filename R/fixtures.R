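# Generator of small, valid SBML documents with known reference
# solutions. Families with a closed form ship an expected trajectory
# computed from that closed form; the two nonlinear families use the
# fixed-step RK4 reference integrator. One family (a compartment of
# size 2) is deliberately untranslatable and ships no expected CSV.
#
# Documents are emitted in both the Level 2 Version 4 and Level 3
# Version 2 dialects so the reader's dialect handling is exercised.
# Identical (family, parameters, level_version) always yields
# byte-identical SBML.

#' Fixture model families
#'
#' Names accepted by [generate_fixture()] and [generate_mini_suite()].
#' All but `unsupported_compartment` are translatable;
#' `reversible_binding` and `michaelis_menten_fn` have no closed form
#' and use the RK4 reference integrator for expected trajectories.
#'
#' @export
FIXTURE_FAMILIES <- c(
  "decay", "birth_death", "reversible_binding", "michaelis_menten_fn",
  "rate_rule_param", "assignment_rule_derived", "event_dosing",
  "piecewise_input", "boundary_feed", "unsupported_compartment"
)

# Counter-based pseudo-random draw: a small multiplicative congruential
# scheme over 31-bit integers, fully determined by (seed, counter), so
# fixtures are reproducible across platforms without touching R's RNG.
fixture_draw <- function(seed, counter) {
  x <- (as.double(seed) * 2654435761 + as.double(counter) * 40503 + 12345) %%
    2147483647
  for (i in 1:3) x <- (x * 16807) %% 2147483647
  x / 2147483647
}

# scale a base parameter by a deterministic factor in [0.7, 1.4]
perturb <- function(base, seed, counter) {
  base * (0.7 + 0.7 * fixture_draw(seed, counter))
}

sbml_header <- function(level_version, model_id) {
  lv <- level_version
  ns <- if (lv[1] == 2) {
    sprintf("http://www.sbml.org/sbml/level2/version%d", lv[2])
  } else {
    sprintf("http://www.sbml.org/sbml/level3/version%d/core", lv[2])
  }
  paste0("<?xml version=\"1.0\" encoding=\"UTF-8\"?>\n",
         sprintf("<sbml xmlns=\"%s\" level=\"%d\" version=\"%d\">\n",
                 ns, lv[1], lv[2]),
         sprintf("  <model id=\"%s\">\n", model_id))
}

sbml_footer <- "  </model>\n</sbml>\n"

xml_compartment <- function(id, size, lv) {
  if (lv[1] == 3) {
    sprintf("      <compartment id=\"%s\" size=\"%s\" constant=\"true\"/>\n",
            id, fmt_num(size))
  } else {
    sprintf("      <compartment id=\"%s\" size=\"%s\"/>\n", id, fmt_num(size))
  }
}

xml_species <- function(id, compartment, initial, lv, boundary = FALSE) {
  extra <- if (lv[1] == 3) {
    " hasOnlySubstanceUnits=\"true\" constant=\"false\""
  } else ""
  sprintf(paste0("      <species id=\"%s\" compartment=\"%s\"",
                 " initialAmount=\"%s\" boundaryCondition=\"%s\"%s/>\n"),
          id, compartment, fmt_num(initial),
          if (boundary) "true" else "false", extra)
}

xml_parameter <- function(id, value, lv, constant = TRUE) {
  cattr <- if (lv[1] == 3 || !constant) {
    sprintf(" constant=\"%s\"", if (constant) "true" else "false")
  } else ""
  sprintf("      <parameter id=\"%s\" value=\"%s\"%s/>\n",
          id, fmt_num(value), cattr)
}

xml_species_ref <- function(id, lv) {
  if (lv[1] == 3) {
    sprintf("<speciesReference species=\"%s\" stoichiometry=\"1\" constant=\"true\"/>",
            id)
  } else {
    sprintf("<speciesReference species=\"%s\"/>", id)
  }
}

xml_reaction <- function(id, reactants, products, law_expr, lv) {
  refs <- function(ids, tag) {
    if (length(ids) == 0) return("")
    inner <- paste(vapply(ids, xml_species_ref, character(1), lv = lv),
                   collapse = "")
    sprintf("        <listOf%s>%s</listOf%s>\n", tag, inner, tag)
  }
  paste0(
    sprintf("      <reaction id=\"%s\" reversible=\"false\">\n", id),
    refs(reactants, "Reactants"),
    refs(products, "Products"),
    "        <kineticLaw>", write_mathml(law_expr), "</kineticLaw>\n",
    "      </reaction>\n")
}

wrap_list <- function(tag, body) {
  if (!nzchar(body)) return("")
  sprintf("    <listOf%s>\n%s    </listOf%s>\n", tag, body, tag)
}

default_fixture_params <- function(family) {
  switch(family,
    decay = list(k = 1, S0 = 1),
    birth_death = list(b = 2, d = 1, S0 = 0),
    reversible_binding = list(kf = 1, kr = 0.5, A0 = 1, B0 = 0.8, C0 = 0),
    michaelis_menten_fn = list(Vm = 1, Km = 0.5, S0 = 2, P0 = 0),
    rate_rule_param = list(p0 = 0.1, a = 0.05, S0 = 1),
    assignment_rule_derived = list(k = 0.3, alpha = 2, S0 = 2),
    event_dosing = list(k1 = 0.2, k2 = 1, T = 5, S0 = 1),
    piecewise_input = list(a = 1, k = 0.5, T = 4, S0 = 0),
    boundary_feed = list(kf = 1, B0 = 2, d = 0.5, S0 = 0),
    unsupported_compartment = list(k = 1, S0 = 1),
    abort_validation(sprintf("unknown fixture family '%s'", family))
  )
}

default_level_version <- function(family) {
  # families split across the two dialects
  if (family %in% c("decay", "reversible_binding", "boundary_feed",
                    "unsupported_compartment")) c(2L, 4L) else c(3L, 2L)
}

fixture_grid_spec <- function(family) {
  switch(family,
    birth_death = list(duration = 20, steps = 50),
    reversible_binding = list(duration = 5, steps = 50),
    michaelis_menten_fn = list(duration = 5, steps = 50),
    list(duration = 10, steps = 50)
  )
}

settings_text <- function(start, duration, steps, variables) {
  paste0("start: ", fmt_num(start), "\n",
         "duration: ", fmt_num(duration), "\n",
         "steps: ", fmt_num(steps), "\n",
         "variables: ", paste(variables, collapse = ", "), "\n")
}

closed_form_csv <- function(times, columns, fn) {
  vals <- fn(times)  # list of numeric vectors, one per column
  rows <- vapply(seq_along(times), function(i) {
    paste(vapply(c(times[i], vapply(vals, `[[`, numeric(1), i)), fmt_num,
                 character(1)), collapse = ",")
  }, character(1))
  paste0(paste(c(paste(c("time", columns), collapse = ","), rows),
               collapse = "\n"), "\n")
}

#' Generate one SBML fixture with its settings and expected trajectory
#'
#' @param family One of `FIXTURE_FAMILIES`.
#' @param parameters Named list overriding the family defaults.
#' @param level_version Integer pair `(level, version)`; defaults to
#'   the family's dialect.
#' @param seed,draw When given, the family defaults are perturbed by a
#'   deterministic counter-based draw (same seed and draw index always
#'   give the same document).
#' @return `list(family, parameters, level_version, sbml, settings,
#'   results)`; `results` is `NULL` for the untranslatable family.
#' @export
#' @examples
#' fx <- generate_fixture("decay")
#' substr(fx$results, 1, 7)
generate_fixture <- function(family, parameters = list(),
                             level_version = NULL, seed = NULL, draw = 1L) {
  family <- match.arg(family, FIXTURE_FAMILIES)
  p <- default_fixture_params(family)
  if (!is.null(seed)) {
    fam_idx <- match(family, FIXTURE_FAMILIES)
    for (i in seq_along(p)) {
      counter <- fam_idx * 10000L + draw * 100L + i
      p[[i]] <- perturb(p[[i]], seed, counter)
    }
  }
  for (nm in names(parameters)) p[[nm]] <- parameters[[nm]]
  for (nm in names(p)) {
    if (!is.numeric(p[[nm]]) || p[[nm]] < 0) {
      abort_validation(sprintf("fixture parameter '%s' out of range", nm))
    }
  }
  lv <- if (is.null(level_version)) default_level_version(family)
        else as.integer(level_version)
  g <- fixture_grid_spec(family)
  times <- 0 + (0:g$steps) * (g$duration / g$steps)

  fx <- switch(family,
    decay = fixture_decay(p, lv, times, size = 1),
    unsupported_compartment = fixture_decay(p, lv, times, size = 2),
    birth_death = fixture_birth_death(p, lv, times),
    reversible_binding = fixture_reversible_binding(p, lv, times),
    michaelis_menten_fn = fixture_michaelis_menten(p, lv, times),
    rate_rule_param = fixture_rate_rule_param(p, lv, times),
    assignment_rule_derived = fixture_assignment_rule(p, lv, times),
    event_dosing = fixture_event_dosing(p, lv, times),
    piecewise_input = fixture_piecewise_input(p, lv, times),
    boundary_feed = fixture_boundary_feed(p, lv, times)
  )
  list(family = family, parameters = p, level_version = lv,
       sbml = fx$sbml,
       settings = settings_text(0, g$duration, g$steps, fx$variables),
       results = fx$results)
}

fixture_decay <- function(p, lv, times, size = 1) {
  law <- e_call("times", e_sym("k"), e_sym("S"))
  sbml <- paste0(
    sbml_header(lv, if (size == 1) "decay" else "decay_big_compartment"),
    wrap_list("Compartments", xml_compartment("cell", size, lv)),
    wrap_list("Species", xml_species("S", "cell", p$S0, lv)),
    wrap_list("Parameters", xml_parameter("k", p$k, lv)),
    wrap_list("Reactions", xml_reaction("degradation", "S", character(0),
                                        law, lv)),
    sbml_footer)
  results <- if (size == 1) {
    closed_form_csv(times, "S", function(t) list(p$S0 * exp(-p$k * t)))
  } else NULL
  list(sbml = sbml, variables = "S", results = results)
}

fixture_birth_death <- function(p, lv, times) {
  sbml <- paste0(
    sbml_header(lv, "birth_death"),
    wrap_list("Compartments", xml_compartment("cell", 1, lv)),
    wrap_list("Species", xml_species("S", "cell", p$S0, lv)),
    wrap_list("Parameters", paste0(xml_parameter("b", p$b, lv),
                                   xml_parameter("d", p$d, lv))),
    wrap_list("Reactions", paste0(
      xml_reaction("birth", character(0), "S", e_sym("b"), lv),
      xml_reaction("death", "S", character(0),
                   e_call("times", e_sym("d"), e_sym("S")), lv))),
    sbml_footer)
  eq <- p$b / p$d
  results <- closed_form_csv(times, "S", function(t) {
    list(eq + (p$S0 - eq) * exp(-p$d * t))
  })
  list(sbml = sbml, variables = "S", results = results)
}

fixture_reversible_binding <- function(p, lv, times) {
  sbml <- paste0(
    sbml_header(lv, "reversible_binding"),
    wrap_list("Compartments", xml_compartment("cell", 1, lv)),
    wrap_list("Species", paste0(
      xml_species("A", "cell", p$A0, lv),
      xml_species("B", "cell", p$B0, lv),
      xml_species("C", "cell", p$C0, lv))),
    wrap_list("Parameters", paste0(xml_parameter("kf", p$kf, lv),
                                   xml_parameter("kr", p$kr, lv))),
    wrap_list("Reactions", paste0(
      xml_reaction("bind", c("A", "B"), "C",
                   e_call("times", e_sym("kf"), e_sym("A"), e_sym("B")), lv),
      xml_reaction("unbind", "C", c("A", "B"),
                   e_call("times", e_sym("kr"), e_sym("C")), lv))),
    sbml_footer)
  list(sbml = sbml, variables = c("A", "B", "C"), results = "rk4")
}

fixture_michaelis_menten <- function(p, lv, times) {
  # rate via a function definition mm(Vm, Km, X) = Vm * X / (Km + X)
  fdef <- paste0(
    "    <listOfFunctionDefinitions>\n",
    "      <functionDefinition id=\"mm\">",
    "<math xmlns=\"http://www.w3.org/1998/Math/MathML\">",
    "<lambda><bvar><ci>Vmax</ci></bvar><bvar><ci>Khalf</ci></bvar>",
    "<bvar><ci>X</ci></bvar>",
    "<apply><divide/><apply><times/><ci>Vmax</ci><ci>X</ci></apply>",
    "<apply><plus/><ci>Khalf</ci><ci>X</ci></apply></apply>",
    "</lambda></math></functionDefinition>\n",
    "    </listOfFunctionDefinitions>\n")
  law <- e_call("mm", e_sym("Vm"), e_sym("Km"), e_sym("S"))
  sbml <- paste0(
    sbml_header(lv, "michaelis_menten"),
    fdef,
    wrap_list("Compartments", xml_compartment("cell", 1, lv)),
    wrap_list("Species", paste0(
      xml_species("S", "cell", p$S0, lv),
      xml_species("P", "cell", p$P0, lv))),
    wrap_list("Parameters", paste0(xml_parameter("Vm", p$Vm, lv),
                                   xml_parameter("Km", p$Km, lv))),
    wrap_list("Reactions", xml_reaction("conversion", "S", "P", law, lv)),
    sbml_footer)
  list(sbml = sbml, variables = c("S", "P"), results = "rk4")
}

fixture_rate_rule_param <- function(p, lv, times) {
  # parameter p_deg grows linearly (rate rule), species decays at p_deg * S
  rules <- paste0(
    "    <listOfRules>\n",
    "      <rateRule variable=\"p_deg\">",
    write_mathml(e_sym("a")), "</rateRule>\n",
    "    </listOfRules>\n")
  sbml <- paste0(
    sbml_header(lv, "rate_rule_param"),
    wrap_list("Compartments", xml_compartment("cell", 1, lv)),
    wrap_list("Species", xml_species("S", "cell", p$S0, lv)),
    wrap_list("Parameters", paste0(
      xml_parameter("p_deg", p$p0, lv, constant = FALSE),
      xml_parameter("a", p$a, lv))),
    rules,
    wrap_list("Reactions", xml_reaction("degradation", "S", character(0),
      e_call("times", e_sym("p_deg"), e_sym("S")), lv)),
    sbml_footer)
  results <- closed_form_csv(times, c("S", "p_deg"), function(t) {
    list(p$S0 * exp(-(p$p0 * t + p$a * t^2 / 2)), p$p0 + p$a * t)
  })
  list(sbml = sbml, variables = c("S", "p_deg"), results = results)
}

fixture_assignment_rule <- function(p, lv, times) {
  rules <- paste0(
    "    <listOfRules>\n",
    "      <assignmentRule variable=\"E\">",
    write_mathml(e_call("times", e_sym("alpha"), e_sym("S"))),
    "</assignmentRule>\n",
    "    </listOfRules>\n")
  sbml <- paste0(
    sbml_header(lv, "assignment_rule_derived"),
    wrap_list("Compartments", xml_compartment("cell", 1, lv)),
    wrap_list("Species", xml_species("S", "cell", p$S0, lv)),
    wrap_list("Parameters", paste0(
      xml_parameter("k", p$k, lv),
      xml_parameter("alpha", p$alpha, lv),
      xml_parameter("E", 0, lv, constant = FALSE))),
    rules,
    wrap_list("Reactions", xml_reaction("degradation", "S", character(0),
      e_call("times", e_sym("k"), e_sym("S")), lv)),
    sbml_footer)
  results <- closed_form_csv(times, c("S", "E"), function(t) {
    s <- p$S0 * exp(-p$k * t)
    list(s, p$alpha * s)
  })
  list(sbml = sbml, variables = c("S", "E"), results = results)
}

fixture_event_dosing <- function(p, lv, times) {
  trigger <- e_call("geq", e_time(), e_sym("t_switch"))
  events <- paste0(
    "    <listOfEvents>\n",
    "      <event id=\"switch_rate\">\n",
    "        <trigger",
    if (lv[1] == 3) " initialValue=\"true\" persistent=\"true\"" else "",
    ">", write_mathml(trigger), "</trigger>\n",
    "        <listOfEventAssignments>\n",
    "          <eventAssignment variable=\"kdeg\">",
    write_mathml(e_sym("k_late")), "</eventAssignment>\n",
    "        </listOfEventAssignments>\n",
    "      </event>\n",
    "    </listOfEvents>\n")
  sbml <- paste0(
    sbml_header(lv, "event_dosing"),
    wrap_list("Compartments", xml_compartment("cell", 1, lv)),
    wrap_list("Species", xml_species("S", "cell", p$S0, lv)),
    wrap_list("Parameters", paste0(
      xml_parameter("kdeg", p$k1, lv, constant = FALSE),
      xml_parameter("k_late", p$k2, lv),
      xml_parameter("t_switch", p$T, lv))),
    wrap_list("Reactions", xml_reaction("degradation", "S", character(0),
      e_call("times", e_sym("kdeg"), e_sym("S")), lv)),
    events,
    sbml_footer)
  results <- closed_form_csv(times, "S", function(t) {
    early <- p$S0 * exp(-p$k1 * t)
    late <- p$S0 * exp(-p$k1 * p$T) * exp(-p$k2 * (t - p$T))
    list(ifelse(t < p$T, early, late))
  })
  list(sbml = sbml, variables = "S", results = results)
}

fixture_piecewise_input <- function(p, lv, times) {
  # dS/dt = (a while t < T, then 0) - k * S via a rate rule
  inflow <- e_piecewise(
    list(list(value = e_sym("a"), cond = e_call("lt", e_time(), e_sym("t_off")))),
    e_num(0))
  rate <- e_call("minus", inflow, e_call("times", e_sym("k"), e_sym("S")))
  rules <- paste0(
    "    <listOfRules>\n",
    "      <rateRule variable=\"S\">", write_mathml(rate), "</rateRule>\n",
    "    </listOfRules>\n")
  sbml <- paste0(
    sbml_header(lv, "piecewise_input"),
    wrap_list("Compartments", xml_compartment("cell", 1, lv)),
    wrap_list("Species", xml_species("S", "cell", p$S0, lv)),
    wrap_list("Parameters", paste0(
      xml_parameter("a", p$a, lv),
      xml_parameter("k", p$k, lv),
      xml_parameter("t_off", p$T, lv))),
    rules,
    sbml_footer)
  results <- closed_form_csv(times, "S", function(t) {
    eq <- p$a / p$k
    on_phase <- eq + (p$S0 - eq) * exp(-p$k * t)
    s_at_T <- eq + (p$S0 - eq) * exp(-p$k * p$T)
    off_phase <- s_at_T * exp(-p$k * (t - p$T))
    list(ifelse(t < p$T, on_phase, off_phase))
  })
  list(sbml = sbml, variables = "S", results = results)
}

fixture_boundary_feed <- function(p, lv, times) {
  sbml <- paste0(
    sbml_header(lv, "boundary_feed"),
    wrap_list("Compartments", xml_compartment("cell", 1, lv)),
    wrap_list("Species", paste0(
      xml_species("B", "cell", p$B0, lv, boundary = TRUE),
      xml_species("S", "cell", p$S0, lv))),
    wrap_list("Parameters", paste0(xml_parameter("kf", p$kf, lv),
                                   xml_parameter("d", p$d, lv))),
    wrap_list("Reactions", paste0(
      xml_reaction("feed", "B", "S",
                   e_call("times", e_sym("kf"), e_sym("B")), lv),
      xml_reaction("clear", "S", character(0),
                   e_call("times", e_sym("d"), e_sym("S")), lv))),
    sbml_footer)
  results <- closed_form_csv(times, c("S", "B"), function(t) {
    eq <- p$kf * p$B0 / p$d
    list(eq + (p$S0 - eq) * exp(-p$d * t), rep(p$B0, length(t)))
  })
  list(sbml = sbml, variables = c("S", "B"), results = results)
}

#' Write a deterministic mini suite of fixture cases
#'
#' Emits one case directory per (family, draw) in the test-suite
#' layout: `<case>-sbml-lXvY.xml`, `<case>-settings.txt`,
#' `<case>-results.csv`. Case numbering is a fixed enumeration of the
#' requested families and draws, and all parameter draws derive from
#' the seed through the counter-based scheme, so running the generator
#' twice produces byte-identical trees.
#'
#' Families without a closed form get their expected trajectory from
#' the fixed-step RK4 reference integrator ([rk4_trajectory()]); the
#' untranslatable family ships no expected CSV.
#'
#' @param out_dir Output directory (created if needed).
#' @param families Families to include.
#' @param n_random_per_family Number of random parameter draws each.
#' @param seed Integer seed for the counter-based draws.
#' @param rk4_step Step size for the RK4 reference trajectories.
#' @return The vector of case directories, invisibly.
#' @export
generate_mini_suite <- function(out_dir, families = FIXTURE_FAMILIES,
                                n_random_per_family = 1, seed = 1,
                                rk4_step = 1e-4) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  case_dirs <- character(0)
  idx <- 0L
  for (family in families) {
    for (draw in seq_len(n_random_per_family)) {
      idx <- idx + 1L
      fx <- generate_fixture(family, seed = seed, draw = draw)
      case_id <- sprintf("%05d-%s", idx, family)
      dir <- file.path(out_dir, case_id)
      dir.create(dir, showWarnings = FALSE)
      lv_tag <- sprintf("l%dv%d", fx$level_version[1], fx$level_version[2])
      writeLines(sub("\n$", "", fx$sbml),
                 file.path(dir, sprintf("%s-sbml-%s.xml", case_id, lv_tag)))
      writeLines(sub("\n$", "", fx$settings),
                 file.path(dir, sprintf("%s-settings.txt", case_id)))
      results <- fixture_results(fx, rk4_step)
      if (!is.null(results)) {
        writeLines(sub("\n$", "", results),
                   file.path(dir, sprintf("%s-results.csv", case_id)))
      }
      case_dirs <- c(case_dirs, dir)
    }
  }
  invisible(case_dirs)
}

# resolve a fixture's expected CSV, running the RK4 reference
# integrator for the families without a closed form
fixture_results <- function(fx, rk4_step = 1e-4) {
  if (is.null(fx$results)) return(NULL)
  if (!identical(fx$results, "rk4")) return(fx$results)
  sys <- build_ode_system(parse_sbml(fx$sbml))
  settings <- read_settings(fx$settings)
  tr <- rk4_trajectory(sys, settings_grid(settings), h = rk4_step)
  keep <- match(settings$variables, tr$columns)
  tr$columns <- settings$variables
  tr$values <- tr$values[, keep, drop = FALSE]
  write_trajectory_csv(tr)
}
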