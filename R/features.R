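# Unsupported-feature detection.
#
# A model is translatable if and only if the feature report is empty.
# The checks mirror the restrictions of the translation pipeline:
# compartment sizes other than one, algebraic rules, conversion factors,
# assignment rules for non-boundary species, events touching species or
# referencing their own target, fast reactions, plus structural gates
# (delayed events, stoichiometry math, unparsable MathML).

FEATURE_TAGS <- c(
  "compartment_size_ne_1", "algebraic_rule", "conversion_factor",
  "assignment_rule_nonboundary_species", "event_targets_species",
  "event_self_reference", "fast_reaction", "delayed_event",
  "variable_stoichiometry", "unsupported_package", "unsupported_mathml"
)

new_feature_report <- function(findings, warnings = character(0)) {
  structure(list(findings = findings, warnings = warnings),
            class = "feature_report")
}

#' Scan a parsed model for unsupported features
#'
#' Returns a report with one finding per violating element. An empty
#' report means the model can be compiled with [build_ode_system()].
#' Event triggers that merely reference species are recorded as
#' warnings, not findings; only assignments that *target* a species are
#' refused.
#'
#' @param model An `sbml_model` from [parse_sbml()].
#' @return A `feature_report` with `findings` (list of
#'   `feature_tag`/`element_id`/`message`) and `warnings`.
#' @export
#' @examples
#' rep <- detect_unsupported(parse_sbml(generate_fixture("decay")$sbml))
#' report_is_clean(rep)
detect_unsupported <- function(model) {
  findings <- list()
  warnings <- character(0)
  add <- function(tag, id, msg) {
    findings[[length(findings) + 1L]] <<-
      list(feature_tag = tag, element_id = id, message = msg)
  }

  sp_ids <- vapply(model$species, `[[`, character(1), "id")
  boundary <- stats::setNames(
    vapply(model$species, `[[`, logical(1), "boundary_condition"), sp_ids)

  rule_targets <- vapply(model$rules, function(r) {
    if (is.na(r$variable)) "" else r$variable
  }, character(1))

  for (cmp in model$compartments) {
    if (!is.na(cmp$size) && cmp$size != 1) {
      add("compartment_size_ne_1", cmp$id,
          sprintf("compartment '%s' has size %s; only size 1 is supported",
                  cmp$id, format(cmp$size)))
    }
    if (!cmp$constant && cmp$id %in% rule_targets) {
      add("compartment_size_ne_1", cmp$id,
          sprintf("compartment '%s' is non-constant and rule-governed", cmp$id))
    }
  }

  if (isTRUE(model$has_model_conversion_factor)) {
    add("conversion_factor", model$model_id, "model declares a conversionFactor")
  }
  for (sp in model$species) {
    if (isTRUE(sp$has_conversion_factor)) {
      add("conversion_factor", sp$id,
          sprintf("species '%s' declares a conversionFactor", sp$id))
    }
  }

  for (r in model$rules) {
    if (r$rule_kind == "algebraic") {
      add("algebraic_rule", "algebraicRule", "algebraic rules are not supported")
    } else if (r$rule_kind == "assignment" && r$variable %in% sp_ids &&
               !isTRUE(boundary[[r$variable]])) {
      add("assignment_rule_nonboundary_species", r$variable,
          sprintf("assignment rule targets non-boundary species '%s'",
                  r$variable))
    }
  }

  for (rx in model$reactions) {
    if (isTRUE(rx$fast)) {
      add("fast_reaction", rx$id, sprintf("reaction '%s' is fast", rx$id))
    }
    refs <- c(rx$reactants, rx$products)
    for (sr in refs) {
      if (isTRUE(sr$has_stoichiometry_math)) {
        add("variable_stoichiometry", rx$id,
            sprintf("reaction '%s' uses stoichiometryMath", rx$id))
      }
    }
  }

  for (ev in model$events) {
    if (isTRUE(ev$has_delay)) {
      add("delayed_event", ev$id,
          sprintf("event '%s' has a delay or priority", ev$id))
    }
    for (ea in ev$assignments) {
      if (ea$variable %in% sp_ids) {
        add("event_targets_species", ev$id,
            sprintf("event '%s' assigns to species '%s'", ev$id, ea$variable))
      }
      if (!is.null(ea$math) && ea$variable %in% expr_symbols(ea$math)) {
        add("event_self_reference", ev$id,
            sprintf("event '%s' assignment to '%s' references itself",
                    ev$id, ea$variable))
      }
    }
    if (!is.null(ev$trigger)) {
      trig_species <- intersect(expr_symbols(ev$trigger), sp_ids)
      if (length(trig_species) > 0) {
        warnings <- c(warnings,
          sprintf("event '%s' trigger references species: %s",
                  ev$id, paste(trig_species, collapse = ", ")))
      }
    }
  }

  for (bm in model$unsupported_math) {
    add("unsupported_mathml", bm$element_id, bm$message)
  }

  new_feature_report(findings, warnings)
}

#' @rdname detect_unsupported
#' @param report A `feature_report`.
#' @export
report_is_clean <- function(report) {
  length(report$findings) == 0L
}

#' @rdname detect_unsupported
#' @export
report_tags <- function(report) {
  vapply(report$findings, `[[`, character(1), "feature_tag")
}

#' @export
print.feature_report <- function(x, ...) {
  if (report_is_clean(x)) {
    cat("<feature_report: clean (translatable)>\n")
  } else {
    cat(sprintf("<feature_report: %d finding(s)>\n", length(x$findings)))
    for (f in x$findings) {
      cat(sprintf("  [%s] %s: %s\n", f$feature_tag, f$element_id, f$message))
    }
  }
  for (w in x$warnings) cat(sprintf("  warning: %s\n", w))
  invisible(x)
}
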