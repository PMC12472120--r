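# SBML Level 2/3 core reader.
#
# Produces a faithful intermediate representation (class "sbml_model")
# of one model: compartments, species, parameters, reactions, rules,
# events, function definitions and initial assignments, with SBML
# defaults applied. MathML subtrees that use unsupported constructs do
# not abort the parse; they are replaced by a NaN literal and recorded
# so that detect_unsupported() can report them.

attr_chr <- function(node, name, default = NA_character_) {
  v <- xml2::xml_attr(node, name)
  if (is.na(v)) default else v
}

attr_num <- function(node, name) {
  v <- xml2::xml_attr(node, name)
  if (is.na(v)) NA_real_ else suppressWarnings(as.numeric(v))
}

attr_flag <- function(node, name, default) {
  v <- xml2::xml_attr(node, name)
  if (is.na(v)) default else identical(v, "true") || identical(v, "1")
}

find_list_of <- function(model_node, name) {
  for (kid in xml2::xml_children(model_node)) {
    if (local_name(kid) == name) return(element_children(kid))
  }
  list()
}

find_child <- function(node, name) {
  for (kid in xml2::xml_children(node)) {
    if (local_name(kid) == name) return(kid)
  }
  NULL
}

#' Parse an SBML document into the intermediate representation
#'
#' Accepts SBML Level 2 (versions 1-5) and Level 3 (versions 1-2) core
#' documents. Level 1 documents and documents requiring an SBML package
#' (comp, fbc, qual, ...) are rejected with an unsupported-document
#' error. Formulas using MathML constructs outside the supported subset
#' are kept as placeholders and surface as findings in
#' [detect_unsupported()].
#'
#' @param xml_text SBML document as a string, or a path to a file.
#' @return An object of class `sbml_model` with fields `model_id`,
#'   `level`, `version`, `compartments`, `species`, `parameters`,
#'   `reactions`, `rules`, `events`, `function_defs`,
#'   `initial_assignments` and bookkeeping flags used by feature
#'   detection.
#' @export
#' @examples
#' m <- parse_sbml(generate_fixture("decay")$sbml)
#' length(m$species)
parse_sbml <- function(xml_text) {
  doc <- tryCatch(
    xml2::read_xml(xml_text),
    error = function(e) {
      abort_parse(paste0("malformed XML: ", conditionMessage(e)))
    }
  )
  root <- xml2::xml_root(doc)
  if (local_name(root) != "sbml") {
    abort_parse("root element is not <sbml>")
  }
  level <- suppressWarnings(as.integer(xml2::xml_attr(root, "level")))
  version <- suppressWarnings(as.integer(xml2::xml_attr(root, "version")))
  if (is.na(level) || is.na(version)) {
    abort_parse("missing level/version attributes on <sbml>")
  }
  if (level == 1L) {
    abort_unsupported_document("SBML Level 1 is not supported")
  }
  if (!(level == 2L && version %in% 1:5) &&
      !(level == 3L && version %in% 1:2)) {
    abort_unsupported_document(
      sprintf("SBML Level %d Version %d is not supported", level, version))
  }
  # any package declared required on the document is a hard gate
  attrs <- xml2::xml_attrs(root)
  # package declarations carry a (namespaced) "required" attribute
  req <- attrs[names(attrs) == "required" | grepl(":required$", names(attrs))]
  if (any(req == "true")) {
    abort_unsupported_document(
      "document requires an SBML package (comp/fbc/...), which is not supported")
  }

  model_node <- find_child(root, "model")
  if (is.null(model_node)) abort_parse("no <model> element")

  bad_math <- list()  # (element_id, message) for unsupported MathML
  grab_math <- function(parent, element_id) {
    mnode <- find_child(parent, "math")
    if (is.null(mnode)) return(NULL)
    tryCatch(
      parse_mathml(mnode),
      sbml_unsupported_mathml = function(e) {
        bad_math[[length(bad_math) + 1L]] <<-
          list(element_id = element_id, message = conditionMessage(e))
        e_num(NaN)
      }
    )
  }

  compartments <- lapply(find_list_of(model_node, "listOfCompartments"),
    function(n) {
      list(id = attr_chr(n, "id"),
           size = {
             s <- attr_num(n, "size")
             if (is.na(s) && level == 2L) s <- attr_num(n, "volume")
             s
           },
           constant = attr_flag(n, "constant", TRUE))
    })

  species <- lapply(find_list_of(model_node, "listOfSpecies"), function(n) {
    amt <- attr_num(n, "initialAmount")
    conc <- attr_num(n, "initialConcentration")
    initial_kind <- if (!is.na(amt)) "amount"
                    else if (!is.na(conc)) "concentration"
                    else "unset"
    list(id = attr_chr(n, "id"),
         name = attr_chr(n, "name", ""),
         compartment_id = attr_chr(n, "compartment"),
         initial_value = if (!is.na(amt)) amt
                         else if (!is.na(conc)) conc
                         else NA_real_,
         initial_kind = initial_kind,
         boundary_condition = attr_flag(n, "boundaryCondition", FALSE),
         constant = attr_flag(n, "constant", FALSE),
         has_conversion_factor = !is.na(xml2::xml_attr(n, "conversionFactor")))
  })

  parameters <- lapply(find_list_of(model_node, "listOfParameters"),
    function(n) {
      list(id = attr_chr(n, "id"),
           value = attr_num(n, "value"),
           constant = attr_flag(n, "constant", TRUE))
    })

  function_defs <- lapply(find_list_of(model_node, "listOfFunctionDefinitions"),
    function(n) {
      fid <- attr_chr(n, "id")
      mnode <- find_child(n, "math")
      lam <- if (!is.null(mnode)) find_child(mnode, "lambda") else NULL
      if (is.null(lam)) {
        abort_parse(sprintf("function definition '%s' has no lambda", fid))
      }
      arg_names <- character(0)
      body <- NULL
      for (kid in element_children(lam)) {
        if (local_name(kid) == "bvar") {
          ci <- find_child(kid, "ci")
          arg_names <- c(arg_names, trimws(xml2::xml_text(ci)))
        } else {
          body <- tryCatch(
            parse_mathml(kid),
            sbml_unsupported_mathml = function(e) {
              bad_math[[length(bad_math) + 1L]] <<-
                list(element_id = fid, message = conditionMessage(e))
              e_num(NaN)
            })
        }
      }
      if (is.null(body)) {
        abort_parse(sprintf("function definition '%s' has no body", fid))
      }
      list(id = fid, arg_names = arg_names, body = body)
    })

  parse_species_refs <- function(rnode, list_name) {
    out <- list()
    lst <- find_child(rnode, list_name)
    if (is.null(lst)) return(out)
    for (sr in element_children(lst)) {
      stoich <- attr_num(sr, "stoichiometry")
      if (is.na(stoich)) stoich <- 1
      has_math <- !is.null(find_child(sr, "stoichiometryMath"))
      out[[length(out) + 1L]] <- list(species_id = attr_chr(sr, "species"),
                                      stoichiometry = stoich,
                                      has_stoichiometry_math = has_math)
    }
    out
  }

  reactions <- lapply(find_list_of(model_node, "listOfReactions"),
    function(n) {
      rid <- attr_chr(n, "id")
      klaw <- find_child(n, "kineticLaw")
      math <- NULL
      local_parameters <- list()
      if (!is.null(klaw)) {
        math <- grab_math(klaw, rid)
        lp_list <- find_child(klaw, "listOfLocalParameters")
        if (is.null(lp_list)) lp_list <- find_child(klaw, "listOfParameters")
        if (!is.null(lp_list)) {
          for (lp in element_children(lp_list)) {
            local_parameters[[length(local_parameters) + 1L]] <-
              list(id = attr_chr(lp, "id"), value = attr_num(lp, "value"))
          }
        }
      }
      modifiers <- vapply(
        if (is.null(find_child(n, "listOfModifiers"))) list()
        else element_children(find_child(n, "listOfModifiers")),
        function(m) attr_chr(m, "species"), character(1))
      # local kinetic parameters are renamed into the global namespace
      if (length(local_parameters) > 0 && !is.null(math)) {
        map <- stats::setNames(
          paste0(rid, "__", vapply(local_parameters, `[[`, character(1), "id")),
          vapply(local_parameters, `[[`, character(1), "id"))
        math <- expr_rename(math, map)
        local_parameters <- lapply(local_parameters, function(lp) {
          lp$id <- paste0(rid, "__", lp$id)
          lp
        })
      }
      list(id = rid,
           reactants = parse_species_refs(n, "listOfReactants"),
           products = parse_species_refs(n, "listOfProducts"),
           modifiers = as.character(modifiers),
           kinetic_law = math,
           local_parameters = local_parameters,
           fast = attr_flag(n, "fast", FALSE))
    })

  rules <- lapply(find_list_of(model_node, "listOfRules"), function(n) {
    kind <- switch(local_name(n),
      assignmentRule = "assignment",
      rateRule = "rate",
      algebraicRule = "algebraic",
      abort_parse(sprintf("unknown rule element <%s>", local_name(n))))
    variable <- attr_chr(n, "variable")
    rule_id <- if (!is.na(variable)) variable else local_name(n)
    list(rule_kind = kind,
         variable = variable,
         math = grab_math(n, rule_id))
  })

  events <- lapply(find_list_of(model_node, "listOfEvents"), function(n) {
    eid <- attr_chr(n, "id", "event")
    trig_node <- find_child(n, "trigger")
    trigger <- if (!is.null(trig_node)) grab_math(trig_node, eid) else NULL
    initial_trigger_value <- if (!is.null(trig_node)) {
      attr_flag(trig_node, "initialValue", TRUE)
    } else TRUE
    has_delay <- !is.null(find_child(n, "delay")) ||
      !is.null(find_child(n, "priority"))
    assignments <- list()
    ea_list <- find_child(n, "listOfEventAssignments")
    if (!is.null(ea_list)) {
      for (ea in element_children(ea_list)) {
        assignments[[length(assignments) + 1L]] <-
          list(variable = attr_chr(ea, "variable"),
               math = grab_math(ea, eid))
      }
    }
    list(id = eid, trigger = trigger, assignments = assignments,
         initial_trigger_value = initial_trigger_value,
         has_delay = has_delay)
  })

  initial_assignments <- lapply(
    find_list_of(model_node, "listOfInitialAssignments"), function(n) {
      sym <- attr_chr(n, "symbol")
      list(symbol = sym, math = grab_math(n, sym))
    })

  model <- structure(list(
    model_id = attr_chr(model_node, "id", "model"),
    level = level,
    version = version,
    compartments = compartments,
    species = species,
    parameters = parameters,
    reactions = reactions,
    rules = rules,
    events = events,
    function_defs = function_defs,
    initial_assignments = initial_assignments,
    has_model_conversion_factor =
      !is.na(xml2::xml_attr(model_node, "conversionFactor")),
    unsupported_math = bad_math
  ), class = "sbml_model")

  validate_model_ids(model)
  model
}

validate_model_ids <- function(model) {
  ids <- c(
    vapply(model$compartments, `[[`, character(1), "id"),
    vapply(model$species, `[[`, character(1), "id"),
    vapply(model$parameters, `[[`, character(1), "id"),
    vapply(model$reactions, `[[`, character(1), "id"),
    vapply(model$function_defs, `[[`, character(1), "id"),
    unlist(lapply(model$reactions, function(r) {
      vapply(r$local_parameters, `[[`, character(1), "id")
    }))
  )
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    abort_validation(sprintf("duplicate identifier(s): %s",
                             paste(dup, collapse = ", ")))
  }
  comp_ids <- vapply(model$compartments, `[[`, character(1), "id")
  for (sp in model$species) {
    if (!is.na(sp$compartment_id) && !(sp$compartment_id %in% comp_ids)) {
      abort_validation(sprintf("species '%s' references unknown compartment '%s'",
                               sp$id, sp$compartment_id))
    }
  }
  sp_ids <- vapply(model$species, `[[`, character(1), "id")
  for (r in model$reactions) {
    refs <- c(
      vapply(r$reactants, `[[`, character(1), "species_id"),
      vapply(r$products, `[[`, character(1), "species_id"),
      r$modifiers)
    bad <- setdiff(refs, sp_ids)
    if (length(bad) > 0) {
      abort_validation(sprintf("reaction '%s' references unknown species: %s",
                               r$id, paste(bad, collapse = ", ")))
    }
  }
  invisible(model)
}

#' @export
print.sbml_model <- function(x, ...) {
  cat(sprintf("<sbml_model '%s' L%dV%d>\n", x$model_id, x$level, x$version))
  cat(sprintf("  compartments: %d  species: %d  parameters: %d\n",
              length(x$compartments), length(x$species), length(x$parameters)))
  cat(sprintf("  reactions: %d  rules: %d  events: %d  functions: %d\n",
              length(x$reactions), length(x$rules), length(x$events),
              length(x$function_defs)))
  invisible(x)
}
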