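# Reaction network -> executable ODE system.
#
# States are the non-boundary, non-constant species (document order)
# followed by rate-rule-governed parameters and parameters promoted
# because an event assigns to them. Each state's derivative is the sum
# over reactions of net stoichiometry times kinetic law, or its rate
# rule. Assignment rules become an ordered derived-quantity list.
# Compartment sizes are pinned to one by the feature gate, so kinetic
# laws are rates in substance per time and no volume factors appear.

#' Inline user-defined function calls
#'
#' Substitutes every application of a function definition by its body
#' with the actual arguments bound to the formal names. Substitution is
#' capture-free because a function body may reference only its own
#' formals. Definitions may call other definitions, but cycles are
#' refused.
#'
#' @param expr Expression node.
#' @param defs List of function definitions (`id`, `arg_names`, `body`).
#' @return Expression with no user-function calls left.
#' @export
inline_functions <- function(expr, defs) {
  if (length(defs) == 0) return(expr)
  by_id <- stats::setNames(defs, vapply(defs, `[[`, character(1), "id"))
  walk <- function(e, stack) {
    switch(e$kind,
      number = e,
      symbol = e,
      time = e,
      call = {
        args <- lapply(e$args, walk, stack = stack)
        if (e$op %in% BUILTIN_OPS) {
          e_call(e$op, args = args)
        } else {
          def <- by_id[[e$op]]
          if (is.null(def)) {
            abort_compile(sprintf("unknown function '%s'", e$op))
          }
          if (e$op %in% stack) {
            abort_compile(sprintf(
              "recursive function definition involving '%s'", e$op))
          }
          if (length(args) != length(def$arg_names)) {
            abort_compile(sprintf(
              "function '%s' called with %d argument(s), expects %d",
              e$op, length(args), length(def$arg_names)))
          }
          body <- expr_substitute(def$body,
                                  stats::setNames(args, def$arg_names))
          walk(body, stack = c(stack, e$op))
        }
      },
      piecewise = e_piecewise(
        lapply(e$pieces, function(p) list(value = walk(p$value, stack),
                                          cond = walk(p$cond, stack))),
        if (!is.null(e$otherwise)) walk(e$otherwise, stack)
      )
    )
  }
  walk(expr, character(0))
}

#' Topologically order assignment rules
#'
#' Orders `(id, expression)` pairs so that each expression references
#' only earlier entries (besides states, constants and time). Ties are
#' broken by document order. A dependency cycle is an error naming the
#' variables on the cycle.
#'
#' @param rules List of `list(variable =, math =)` assignment rules.
#' @return Ordered list of `list(id =, expr =)`.
#' @export
order_assignments <- function(rules) {
  n <- length(rules)
  if (n == 0) return(list())
  ids <- vapply(rules, `[[`, character(1), "variable")
  if (anyDuplicated(ids)) {
    abort_compile(sprintf("multiple assignment rules for: %s",
                          paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  deps <- lapply(rules, function(r) intersect(expr_symbols(r$math), ids))
  ordered <- integer(0)
  placed <- rep(FALSE, n)
  repeat {
    progress <- FALSE
    for (i in seq_len(n)) {
      if (placed[i]) next
      if (all(deps[[i]] %in% ids[ordered])) {
        ordered <- c(ordered, i)
        placed[i] <- TRUE
        progress <- TRUE
      }
    }
    if (all(placed)) break
    if (!progress) {
      abort_compile(sprintf("assignment rule dependency cycle among: %s",
                            paste(ids[!placed], collapse = ", ")))
    }
  }
  lapply(ordered, function(i) list(id = ids[i], expr = rules[[i]]$math))
}

#' Compile a translatable model to an ODE system
#'
#' Precondition: [detect_unsupported()] reports no findings. The result
#' holds the ordered state vector, one derivative expression per state,
#' the ordered derived-quantity list from assignment rules, a constants
#' table, an initial-value program and the compiled events.
#'
#' @param model An `sbml_model`.
#' @return An object of class `ode_system`.
#' @export
#' @examples
#' sys <- build_ode_system(parse_sbml(generate_fixture("decay")$sbml))
#' sys$state_ids
build_ode_system <- function(model) {
  report <- detect_unsupported(model)
  if (!report_is_clean(report)) {
    abort_compile(paste0("model has unsupported features: ",
                         paste(report_tags(report), collapse = ", ")))
  }

  defs <- model$function_defs
  inl <- function(e) if (is.null(e)) NULL else inline_functions(e, defs)

  sp_ids <- vapply(model$species, `[[`, character(1), "id")
  par_ids <- vapply(model$parameters, `[[`, character(1), "id")
  comp_ids <- vapply(model$compartments, `[[`, character(1), "id")

  rate_rules <- Filter(function(r) r$rule_kind == "rate", model$rules)
  assign_rules <- Filter(function(r) r$rule_kind == "assignment", model$rules)
  rate_targets <- vapply(rate_rules, `[[`, character(1), "variable")
  assign_targets <- vapply(assign_rules, function(r) r$variable, character(1))
  if (length(assign_targets) == 0) assign_targets <- character(0)

  # net stoichiometry per species per reaction
  net_stoich <- function(rx, sid) {
    s <- 0
    for (sr in rx$reactants) if (sr$species_id == sid) s <- s - sr$stoichiometry
    for (sr in rx$products) if (sr$species_id == sid) s <- s + sr$stoichiometry
    s
  }

  in_reactions <- function(sid) {
    any(vapply(model$reactions, function(rx) net_stoich(rx, sid) != 0,
               logical(1)))
  }

  state_ids <- character(0)
  derivatives <- list()
  constants <- list()
  state_initials <- list()  # declared numeric initial values of states

  add_state <- function(id, expr, initial = NA_real_) {
    state_ids[[length(state_ids) + 1L]] <<- id
    derivatives[[id]] <<- expr
    if (!is.na(initial)) state_initials[[id]] <<- initial
  }

  # species classification, document order
  for (sp in model$species) {
    sid <- sp$id
    if (sid %in% assign_targets) {
      next  # boundary species under an assignment rule -> derived
    }
    if (sid %in% rate_targets) {
      if (in_reactions(sid) && !sp$boundary_condition) {
        abort_compile(sprintf(
          "species '%s' is both rate-ruled and changed by reactions", sid))
      }
      rule <- rate_rules[[match(sid, rate_targets)]]
      add_state(sid, inl(rule$math), initial = sp$initial_value)
      next
    }
    if (sp$boundary_condition || sp$constant) {
      constants[[sid]] <- sp$initial_value
      next
    }
    # ordinary state: sum of net stoichiometry x kinetic law
    terms <- list()
    for (rx in model$reactions) {
      nu <- net_stoich(rx, sid)
      if (nu == 0) next
      if (is.null(rx$kinetic_law)) {
        abort_compile(sprintf("reaction '%s' has no kinetic law", rx$id))
      }
      law <- inl(rx$kinetic_law)
      term <- if (nu == 1) law
              else if (nu == -1) e_call("minus", law)
              else e_call("times", e_num(nu), law)
      terms[[length(terms) + 1L]] <- term
    }
    dexpr <- if (length(terms) == 0) e_num(0)
             else if (length(terms) == 1) terms[[1L]]
             else e_call("plus", args = terms)
    add_state(sid, dexpr, initial = sp$initial_value)
  }

  # parameters: rate-ruled -> states; assignment-ruled -> derived;
  # otherwise constants
  for (p in model$parameters) {
    if (p$id %in% assign_targets) next
    if (p$id %in% rate_targets) {
      rule <- rate_rules[[match(p$id, rate_targets)]]
      add_state(p$id, inl(rule$math), initial = p$value)
    } else {
      constants[[p$id]] <- p$value
    }
  }

  # compartments (size pinned to 1; absent size means 1)
  for (cmp in model$compartments) {
    if (cmp$id %in% c(assign_targets, rate_targets)) {
      abort_compile(sprintf("rule-governed compartment '%s' is not supported",
                            cmp$id))
    }
    constants[[cmp$id]] <- if (is.na(cmp$size)) 1 else cmp$size
  }

  # kinetic-law local parameters (already namespaced by the reader)
  for (rx in model$reactions) {
    for (lp in rx$local_parameters) constants[[lp$id]] <- lp$value
  }

  # derived quantities in evaluation order
  derived <- order_assignments(lapply(assign_rules, function(r) {
    list(variable = r$variable, math = inl(r$math))
  }))

  # events; parameters they assign to are promoted to zero-derivative
  # states so the constants table stays immutable
  events <- list()
  for (ev in model$events) {
    if (is.null(ev$trigger)) {
      abort_compile(sprintf("event '%s' has no trigger", ev$id))
    }
    assignments <- lapply(ev$assignments, function(ea) {
      list(target = ea$variable, expr = inl(ea$math))
    })
    for (ea in assignments) {
      tgt <- ea$target
      if (tgt %in% state_ids) next
      if (tgt %in% names(constants)) {
        val <- constants[[tgt]]
        constants[[tgt]] <- NULL
        add_state(tgt, e_num(0),
                  initial = if (is.null(val)) NA_real_ else val)
      } else {
        abort_compile(sprintf(
          "event '%s' assigns to '%s', which is neither a state nor a parameter",
          ev$id, tgt))
      }
    }
    events[[length(events) + 1L]] <- list(
      id = ev$id,
      trigger = inl(ev$trigger),
      assignments = assignments,
      initial_trigger_value = ev$initial_trigger_value)
  }

  # drop NA constants that are never resolvable
  const_num <- constants

  # initial assignments, split into constant-targeting (resolved now)
  # and state-targeting (kept in the initial program)
  ia <- lapply(model$initial_assignments, function(x) {
    list(symbol = x$symbol, math = inl(x$math))
  })
  ia_syms <- vapply(ia, `[[`, character(1), "symbol")
  ia_sorted <- topo_sort_initial(ia, ia_syms)

  base_env <- const_num[!vapply(const_num, function(v) is.null(v) || is.na(v),
                                logical(1))]
  # plain declared initial values, seeded so initial assignments may
  # reference them
  plain_initials <- state_initials

  eval_env <- c(base_env, plain_initials)
  for (x in ia_sorted) {
    v <- evaluate(x$math, eval_env, t = 0)
    eval_env[[x$symbol]] <- v
    if (x$symbol %in% names(const_num)) const_num[[x$symbol]] <- v
  }

  # final constants table must be fully numeric
  for (nm in names(const_num)) {
    if (is.null(const_num[[nm]]) || is.na(const_num[[nm]])) {
      if (nm %in% unlist(lapply(c(unname(derivatives),
                                  lapply(derived, `[[`, "expr"),
                                  lapply(events, `[[`, "trigger")),
                                expr_symbols))) {
        abort_compile(sprintf("'%s' has no value and no initial assignment", nm))
      }
      const_num[[nm]] <- NA_real_
    }
  }

  # initial program: constants, then plain initial values, then initial
  # assignments in dependency order
  initial_program <- c(
    lapply(names(const_num), function(nm) list(id = nm,
                                               expr = e_num0(const_num[[nm]]))),
    lapply(names(plain_initials), function(nm) {
      list(id = nm, expr = e_num(plain_initials[[nm]]))
    }),
    lapply(ia_sorted, function(x) list(id = x$symbol, expr = x$math))
  )

  covered <- c(names(plain_initials), ia_syms)
  missing <- setdiff(state_ids, covered)
  if (length(missing) > 0) {
    abort_compile(sprintf(
      "state(s) with neither initial value nor initial assignment: %s",
      paste(missing, collapse = ", ")))
  }

  sys <- structure(list(
    state_ids = state_ids,
    derivatives = derivatives[state_ids],
    derived = derived,
    constants = const_num,
    initial_program = initial_program,
    events = events,
    source_model_id = model$model_id
  ), class = "ode_system")
  validate_ode_system(sys)
  sys
}

e_num0 <- function(v) if (is.na(v)) e_num(0) else e_num(v)

topo_sort_initial <- function(ia, syms) {
  if (length(ia) == 0) return(list())
  deps <- lapply(ia, function(x) intersect(expr_symbols(x$math), syms))
  ordered <- integer(0)
  placed <- rep(FALSE, length(ia))
  repeat {
    progress <- FALSE
    for (i in seq_along(ia)) {
      if (placed[i]) next
      if (all(deps[[i]] %in% syms[ordered])) {
        ordered <- c(ordered, i); placed[i] <- TRUE; progress <- TRUE
      }
    }
    if (all(placed)) break
    if (!progress) {
      abort_compile(sprintf("initial assignment dependency cycle among: %s",
                            paste(syms[!placed], collapse = ", ")))
    }
  }
  ia[ordered]
}

#' Check the internal consistency of a compiled system
#'
#' Asserts symbol closure (every referenced symbol is a state, derived
#' quantity, constant or time), topological ordering of the derived
#' list, and disjointness of the three namespaces.
#'
#' @param sys An `ode_system`.
#' @return The system, invisibly; errors on violation.
#' @export
validate_ode_system <- function(sys) {
  states <- sys$state_ids
  derived_ids <- vapply(sys$derived, `[[`, character(1), "id")
  const_ids <- names(sys$constants)
  if (length(intersect(states, derived_ids)) > 0 ||
      length(intersect(states, const_ids)) > 0 ||
      length(intersect(derived_ids, const_ids)) > 0) {
    abort_compile("state, derived and constant namespaces overlap")
  }
  known <- c(states, derived_ids, const_ids)
  check <- function(e, where, allowed = known) {
    bad <- setdiff(expr_symbols(e), allowed)
    if (length(bad) > 0) {
      abort_compile(sprintf("%s references unknown symbol(s): %s",
                            where, paste(bad, collapse = ", ")))
    }
  }
  for (sid in states) check(sys$derivatives[[sid]], sprintf("deriv(%s)", sid))
  for (i in seq_along(sys$derived)) {
    allowed <- c(states, const_ids, derived_ids[seq_len(i - 1L)])
    check(sys$derived[[i]]$expr, sprintf("derived '%s'", derived_ids[i]),
          allowed)
  }
  for (ev in sys$events) {
    check(ev$trigger, sprintf("event '%s' trigger", ev$id))
    for (ea in ev$assignments) {
      check(ea$expr, sprintf("event '%s' assignment", ev$id))
      if (ea$target %in% expr_symbols(ea$expr)) {
        abort_compile(sprintf("event '%s' assignment to '%s' is self-referencing",
                              ev$id, ea$target))
      }
    }
  }
  invisible(sys)
}

#' @export
print.ode_system <- function(x, ...) {
  cat(sprintf("<ode_system '%s': %d state(s), %d derived, %d constant(s), %d event(s)>\n",
              x$source_model_id, length(x$state_ids), length(x$derived),
              length(x$constants), length(x$events)))
  invisible(x)
}
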