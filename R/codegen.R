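# Rendering a compiled system as readable declarative equation text and
# as a compiled-model JSON document for external viewers.
#
# Both renderings are pure functions of the system and byte-stable:
# rendering the same system twice yields identical text. Numbers use
# the shortest decimal representation that round-trips through a
# double (fmt_num), so JSON -> parse -> JSON is the identity.

# infix precedence levels (higher binds tighter)
PREC <- c(or = 1, and = 2, not = 3,
          eq = 4, neq = 4, lt = 4, leq = 4, gt = 4, geq = 4,
          plus = 5, minus = 5, times = 6, divide = 6,
          uminus = 7, power = 8)

INFIX_SYM <- c(plus = "+", minus = "-", times = "*", divide = "/",
               power = "^", eq = "==", neq = "!=", lt = "<", leq = "<=",
               gt = ">", geq = ">=", and = "&&", or = "||")

#' Render an expression with infix syntax and minimal parentheses
#'
#' @param expr Expression node.
#' @return A string such as `-(k * S)` or `if (t < 5) 1 else 0`.
#' @export
render_infix <- function(expr) {
  ri(expr, 0)
}

ri <- function(e, parent_prec) {
  switch(e$kind,
    number = fmt_num(e$value),
    symbol = e$name,
    time = "t",
    call = ri_call(e, parent_prec),
    piecewise = {
      parts <- vapply(e$pieces, function(p) {
        paste0("if (", ri(p$cond, 0), ") ", ri(p$value, 9))
      }, character(1))
      tail <- if (!is.null(e$otherwise)) {
        paste0(" else ", ri(e$otherwise, 9))
      } else ""
      wrap(paste0(paste(parts, collapse = " else "), tail),
           0, parent_prec)
    }
  )
}

wrap <- function(s, prec, parent_prec) {
  if (prec < parent_prec) paste0("(", s, ")") else s
}

ri_call <- function(e, parent_prec) {
  op <- e$op
  n <- length(e$args)
  if (op == "minus" && n == 1L) {
    arg <- e$args[[1L]]
    inner <- if (arg$kind %in% c("call", "piecewise")) {
      paste0("(", ri(arg, 0), ")")
    } else {
      ri(arg, PREC[["uminus"]])
    }
    return(wrap(paste0("-", inner), PREC[["uminus"]], parent_prec))
  }
  if (op == "not") {
    return(wrap(paste0("!", ri(e$args[[1L]], PREC[["not"]] + 1)),
                PREC[["not"]], parent_prec))
  }
  if (op %in% names(INFIX_SYM) && n >= 2L) {
    prec <- PREC[[op]]
    right_assoc <- op == "power"
    # left operand at own precedence, right operand one tighter (or the
    # mirror image for right-associative power)
    pieces <- character(n)
    for (i in seq_len(n)) {
      child_prec <- if (i == 1L) {
        if (right_assoc) prec + 1 else prec
      } else {
        if (right_assoc && i == n) prec else prec + 1
      }
      pieces[i] <- ri(e$args[[i]], child_prec)
    }
    return(wrap(paste(pieces, collapse = paste0(" ", INFIX_SYM[[op]], " ")),
                prec, parent_prec))
  }
  # function-style rendering (exp, ln, min, root with degree, ...)
  paste0(op, "(", paste(vapply(e$args, ri, character(1), parent_prec = 0),
                        collapse = ", "), ")")
}

#' Render a compiled system as declarative equation text
#'
#' One line per constant (`const k = 1`), initial value
#' (`init S = 1`), derived quantity (`let p = 2 * k`, in evaluation
#' order, before any derivative that uses it) and derivative
#' (`deriv(S) = -(k * S)`). Ordering follows the compiler's stable
#' ordering, so repeated renderings are byte-identical.
#'
#' @param system An `ode_system`.
#' @return A single string (lines joined by `\n`, trailing newline).
#' @export
#' @examples
#' sys <- build_ode_system(parse_sbml(generate_fixture("decay")$sbml))
#' cat(render_equations(sys))
render_equations <- function(system) {
  lines <- character(0)
  add <- function(...) lines[[length(lines) + 1L]] <<- paste0(...)
  add("# model: ", system$source_model_id)
  for (nm in names(system$constants)) {
    v <- system$constants[[nm]]
    add("const ", nm, " = ", if (is.na(v)) "NA" else fmt_num(v))
  }
  init_vals <- initial_state_values(system)
  for (sid in system$state_ids) {
    add("init ", sid, " = ", fmt_num(init_vals[[sid]]))
  }
  for (d in system$derived) {
    add("let ", d$id, " = ", render_infix(d$expr))
  }
  for (sid in system$state_ids) {
    add("deriv(", sid, ") = ", render_infix(system$derivatives[[sid]]))
  }
  for (ev in system$events) {
    add("event ", ev$id, " when ", render_infix(ev$trigger), " {")
    for (ea in ev$assignments) {
      add("  ", ea$target, " <- ", render_infix(ea$expr))
    }
    add("}")
  }
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' Run a system's initial-value program
#'
#' Evaluates the ordered initial program at the given start time and
#' returns the numeric value of every state.
#'
#' @param system An `ode_system`.
#' @param t0 Time at which initial assignments are evaluated.
#' @return Named numeric vector over `system$state_ids`.
#' @export
initial_state_values <- function(system, t0 = 0) {
  env <- new.env(parent = emptyenv())
  for (entry in system$initial_program) {
    assign(entry$id, evaluate(entry$expr, env, t = t0), envir = env)
  }
  vapply(system$state_ids, function(sid) {
    v <- get0(sid, envir = env, inherits = FALSE)
    if (is.null(v)) {
      abort_compile(sprintf("initial program does not define state '%s'", sid))
    }
    v
  }, numeric(1))
}

# --- prefix-tree JSON ---------------------------------------------------

expr_to_tree <- function(e) {
  switch(e$kind,
    number = list(kind = "number", value = e$value),
    symbol = list(kind = "symbol", name = e$name),
    time = list(kind = "time"),
    call = list(kind = "call", op = e$op, args = lapply(e$args, expr_to_tree)),
    piecewise = list(
      kind = "piecewise",
      pieces = lapply(e$pieces, function(p) {
        list(value = expr_to_tree(p$value), cond = expr_to_tree(p$cond))
      }),
      otherwise = if (!is.null(e$otherwise)) expr_to_tree(e$otherwise)
    )
  )
}

tree_to_expr <- function(x) {
  switch(x$kind,
    number = e_num(x$value),
    symbol = e_sym(x$name),
    time = e_time(),
    call = e_call(x$op, args = lapply(x$args, tree_to_expr)),
    piecewise = e_piecewise(
      lapply(x$pieces, function(p) list(value = tree_to_expr(p$value),
                                        cond = tree_to_expr(p$cond))),
      if (!is.null(x$otherwise)) tree_to_expr(x$otherwise)
    ),
    abort_parse(sprintf("unknown expression node kind '%s'", x$kind))
  )
}

# Deterministic JSON emitter for the compiled-model schema. Identifiers
# are SBML SIds (no escaping beyond the JSON minimum is ever needed)
# and numbers use the shortest round-trip decimal form, which is what
# makes parse -> export the byte identity.
json_str <- function(s) {
  s <- gsub("\\", "\\\\", s, fixed = TRUE)
  s <- gsub("\"", "\\\"", s, fixed = TRUE)
  paste0("\"", s, "\"")
}

json_tree <- function(x) {
  if (is.null(x)) return("null")
  if (is.list(x) && !is.null(x$kind)) {
    fields <- switch(x$kind,
      number = paste0("\"kind\":\"number\",\"value\":", fmt_num(x$value)),
      symbol = paste0("\"kind\":\"symbol\",\"name\":", json_str(x$name)),
      time = "\"kind\":\"time\"",
      call = paste0("\"kind\":\"call\",\"op\":", json_str(x$op),
                    ",\"args\":[",
                    paste(vapply(x$args, json_tree, character(1)),
                          collapse = ","), "]"),
      piecewise = paste0(
        "\"kind\":\"piecewise\",\"pieces\":[",
        paste(vapply(x$pieces, function(p) {
          paste0("{\"value\":", json_tree(p$value),
                 ",\"cond\":", json_tree(p$cond), "}")
        }, character(1)), collapse = ","),
        "],\"otherwise\":", json_tree(x$otherwise))
    )
    return(paste0("{", fields, "}"))
  }
  stop("cannot serialize node")
}

#' Export a compiled system as a compiled-model JSON document
#'
#' Schema: `{model_id, states:[{id, initial}], constants:{id: value},
#' derived:[{id, expr}], derivatives:{id: expr}, events:[...]}` with
#' every expression serialized as a prefix tree (`kind`/`op`/`args`),
#' so that consumers need no formula parser. The document is
#' byte-stable: exporting the same system twice, or re-exporting after
#' [import_compiled_json()], yields identical bytes.
#'
#' @param system An `ode_system`.
#' @return JSON text (UTF-8, single line, trailing newline).
#' @export
export_compiled_json <- function(system) {
  init_vals <- initial_state_values(system)
  states <- paste(vapply(system$state_ids, function(sid) {
    paste0("{\"id\":", json_str(sid),
           ",\"initial\":", fmt_num(init_vals[[sid]]), "}")
  }, character(1)), collapse = ",")
  consts <- paste(vapply(names(system$constants), function(nm) {
    v <- system$constants[[nm]]
    paste0(json_str(nm), ":", if (is.na(v)) "null" else fmt_num(v))
  }, character(1)), collapse = ",")
  derived <- paste(vapply(system$derived, function(d) {
    paste0("{\"id\":", json_str(d$id),
           ",\"expr\":", json_tree(expr_to_tree(d$expr)), "}")
  }, character(1)), collapse = ",")
  derivs <- paste(vapply(system$state_ids, function(sid) {
    paste0(json_str(sid), ":",
           json_tree(expr_to_tree(system$derivatives[[sid]])))
  }, character(1)), collapse = ",")
  events <- paste(vapply(system$events, function(ev) {
    asg <- paste(vapply(ev$assignments, function(ea) {
      paste0("{\"target\":", json_str(ea$target),
             ",\"expr\":", json_tree(expr_to_tree(ea$expr)), "}")
    }, character(1)), collapse = ",")
    paste0("{\"id\":", json_str(ev$id),
           ",\"trigger\":", json_tree(expr_to_tree(ev$trigger)),
           ",\"initial_trigger_value\":",
           if (isTRUE(ev$initial_trigger_value)) "true" else "false",
           ",\"assignments\":[", asg, "]}")
  }, character(1)), collapse = ",")
  paste0("{\"model_id\":", json_str(system$source_model_id),
         ",\"states\":[", states, "]",
         ",\"constants\":{", consts, "}",
         ",\"derived\":[", derived, "]",
         ",\"derivatives\":{", derivs, "}",
         ",\"events\":[", events, "]}\n")
}

#' Read a compiled-model JSON document back into an ODE system
#'
#' @param json_text JSON produced by [export_compiled_json()].
#' @return An `ode_system`. Initial values recorded in the document
#'   become the initial program.
#' @export
import_compiled_json <- function(json_text) {
  x <- jsonlite::fromJSON(json_text, simplifyVector = FALSE)
  state_ids <- vapply(x$states, function(s) s$id, character(1))
  initials <- lapply(x$states, function(s) as.numeric(s$initial))
  constants <- lapply(x$constants, function(v) {
    if (is.null(v)) NA_real_ else as.numeric(v)
  })
  derivatives <- stats::setNames(
    lapply(state_ids, function(sid) tree_to_expr(x$derivatives[[sid]])),
    state_ids)
  derived <- lapply(x$derived, function(d) {
    list(id = d$id, expr = tree_to_expr(d$expr))
  })
  events <- lapply(x$events, function(ev) {
    list(id = ev$id,
         trigger = tree_to_expr(ev$trigger),
         assignments = lapply(ev$assignments, function(ea) {
           list(target = ea$target, expr = tree_to_expr(ea$expr))
         }),
         initial_trigger_value = isTRUE(ev$initial_trigger_value))
  })
  initial_program <- c(
    lapply(names(constants), function(nm) {
      list(id = nm, expr = e_num0(constants[[nm]]))
    }),
    lapply(seq_along(state_ids), function(i) {
      list(id = state_ids[[i]], expr = e_num(initials[[i]]))
    })
  )
  sys <- structure(list(
    state_ids = state_ids,
    derivatives = derivatives,
    derived = derived,
    constants = constants,
    initial_program = initial_program,
    events = events,
    source_model_id = x$model_id
  ), class = "ode_system")
  validate_ode_system(sys)
  sys
}
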