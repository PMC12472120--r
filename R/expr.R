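# Operator-tree representation of mathematical formulas.
#
# Every formula extracted from a model (kinetic law, rule, trigger,
# event assignment, initial assignment, function body) is held as a tree
# of nodes of kind "number", "symbol", "time", "call" or "piecewise".
# Booleans live in the numeric domain: relational and logical operators
# return 1 (true) or 0 (false).

#' Built-in operator tags understood by the expression engine
#'
#' Calls whose `op` is not in this set are treated as user-defined
#' function applications and must be inlined (see [inline_functions()])
#' before evaluation or code generation.
#'
#' @keywords internal
BUILTIN_OPS <- c(
  "plus", "minus", "times", "divide", "power", "exp", "ln", "log10",
  "root", "abs", "floor", "ceiling", "sin", "cos", "tan", "asin",
  "acos", "atan", "sinh", "cosh", "tanh", "eq", "neq", "lt", "leq",
  "gt", "geq", "and", "or", "not", "min", "max"
)

#' Construct expression nodes
#'
#' Low-level constructors for the operator tree. `e_num()` wraps a
#' numeric literal, `e_sym()` a model identifier, `e_time()` the
#' simulation time, `e_call()` an operator application and
#' `e_piecewise()` a conditional with ordered (value, condition) pieces
#' and an optional otherwise branch.
#'
#' @param value Numeric scalar.
#' @param name Identifier string.
#' @param op Operator tag; one of [BUILTIN_OPS] or a user function id.
#' @param args List of child expression nodes (an operator application
#'   may also receive them as `...`).
#' @param pieces List of `list(value =, cond =)` pairs.
#' @param otherwise Expression node or `NULL`.
#' @return An object of class `sbml_expr`.
#' @export
e_num <- function(value) {
  stopifnot(is.numeric(value), length(value) == 1L)
  structure(list(kind = "number", value = as.numeric(value)),
            class = "sbml_expr")
}

#' @rdname e_num
#' @export
e_sym <- function(name) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  structure(list(kind = "symbol", name = name), class = "sbml_expr")
}

#' @rdname e_num
#' @export
e_time <- function() {
  structure(list(kind = "time"), class = "sbml_expr")
}

#' @rdname e_num
#' @param ... Child nodes, used when `args` is missing.
#' @export
e_call <- function(op, ..., args = list(...)) {
  stopifnot(is.character(op), length(op) == 1L)
  if (op %in% BUILTIN_OPS) check_arity(op, length(args))
  for (a in args) stopifnot(inherits(a, "sbml_expr"))
  structure(list(kind = "call", op = op, args = args), class = "sbml_expr")
}

#' @rdname e_num
#' @export
e_piecewise <- function(pieces, otherwise = NULL) {
  stopifnot(is.list(pieces))
  for (p in pieces) {
    stopifnot(inherits(p$value, "sbml_expr"), inherits(p$cond, "sbml_expr"))
  }
  if (!is.null(otherwise)) stopifnot(inherits(otherwise, "sbml_expr"))
  structure(list(kind = "piecewise", pieces = pieces, otherwise = otherwise),
            class = "sbml_expr")
}

check_arity <- function(op, n) {
  ok <- switch(op,
    minus = n %in% c(1L, 2L),
    not = , exp = , ln = , log10 = , abs = , floor = , ceiling = ,
    sin = , cos = , tan = , asin = , acos = , atan = ,
    sinh = , cosh = , tanh = n == 1L,
    divide = , power = n == 2L,
    root = n %in% c(1L, 2L),
    eq = , neq = , lt = , leq = , gt = , geq = n >= 2L,
    plus = , times = , and = , or = , min = , max = n >= 1L,
    TRUE
  )
  if (!ok) {
    stop(sprintf("operator '%s' does not take %d argument(s)", op, n),
         call. = FALSE)
  }
  invisible(TRUE)
}

is_expr <- function(x) inherits(x, "sbml_expr")

#' Collect the symbols referenced by an expression
#'
#' @param expr Expression node.
#' @return Character vector of distinct identifiers, in first-appearance
#'   order. The time leaf is not a symbol and is not included.
#' @export
expr_symbols <- function(expr) {
  out <- character(0)
  walk <- function(e) {
    switch(e$kind,
      number = NULL,
      time = NULL,
      symbol = out[[length(out) + 1L]] <<- e$name,
      call = for (a in e$args) walk(a),
      piecewise = {
        for (p in e$pieces) { walk(p$value); walk(p$cond) }
        if (!is.null(e$otherwise)) walk(e$otherwise)
      }
    )
    invisible(NULL)
  }
  walk(expr)
  unique(out)
}

#' Does an expression depend on time (directly)?
#' @keywords internal
expr_uses_time <- function(expr) {
  found <- FALSE
  walk <- function(e) {
    if (found) return(invisible(NULL))
    switch(e$kind,
      time = found <<- TRUE,
      call = for (a in e$args) walk(a),
      piecewise = {
        for (p in e$pieces) { walk(p$value); walk(p$cond) }
        if (!is.null(e$otherwise)) walk(e$otherwise)
      }
    )
    invisible(NULL)
  }
  walk(expr)
  found
}

#' Rename symbols throughout an expression
#'
#' @param expr Expression node.
#' @param map Named character vector: `old_name = new_name`.
#' @return Expression with every matching symbol renamed.
#' @keywords internal
expr_rename <- function(expr, map) {
  expr_substitute(expr, lapply(map, e_sym))
}

#' Substitute expressions for symbols
#'
#' @param expr Expression node.
#' @param env Named list mapping symbol names to replacement expression
#'   nodes.
#' @keywords internal
expr_substitute <- function(expr, env) {
  walk <- function(e) {
    switch(e$kind,
      number = e,
      time = e,
      symbol = if (!is.null(env[[e$name]])) env[[e$name]] else e,
      call = e_call(e$op, args = lapply(e$args, walk)),
      piecewise = e_piecewise(
        lapply(e$pieces, function(p) list(value = walk(p$value),
                                          cond = walk(p$cond))),
        if (!is.null(e$otherwise)) walk(e$otherwise)
      )
    )
  }
  walk(expr)
}

#' Evaluate an expression numerically
#'
#' Tree-walking evaluation in IEEE-754 double arithmetic. Relational and
#' logical operators return 1 or 0; a piecewise returns the value of the
#' first piece whose condition is true (nonzero), otherwise the
#' `otherwise` branch.
#'
#' @param expr Expression node.
#' @param env Named list or environment binding every symbol in `expr`
#'   to a number.
#' @param t Time value substituted for the time leaf (default 0).
#' @return A numeric scalar.
#' @export
evaluate <- function(expr, env = list(), t = 0) {
  if (is.list(env)) env <- list2env(env, parent = emptyenv())
  ev <- function(e) {
    switch(e$kind,
      number = e$value,
      time = t,
      symbol = {
        v <- get0(e$name, envir = env, inherits = FALSE)
        if (is.null(v)) {
          stop(sprintf("unbound symbol '%s' in expression", e$name),
               call. = FALSE)
        }
        v
      },
      call = ev_call(e),
      piecewise = {
        for (p in e$pieces) {
          if (ev(p$cond) != 0) return(ev(p$value))
        }
        if (is.null(e$otherwise)) {
          stop("piecewise: no condition matched and no otherwise branch",
               call. = FALSE)
        }
        ev(e$otherwise)
      }
    )
  }
  ev_call <- function(e) {
    op <- e$op
    if (!(op %in% BUILTIN_OPS)) {
      stop(sprintf("cannot evaluate user function call '%s'; inline first", op),
           call. = FALSE)
    }
    a <- vapply(e$args, ev, numeric(1))
    switch(op,
      plus = sum(a),
      minus = if (length(a) == 1L) -a[[1L]] else a[[1L]] - a[[2L]],
      times = prod(a),
      divide = a[[1L]] / a[[2L]],
      power = a[[1L]]^a[[2L]],
      exp = exp(a[[1L]]),
      ln = {
        if (a[[1L]] <= 0) {
          stop(sprintf("domain error: ln of non-positive value in %s",
                       render_prefix(e)), call. = FALSE)
        }
        log(a[[1L]])
      },
      log10 = {
        if (a[[1L]] <= 0) {
          stop(sprintf("domain error: log10 of non-positive value in %s",
                       render_prefix(e)), call. = FALSE)
        }
        log10(a[[1L]])
      },
      root = if (length(a) == 1L) sqrt(a[[1L]]) else a[[2L]]^(1 / a[[1L]]),
      abs = abs(a[[1L]]),
      floor = floor(a[[1L]]),
      ceiling = ceiling(a[[1L]]),
      sin = sin(a[[1L]]), cos = cos(a[[1L]]), tan = tan(a[[1L]]),
      asin = asin(a[[1L]]), acos = acos(a[[1L]]), atan = atan(a[[1L]]),
      sinh = sinh(a[[1L]]), cosh = cosh(a[[1L]]), tanh = tanh(a[[1L]]),
      eq = as.numeric(all(a == a[[1L]])),
      neq = as.numeric(a[[1L]] != a[[2L]]),
      lt = as.numeric(all(diff(a) > 0)),
      leq = as.numeric(all(diff(a) >= 0)),
      gt = as.numeric(all(diff(a) < 0)),
      geq = as.numeric(all(diff(a) <= 0)),
      and = as.numeric(all(a != 0)),
      or = as.numeric(any(a != 0)),
      not = as.numeric(a[[1L]] == 0),
      min = min(a),
      max = max(a)
    )
  }
  ev(expr)
}

#' Render an expression as a prefix-notation debug string
#'
#' A compact serialization used in error messages and identity tests:
#' `(times k S)`, `(piecewise (1 (lt time 5)) 0)`.
#'
#' @param expr Expression node.
#' @return A single string.
#' @export
render_prefix <- function(expr) {
  switch(expr$kind,
    number = fmt_num(expr$value),
    symbol = expr$name,
    time = "time",
    call = paste0("(", paste(c(expr$op, vapply(expr$args, render_prefix,
                                               character(1))),
                             collapse = " "), ")"),
    piecewise = {
      ps <- vapply(expr$pieces, function(p) {
        paste0("(", render_prefix(p$value), " ", render_prefix(p$cond), ")")
      }, character(1))
      tail <- if (!is.null(expr$otherwise)) {
        paste0(" ", render_prefix(expr$otherwise))
      } else ""
      paste0("(piecewise ", paste(ps, collapse = " "), tail, ")")
    }
  )
}

#' Shortest round-trip decimal representation of a double
#'
#' Returns the shortest decimal string that parses back (via
#' `as.numeric`) to exactly the same IEEE-754 double. Used everywhere a
#' number is written to text so that repeated renderings are
#' byte-identical and lossless.
#'
#' @param x Numeric scalar.
#' @return A string.
#' @export
fmt_num <- function(x) {
  stopifnot(length(x) == 1L)
  if (!is.finite(x)) {
    stop("cannot serialize non-finite number", call. = FALSE)
  }
  if (x == floor(x) && abs(x) < 1e15) {
    # integral doubles print without exponent or decimal point
    return(sprintf("%.0f", x))
  }
  for (d in 1:17) {
    s <- formatC(x, digits = d, format = "g", width = 1)
    if (as.numeric(s) == x) return(s)
  }
  formatC(x, digits = 17, format = "g", width = 1)
}

# --- compilation to R language objects ---------------------------------

# Reserved name for the time variable in compiled expressions. SBML
# identifiers match [A-Za-z_][A-Za-z0-9_]* and can never contain dots,
# so this cannot collide with a model symbol.
TIME_NAME <- "..t.."

#' Compile an expression node to an R language object
#'
#' The returned call evaluates with `eval()` in an environment binding
#' the model symbols plus `..t..` for time. This is the fast evaluation
#' path used by the integrator; [evaluate()] is the reference
#' tree-walker.
#'
#' @param expr Expression node (no user function calls).
#' @return An R language object or numeric literal.
#' @keywords internal
compile_expr <- function(expr) {
  num1 <- function(x) call("as.numeric", x)
  cx <- function(e) {
    switch(e$kind,
      number = e$value,
      symbol = as.name(e$name),
      time = as.name(TIME_NAME),
      call = cx_call(e),
      piecewise = {
        # nested if/else chain; evaluation error when nothing matches
        tail <- if (!is.null(e$otherwise)) {
          cx(e$otherwise)
        } else {
          quote(stop("piecewise: no condition matched", call. = FALSE))
        }
        for (p in rev(e$pieces)) {
          tail <- call("if", call("!=", cx(p$cond), 0), cx(p$value), tail)
        }
        tail
      }
    )
  }
  fold <- function(op, xs) Reduce(function(l, r) call(op, l, r), xs)
  chain <- function(op, xs) {
    # n-ary relational chain: x1 op x2 && x2 op x3 ...
    cmp <- mapply(function(l, r) call(op, l, r),
                  xs[-length(xs)], xs[-1L], SIMPLIFY = FALSE)
    num1(fold("&&", cmp))
  }
  cx_call <- function(e) {
    op <- e$op
    if (!(op %in% BUILTIN_OPS)) {
      stop(sprintf("cannot compile user function call '%s'; inline first", op),
           call. = FALSE)
    }
    a <- lapply(e$args, cx)
    switch(op,
      plus = fold("+", a),
      minus = if (length(a) == 1L) call("-", a[[1L]]) else call("-", a[[1L]], a[[2L]]),
      times = fold("*", a),
      divide = call("/", a[[1L]], a[[2L]]),
      power = call("^", a[[1L]], a[[2L]]),
      exp = call("exp", a[[1L]]),
      ln = call("log", a[[1L]]),
      log10 = call("log10", a[[1L]]),
      root = if (length(a) == 1L) call("sqrt", a[[1L]])
             else call("^", a[[2L]], call("/", 1, a[[1L]])),
      abs = call("abs", a[[1L]]),
      floor = call("floor", a[[1L]]),
      ceiling = call("ceiling", a[[1L]]),
      sin = call("sin", a[[1L]]), cos = call("cos", a[[1L]]),
      tan = call("tan", a[[1L]]),
      asin = call("asin", a[[1L]]), acos = call("acos", a[[1L]]),
      atan = call("atan", a[[1L]]),
      sinh = call("sinh", a[[1L]]), cosh = call("cosh", a[[1L]]),
      tanh = call("tanh", a[[1L]]),
      eq = chain("==", a),
      neq = num1(call("!=", a[[1L]], a[[2L]])),
      lt = chain("<", a),
      leq = chain("<=", a),
      gt = chain(">", a),
      geq = chain(">=", a),
      and = num1(fold("&&", lapply(a, function(x) call("!=", x, 0)))),
      or = num1(fold("||", lapply(a, function(x) call("!=", x, 0)))),
      not = num1(call("==", a[[1L]], 0)),
      min = if (length(a) == 1L) a[[1L]] else fold_fn("pmin2", "min", a),
      max = if (length(a) == 1L) a[[1L]] else fold_fn("pmax2", "max", a)
    )
  }
  fold_fn <- function(unused, fn, a) {
    as.call(c(as.name(fn), a))
  }
  cx(expr)
}
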