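# MathML <-> operator tree.
#
# SBML embeds formulas as MathML content markup. Only the subset that
# appears in core ODE models is supported; anything else raises a
# classed condition that the reader records as an unsupported-MathML
# finding.

MATHML_TIME_URLS <- c(
  "http://www.sbml.org/sbml/symbols/time"
)
MATHML_UNSUPPORTED_CSYMBOLS <- c(
  "http://www.sbml.org/sbml/symbols/delay",
  "http://www.sbml.org/sbml/symbols/avogadro",
  "http://www.sbml.org/sbml/symbols/rateOf"
)

# MathML tag -> builtin op. Tags absent here and not handled specially
# are unsupported.
MATHML_OP_MAP <- c(
  plus = "plus", minus = "minus", times = "times", divide = "divide",
  power = "power", exp = "exp", ln = "ln", abs = "abs",
  floor = "floor", ceiling = "ceiling",
  sin = "sin", cos = "cos", tan = "tan",
  arcsin = "asin", arccos = "acos", arctan = "atan",
  sinh = "sinh", cosh = "cosh", tanh = "tanh",
  eq = "eq", neq = "neq", lt = "lt", leq = "leq", gt = "gt", geq = "geq",
  and = "and", or = "or", not = "not", min = "min", max = "max"
)

local_name <- function(node) {
  sub("^.*:", "", xml2::xml_name(node))
}

element_children <- function(node) {
  kids <- xml2::xml_children(node)
  kids[vapply(kids, function(k) !local_name(k) %in% c("annotation",
      "annotation-xml", "semantics"), logical(1))]
}

unsupported_mathml <- function(msg) {
  cond <- structure(
    class = c("sbml_unsupported_mathml", "sbml_error", "error", "condition"),
    list(message = msg, call = NULL)
  )
  stop(cond)
}

#' Parse a MathML element into an expression tree
#'
#' Accepts a `math` element or any content-markup subtree (`apply`,
#' `cn`, `ci`, `piecewise`, ...). Numeric constants handle the integer,
#' real, e-notation and rational `cn` forms; `pi` and `exponentiale`
#' become numeric literals; `true`/`false` become 1/0; a `csymbol` with
#' the time definitionURL becomes the time leaf.
#'
#' @param node An `xml2` node, or a string containing a MathML fragment.
#' @return An expression node (see [e_num()]).
#' @export
parse_mathml <- function(node) {
  if (is.character(node)) {
    node <- xml2::xml_root(xml2::read_xml(node))
  }
  name <- local_name(node)
  if (name == "math") {
    kids <- element_children(node)
    if (length(kids) != 1L) {
      unsupported_mathml("math element must contain exactly one expression")
    }
    return(parse_mathml(kids[[1L]]))
  }
  switch(name,
    cn = parse_cn(node),
    ci = e_sym(trimws(xml2::xml_text(node))),
    csymbol = parse_csymbol(node),
    apply = parse_apply(node),
    piecewise = parse_piecewise(node),
    pi = e_num(pi),
    exponentiale = e_num(exp(1)),
    true = e_num(1),
    false = e_num(0),
    unsupported_mathml(sprintf("unsupported MathML element <%s>", name))
  )
}

parse_cn <- function(node) {
  type <- xml2::xml_attr(node, "type")
  if (is.na(type)) type <- "real"
  txt <- xml2::xml_text(node)
  if (type %in% c("real", "integer")) {
    v <- suppressWarnings(as.numeric(trimws(txt)))
    if (is.na(v)) unsupported_mathml(sprintf("cannot parse <cn> value '%s'", txt))
    return(e_num(v))
  }
  # e-notation and rational use a <sep/> child splitting two text parts
  txts <- xml2::xml_find_all(node, "./text()")
  vals <- suppressWarnings(as.numeric(trimws(vapply(
    seq_along(txts), function(i) xml2::xml_text(txts[[i]]), character(1)))))
  vals <- vals[!is.na(vals)]
  if (length(vals) != 2L) {
    unsupported_mathml(sprintf("cannot parse <cn type='%s'>", type))
  }
  if (type == "e-notation") {
    e_num(vals[[1L]] * 10^vals[[2L]])
  } else if (type == "rational") {
    e_num(vals[[1L]] / vals[[2L]])
  } else {
    unsupported_mathml(sprintf("unsupported <cn> type '%s'", type))
  }
}

parse_csymbol <- function(node) {
  url <- xml2::xml_attr(node, "definitionURL")
  if (!is.na(url) && url %in% MATHML_TIME_URLS) return(e_time())
  unsupported_mathml(sprintf("unsupported csymbol '%s'",
                             if (is.na(url)) xml2::xml_text(node) else url))
}

parse_piecewise <- function(node) {
  pieces <- list()
  otherwise <- NULL
  for (kid in element_children(node)) {
    kname <- local_name(kid)
    gkids <- element_children(kid)
    if (kname == "piece") {
      if (length(gkids) != 2L) {
        unsupported_mathml("<piece> must hold value and condition")
      }
      pieces[[length(pieces) + 1L]] <- list(value = parse_mathml(gkids[[1L]]),
                                            cond = parse_mathml(gkids[[2L]]))
    } else if (kname == "otherwise") {
      if (length(gkids) != 1L) {
        unsupported_mathml("<otherwise> must hold one expression")
      }
      otherwise <- parse_mathml(gkids[[1L]])
    } else {
      unsupported_mathml(sprintf("unexpected <%s> inside <piecewise>", kname))
    }
  }
  e_piecewise(pieces, otherwise)
}

parse_apply <- function(node) {
  kids <- element_children(node)
  if (length(kids) == 0L) unsupported_mathml("empty <apply>")
  head <- kids[[1L]]
  hname <- local_name(head)
  rest <- kids[-1L]

  if (hname == "ci") {
    # user-defined function application
    fname <- trimws(xml2::xml_text(head))
    return(e_call(fname, args = lapply(rest, parse_mathml)))
  }
  if (hname == "csymbol") {
    url <- xml2::xml_attr(head, "definitionURL")
    unsupported_mathml(sprintf("unsupported csymbol operator '%s'",
                               if (is.na(url)) xml2::xml_text(head) else url))
  }
  if (hname == "root") {
    return(parse_root(rest))
  }
  if (hname == "log") {
    return(parse_log(rest))
  }
  if (!(hname %in% names(MATHML_OP_MAP))) {
    unsupported_mathml(sprintf("unsupported MathML operator <%s>", hname))
  }
  op <- MATHML_OP_MAP[[hname]]
  args <- lapply(rest, parse_mathml)
  tryCatch(e_call(op, args = args), error = function(e) {
    unsupported_mathml(conditionMessage(e))
  })
}

parse_root <- function(rest) {
  if (length(rest) >= 1L && local_name(rest[[1L]]) == "degree") {
    dkids <- element_children(rest[[1L]])
    if (length(dkids) != 1L || length(rest) != 2L) {
      unsupported_mathml("malformed <root> with <degree>")
    }
    deg <- parse_mathml(dkids[[1L]])
    e_call("root", deg, parse_mathml(rest[[2L]]))
  } else if (length(rest) == 1L) {
    e_call("root", parse_mathml(rest[[1L]]))
  } else {
    unsupported_mathml("malformed <root>")
  }
}

parse_log <- function(rest) {
  if (length(rest) >= 1L && local_name(rest[[1L]]) == "logbase") {
    bkids <- element_children(rest[[1L]])
    if (length(bkids) != 1L || length(rest) != 2L) {
      unsupported_mathml("malformed <log> with <logbase>")
    }
    base <- parse_mathml(bkids[[1L]])
    x <- parse_mathml(rest[[2L]])
    # log_b(x) = ln(x) / ln(b)
    e_call("divide", e_call("ln", x), e_call("ln", base))
  } else if (length(rest) == 1L) {
    e_call("log10", parse_mathml(rest[[1L]]))
  } else {
    unsupported_mathml("malformed <log>")
  }
}

# --- operator tree -> MathML (used by the fixture generator) -----------

MATHML_TAG_FOR_OP <- c(
  plus = "plus", minus = "minus", times = "times", divide = "divide",
  power = "power", exp = "exp", ln = "ln", abs = "abs",
  floor = "floor", ceiling = "ceiling",
  sin = "sin", cos = "cos", tan = "tan",
  asin = "arcsin", acos = "arccos", atan = "arctan",
  sinh = "sinh", cosh = "cosh", tanh = "tanh",
  eq = "eq", neq = "neq", lt = "lt", leq = "leq", gt = "gt", geq = "geq",
  and = "and", or = "or", not = "not", min = "min", max = "max"
)

#' Serialize an expression tree as MathML
#'
#' Inverse of [parse_mathml()] for the supported subset; used by the
#' fixture generator to embed formulas in emitted SBML documents and in
#' round-trip identity tests.
#'
#' @param expr Expression node.
#' @param math_element Wrap the result in a namespaced `<math>` element.
#' @return A MathML string.
#' @export
write_mathml <- function(expr, math_element = TRUE) {
  body <- wm(expr)
  if (math_element) {
    paste0("<math xmlns=\"http://www.w3.org/1998/Math/MathML\">",
           body, "</math>")
  } else {
    body
  }
}

wm <- function(e) {
  switch(e$kind,
    number = wm_number(e$value),
    symbol = paste0("<ci>", e$name, "</ci>"),
    time = paste0("<csymbol encoding=\"text\" definitionURL=",
                  "\"http://www.sbml.org/sbml/symbols/time\">t</csymbol>"),
    call = wm_call(e),
    piecewise = wm_piecewise(e)
  )
}

wm_number <- function(v) {
  if (v == floor(v) && abs(v) < 1e15) {
    sprintf("<cn type=\"integer\">%.0f</cn>", v)
  } else {
    paste0("<cn>", fmt_num(v), "</cn>")
  }
}

wm_call <- function(e) {
  if (e$op == "root" && length(e$args) == 2L) {
    return(paste0("<apply><root/><degree>", wm(e$args[[1L]]), "</degree>",
                  wm(e$args[[2L]]), "</apply>"))
  }
  if (e$op == "log10") {
    return(paste0("<apply><log/>", wm(e$args[[1L]]), "</apply>"))
  }
  tag <- if (e$op %in% names(MATHML_TAG_FOR_OP)) {
    MATHML_TAG_FOR_OP[[e$op]]
  } else {
    NA_character_
  }
  inner <- paste(vapply(e$args, wm, character(1)), collapse = "")
  if (is.na(tag)) {
    # user function application
    paste0("<apply><ci>", e$op, "</ci>", inner, "</apply>")
  } else {
    paste0("<apply><", tag, "/>", inner, "</apply>")
  }
}

wm_piecewise <- function(e) {
  ps <- vapply(e$pieces, function(p) {
    paste0("<piece>", wm(p$value), wm(p$cond), "</piece>")
  }, character(1))
  ow <- if (!is.null(e$otherwise)) {
    paste0("<otherwise>", wm(e$otherwise), "</otherwise>")
  } else ""
  paste0("<piecewise>", paste(ps, collapse = ""), ow, "</piecewise>")
}
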