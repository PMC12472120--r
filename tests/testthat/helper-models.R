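# Shared fixtures and oracles, built in code at test time.

decay_system <- function(k = 1, S0 = 1) {
  build_ode_system(parse_sbml(
    generate_fixture("decay", parameters = list(k = k, S0 = S0))$sbml))
}

# SBML document with a function definition f(x) = 2 * x used in the
# kinetic law; exercises lambda parsing and inlining through the reader
sbml_with_function_def <- function() {
  paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version2/core" level="3" version="2">\n',
    '<model id="fn_model">\n',
    '<listOfFunctionDefinitions>\n',
    '<functionDefinition id="f">',
    '<math xmlns="http://www.w3.org/1998/Math/MathML">',
    '<lambda><bvar><ci>x</ci></bvar>',
    '<apply><times/><cn type="integer">2</cn><ci>x</ci></apply>',
    '</lambda></math></functionDefinition>\n',
    '</listOfFunctionDefinitions>\n',
    '<listOfCompartments><compartment id="cell" size="1" constant="true"/></listOfCompartments>\n',
    '<listOfSpecies><species id="S" compartment="cell" initialAmount="1"',
    ' boundaryCondition="false" hasOnlySubstanceUnits="true" constant="false"/></listOfSpecies>\n',
    '<listOfParameters><parameter id="k" value="0.5" constant="true"/></listOfParameters>\n',
    '<listOfReactions><reaction id="r1" reversible="false">\n',
    '<listOfReactants><speciesReference species="S" stoichiometry="1" constant="true"/></listOfReactants>\n',
    '<kineticLaw><math xmlns="http://www.w3.org/1998/Math/MathML">',
    '<apply><times/><ci>k</ci><apply><ci>f</ci><ci>S</ci></apply></apply>',
    '</math></kineticLaw>\n',
    '</reaction></listOfReactions>\n',
    '</model>\n</sbml>\n')
}

# patch one attribute / inject one element into a fixture document
sbml_with <- function(base_family, sub, replacement) {
  txt <- generate_fixture(base_family)$sbml
  sub(sub, replacement, txt, fixed = TRUE)
}

# Independent tree-walking evaluator over the compiled-model JSON
# document (parsed with jsonlite); deliberately separate from the
# package's own evaluator.
json_eval <- function(node, env, t) {
  k <- node$kind
  if (k == "number") return(node$value)
  if (k == "symbol") return(env[[node$name]])
  if (k == "time") return(t)
  if (k == "piecewise") {
    for (p in node$pieces) {
      if (json_eval(p$cond, env, t) != 0) return(json_eval(p$value, env, t))
    }
    return(json_eval(node$otherwise, env, t))
  }
  a <- vapply(node$args, json_eval, numeric(1), env = env, t = t)
  switch(node$op,
    plus = sum(a), times = prod(a),
    minus = if (length(a) == 1) -a[1] else a[1] - a[2],
    divide = a[1] / a[2], power = a[1]^a[2],
    exp = exp(a[1]), ln = log(a[1]), log10 = log10(a[1]),
    root = if (length(a) == 1) sqrt(a[1]) else a[2]^(1 / a[1]),
    abs = abs(a[1]), floor = floor(a[1]), ceiling = ceiling(a[1]),
    sin = sin(a[1]), cos = cos(a[1]), tan = tan(a[1]),
    asin = asin(a[1]), acos = acos(a[1]), atan = atan(a[1]),
    sinh = sinh(a[1]), cosh = cosh(a[1]), tanh = tanh(a[1]),
    eq = as.numeric(a[1] == a[2]), neq = as.numeric(a[1] != a[2]),
    lt = as.numeric(a[1] < a[2]), leq = as.numeric(a[1] <= a[2]),
    gt = as.numeric(a[1] > a[2]), geq = as.numeric(a[1] >= a[2]),
    and = as.numeric(all(a != 0)), or = as.numeric(any(a != 0)),
    not = as.numeric(a[1] == 0), min = min(a), max = max(a),
    stop("json_eval: unknown op ", node$op))
}

translatable_families <- function() {
  setdiff(FIXTURE_FAMILIES, "unsupported_compartment")
}

event_free_families <- function() {
  setdiff(translatable_families(), "event_dosing")
}
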