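---
title: "From SBML to executable ODEs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From SBML to executable ODEs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sbmlode)
```

## Scope and model

`sbmlode` turns SBML Level 2 (versions 1–5) and Level 3 (versions 1–2)
core documents into executable ODE systems. Level 1 documents and any
document that declares an SBML package (comp, fbc, qual, ...) as
required are rejected outright, since package semantics change the
meaning of the core elements.

For each species that is neither a boundary condition nor constant, the
derivative is the stoichiometry-weighted sum of kinetic laws:

$$\frac{ds}{dt} \;=\; \sum_r \nu_{rs}\, v_r(x, p, t),
\qquad \nu_{rs} = \sum \text{product stoich} - \sum \text{reactant stoich}.$$

Rate rules supply derivatives directly (for species outside all
reactions, or for parameters). Assignment rules become *derived
quantities*, topologically sorted by symbol dependency with ties broken
by document order; a dependency cycle is an error naming the variables
involved. User-defined functions are inlined before compilation by
capture-free substitution — safe because an SBML function body may
reference only its own formal arguments — with mutual calls allowed and
recursion refused.

### The supported subset

A model is translatable exactly when the feature report is empty. The
refused constructs are: compartments with size ≠ 1 (and non-constant
rule-governed compartments, refused conservatively), algebraic rules
(they would require a DAE solver), conversion factors, assignment rules
targeting non-boundary species, event assignments targeting species or
referencing their own target, fast reactions, delayed or prioritised
events, stoichiometry math, and MathML outside the supported operator
set. Event *triggers* that merely read species are allowed; such
references are recorded as warnings because the borderline is genuinely
ambiguous, and refusing them would exclude common dosing patterns that
simulate correctly.

Pinning compartment sizes to one has a useful consequence: amount and
concentration coincide, so `hasOnlySubstanceUnits` needs no special
handling and kinetic laws need no volume factors. This is exact within
the subset, not an approximation.

### Booleans as numbers

The whole evaluation domain is IEEE-754 doubles. Relational and logical
operators return 1/0 and `true`/`false` literals parse as 1/0. One
numeric domain keeps the evaluator, the compiled R expressions, the
JSON interpreter contract and the equation text mutually consistent;
piecewise conditions are "true" when nonzero.

## Compilation choices

**State ordering.** Species in document order, then rate-rule
parameters in document order, then parameters promoted by events. The
ordering is part of the contract: rendered text, JSON documents and CSV
columns are byte-stable across runs.

**Event-writable parameters.** A parameter targeted by an event
assignment is promoted to a state with derivative 0 rather than being
special-cased in the constants table. Constants stay immutable, and the
event machinery only ever writes to the state vector.

**The initial-value program.** Initial values are an ordered program:
constant values first, then plainly declared state initial values, then
initial assignments in dependency order. Placing plain initial values
*before* the initial assignments lets an initial assignment reference
another species' declared starting amount, which would otherwise be
unbound at evaluation time. Initial assignments that target constants
are resolved at compile time (at t = 0) so the constants table remains
fully numeric.

**Local kinetic parameters** are renamed to
`<reaction_id>__<parameter_id>` at parse time, giving a flat global
symbol table downstream; SBML identifiers cannot contain the dot, so
the internal time symbol (`..t..`) can never collide with a model
symbol.

## Numerical integration

The solver is deSolve's Dormand–Prince 4(5) pair at internal tolerances
rtol 10⁻⁸ / atol 10⁻¹⁰ (configurable). A segment that fails under the
explicit pair is retried with the implicit multistep method (`lsoda`)
before the run is abandoned with the last good time; this retry policy
keeps moderately stiff models passing without asking the user to pick a
solver.

The output grid `start + i·duration/steps` is *constructed*, never
accumulated, so returned times are bitwise equal to the requested grid.

**Discontinuities.** Piecewise conditions and event triggers that
compare time against a constant contribute internal breakpoints where
integration is restarted, so the right-hand side presented to the
adaptive solver is smooth inside every segment. This matters: an
adaptive pair stepping across a derivative jump silently loses its
error estimate.

**Events.** After each segment the triggers are evaluated; a
false→true transition is localized by bisection on the segment to
within 10⁻⁹ time units. Bisection rather than root polishing because
triggers are generally non-smooth (logical combinations, piecewise).
All assignments of simultaneously firing events are evaluated against
the pre-event environment before any is applied — the SBML
simultaneous-assignment semantics. A trigger already true at the start
does not fire unless the trigger's initial value is declared false. A
configurable guard (default 10⁴ firings) aborts runaway event loops.
Because triggers are inspected at segment boundaries, a trigger that
flips true and back *strictly inside* one segment is not observed; with
time-threshold breakpoints added to the segment set this requires a
state-dependent trigger pulse narrower than an output interval, which
the harness's model class does not produce.

**Derived quantities** are recomputed at every reported time from the
current state, so reported assignment-rule variables are always
consistent with the states they depend on.

## Rendering and the JSON contract

The equation text (`init` / `let` / `deriv` / `const` / `event` lines,
infix with minimal parentheses) is meant for human eyes. The
compiled-model JSON serializes expressions as prefix trees
(`kind`/`op`/`args`) precisely so that consumers need no formula
parser; a ~20-line tree walk suffices to evaluate a model, and the test
suite contains exactly such an independent interpreter as a
cross-check. Numbers are written in the shortest decimal form that
round-trips through a double, which makes export → import → export the
byte identity while losing no precision.

## The fixture generator

Ten families of small SBML documents cover the feature axes the
compiler must handle: plain mass action (`decay`, `birth_death`,
`reversible_binding`), function definitions (`michaelis_menten_fn`),
rate rules on parameters (`rate_rule_param`), assignment rules
(`assignment_rule_derived`), parameter-switching events
(`event_dosing`), piecewise time inputs (`piecewise_input`), boundary
species (`boundary_feed`), and one deliberately untranslatable family
(`unsupported_compartment`, compartment size 2). Families are split
across the L2V4 and L3V2 dialects to exercise reader dialect handling.

Default parameters are chosen so every trajectory evolves on an O(1)
scale over its settings grid (rates near 1, initial amounts 0–2,
horizons of 5–20 time units — the regime typical of normalized
biochemical benchmark models). Random draws perturb the defaults by a
factor in [0.7, 1.4] through a counter-based congruential scheme keyed
on (seed, family, draw, parameter), so fixture trees are byte-identical
across platforms and runs without touching R's RNG state.

Expected trajectories come from closed forms where they exist
(exponentials, piecewise exponentials, an
exponential-of-polynomial for the rate-rule family). The two nonlinear
families use an in-package fixed-step classical RK4 integrator at step
10⁻⁴; it shares only expression compilation with the adaptive path and
serves as the independent oracle in solver-agreement tests. Its
step-halving convergence (10⁻⁴ vs 10⁻⁵) is itself under test.

**What the corpus does not emulate:** real curated models are larger
(tens to hundreds of species), carry annotation/RDF metadata, use
non-unit compartments and unit declarations, and sometimes combine
many rule types. Passing the bundled suite therefore demonstrates
correctness of the translation semantics per feature, not performance
or coverage on any external corpus; the harness accepts any directory
tree in the standard test-suite layout, so an externally obtained
corpus can be validated with the same `run_suite()` call.

## Validation tolerances

The harness compares per cell: pass iff `|a − e| ≤ atol + rtol·|e|`.
The suite-level margin defaults to an *absolute* 10⁻⁵ with zero
relative component — the stricter reading of a bare "10⁻⁵ error
margin" for trajectories on an O(1) scale — while a case's own settings
file, when tolerances are given and no global margin is imposed, takes
precedence. The expected CSV's time column must match the constructed
grid within 10⁻⁹ and is then excluded from comparison. When several
level/version variants of a case file are present, the highest is
preferred.

Problem sizes used by the bundled acceptance run: all ten families,
three draws each (30 cases, 51 output points per case), RK4 references
at step 10⁻⁴, and oracle-agreement spot checks over a 0–2 horizon to
keep the fixed-step reference cheap.

## Known limitations

- No algebraic rules (no DAE solving), no delay constructs, no
  stochastic simulation, no unit analysis, no SBML packages.
- Event triggers are treated as persistent; trigger de-activation
  between segment boundaries is not detected (see above).
- `log`, `ln` and `root` follow real-valued semantics and error on
  out-of-domain arguments rather than returning complex results.
- The BioModels fetcher treats the download URL as configuration and
  performs no content negotiation; it is a convenience, not a client
  library.
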