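# Classed conditions shared across the package.

sbml_error <- function(class, msg, ...) {
  cond <- structure(
    class = c(class, "sbml_error", "error", "condition"),
    list(message = msg, call = NULL, ...)
  )
  stop(cond)
}

abort_parse <- function(msg) sbml_error("sbml_parse_error", msg)
abort_unsupported_document <- function(msg) {
  sbml_error("sbml_unsupported_document", msg)
}
abort_validation <- function(msg) sbml_error("sbml_validation_error", msg)
abort_compile <- function(msg) sbml_error("sbml_compile_error", msg)
abort_numeric <- function(msg, ...) sbml_error("sbml_numeric_error", msg, ...)
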