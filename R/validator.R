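# Test-suite harness: settings files, trajectory comparison under
# tolerance rules, and suite-level bookkeeping in the test-suite
# directory layout (<case>-sbml-lXvY.xml, <case>-settings.txt,
# <case>-results.csv).

#' Parse a settings file
#'
#' Key:value lines with keys `start`, `duration`, `steps`, `variables`
#' (comma-separated), `absolute`, `relative`; unknown keys are
#' ignored. Absent tolerances default to absolute 1e-5, relative 0.
#'
#' @param text Settings text or a file path.
#' @return A `sim_settings`.
#' @export
read_settings <- function(text) {
  if (length(text) == 1 && !grepl("\n", text) && file.exists(text)) {
    text <- paste(readLines(text, warn = FALSE), collapse = "\n")
  }
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  kv <- list()
  for (ln in lines) {
    ln <- trimws(ln)
    if (!nzchar(ln) || !grepl(":", ln, fixed = TRUE)) next
    key <- trimws(sub(":.*$", "", ln))
    val <- trimws(sub("^[^:]*:", "", ln))
    kv[[tolower(key)]] <- val
  }
  need <- function(key) {
    if (is.null(kv[[key]]) || !nzchar(kv[[key]])) {
      abort_validation(sprintf("settings: missing required key '%s'", key))
    }
    kv[[key]]
  }
  num <- function(key, default = NULL) {
    if (is.null(kv[[key]]) || !nzchar(kv[[key]])) return(default)
    as.numeric(kv[[key]])
  }
  duration <- as.numeric(need("duration"))
  steps <- as.numeric(need("steps"))
  variables <- if (!is.null(kv[["variables"]]) && nzchar(kv[["variables"]])) {
    trimws(strsplit(kv[["variables"]], ",", fixed = TRUE)[[1]])
  } else NULL
  sim_settings(start = num("start", 0), duration = duration, steps = steps,
               variables = variables,
               atol = num("absolute", 1e-5), rtol = num("relative", 0))
}

#' Compare two trajectories under tolerance rules
#'
#' Columns are matched by id (never by position); both trajectories
#' must share the grid length. The comparison passes when every cell
#' satisfies `|a - e| <= atol + rtol * |e|`. The expected trajectory's
#' time column must match the actual grid within 1e-9 and is then
#' excluded from the value comparison.
#'
#' @param actual,expected `trajectory` objects.
#' @param atol,rtol Absolute and relative tolerance.
#' @return `list(pass =, max_abs_deviation =)`.
#' @export
compare_trajectories <- function(actual, expected, atol = 1e-5, rtol = 0) {
  if (length(actual$times) != length(expected$times)) {
    abort_validation(sprintf("grid mismatch: %d vs %d time points",
                             length(actual$times), length(expected$times)))
  }
  if (max(abs(actual$times - expected$times)) > 1e-9) {
    abort_validation("time grids differ by more than 1e-9")
  }
  missing <- setdiff(expected$columns, actual$columns)
  if (length(missing) > 0) {
    abort_validation(sprintf("missing column(s) in actual trajectory: %s",
                             paste(missing, collapse = ", ")))
  }
  max_dev <- 0
  pass <- TRUE
  for (col in expected$columns) {
    a <- actual$values[, col]
    e <- expected$values[, col]
    dev <- abs(a - e)
    max_dev <- max(max_dev, dev)
    if (any(dev > atol + rtol * abs(e))) pass <- FALSE
  }
  list(pass = pass, max_abs_deviation = max_dev)
}

find_case_files <- function(dir) {
  files <- list.files(dir)
  sbml <- files[grepl("-sbml-l[0-9]+v[0-9]+\\.xml$", files)]
  if (length(sbml) == 0) return(NULL)
  lv <- regmatches(sbml, regexpr("l[0-9]+v[0-9]+", sbml))
  level <- as.integer(sub("l([0-9]+)v[0-9]+", "\\1", lv))
  version <- as.integer(sub("l[0-9]+v([0-9]+)", "\\1", lv))
  ord <- order(level, version, decreasing = TRUE)
  list(
    sbml = file.path(dir, sbml[ord[1]]),
    settings = {
      s <- files[grepl("-settings\\.txt$", files)]
      if (length(s) == 0) NULL else file.path(dir, s[1])
    },
    results = {
      r <- files[grepl("-results\\.csv$", files)]
      if (length(r) == 0) NULL else file.path(dir, r[1])
    }
  )
}

run_case <- function(dir, margin) {
  case_id <- basename(dir)
  files <- find_case_files(dir)
  if (is.null(files)) {
    return(list(case_id = case_id, status = "error",
                message = "no SBML file in case directory",
                max_abs_deviation = NA_real_, findings = NULL))
  }
  model <- tryCatch(parse_sbml(files$sbml),
    sbml_unsupported_document = function(e) e,
    error = function(e) e)
  if (inherits(model, "sbml_unsupported_document")) {
    rep <- new_feature_report(list(list(
      feature_tag = "unsupported_package", element_id = case_id,
      message = conditionMessage(model))))
    return(list(case_id = case_id, status = "skipped_unsupported",
                message = conditionMessage(model),
                max_abs_deviation = NA_real_, findings = rep))
  }
  if (inherits(model, "condition")) {
    return(list(case_id = case_id, status = "error",
                message = conditionMessage(model),
                max_abs_deviation = NA_real_, findings = NULL))
  }
  report <- detect_unsupported(model)
  if (!report_is_clean(report)) {
    return(list(case_id = case_id, status = "skipped_unsupported",
                message = paste(report_tags(report), collapse = ", "),
                max_abs_deviation = NA_real_, findings = report))
  }
  if (is.null(files$settings) || is.null(files$results)) {
    return(list(case_id = case_id, status = "error",
                message = "missing settings or results file",
                max_abs_deviation = NA_real_, findings = NULL))
  }
  res <- tryCatch({
    settings <- read_settings(files$settings)
    sys <- build_ode_system(model)
    actual <- simulate(sys, settings)
    expected <- read_trajectory_csv(files$results)
    # the case's own tolerances win over the global margin when present
    atol <- if (!is.null(margin)) margin else settings$atol
    rtol <- if (!is.null(margin)) 0 else settings$rtol
    cmp <- compare_trajectories(actual, expected, atol = atol, rtol = rtol)
    list(case_id = case_id,
         status = if (cmp$pass) "passed" else "failed",
         message = "",
         max_abs_deviation = cmp$max_abs_deviation, findings = NULL)
  }, error = function(e) {
    list(case_id = case_id, status = "error", message = conditionMessage(e),
         max_abs_deviation = NA_real_, findings = NULL)
  })
  res
}

#' Run a suite of validation cases
#'
#' Each directory holds one SBML file (when several level/version
#' variants are present the highest is preferred), one settings file
#' and one expected-results CSV. Per case: parse, feature-detect, then
#' either skip (unsupported) or compile, simulate and compare. Cases
#' run in lexicographic order.
#'
#' @param case_dirs Character vector of case directories, or one parent
#'   directory whose subdirectories are the cases.
#' @param margin Absolute comparison margin applied to every case
#'   (relative tolerance 0). Pass `NULL` to use each case's own
#'   settings tolerances instead.
#' @return A `suite_report` with counts `total`, `translated`,
#'   `skipped`, `passed`, `failed`, `errors` and `per_case` results.
#' @export
run_suite <- function(case_dirs, margin = 1e-5) {
  if (length(case_dirs) == 1 && dir.exists(case_dirs) &&
      is.null(find_case_files(case_dirs))) {
    case_dirs <- list.dirs(case_dirs, recursive = FALSE)
  }
  case_dirs <- sort(case_dirs)
  per_case <- lapply(case_dirs, function(d) {
    if (!dir.exists(d)) {
      list(case_id = basename(d), status = "error",
           message = "unreadable directory", max_abs_deviation = NA_real_,
           findings = NULL)
    } else {
      run_case(d, margin)
    }
  })
  statuses <- vapply(per_case, `[[`, character(1), "status")
  report <- structure(list(
    total = length(per_case),
    translated = sum(statuses != "skipped_unsupported"),
    skipped = sum(statuses == "skipped_unsupported"),
    passed = sum(statuses == "passed"),
    failed = sum(statuses == "failed"),
    errors = sum(statuses == "error"),
    per_case = per_case
  ), class = "suite_report")
  report
}

#' Serialize a suite report as JSON
#'
#' @param report A `suite_report`.
#' @param path Optional output file.
#' @return JSON text, invisibly when written to a file.
#' @export
suite_report_json <- function(report, path = NULL) {
  doc <- list(
    total = report$total, translated = report$translated,
    skipped = report$skipped, passed = report$passed,
    failed = report$failed, errors = report$errors,
    cases = lapply(report$per_case, function(cs) {
      out <- list(case_id = cs$case_id, status = cs$status)
      if (!is.na(cs$max_abs_deviation)) {
        out$max_abs_deviation <- cs$max_abs_deviation
      }
      if (!is.null(cs$findings)) out$findings <- report_tags(cs$findings)
      if (nzchar(cs$message)) out$message <- cs$message
      out
    })
  )
  txt <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' @export
print.suite_report <- function(x, ...) {
  cat(sprintf("suite: %d case(s) | translated %d | skipped %d | passed %d | failed %d | errors %d\n",
              x$total, x$translated, x$skipped, x$passed, x$failed, x$errors))
  for (cs in x$per_case) {
    dev <- if (is.na(cs$max_abs_deviation)) "" else {
      sprintf(" (max dev %.3g)", cs$max_abs_deviation)
    }
    extra <- if (!is.null(cs$findings)) {
      paste0(" [", paste(report_tags(cs$findings), collapse = ", "), "]")
    } else if (nzchar(cs$message)) paste0(" - ", cs$message) else ""
    cat(sprintf("  %-28s %s%s%s\n", cs$case_id, cs$status, dev, extra))
  }
  invisible(x)
}
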