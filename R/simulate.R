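# Event-aware numerical integration of a compiled ODE system.
#
# The integrator is deSolve's Dormand-Prince 4(5) pair with dense
# output; when a segment fails to integrate it is retried with the
# implicit multistep solver (lsoda) before giving up. Integration is
# carved into segments at the output grid, at time-only breakpoints
# harvested from piecewise conditions and triggers (so the right-hand
# side stays smooth inside every segment), and at event firing times.
# A trigger's false -> true transition inside a segment is localized by
# bisection to 1e-9 time units; all simultaneous assignments are
# evaluated against the pre-event environment before any is applied.

#' Simulation settings
#'
#' Output is requested at `start + i * duration / steps` for
#' `i = 0..steps`. `atol`/`rtol` are the *comparison* tolerances used
#' by the validation harness, not solver tolerances.
#'
#' @param start Start time.
#' @param duration Length of the simulated interval (> 0).
#' @param steps Number of output intervals (>= 1).
#' @param variables Ordered ids to report; states, derived quantities
#'   and constants are all allowed. `NULL` means all states.
#' @param atol,rtol Comparison tolerances carried alongside the grid.
#' @return An object of class `sim_settings`.
#' @export
sim_settings <- function(start = 0, duration, steps, variables = NULL,
                         atol = 1e-5, rtol = 0) {
  stopifnot(is.numeric(duration), duration > 0,
            is.numeric(steps), steps >= 1)
  structure(list(start = start, duration = duration,
                 steps = as.integer(steps),
                 variables = variables, atol = atol, rtol = rtol),
            class = "sim_settings")
}

#' @rdname sim_settings
#' @param settings A `sim_settings`.
#' @return `settings_grid()`: the exact output time grid.
#' @export
settings_grid <- function(settings) {
  settings$start + (0:settings$steps) * (settings$duration / settings$steps)
}

# compile system expressions once; returns closures over a shared
# evaluation environment
make_runtime <- function(system) {
  consts <- system$constants
  consts <- consts[!vapply(consts, is.na, logical(1))]
  env <- list2env(consts, parent = baseenv())
  states <- system$state_ids
  n <- length(states)
  deriv_exprs <- lapply(system$derivatives[states], compile_expr)
  derived_ids <- vapply(system$derived, `[[`, character(1), "id")
  derived_exprs <- lapply(system$derived, function(d) compile_expr(d$expr))
  trigger_exprs <- lapply(system$events, function(ev) compile_expr(ev$trigger))

  bind <- function(t, y) {
    assign(TIME_NAME, t, envir = env)
    for (i in seq_len(n)) assign(states[[i]], y[[i]], envir = env)
    for (i in seq_along(derived_exprs)) {
      assign(derived_ids[[i]], eval(derived_exprs[[i]], env), envir = env)
    }
  }
  deriv <- function(t, y) {
    bind(t, y)
    vapply(deriv_exprs, function(ex) as.numeric(eval(ex, env)), numeric(1))
  }
  triggers <- function(t, y) {
    if (length(trigger_exprs) == 0) return(logical(0))
    bind(t, y)
    vapply(trigger_exprs, function(ex) eval(ex, env) != 0, logical(1))
  }
  lookup <- function(t, y, ids) {
    bind(t, y)
    vapply(ids, function(id) {
      if (identical(id, "time") || identical(id, "t")) return(t)
      v <- get0(id, envir = env, inherits = FALSE)
      if (is.null(v)) {
        abort_numeric(sprintf("cannot report unknown variable '%s'", id))
      }
      as.numeric(v)
    }, numeric(1))
  }
  env_snapshot <- function(t, y) {
    bind(t, y)
    env
  }
  list(deriv = deriv, triggers = triggers, lookup = lookup,
       env_snapshot = env_snapshot, states = states)
}

# harvest breakpoints: constants compared against time inside piecewise
# conditions or triggers
time_breakpoints <- function(system) {
  out <- numeric(0)
  consts <- system$constants
  scan <- function(e) {
    switch(e$kind,
      call = {
        if (e$op %in% c("lt", "leq", "gt", "geq", "eq", "neq") &&
            length(e$args) == 2L) {
          a <- e$args[[1L]]; b <- e$args[[2L]]
          other <- NULL
          if (a$kind == "time") other <- b
          if (b$kind == "time") other <- a
          if (!is.null(other)) {
            v <- const_value(other, consts)
            if (!is.null(v)) out[[length(out) + 1L]] <<- v
          }
        }
        for (x in e$args) scan(x)
      },
      piecewise = {
        for (p in e$pieces) { scan(p$value); scan(p$cond) }
        if (!is.null(e$otherwise)) scan(e$otherwise)
      }
    )
    invisible(NULL)
  }
  for (e in system$derivatives) scan(e)
  for (d in system$derived) scan(d$expr)
  for (ev in system$events) scan(ev$trigger)
  unique(out)
}

const_value <- function(e, consts) {
  v <- tryCatch(evaluate(e, consts[!vapply(consts, is.na, logical(1))], t = NaN),
                error = function(err) NULL)
  if (is.null(v) || !is.finite(v)) NULL else v
}

integrate_segment <- function(deriv, y0, t0, t1, rtol, atol) {
  func <- function(t, y, parms) list(deriv(t, y))
  run <- function(method) {
    out <- tryCatch(
      suppressWarnings(deSolve::ode(
        y = y0, times = c(t0, t1), func = func, parms = NULL,
        method = method, rtol = rtol, atol = atol)),
      error = function(e) NULL)
    if (is.null(out) || nrow(out) < 2L || anyNA(out[nrow(out), ])) {
      return(NULL)
    }
    as.numeric(out[nrow(out), -1L, drop = TRUE])
  }
  # Dormand-Prince first; implicit multistep fallback for stiff cases
  y1 <- run(deSolve::rkMethod("rk45dp7"))
  if (is.null(y1)) y1 <- run("lsoda")
  y1
}

#' Simulate a compiled system over an output grid
#'
#' @param system An `ode_system`.
#' @param settings A `sim_settings` (see [sim_settings()]).
#' @param rtol,atol Internal solver tolerances.
#' @param max_events Runaway guard: total number of event firings
#'   allowed before the run is aborted.
#' @return A `trajectory` with fields `times`, `columns` and `values`
#'   (a `(steps + 1) x length(columns)` matrix).
#' @export
#' @examples
#' sys <- build_ode_system(parse_sbml(generate_fixture("decay")$sbml))
#' tr <- simulate(sys, sim_settings(0, 1, 10, "S"))
#' tr$values[nrow(tr$values), "S"]  # ~ exp(-1)
simulate <- function(system, settings, rtol = 1e-8, atol = 1e-10,
                     max_events = 1e4) {
  stopifnot(inherits(system, "ode_system"), inherits(settings, "sim_settings"))
  grid <- settings_grid(settings)
  t_end <- grid[length(grid)]
  vars <- settings$variables
  if (is.null(vars)) vars <- system$state_ids

  rt <- make_runtime(system)
  y <- unname(initial_state_values(system, t0 = settings$start))
  n_states <- length(y)

  bps <- time_breakpoints(system)
  bps <- bps[bps > grid[1] & bps < t_end]
  bounds <- sort(unique(c(grid, bps)))
  is_grid <- bounds %in% grid

  values <- matrix(NA_real_, nrow = length(grid), ncol = length(vars),
                   dimnames = list(NULL, vars))

  n_events <- length(system$events)
  fired_total <- 0L

  apply_events <- function(t, y, idx) {
    # all assignments evaluated against the pre-event environment
    env <- rt$env_snapshot(t, y)
    pre <- as.list(env)
    updates <- list()
    for (i in idx) {
      for (ea in system$events[[i]]$assignments) {
        updates[[ea$target]] <- evaluate(ea$expr, pre, t = t)
      }
    }
    for (nm in names(updates)) {
      j <- match(nm, rt$states)
      y[[j]] <- updates[[nm]]
    }
    y
  }

  # initial trigger states; initial_trigger_value = FALSE means the
  # trigger is assumed false just before the start, so a true trigger
  # at t = start fires immediately
  if (n_events > 0) {
    trig_now <- rt$triggers(settings$start, y)
    fire0 <- which(trig_now & !vapply(system$events, `[[`, logical(1),
                                      "initial_trigger_value"))
    if (length(fire0) > 0) {
      y <- apply_events(settings$start, y, fire0)
      fired_total <- fired_total + length(fire0)
    }
    trig_prev <- rt$triggers(settings$start, y)
  } else {
    trig_prev <- logical(0)
  }

  record <- function(t, y) {
    i <- match(TRUE, abs(grid - t) < 1e-12)
    if (!is.na(i)) values[i, ] <<- rt$lookup(t, y, vars)
  }
  record(grid[1], y)

  t_cur <- bounds[1]
  for (k in seq_along(bounds)[-1]) {
    t_next <- bounds[k]
    repeat {
      y_next <- integrate_segment(rt$deriv, y, t_cur, t_next, rtol, atol)
      if (is.null(y_next)) {
        abort_numeric(sprintf(
          "integration failed between t = %g and t = %g (last good time %g)",
          t_cur, t_next, t_cur), last_good_time = t_cur)
      }
      if (n_events == 0) { t_cur <- t_next; y <- y_next; break }
      trig_now <- rt$triggers(t_next, y_next)
      newly <- trig_now & !trig_prev
      if (!any(newly)) {
        trig_prev <- trig_now
        t_cur <- t_next; y <- y_next
        break
      }
      # bisection: localize the earliest false -> true transition
      lo <- t_cur; hi <- t_next; y_hi <- y_next
      while (hi - lo > 1e-9) {
        mid <- (lo + hi) / 2
        y_mid <- integrate_segment(rt$deriv, y, t_cur, mid, rtol, atol)
        if (is.null(y_mid)) {
          abort_numeric(sprintf(
            "integration failed during event localization near t = %g", mid),
            last_good_time = lo)
        }
        if (any(rt$triggers(mid, y_mid) & !trig_prev)) {
          hi <- mid; y_hi <- y_mid
        } else {
          lo <- mid
        }
      }
      fire <- which(rt$triggers(hi, y_hi) & !trig_prev)
      y_event <- apply_events(hi, y_hi, fire)
      fired_total <- fired_total + length(fire)
      if (fired_total > max_events) {
        abort_numeric(sprintf(
          "more than %g event firings; runaway event guard triggered",
          max_events))
      }
      trig_prev <- rt$triggers(hi, y_event)
      t_cur <- hi
      y <- y_event
      if (t_next - t_cur <= 1e-12) { t_cur <- t_next; break }
    }
    if (is_grid[k]) record(t_next, y)
  }

  if (anyNA(values)) {
    abort_numeric("trajectory contains unset values; integration incomplete")
  }
  structure(list(times = grid, columns = vars, values = values),
            class = "trajectory")
}

#' Write a trajectory as CSV
#'
#' Header `time,<var1>,...`; one row per grid point; numbers in the
#' shortest round-trip decimal form.
#'
#' @param trajectory A `trajectory`.
#' @param path Output file; when `NULL` the CSV text is returned.
#' @export
write_trajectory_csv <- function(trajectory, path = NULL) {
  header <- paste(c("time", trajectory$columns), collapse = ",")
  rows <- vapply(seq_along(trajectory$times), function(i) {
    paste(vapply(c(trajectory$times[i], trajectory$values[i, ]), fmt_num,
                 character(1)), collapse = ",")
  }, character(1))
  text <- paste0(paste(c(header, rows), collapse = "\n"), "\n")
  if (is.null(path)) return(text)
  writeLines(sub("\n$", "", text), path)
  invisible(path)
}

#' Read a trajectory CSV
#'
#' @param path File path or literal CSV text.
#' @return A `trajectory`.
#' @export
read_trajectory_csv <- function(path) {
  df <- if (length(path) == 1 && grepl("\n", path)) {
    utils::read.csv(text = path, check.names = FALSE)
  } else {
    utils::read.csv(path, check.names = FALSE)
  }
  time_col <- which(tolower(names(df)) == "time")[1]
  if (is.na(time_col)) abort_validation("expected a 'time' column")
  cols <- names(df)[-time_col]
  structure(list(
    times = as.numeric(df[[time_col]]),
    columns = cols,
    values = as.matrix(df[, cols, drop = FALSE])
  ), class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory: %d time point(s) x %d variable(s): %s>\n",
              length(x$times), length(x$columns),
              paste(x$columns, collapse = ", ")))
  invisible(x)
}

#' Fixed-step fourth-order Runge-Kutta reference integration
#'
#' An independent oracle used to generate expected trajectories for
#' fixtures without a closed form and to cross-check the adaptive
#' solver: the classical RK4 scheme marched at a fixed step between
#' output points. Events are not supported; use it on event-free
#' systems only.
#'
#' @param system An `ode_system` without events.
#' @param grid Output times (first entry is the initial time).
#' @param h Fixed step size.
#' @return A `trajectory` over the system's states.
#' @export
rk4_trajectory <- function(system, grid, h = 1e-4) {
  if (length(system$events) > 0) {
    abort_numeric("the RK4 reference integrator does not support events")
  }
  rt <- make_runtime(system)
  y <- unname(initial_state_values(system, t0 = grid[1]))
  n_out <- length(grid)
  values <- matrix(NA_real_, nrow = n_out, ncol = length(rt$states),
                   dimnames = list(NULL, rt$states))
  values[1, ] <- y
  f <- rt$deriv
  for (k in 2:n_out) {
    t0 <- grid[k - 1]; t1 <- grid[k]
    nstep <- max(1L, ceiling((t1 - t0) / h - 1e-9))
    hh <- (t1 - t0) / nstep
    t <- t0
    for (s in seq_len(nstep)) {
      k1 <- f(t, y)
      k2 <- f(t + hh / 2, y + hh / 2 * k1)
      k3 <- f(t + hh / 2, y + hh / 2 * k2)
      k4 <- f(t + hh, y + hh * k3)
      y <- y + hh / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      t <- t0 + s * hh
    }
    values[k, ] <- y
  }
  structure(list(times = grid, columns = rt$states, values = values),
            class = "trajectory")
}
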