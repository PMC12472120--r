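# Settings parsing, trajectory comparison, suite bookkeeping.

test_that("settings files parse with defaults and required keys", {
  s <- read_settings(paste0("start: 0\nduration: 50\nsteps: 50\n",
                            "variables: S1, S2\nabsolute: 1e-07\n",
                            "relative: 1e-05"))
  expect_identical(s$steps, 50L)
  expect_identical(s$variables, c("S1", "S2"))
  expect_equal(s$atol, 1e-7)
  expect_equal(s$rtol, 1e-5)

  s <- read_settings("duration: 10\nsteps: 2")
  expect_equal(s$start, 0)
  expect_equal(settings_grid(s), c(0, 5, 10))
  expect_equal(s$atol, 1e-5)
  expect_equal(s$rtol, 0)

  expect_error(read_settings("start: 0"), class = "sbml_validation_error")
  # unknown keys are ignored
  expect_silent(read_settings("duration: 1\nsteps: 1\ncolor: blue"))
})

traj <- function(times, ...) {
  cols <- list(...)
  structure(list(times = times, columns = names(cols),
                 values = do.call(cbind, cols)),
            class = "trajectory")
}

test_that("comparison implements |a - e| <= atol + rtol * |e| per cell", {
  x <- traj(0:2, S = c(1, 2, 3))
  self <- compare_trajectories(x, x, atol = 0, rtol = 0)
  expect_true(self$pass)
  expect_equal(self$max_abs_deviation, 0)

  a <- traj(0, S = 1.0)
  e <- traj(0, S = 1.00002)
  cmp <- compare_trajectories(a, e, atol = 1e-5, rtol = 0)
  expect_false(cmp$pass)
  expect_equal(cmp$max_abs_deviation, 2e-5, tolerance = 1e-9)

  a <- traj(0, S = 100.0005)
  e <- traj(0, S = 100)
  cmp <- compare_trajectories(a, e, atol = 1e-7, rtol = 1e-5)
  expect_true(cmp$pass)
})

test_that("comparison matches columns by id and refuses silent alignment", {
  a <- traj(0:1, S = c(1, 2), P = c(3, 4))
  e <- traj(0:1, P = c(3, 4), S = c(1, 2))  # other column order
  expect_true(compare_trajectories(a, e, 0, 0)$pass)
  e2 <- traj(0:1, Q = c(1, 2))
  expect_error(compare_trajectories(a, e2, 0, 0),
               class = "sbml_validation_error")
  e3 <- traj(0:2, S = c(1, 2, 3))
  expect_error(compare_trajectories(a, e3, 0, 0),
               class = "sbml_validation_error")
})

test_that("self-comparison passes for arbitrary finite trajectories", {
  set.seed(3)
  for (i in 1:20) {
    x <- traj(seq(0, 1, length.out = 5),
              A = rnorm(5, sd = 10^runif(1, -3, 3)),
              B = rnorm(5))
    expect_true(compare_trajectories(x, x, atol = 0, rtol = 0)$pass)
  }
})

test_that("the generated mini-suite validates and skips the right case", {
  dir <- withr::local_tempdir()
  generate_mini_suite(dir, n_random_per_family = 1, seed = 5)
  rep <- run_suite(dir, margin = 1e-5)
  expect_identical(rep$total, 10L)
  expect_identical(rep$skipped, 1L)
  expect_identical(rep$translated, 9L)
  expect_identical(rep$passed, 9L)
  expect_identical(rep$failed, 0L)
  expect_identical(rep$errors, 0L)
  skipped <- Filter(function(cs) cs$status == "skipped_unsupported",
                    rep$per_case)
  expect_length(skipped, 1)
  expect_true("compartment_size_ne_1" %in% report_tags(skipped[[1]]$findings))
  # counts are invariant under re-running
  rep2 <- run_suite(dir, margin = 1e-5)
  expect_identical(rep2[c("total", "translated", "skipped", "passed",
                          "failed", "errors")],
                   rep[c("total", "translated", "skipped", "passed",
                         "failed", "errors")])
})

test_that("a perturbed expected trajectory fails; empty suites are empty", {
  dir <- withr::local_tempdir()
  generate_mini_suite(dir, families = "decay", n_random_per_family = 1,
                      seed = 5)
  case_dir <- list.dirs(dir, recursive = FALSE)[1]
  csv <- list.files(case_dir, pattern = "-results\\.csv$", full.names = TRUE)
  df <- utils::read.csv(csv)
  df$S <- df$S + 1e-3   # well beyond the 1e-5 margin
  utils::write.csv(df, csv, row.names = FALSE, quote = FALSE)
  rep <- run_suite(dir, margin = 1e-5)
  expect_identical(rep$failed, 1L)

  expect_identical(run_suite(character(0))$total, 0L)
})

test_that("suite report JSON carries counts and per-case statuses", {
  dir <- withr::local_tempdir()
  generate_mini_suite(dir, families = c("decay", "unsupported_compartment"),
                      n_random_per_family = 1, seed = 5)
  rep <- run_suite(dir, margin = 1e-5)
  doc <- jsonlite::fromJSON(suite_report_json(rep), simplifyVector = FALSE)
  expect_identical(doc$total, 2L)
  expect_identical(doc$passed, 1L)
  statuses <- vapply(doc$cases, `[[`, character(1), "status")
  expect_setequal(statuses, c("passed", "skipped_unsupported"))
})
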