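# One shared mini-suite (all families, three draws each, fixed seed),
# generated once per test session.

.suite_cache <- new.env(parent = emptyenv())

acceptance_suite_dir <- function() {
  if (is.null(.suite_cache$dir)) {
    dir <- file.path(tempdir(), "sbmlode-acceptance-suite")
    if (!dir.exists(dir)) {
      generate_mini_suite(dir, families = FIXTURE_FAMILIES,
                          n_random_per_family = 3, seed = 20260922)
    }
    .suite_cache$dir <- dir
  }
  .suite_cache$dir
}
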