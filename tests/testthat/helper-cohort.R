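# The default 15-subject cohort pipeline run is expensive (~8 min), so it is
# computed once per test session and shared by every file that needs it.
# The classification permutation count is reduced to 200 (its only role in
# tests is a p < 0.05 check, which 200 permutations resolves).

.rn400_test_cache <- new.env(parent = emptyenv())

default_cohort_report <- function() {
  if (is.null(.rn400_test_cache$report)) {
    cfg <- pipeline_config(n_perm_class = 200)
    .rn400_test_cache$report <-
      suppressMessages(run_pipeline(cfg, progress = FALSE))
    .rn400_test_cache$cfg <- cfg
  }
  .rn400_test_cache$report
}
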