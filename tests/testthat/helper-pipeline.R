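# One shared full-scale synthetic-recovery run (200 subjects, 50%
# hypotensive, 24-h records), computed once per test session and reused by
# the recovery and alert-system tests.
.recovery_cache <- new.env(parent = emptyenv())

recovery_run <- function() {
  if (is.null(.recovery_cache$res)) {
    .recovery_cache$res <- run_pipeline(
      sim_config(n_subjects = 200L, frac_hypotensive = 0.5,
                 record_len_min = 1440L, seed = 101L),
      seed = 7L)
  }
  .recovery_cache$res
}

# a small, fast cohort for structural tests
small_pipeline <- function(seed = 5L, out_dir = NULL) {
  run_pipeline(sim_config(n_subjects = 24L, record_len_min = 420L,
                          seed = 11L),
               families = c("random_forest", "logistic_l2"),
               k = 3L, score_window_min = 200L,
               trajectory_grid = seq(0, 120, by = 5),
               seed = seed, out_dir = out_dir)
}
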