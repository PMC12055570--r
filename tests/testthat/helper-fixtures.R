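# Shared fixtures, built once per test run.

# Deterministic noise-free control cohort and its reference: the anchor for
# round-trip checks.
noise_free_reference <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      coh <- simulate_cohort(3, noise = noise_free(), inter_subject_cv = 0,
                             seed = 1)
      cache <<- run_pipeline(coh$records, coh$subjects)
    }
    cache
  }
})

# One-subject pipeline run for a preset under noise-free conditions,
# scored against the noise-free control reference.
ruf_for_preset <- function(preset) {
  coh <- simulate_cohort(1, preset = preset, noise = noise_free(),
                         inter_subject_cv = 0, seed = 1)
  pl <- run_pipeline(coh$records, coh$subjects,
                     reference = noise_free_reference()$reference)
  pl$results
}
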