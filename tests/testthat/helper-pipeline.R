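# One full study pipeline (virtual patient -> reference gait -> noiseless
# trial -> four-stage personalization + verification -> treatment sequence),
# computed lazily on first use and shared by the recovery, treatment, and
# acceptance tests. Everything is deterministic (seed 1).
.pipeline_cache <- new.env(parent = emptyenv())

pipeline_results <- function() {
  if (!is.null(.pipeline_cache$res)) return(.pipeline_cache$res)
  pat <- make_virtual_patient(seed = 1)
  ref <- generate_reference_gait(pat, assert = FALSE,
                                 max_outer = 14, max_inner = 60)
  trial <- synthesize_measurements(ref, pat, seed = 1,
                                   noise = list(marker_sd = 0, grf_sd = 0,
                                                emg_sd = 0))
  model_init <- perturbed_initial_model(pat, seed = 1)
  mdefs <- gaitfes:::expand_marker_defs(pat$markers)
  pm <- personalize(trial, model_init, mdefs, passive_reference(pat),
                    N = pat$config$N)
  tx <- design_treatment(pm$model, pm$verification, N = pat$config$N)
  .pipeline_cache$res <- list(pat = pat, ref = ref, trial = trial,
                              model_init = model_init, pm = pm, tx = tx)
  .pipeline_cache$res
}
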