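# The default desk-scale simulation and pipeline run are shared by several
# tests; compute them once per session.
.hsm_cache <- new.env(parent = emptyenv())

desk_sim <- function() {
  if (is.null(.hsm_cache$sim))
    .hsm_cache$sim <- simulate_cohorts(simulation_config())
  .hsm_cache$sim
}

desk_scan <- function() {
  if (is.null(.hsm_cache$scan))
    .hsm_cache$scan <- suppressMessages(run_hsm_pipeline(desk_sim()))
  .hsm_cache$scan
}

# Null-panel permutation empirical p-values over three independent panels.
null_permutation_ps <- function() {
  if (is.null(.hsm_cache$null_perm_ps)) {
    .hsm_cache$null_perm_ps <- vapply(c(66L, 76L, 86L), function(s) {
      arr <- simulate_array_data(n_samples = 150, n_probes = 60,
                                 n_mqtl = 0, seed = s)
      permute_genotypes(arr$betas, arr$genotype, arr$meta, B = 100,
                        seed = s + 1L)$empirical_p_nominal
    }, numeric(1))
  }
  .hsm_cache$null_perm_ps
}
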