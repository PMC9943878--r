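# The two expensive replication studies are shared across acceptance test
# blocks; computed once per test run at the package's reference seed.
.study_cache <- new.env(parent = emptyenv())

cached_map_study <- function() {
  if (is.null(.study_cache$map)) {
    .study_cache$map <- run_study(study_design(seed = 1), mode = "map_only")
  }
  .study_cache$map
}

cached_mcmc_study <- function() {
  if (is.null(.study_cache$mcmc)) {
    .study_cache$mcmc <- run_study(study_design(n_obs = 500, seed = 1),
                                   mode = "full_mcmc", chains = 4,
                                   iterations = 1000)
  }
  .study_cache$mcmc
}
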