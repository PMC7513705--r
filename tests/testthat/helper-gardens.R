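# Shared simulated fixtures, built once per test run. Configurations are the
# study conditions; tests that need special structure (zero components,
# many families) build their own.

tiny_config <- function(...) {
  defaults <- list(n_sites = 2, n_provenances = 3, n_blocks_per_site = 2,
                   n_families_per_provenance = 4,
                   n_offspring_per_family_per_block = 3,
                   survival_prob = 1, transfer_curvature = 0)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# one-site garden with known h2 = 0.5 used across REML/quantgen tests
one_site_garden <- local({
  sim <- NULL
  function() {
    if (is.null(sim)) {
      sim <<- simulate_garden(sim_config(
        n_sites = 1, transfer_curvature = 0,
        var_site = 0, var_prov_x_site = 0, var_fam_x_site = 0,
        var_additive = 3600, var_residual = 3600, seed = 101))
    }
    sim
  }
})
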