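test_that("the default design reproduces the trial dimensions", {
  sim <- simulate_garden(sim_config(seed = 1))
  expect_equal(nrow(sim$trees), 9900) # 3 sites x 10 prov x 3 blocks x 22 fam x 5
  counts <- dplyr::count(sim$trees, site_id)
  expect_equal(counts$n, rep(3300, 3))
  fam <- dplyr::count(sim$trees, site_id, mother_id)
  expect_equal(unique(fam$n), 15) # 5 per block x 3 blocks
  expect_equal(dplyr::n_distinct(sim$trees$mother_id), 220)
  # pedigree covers mothers as founders plus every tree
  expect_equal(nrow(sim$pedigree), 220 + 9900)
  expect_silent(validate_trial(sim$trees))
  expect_silent(validate_pedigree(sim$pedigree))
  # provenance climate defaults to the shipped reference table
  expect_setequal(sim$climate$unit_id[sim$climate$role == "provenance"],
                  oak_provenance_climate()$provenance_id)
})

test_that("same seed gives bit-identical output, different seed does not", {
  a <- simulate_garden(tiny_config(seed = 42))
  b <- simulate_garden(tiny_config(seed = 42))
  c <- simulate_garden(tiny_config(seed = 43))
  expect_identical(a$trees, b$trees)
  expect_identical(a$climate, b$climate)
  expect_identical(a$truth$realized, b$truth$realized)
  expect_false(identical(a$trees$height, c$trees$height))
  # the generator does not disturb the caller's RNG stream
  set.seed(99); before <- rnorm(1)
  set.seed(99); invisible(simulate_garden(tiny_config(seed = 1))); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("all-zero variances and curvature collapse to the grand mean", {
  cfg <- tiny_config(var_site = 0, var_provenance = 0, var_block = 0,
                     var_additive = 0, var_prov_x_site = 0, var_fam_x_site = 0,
                     var_residual = 0, seed = 2)
  sim <- simulate_garden(cfg)
  expect_true(all(sim$trees$height == cfg$mean_height))
})

test_that("half-sibs share covariance sigma_a^2 / 4 by construction", {
  # sigma_a = 80, sigma_e = 80: covariance between two offspring of the same
  # mother should be 20, estimated over 10,000 families
  cfg <- sim_config(n_sites = 1, n_provenances = 1, n_blocks_per_site = 1,
                    n_families_per_provenance = 10000,
                    n_offspring_per_family_per_block = 2,
                    var_site = 0, var_provenance = 0, var_block = 0,
                    var_additive = 80, var_prov_x_site = 0, var_fam_x_site = 0,
                    var_residual = 80, transfer_curvature = 0,
                    survival_prob = 1, seed = 33)
  sim <- simulate_garden(cfg)
  w <- tidyr::pivot_wider(
    dplyr::mutate(sim$trees, k = sub(".*_(T\\d+)$", "\\1", tree_id)),
    id_cols = "mother_id", names_from = "k", values_from = "height")
  emp_cov <- cov(w$T01, w$T02)
  expect_equal(emp_cov, 20, tolerance = 0.25) # Monte-Carlo tolerance ~5 units
  # and the total phenotypic variance is sigma_a + sigma_e
  expect_equal(var(sim$trees$height), 160, tolerance = 0.05 * 160)
})

test_that("simulated component draws match their configured variances", {
  # components with enough independent draws for a 5% relative check
  cfg <- sim_config(n_sites = 2, n_provenances = 500, n_blocks_per_site = 2,
                    n_families_per_provenance = 10,
                    n_offspring_per_family_per_block = 1,
                    var_site = 100, var_provenance = 300, var_block = 50,
                    var_additive = 400, var_prov_x_site = 150,
                    var_fam_x_site = 200, var_residual = 500,
                    transfer_curvature = 0, survival_prob = 1, seed = 44)
  sim <- simulate_garden(cfg)
  eff <- sim$truth$effects
  expect_equal(var(eff$provenance), 300, tolerance = 0.05 * 300) # 500 draws
  expect_equal(var(eff$maternal_bv), 400, tolerance = 0.05 * 400) # 5000 draws
  expect_equal(var(eff$fam_x_site), 200, tolerance = 0.05 * 200) # 10000 draws
  expect_equal(var(eff$prov_x_site), 150, tolerance = 0.05 * 150) # 1000 draws
  expect_equal(unname(sim$truth$realized["residual"]), 500,
               tolerance = 0.05 * 500) # 20000 draws
})

test_that("mortality is Bernoulli and leaves growth traits missing", {
  sim <- simulate_garden(tiny_config(
    n_families_per_provenance = 40, n_offspring_per_family_per_block = 10,
    survival_prob = 0.9, seed = 13))
  expect_equal(mean(sim$trees$alive), 0.9, tolerance = 0.02)
  expect_true(all(is.na(sim$trees$height[!sim$trees$alive])))
  expect_true(all(!is.na(sim$trees$height[sim$trees$alive])))
})

test_that("the truth report carries the config and derived true parameters", {
  sim <- simulate_garden(tiny_config(var_additive = 1, var_residual = 1,
                                     seed = 3))
  tr <- truth_report(sim)
  expect_true(all(c("n_sites", "var_additive", "survival_prob", "seed",
                    "true_h2", "true_qst", "true_qst_realized") %in%
                    tr$parameter))
  expect_equal(tr$value[tr$parameter == "true_h2"], 0.5)
  sim0 <- simulate_garden(tiny_config(var_provenance = 0, seed = 3))
  tr0 <- truth_report(sim0)
  expect_equal(tr0$value[tr0$parameter == "true_qst"], 0)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_sites = 0), class = "provtrial_config_error")
  expect_error(sim_config(var_additive = -1), class = "provtrial_config_error")
  expect_error(sim_config(survival_prob = 0), class = "provtrial_config_error")
  expect_error(sim_config(transfer_curvature = -2), class = "provtrial_config_error")
})
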