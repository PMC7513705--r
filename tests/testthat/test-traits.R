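test_that("SHM follows its defining arithmetic", {
  expect_equal(compute_shm(20, 500), 40)
  expect_equal(compute_shm(0, 400), 0)
  expect_equal(compute_shm(18.3, 305), 60)
  expect_error(compute_shm(20, 0), class = "provtrial_domain_error")
  expect_error(compute_shm(20, -10), class = "provtrial_domain_error")
})

test_that("Kh matches the Hagen-Poiseuille constant-folding oracle", {
  # one circular vessel, D = 50 um, in 0.01 mm2 -> VD = 1e8 m^-2
  v <- tibble::tibble(area = pi * 25^2, minor = 50, major = 50)
  kh <- compute_kh(v, section_area_mm2 = 0.01)
  oracle <- (pi * 998.2 / (128 * 1.002e-3)) * 1e8 * (50e-6)^4
  expect_equal(kh, oracle, tolerance = 1e-12)

  expect_equal(compute_kh(v[0, ], 0.01), 0) # no vessels, no conductivity

  # D^4 scaling: doubling all diameters at fixed VD multiplies Kh by 16
  v2 <- dplyr::mutate(v, minor = minor * 2, major = major * 2)
  expect_equal(compute_kh(v2, 0.01) / kh, 16, tolerance = 1e-12)

  expect_error(compute_kh(tibble::tibble(minor = -1, major = 2), 0.01),
               class = "provtrial_domain_error")
  expect_error(compute_kh(tibble::tibble(minor = 5, major = 2), 0.01),
               class = "provtrial_domain_error")
})

test_that("Kh is invariant to splitting a section when VD stays consistent", {
  set.seed(91)
  v <- tibble::tibble(minor = runif(40, 20, 60))
  v$major <- v$minor + runif(40, 0, 15)
  v$area <- pi * ((v$minor + v$major) / 4)^2
  whole <- compute_kh(v, section_area_mm2 = 2)
  # split into two sub-sections, area-weight the sub-Kh values
  a1 <- 0.8; a2 <- 1.2
  kh1 <- compute_kh(v[1:15, ], a1)
  kh2 <- compute_kh(v[16:40, ], a2)
  expect_equal((a1 * kh1 + a2 * kh2) / (a1 + a2), whole, tolerance = 1e-10)
})

test_that("leaf traits follow their printed definitions", {
  lt <- leaf_traits(dry_mass = 1, saturated_mass = 2.5, leaf_area = 100)
  expect_equal(lt$SLA_mass_per_area, 0.01)
  expect_equal(lt$LDMC, 0.4)
  expect_equal(leaf_traits(1, 1, 50)$LDMC, 1)
  expect_equal(leaf_traits(0.4, 1.0, 80)$LDMC, 0.4)
  expect_error(leaf_traits(1.2, 1.0, 80), class = "provtrial_domain_error")
  expect_error(leaf_traits(0, 1, 80), class = "provtrial_domain_error")
})

test_that("vessel summaries match a sort-and-interpolate quantile oracle", {
  one <- vessel_summary(tibble::tibble(area = 777), section_area_mm2 = 1)
  expect_equal(one$VA, 777); expect_equal(one$VA_max, 777)

  many <- vessel_summary(tibble::tibble(area = rep(1, 100)),
                         section_area_mm2 = 200 * 1e-6) # same units as areas
  expect_equal(many$F, 0.5)
  expect_equal(many$VD, 100 / (200 * 1e-6))

  # areas 1..100: type-7 interpolation puts the 95% quantile at 95.05
  vs <- vessel_summary(tibble::tibble(area = sample(1:100)), 1)
  x <- sort(1:100); h <- (100 - 1) * 0.95 + 1
  oracle <- x[floor(h)] + (h - floor(h)) * (x[floor(h) + 1] - x[floor(h)])
  expect_equal(vs$VA_max, oracle)
  expect_equal(vs$VA, mean(1:100))

  expect_error(vessel_summary(tibble::tibble(area = numeric()), 1),
               class = "provtrial_domain_error")
  expect_error(vessel_summary(tibble::tibble(area = 2e6), 1),
               class = "provtrial_measurement_error") # lumen fraction > 1
})

test_that("per-tree vessel traits aggregate the long table", {
  d <- tibble::tibble(
    tree_id = rep(c("t1", "t2"), c(3, 2)),
    minor = c(30, 40, 50, 20, 25), major = c(35, 45, 55, 25, 30),
    section_area_mm2 = rep(c(1, 2), c(3, 2)))
  d$area <- pi * ((d$minor + d$major) / 4)^2
  out <- vessel_traits(d)
  expect_equal(out$tree_id, c("t1", "t2"))
  expect_equal(out$n_vessels, c(3, 2))
  expect_equal(out$Kh[1], compute_kh(d[1:3, ], 1))
})

test_that("BH adjustment reproduces the hand-worked step-up example", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(bh_adjust(0.2), 0.2) # single test family: unchanged
  expect_equal(bh_adjust(rep(0.07, 5)), rep(0.07, 5))
  expect_error(bh_adjust(c(0.1, 1.2)), class = "provtrial_domain_error")
  # monotone in ranks and capped at 1
  set.seed(92)
  for (i in 1:10) {
    p <- runif(8)
    adj <- bh_adjust(p)
    expect_true(all(adj >= p - 1e-12))
    expect_true(all(adj <= 1))
    expect_true(all(diff(adj[order(p)]) >= -1e-12)) # rank-monotone
  }
})

test_that("trait-climate regressions recover exact linear signals", {
  clim <- oak_provenance_climate(as_climate_table = TRUE)
  clim$MSP <- 0.5 * clim$MAP
  shm <- compute_shm(clim$MWMT, clim$MSP)
  d <- tidyr::expand_grid(provenance_id = clim$unit_id, rep = 1:3)
  d$site_id <- "S1"
  d$ldmc <- 0.2 + 0.003 * shm[match(d$provenance_id, clim$unit_id)]
  out <- suppressWarnings(trait_climate_regression(d, traits = "ldmc",
                                                   climate = clim))
  expect_equal(out$slope, 0.003, tolerance = 1e-10)
  expect_lt(out$p_value, 1e-12)
  expect_equal(out$p_adjusted, out$p_value) # single-trait family
  expect_equal(out$r_squared, 1, tolerance = 1e-10)

  few <- dplyr::filter(d, provenance_id %in% unique(d$provenance_id)[1:2])
  expect_error(trait_climate_regression(few, "ldmc", clim),
               class = "provtrial_spec_error")
})

test_that("trait-growth correlations behave like Pearson's r", {
  d <- tibble::tibble(provenance_id = rep(paste0("P", 1:5), each = 4),
                      site_id = "S1")
  set.seed(93)
  d$sla <- rnorm(20)
  d$height <- 2 * d$sla + 1 # exact linear map
  out <- trait_growth_correlation(d, "sla", "height", by_site = FALSE)
  expect_equal(out$r, 1, tolerance = 1e-12)

  # orthogonalized response: r = 0 by construction
  x <- rnorm(20)
  y <- rnorm(20)
  xc <- x - mean(x); yc <- y - mean(y)
  d$sla <- x; d$height <- 5 + yc - xc * sum(xc * yc) / sum(xc^2)
  out0 <- trait_growth_correlation(d, "sla", "height", by_site = FALSE)
  expect_lt(abs(out0$r), 1e-10)

  d$height <- 7
  expect_error(trait_growth_correlation(d, "sla", "height", by_site = FALSE),
               class = "provtrial_domain_error")
})

test_that("provenance-level correlations and per-site scoping work", {
  sim <- simulate_garden(tiny_config(seed = 94))
  d <- sim$trees
  set.seed(94)
  d$ldmc <- 0.5 - 0.0004 * d$height + rnorm(nrow(d), 0, 0.01)
  out <- trait_growth_correlation(d, "ldmc", "height", level = "tree")
  expect_setequal(unique(out$site), c("pooled", "S1", "S2"))
  expect_true(all(out$r < 0)) # built-in negative association
  prov <- trait_growth_correlation(d, "ldmc", "height", level = "provenance",
                                   by_site = FALSE)
  expect_equal(prov$n, dplyr::n_distinct(d$provenance_id))
})
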