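make_climate <- function(prov_vals, site_val, variable = "MAT") {
  n <- length(prov_vals)
  tibble::tibble(
    unit_id = c(paste0("P", seq_len(n)), "S1"),
    role = c(rep("provenance", n), "site"),
    MAT = c(if (variable == "MAT") prov_vals else rep(9, n),
            if (variable == "MAT") site_val else 9),
    MAP = c(if (variable == "MAP") prov_vals else rep(800, n),
            if (variable == "MAP") site_val else 800),
    MWMT = 21, MCMT = -3
  )
}

# trees at one site whose heights follow y = f(D) exactly, 2 trees per prov
noiseless_trees <- function(D, f) {
  tibble::tibble(
    tree_id = paste0("t", seq_len(2 * length(D))),
    site_id = "S1", block_id = "S1_B1",
    provenance_id = rep(paste0("P", seq_along(D)), each = 2),
    mother_id = rep(paste0("P", seq_along(D), "_F1"), each = 2),
    height = rep(f(D), each = 2), dbh = 4, alive = TRUE
  )
}

test_that("transfer_distance is a guarded subtraction", {
  expect_equal(transfer_distance(10.85, 8.90), 1.95)
  expect_equal(transfer_distance(7, 7), 0)
  expect_equal(transfer_distance(497.90, 590), -92.1)
  expect_error(transfer_distance(1, 2, "MAT", "MAP"),
               class = "provtrial_unit_error")
})

test_that("a noiseless quadratic is recovered exactly, vertex included", {
  D <- -2:2
  clim <- make_climate(9 + D, 9)
  trees <- noiseless_trees(D, function(d) 500 - 20 * d - 15 * d^2)
  fit <- suppressWarnings(fit_transfer(trees, clim, site = "S1"))
  expect_equal(tidy(fit)$estimate, c(500, -20, -15), tolerance = 1e-9)
  expect_equal(vertex(fit), -2 / 3, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)

  # symmetric response: vertex at zero
  trees2 <- noiseless_trees(D, function(d) 480 - 10 * d^2)
  fit2 <- suppressWarnings(fit_transfer(trees2, clim, site = "S1"))
  expect_equal(vertex(fit2), 0, tolerance = 1e-9)

  # convex response: flagged, no interior maximum
  trees3 <- noiseless_trees(D, function(d) 400 + 1 * d^2)
  fit3 <- suppressWarnings(fit_transfer(trees3, clim, site = "S1"))
  expect_false(fit3$has_maximum)
  expect_warning(v <- vertex(fit3), "no interior maximum")
  expect_true(is.na(v))
})

test_that("the fit equals a generic polynomial least-squares oracle", {
  set.seed(61)
  D <- round(runif(8, -3, 3), 2)
  clim <- make_climate(9 + D, 9)
  trees <- noiseless_trees(D, function(d) 500 - 15 * d - 10 * d^2)
  trees$height <- trees$height + rnorm(nrow(trees), 0, 25)
  fit <- fit_transfer(trees, clim, site = "S1")
  # oracle: normal equations of the degree-2 Vandermonde system
  Dd <- rep(D, each = 2)
  V <- cbind(1, Dd, Dd^2)
  beta <- solve(t(V) %*% V, t(V) %*% trees$height)
  expect_equal(tidy(fit)$estimate, as.numeric(beta), tolerance = 1e-9)
})

test_that("shifting D shifts the vertex exactly and R2 survives affine Y", {
  set.seed(62)
  D <- seq(-2, 2, by = 0.5)
  y <- 500 - 18 * D - 12 * D^2 + rnorm(length(D), 0, 10)
  fit_at <- function(dvals, yvals) {
    clim <- make_climate(9 + dvals, 9)
    trees <- noiseless_trees(dvals, function(d) 0 * d)
    trees$height <- rep(yvals, each = 2)
    fit_transfer(trees, clim, site = "S1")
  }
  f0 <- fit_at(D, y)
  delta <- 1.3
  f1 <- fit_at(D + delta, y)
  expect_equal(vertex(f1), vertex(f0) + delta, tolerance = 1e-8)
  f2 <- fit_at(D, 3 * y + 100)
  expect_equal(f2$r_squared, f0$r_squared, tolerance = 1e-10)
})

test_that("degenerate designs are rejected", {
  clim <- make_climate(c(9, 9, 9), 9)
  trees <- noiseless_trees(c(0, 0, 0), function(d) 500 + d)
  expect_error(fit_transfer(trees, clim, site = "S1"),
               class = "provtrial_spec_error")
  expect_error(fit_transfer(trees, clim, site = "S9"),
               class = "provtrial_spec_error")
})

test_that("the simulator's transfer curvature is recovered by the fit", {
  # many provenances and no random provenance effect isolate the quadratic
  # climate surface; residual/family noise averages out over trees
  cfg <- sim_config(n_provenances = 40, n_families_per_provenance = 8,
                    n_offspring_per_family_per_block = 3,
                    transfer_curvature = 19, var_provenance = 0,
                    var_prov_x_site = 0, seed = 63)
  sim <- simulate_garden(cfg)
  for (s in c("S1", "S2")) {
    fit <- fit_transfer(sim$trees, sim$climate, site = s)
    b2 <- tidy(fit)$estimate[3]
    se2 <- tidy(fit)$std_error[3]
    expect_true(fit$has_maximum)
    expect_lt(abs(b2 - (-19)), 4 * se2 + 1)
  }
})
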