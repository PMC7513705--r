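balanced_one_factor <- function(n_groups = 50, n_per = 10, sg2 = 2, se2 = 1,
                                seed = 21) {
  set.seed(seed)
  g <- rep(sprintf("g%02d", seq_len(n_groups)), each = n_per)
  u <- rnorm(n_groups, 0, sqrt(sg2))
  tibble::tibble(g = g, y = u[as.integer(factor(g))] + rnorm(length(g), 0, sqrt(se2)))
}

test_that("REML equals the balanced-ANOVA closed form on one-factor designs", {
  d <- balanced_one_factor()
  fit <- reml_fit(d, "y", random = "g")
  ms <- summary(stats::aov(y ~ g, data = d))[[1]]$`Mean Sq`
  sg_anova <- (ms[1] - ms[2]) / 10 # expected mean squares, interior solution
  vc <- tidy(fit)
  expect_equal(vc$variance[vc$term == "g"], sg_anova, tolerance = 1e-6)
  expect_equal(vc$variance[vc$term == "residual"], ms[2], tolerance = 1e-6)
  expect_true(fit$converged)
})

test_that("restricted log-likelihood matches the dense-matrix oracle and lme4", {
  d <- balanced_one_factor(n_groups = 12, n_per = 4)
  fit <- reml_fit(d, "y", random = "g")
  vc <- tidy(fit)
  Z <- Matrix::sparseMatrix(i = seq_len(nrow(d)), j = as.integer(factor(d$g)), x = 1)
  ll_dense <- provtrial:::dense_reml_loglik(
    d$y, matrix(1, nrow(d), 1), list(Z), list(Matrix::Diagonal(12)),
    vc$variance[1], vc$variance[2])
  expect_equal(fit$loglik, ll_dense, tolerance = 1e-8)

  lf <- lme4::lmer(y ~ 1 + (1 | g), data = d, REML = TRUE)
  expect_equal(fit$loglik, as.numeric(stats::logLik(lf)), tolerance = 1e-6)
  expect_equal(vc$variance[1], as.data.frame(lme4::VarCorr(lf))$vcov[1],
               tolerance = 1e-4)
})

test_that("a variance simulated as zero is pinned at the boundary", {
  d <- balanced_one_factor(sg2 = 0, seed = 22)
  fit <- reml_fit(d, "y", random = "g")
  vc <- tidy(fit)
  expect_lt(vc$variance[vc$term == "g"], 1e-4 * sum(vc$variance))
  expect_true(vc$boundary[vc$term == "g"])
  expect_true(is.na(vc$se[vc$term == "g"])) # SE not applicable at the bound
})

test_that("animal model and family model imply the same additive variance", {
  sim <- one_site_garden()
  d <- sim$trees
  animal <- reml_fit(d, "height", random = c("provenance_id", "block_id"),
                     genetic = "tree_id", pedigree = pedigree_from_trees(d))
  fam <- reml_fit(d, "height",
                  random = c("provenance_id", "block_id", "mother_id"))
  va_animal <- unname(tidy(animal)$variance[tidy(animal)$term == "tree_id"])
  va_family <- unname(4 * tidy(fam)$variance[tidy(fam)$term == "mother_id"])
  expect_equal(va_family, va_animal, tolerance = 0.01)
  # the two parameterizations have identical restricted likelihoods
  expect_equal(animal$loglik, fam$loglik, tolerance = 1e-4)
})

test_that("estimates are invariant to row permutation", {
  sim <- simulate_garden(tiny_config(seed = 5))
  d <- sim$trees
  f1 <- reml_fit(d, "height", random = c("provenance_id", "block_id", "mother_id"))
  set.seed(9)
  f2 <- reml_fit(d[sample(nrow(d)), ], "height",
                 random = c("provenance_id", "block_id", "mother_id"))
  expect_equal(tidy(f1)$variance, tidy(f2)$variance, tolerance = 1e-8)
})

test_that("a fixed-effect-only model reduces to ordinary least squares", {
  set.seed(31)
  d <- tibble::tibble(x = rnorm(40))
  d$y <- 2 + 3 * d$x + rnorm(40)
  fit <- reml_fit(d, "y", random = character(), fixed = ~x)
  ols <- stats::lm(y ~ x, data = d)
  expect_equal(fit$fixef$estimate, unname(coef(ols)), tolerance = 1e-10)
})

test_that("the optimizer never returns a worse point than its starting value", {
  d <- balanced_one_factor(n_groups = 15, n_per = 6, seed = 23)
  fit <- reml_fit(d, "y", random = "g")
  # equal-split start: sigma_g = sigma_e = var(y)/2
  vy <- var(d$y)
  Z <- Matrix::sparseMatrix(i = seq_len(nrow(d)), j = as.integer(factor(d$g)), x = 1)
  ll_start <- provtrial:::dense_reml_loglik(
    d$y, matrix(1, nrow(d), 1), list(Z), list(Matrix::Diagonal(15)),
    vy / 2, vy / 2)
  expect_gte(fit$loglik, ll_start - 1e-8)
})

test_that("BLUPs of balanced designs are centered and shrink toward zero", {
  sim <- simulate_garden(tiny_config(seed = 6))
  fit <- reml_fit(sim$trees, "height",
                  random = c("provenance_id", "mother_id"))
  b <- fit$blup
  for (tm in unique(b$term)) {
    expect_lt(abs(sum(b$blup[b$term == tm])), 1e-6 * sd(sim$trees$height))
  }
  # shrinkage: BLUPs vary less than raw group-mean deviations
  raw <- tapply(sim$trees$height, sim$trees$mother_id, mean)
  expect_lt(sd(b$blup[b$term == "mother_id"]), sd(raw))
})

test_that("prediction error variances are positive and bounded by the prior", {
  sim <- simulate_garden(tiny_config(seed = 8))
  fit <- reml_fit(sim$trees, "height", random = c("provenance_id", "mother_id"),
                  pev_terms = "mother_id")
  b <- dplyr::filter(fit$blup, .data$term == "mother_id")
  s2m <- tidy(fit)$variance[tidy(fit)$term == "mother_id"]
  expect_true(all(b$pev > 0))
  expect_true(all(b$pev <= s2m + 1e-8)) # PEV cannot exceed the prior variance
})

test_that("specification errors are raised before fitting", {
  d <- balanced_one_factor(n_groups = 4, n_per = 3)
  d$one <- "same"
  expect_error(reml_fit(d, "y", random = "one"), class = "provtrial_spec_error")
  expect_error(reml_fit(d, "nope", random = "g"), class = "provtrial_spec_error")
  expect_error(reml_fit(d, "y", random = "g", genetic = "g"),
               class = "provtrial_spec_error") # pedigree missing
})

test_that("variance percentages recompute the published component shares", {
  pub <- oak_growth_varcomp()
  h <- variance_percentages(dplyr::filter(pub, trait == "height"))
  expect_equal(round(h$pct[h$term == "site"], 2), 22.05)
  expect_equal(round(h$pct[h$term == "provenance"], 2), 9.12)
  expect_equal(round(h$pct[h$term == "residual"], 2), 60.62)
  d <- variance_percentages(dplyr::filter(pub, trait == "dbh"))
  expect_equal(round(d$pct[d$term == "site"], 2), 15.91)
  expect_equal(round(d$pct[d$term == "residual"], 2), 71.84)
  expect_equal(sum(h$pct), 100)
  # degenerate inputs
  one <- tibble::tibble(term = c("a", "residual"), variance = c(3, 0))
  expect_equal(variance_percentages(one)$pct, c(100, 0))
  expect_error(variance_percentages(tibble::tibble(term = "a", variance = 0)),
               class = "provtrial_domain_error")
})
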