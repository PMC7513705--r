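#' Narrow-sense heritability from variance components
#'
#' `h2 = s2_a / (s2_a + s2_e)`: the additive genetic variance over the sum of
#' additive and residual variance. Note the denominator deliberately excludes
#' provenance and block variance, matching the estimand used throughout this
#' package's within-site animal models; see [estimate_h2()] for a
#' phenotypic-total alternative.
#'
#' @param sigma_a Additive genetic variance (`>= 0`).
#' @param sigma_e Residual variance (`>= 0`; not both zero).
#' @return `h2` in `[0, 1]`.
#' @examples
#' heritability(3, 1) # 0.75
#' @export
heritability <- function(sigma_a, sigma_e) {
  if (any(sigma_a < 0) || any(sigma_e < 0)) {
    abort("variances must be non-negative", class = "provtrial_domain_error")
  }
  if (any(sigma_a + sigma_e == 0)) {
    abort("sigma_a and sigma_e cannot both be zero",
          class = "provtrial_domain_error")
  }
  sigma_a / (sigma_a + sigma_e)
}

#' Quantitative trait differentiation Qst from variance components
#'
#' `Qst = s2_pop / (s2_pop + 2 s2_a)`. The factor 2 assumes a fully
#' outcrossing species and purely additive gene action.
#'
#' @param sigma_pop Among-population (provenance or cluster) variance (`>= 0`).
#' @param sigma_a Additive genetic variance (`>= 0`; not both zero).
#' @return `Qst` in `[0, 1]`.
#' @examples
#' qst(2, 1) # 0.5
#' qst(1, 1) # 1/3
#' @export
qst <- function(sigma_pop, sigma_a) {
  if (any(sigma_pop < 0) || any(sigma_a < 0)) {
    abort("variances must be non-negative", class = "provtrial_domain_error")
  }
  if (any(sigma_pop + sigma_a == 0)) {
    abort("sigma_pop and sigma_a cannot both be zero",
          class = "provtrial_domain_error")
  }
  sigma_pop / (sigma_pop + 2 * sigma_a)
}

#' Estimate narrow-sense heritability from a trial via the animal model
#'
#' Fits the within-site individual-tree ("animal") model by REML and applies
#' `h2 = s2_a / (s2_a + s2_e)`. With `scope = "across"` the model contains
#' random provenance and block effects plus the pedigree-structured additive
#' term (the across-provenance heritability); with `scope = "within"` the data
#' are restricted to one provenance and the provenance term drops out. When
#' `site = NULL` all sites are pooled and a random site term is added.
#'
#' The 95% confidence interval is a normal (delta-method) approximation using
#' the average-information covariance of the variance estimates, truncated to
#' `[0, 1]`. The estimate is flagged significant when the lower bound exceeds
#' zero. Non-convergence of the underlying REML fit is propagated in the
#' `converged` column, not raised.
#'
#' @param trees Trial tibble (see [read_trial()]).
#' @param site Site id to subset to, or `NULL` for a pooled fit across sites.
#' @param scope `"across"` (provenances, default) or `"within"` (one
#'   provenance, named in `provenance`).
#' @param provenance Provenance id, required for `scope = "within"`.
#' @param trait Response column, default `"height"`.
#' @param group_col Column holding the population grouping used for the
#'   provenance random term (swap in a climatic-cluster column to group by
#'   cluster).
#' @param level Confidence level for the interval.
#' @param denominator `"additive_residual"` (as printed formula, default) or
#'   `"phenotypic"` to divide by the full phenotypic variance instead (a
#'   sensitivity option).
#' @return A one-row tibble: `trait`, `site`, `scope`, `provenance`, `h2`,
#'   `se`, `lower`, `upper`, `significant`, `sigma_a`, `sigma_e`, `n`,
#'   `converged`. The underlying [reml_fit()] is attached as attribute
#'   `"fit"`.
#' @export
estimate_h2 <- function(trees, site = NULL, scope = c("across", "within"),
                        provenance = NULL, trait = "height",
                        group_col = "provenance_id", level = 0.95,
                        denominator = c("additive_residual", "phenotypic")) {
  scope <- match.arg(scope)
  denominator <- match.arg(denominator)
  d <- trees
  if (!is.null(site)) d <- dplyr::filter(d, .data$site_id == site)
  if (scope == "within") {
    if (is.null(provenance)) {
      abort("scope = 'within' needs a provenance", class = "provtrial_spec_error")
    }
    d <- dplyr::filter(d, .data[[group_col]] == provenance)
    random <- "block_id"
  } else {
    random <- c(group_col, "block_id")
  }
  if (is.null(site)) random <- c("site_id", random)
  if (nrow(d) == 0) abort("empty site/provenance subset", class = "provtrial_spec_error")

  ped <- pedigree_from_trees(d)
  fit <- reml_fit(d, trait, random = random, genetic = "tree_id", pedigree = ped)
  vc <- fit$varcomp
  s_a <- vc$variance[vc$term == "tree_id"]
  s_e <- vc$variance[vc$term == "residual"]
  denom <- if (denominator == "phenotypic") sum(vc$variance) else s_a + s_e
  h2 <- s_a / denom

  ci <- delta_ratio_ci(fit, num_term = "tree_id",
                       denom_terms = if (denominator == "phenotypic")
                         vc$term else c("tree_id", "residual"),
                       scale = 1, level = level)
  out <- tibble::tibble(
    trait = trait, site = site %||% "all", scope = scope,
    provenance = provenance %||% "all",
    h2 = h2, se = ci$se, lower = ci$lower, upper = ci$upper,
    significant = is.finite(ci$lower) && ci$lower > 0,
    sigma_a = s_a, sigma_e = s_e, n = fit$n, converged = fit$converged
  )
  attr(out, "fit") <- fit
  out
}

# delta-method CI for ratio num / sum(denoms) from a reml_fit's AI covariance,
# truncated to [0, 1]
delta_ratio_ci <- function(fit, num_term, denom_terms, scale = 1, level = 0.95) {
  vc <- fit$varcomp
  V <- fit$vcov_theta
  est_num <- vc$variance[vc$term == num_term] * scale
  est_den <- sum(vc$variance[vc$term %in% denom_terms])
  ratio <- est_num / est_den
  if (is.null(V) || anyNA(V[c(num_term, denom_terms), c(num_term, denom_terms)])) {
    return(list(se = NA_real_, lower = NA_real_, upper = NA_real_))
  }
  terms <- rownames(V)
  g <- setNames(numeric(length(terms)), terms)
  # d(ratio)/d(theta_j): num scale/den for the numerator component,
  # minus num/den^2 for every denominator component
  g[num_term] <- g[num_term] + scale / est_den
  g[denom_terms] <- g[denom_terms] - est_num / est_den^2
  v <- as.numeric(t(g) %*% V %*% g)
  if (!is.finite(v) || v < 0) {
    return(list(se = NA_real_, lower = NA_real_, upper = NA_real_))
  }
  se <- sqrt(v)
  zc <- qnorm(1 - (1 - level) / 2)
  list(se = se,
       lower = max(0, ratio - zc * se),
       upper = min(1, ratio + zc * se))
}

#' Estimate Qst from a trial, with a family-bootstrap confidence interval
#'
#' Fits a mixed model with a random population term (provenance or climatic
#' cluster), block, the pedigree-structured additive term (and site when
#' pooling across sites), then applies `Qst = s2_pop / (s2_pop + 2 s2_a)`.
#'
#' The confidence interval is a nonparametric bootstrap over families:
#' families are resampled with replacement within each population, each
#' resample is refitted and the percentile interval of the resampled Qst
#' values is reported. By default the bootstrap refits use the family model
#' (family variance `= s2_a / 4`, an exact reparameterization of the animal
#' model for maternal half-sib data with unphenotyped mothers), which is much
#' faster; `boot_model = "animal"` refits the full animal model instead.
#'
#' @param trees Trial tibble.
#' @param grouping Column holding the population label (default provenance;
#'   join a cluster assignment first to group by climatic cluster).
#' @param site Site id, or `NULL` to pool across sites.
#' @param trait Response column.
#' @param n_boot Number of bootstrap resamples (0 skips the interval).
#' @param seed Seed for the bootstrap resampling.
#' @param level Confidence level.
#' @param boot_model `"family"` (default) or `"animal"`.
#' @return A one-row tibble: `trait`, `site`, `grouping`, `qst`, `lower`,
#'   `upper`, `sigma_pop`, `sigma_a`, `n_groups`, `n`, `n_boot`, `converged`;
#'   the point-estimate [reml_fit()] is attached as attribute `"fit"` and the
#'   bootstrap replicates as attribute `"boot"`.
#' @export
estimate_qst <- function(trees, grouping = "provenance_id", site = NULL,
                         trait = "height", n_boot = 0, seed = 1,
                         level = 0.95, boot_model = c("family", "animal")) {
  boot_model <- match.arg(boot_model)
  d <- trees
  if (!is.null(site)) d <- dplyr::filter(d, .data$site_id == site)
  groups <- unique(d[[grouping]])
  if (length(groups) < 2) {
    abort("Qst needs at least 2 groups", class = "provtrial_spec_error")
  }
  fam_per_group <- d |>
    dplyr::distinct(.data[[grouping]], .data$mother_id) |>
    dplyr::count(.data[[grouping]])
  if (any(fam_per_group$n < 2)) {
    abort("Qst needs at least 2 families per group", class = "provtrial_spec_error")
  }
  random <- c(grouping, "block_id")
  if (is.null(site)) random <- c("site_id", random)

  ped <- pedigree_from_trees(d)
  fit <- reml_fit(d, trait, random = random, genetic = "tree_id", pedigree = ped)
  vc <- fit$varcomp
  s_pop <- vc$variance[vc$term == grouping]
  s_a <- vc$variance[vc$term == "tree_id"]
  q_hat <- qst(s_pop, s_a)

  lower <- upper <- NA_real_
  boot_vals <- numeric(0)
  if (n_boot > 0) {
    old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
    on.exit(restore_seed(old_seed), add = TRUE)
    set.seed(seed)
    fam_tab <- d |> dplyr::distinct(.data[[grouping]], .data$mother_id)
    by_group <- split(fam_tab$mother_id, fam_tab[[grouping]])
    boot_vals <- vapply(seq_len(n_boot), function(b) {
      resampled <- purrr::imap_dfr(by_group, function(fams, grp) {
        pick <- sample(fams, length(fams), replace = TRUE)
        purrr::imap_dfr(pick, function(fam, j) {
          rows <- d[d$mother_id == fam, , drop = FALSE]
          rows$mother_id <- paste0(fam, "_b", j) # copies become distinct families
          rows$tree_id <- paste0(rows$tree_id, "_b", j)
          rows
        })
      })
      qst_refit(resampled, grouping, random, trait, boot_model)
    }, numeric(1))
    probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
    qs <- quantile(boot_vals, probs, na.rm = TRUE, names = FALSE)
    lower <- qs[1]; upper <- qs[2]
  }
  out <- tibble::tibble(
    trait = trait, site = site %||% "all", grouping = grouping,
    qst = q_hat, lower = lower, upper = upper,
    sigma_pop = s_pop, sigma_a = s_a,
    n_groups = length(groups), n = fit$n, n_boot = n_boot,
    converged = fit$converged
  )
  attr(out, "fit") <- fit
  attr(out, "boot") <- boot_vals
  out
}

qst_refit <- function(d, grouping, random, trait, boot_model) {
  est <- tryCatch({
    if (boot_model == "animal") {
      ped <- pedigree_from_trees(d)
      f <- reml_fit(d, trait, random = random, genetic = "tree_id", pedigree = ped)
      vc <- f$varcomp
      qst(vc$variance[vc$term == grouping], vc$variance[vc$term == "tree_id"])
    } else {
      f <- reml_fit(d, trait, random = c(random, "mother_id"))
      vc <- f$varcomp
      # half-sib identity: family variance = s2_a / 4
      qst(vc$variance[vc$term == grouping],
          4 * vc$variance[vc$term == "mother_id"])
    }
  }, error = function(e) NA_real_)
  est
}
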