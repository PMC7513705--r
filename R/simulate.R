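#' Configuration for a synthetic multi-site half-sib common garden
#'
#' The defaults emulate a 10-year, three-site pedunculate oak provenance
#' trial: 3 sites x 10 provenances x 3 blocks per site x 22 open-pollinated
#' families per provenance x 5 offspring per family per block = 9,900 trees,
#' with variance components on the height scale (cm2) matching the reference
#' component table shipped with the package (see [oak_growth_varcomp()]),
#' additive variance equal to four times the published family variance (the
#' half-sib identity), a concave quadratic response of provenance means to
#' the provenance-minus-site mean-annual-temperature distance, and 94%
#' survival.
#'
#' @param n_sites,n_provenances,n_blocks_per_site,n_families_per_provenance,n_offspring_per_family_per_block
#'   Design counts (all `>= 1`).
#' @param mean_height Grand mean of the simulated height (cm).
#' @param var_site,var_provenance,var_block,var_additive,var_prov_x_site,var_fam_x_site,var_residual
#'   Generative variance components (trait^2, all `>= 0`). `var_additive` is
#'   the additive genetic variance `s2_a`; maternal half-sibs share `s2_a/4`.
#' @param transfer_curvature Curvature `c >= 0` (cm per degC^2) of the
#'   deterministic climate penalty `-c * (MAT_prov - MAT_site)^2` added to
#'   provenance-by-site means; `0` disables the transfer surface.
#' @param survival_prob Probability that a tree is alive at measurement;
#'   dead trees keep their design row but have missing growth traits.
#' @param full_sib_fraction Fraction of offspring within each family that
#'   share a single common father (default 0: pure half-sibs).
#' @param dbh_mean,dbh_scale,dbh_noise_sd Parameters of the correlated dbh
#'   trait: `dbh = dbh_mean + dbh_scale * (height - mean_height) + noise`.
#' @param climate Optional climate tibble in [read_climate()] shape providing
#'   provenance and site rows. By default the shipped ten-provenance table is
#'   used when `n_provenances == 10`, otherwise synthetic climates are drawn
#'   uniformly over that table's observed range; site climates are always
#'   drawn over the same range unless supplied.
#' @param seed Integer seed; the whole dataset is reproducible from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_sites = 3, n_provenances = 10, n_blocks_per_site = 3,
                       n_families_per_provenance = 22,
                       n_offspring_per_family_per_block = 5,
                       mean_height = 470,
                       var_site = 5000, var_provenance = 2000, var_block = 60,
                       var_additive = 3600, var_prov_x_site = 620,
                       var_fam_x_site = 280, var_residual = 11000,
                       transfer_curvature = 19, survival_prob = 0.94,
                       full_sib_fraction = 0,
                       dbh_mean = 4.4, dbh_scale = 0.011, dbh_noise_sd = 1.28,
                       climate = NULL, seed = 1L) {
  cfg <- as.list(environment())
  counts <- cfg[c("n_sites", "n_provenances", "n_blocks_per_site",
                  "n_families_per_provenance",
                  "n_offspring_per_family_per_block")]
  if (any(unlist(counts) < 1)) {
    abort("all design counts must be >= 1", class = "provtrial_config_error")
  }
  vars <- cfg[grep("^var_", names(cfg))]
  if (any(unlist(vars) < 0)) {
    abort("variance components must be non-negative",
          class = "provtrial_config_error")
  }
  if (survival_prob <= 0 || survival_prob > 1) {
    abort("survival_prob must lie in (0, 1]", class = "provtrial_config_error")
  }
  if (transfer_curvature < 0) {
    abort("transfer_curvature must be >= 0", class = "provtrial_config_error")
  }
  if (full_sib_fraction < 0 || full_sib_fraction > 1) {
    abort("full_sib_fraction must lie in [0, 1]", class = "provtrial_config_error")
  }
  structure(cfg, class = "sim_config")
}

#' Generate a synthetic common-garden dataset with known ground truth
#'
#' Simulates every term of the multi-site half-sib model: phenotype = grand
#' mean + site + block(site) + provenance + provenance-by-site +
#' family-by-site + individual breeding value + residual, with an optional
#' deterministic quadratic climate-transfer penalty on provenance-by-site
#' means. Breeding values follow the half-sib construction: each founder
#' mother draws `a_m ~ N(0, s2_a)` and each offspring receives
#' `a = a_m / 2 + m` with Mendelian deviation `m ~ N(0, 3/4 s2_a)`, so
#' maternal half-sibs share covariance `s2_a / 4` exactly by construction.
#' Mortality is independent Bernoulli; dead trees keep their design row with
#' missing growth traits. A correlated dbh trait is derived from the height
#' phenotype (see [sim_config()]).
#'
#' The same seed reproduces the dataset bit for bit. The generator's own RNG
#' state is isolated from the caller's.
#'
#' @param config A [sim_config()] object.
#' @return A `garden_sim` list: `trees` (trial tibble, see [read_trial()]),
#'   `pedigree`, `climate`, and `truth` (the config, the realized effect
#'   draws, and derived true parameters). Use [truth_report()] for a flat
#'   view of the truth.
#' @examples
#' sim <- simulate_garden(sim_config(n_provenances = 3,
#'   n_families_per_provenance = 4, n_offspring_per_family_per_block = 2))
#' dplyr::count(sim$trees, site_id)
#' @export
simulate_garden <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(config$seed)
  cfg <- config

  sites <- paste0("S", seq_len(cfg$n_sites))
  provs_n <- cfg$n_provenances

  # --- climate ---------------------------------------------------------------
  ref <- oak_provenance_climate()
  if (!is.null(cfg$climate)) {
    climate <- cfg$climate
    validate_climate(climate)
    provs <- climate$unit_id[climate$role == "provenance"]
    if (length(provs) != provs_n) {
      abort("supplied climate must contain one provenance row per provenance",
            class = "provtrial_config_error")
    }
    site_clim <- climate[climate$role == "site", , drop = FALSE]
    if (nrow(site_clim) != cfg$n_sites) {
      abort("supplied climate must contain one site row per site",
            class = "provtrial_config_error")
    }
    sites <- site_clim$unit_id
  } else {
    if (provs_n == 10) {
      prov_clim <- ref |>
        dplyr::transmute(unit_id = .data$provenance_id, role = "provenance",
                         MAT = .data$MAT, MAP = .data$MAP, MWMT = .data$MWMT,
                         MCMT = .data$MCMT, lat = .data$lat, lon = .data$lon)
    } else {
      prov_clim <- synth_climate(paste0("P", seq_len(provs_n)), "provenance", ref)
    }
    site_clim <- synth_climate(sites, "site", ref)
    climate <- dplyr::bind_rows(prov_clim, site_clim) |>
      dplyr::mutate(MSP = round(runif(dplyr::n(), 0.45, 0.55) * .data$MAP, 2))
    provs <- prov_clim$unit_id
  }
  site_mat <- setNames(site_clim$MAT, site_clim$unit_id %||% sites)
  if (is.null(names(site_mat))) names(site_mat) <- sites
  prov_mat <- setNames(climate$MAT[climate$role == "provenance"], provs)

  # --- effect draws ----------------------------------------------------------
  blocks <- as.vector(outer(paste0("B", seq_len(cfg$n_blocks_per_site)),
                            sites, function(b, s) paste(s, b, sep = "_")))
  mothers <- as.vector(outer(sprintf("F%02d", seq_len(cfg$n_families_per_provenance)),
                             provs, function(f, p) paste0("P", p, "_", f)))
  eff <- list(
    site = setNames(rnorm(length(sites), 0, sqrt(cfg$var_site)), sites),
    block = setNames(rnorm(length(blocks), 0, sqrt(cfg$var_block)), blocks),
    provenance = setNames(rnorm(provs_n, 0, sqrt(cfg$var_provenance)), provs),
    maternal_bv = setNames(rnorm(length(mothers), 0, sqrt(cfg$var_additive)), mothers)
  )
  ps_levels <- as.vector(outer(provs, sites, paste, sep = ":"))
  fs_levels <- as.vector(outer(mothers, sites, paste, sep = ":"))
  eff$prov_x_site <- setNames(rnorm(length(ps_levels), 0, sqrt(cfg$var_prov_x_site)),
                              ps_levels)
  eff$fam_x_site <- setNames(rnorm(length(fs_levels), 0, sqrt(cfg$var_fam_x_site)),
                             fs_levels)
  father_bv <- setNames(rnorm(length(mothers), 0, sqrt(cfg$var_additive)), mothers)

  # --- tree table ------------------------------------------------------------
  design <- tidyr::expand_grid(
    site_id = sites,
    block = paste0("B", seq_len(cfg$n_blocks_per_site)),
    prov = provs,
    fam = sprintf("F%02d", seq_len(cfg$n_families_per_provenance)),
    rep = seq_len(cfg$n_offspring_per_family_per_block)
  ) |>
    dplyr::mutate(
      block_id = paste(.data$site_id, .data$block, sep = "_"),
      provenance_id = .data$prov,
      mother_id = paste0("P", .data$prov, "_", .data$fam),
      tree_id = paste(.data$site_id, .data$block, .data$mother_id,
                      sprintf("T%02d", .data$rep), sep = "_")
    )
  n <- nrow(design)

  full_sib <- runif(n) < cfg$full_sib_fraction
  mend_sd <- ifelse(full_sib, sqrt(0.5 * cfg$var_additive),
                    sqrt(0.75 * cfg$var_additive))
  bv <- 0.5 * eff$maternal_bv[design$mother_id] +
    ifelse(full_sib, 0.5 * father_bv[design$mother_id], 0) +
    rnorm(n, 0, mend_sd)

  transfer_pen <- -cfg$transfer_curvature *
    (prov_mat[design$provenance_id] - site_mat[design$site_id])^2
  resid <- rnorm(n, 0, sqrt(cfg$var_residual))
  height <- cfg$mean_height +
    eff$site[design$site_id] +
    eff$block[design$block_id] +
    eff$provenance[design$provenance_id] +
    eff$prov_x_site[paste(design$provenance_id, design$site_id, sep = ":")] +
    eff$fam_x_site[paste(design$mother_id, design$site_id, sep = ":")] +
    bv + transfer_pen + resid
  dbh <- cfg$dbh_mean + cfg$dbh_scale * (height - cfg$mean_height) +
    rnorm(n, 0, cfg$dbh_noise_sd)

  alive <- runif(n) < cfg$survival_prob
  height[!alive] <- NA_real_
  dbh[!alive] <- NA_real_
  height <- pmax(height, 1)  # floor far in the tail; keeps heights positive
  dbh <- pmax(dbh, 0.1)

  trees <- tibble::tibble(
    tree_id = design$tree_id, site_id = design$site_id,
    block_id = design$block_id, provenance_id = design$provenance_id,
    mother_id = design$mother_id,
    height = round(unname(height), 1), dbh = round(unname(dbh), 2),
    alive = alive
  )
  pedigree <- pedigree_from_trees(trees)

  truth <- list(
    config = cfg, effects = eff,
    breeding_values = setNames(bv, design$tree_id),
    realized = c(
      site = var(eff$site), block = var(eff$block),
      provenance = var(eff$provenance),
      family = var(eff$maternal_bv) / 4, additive = var(bv),
      mendelian = var(bv - 0.5 * eff$maternal_bv[design$mother_id]),
      prov_x_site = var(eff$prov_x_site), fam_x_site = var(eff$fam_x_site),
      residual = var(resid)
    )
  )
  structure(list(trees = trees, pedigree = pedigree, climate = climate,
                 truth = truth),
            class = "garden_sim")
}

#' Ground-truth parameter report for a simulated garden
#'
#' Flattens the generative truth of a [simulate_garden()] result into a
#' two-column tibble for parameter-recovery tests: every scalar configuration
#' field, the implied true narrow-sense heritability
#' `h2 = s2_a / (s2_a + s2_e)`, the true Qst implied by the configured
#' provenance variance (`s2_pop / (s2_pop + 2 s2_a)`), and the same quantity
#' recomputed from the provenance effects actually drawn.
#'
#' @param sim A `garden_sim` object.
#' @return A tibble with columns `parameter` and `value`.
#' @export
truth_report <- function(sim) {
  stopifnot(inherits(sim, "garden_sim"))
  cfg <- sim$truth$config
  scalars <- cfg[vapply(cfg, function(x) is.numeric(x) && length(x) == 1, logical(1))]
  prov_eff <- sim$truth$effects$provenance
  realized_pop_var <- if (length(prov_eff) > 1) var(prov_eff) else 0
  denom_h2 <- cfg$var_additive + cfg$var_residual
  tibble::tibble(
    parameter = c(names(scalars), "n_trees", "n_alive",
                  "true_h2", "true_qst", "realized_provenance_var",
                  "true_qst_realized"),
    value = unname(c(unlist(scalars), nrow(sim$trees), sum(sim$trees$alive),
              if (denom_h2 > 0) cfg$var_additive / denom_h2 else NA_real_,
              qst_safe(cfg$var_provenance, cfg$var_additive),
              realized_pop_var,
              qst_safe(realized_pop_var, cfg$var_additive)))
  )
}

qst_safe <- function(pop, add) {
  if (pop + add <= 0) return(NA_real_)
  pop / (pop + 2 * add)
}

#' @export
print.garden_sim <- function(x, ...) {
  cfg <- x$truth$config
  cat("Synthetic common garden:", nrow(x$trees), "trees |",
      cfg$n_sites, "sites x", cfg$n_provenances, "provenances x",
      cfg$n_families_per_provenance, "families\n")
  cat("alive:", sum(x$trees$alive), sprintf("(%.1f%%)\n",
      100 * mean(x$trees$alive)))
  invisible(x)
}

# uniform synthetic climates over the observed range of the reference table,
# preserving MWMT >= MAT >= MCMT by drawing offsets over their observed range
synth_climate <- function(ids, role, ref) {
  k <- length(ids)
  mat <- runif(k, min(ref$MAT), max(ref$MAT))
  wo <- ref$MWMT - ref$MAT; co <- ref$MAT - ref$MCMT
  tibble::tibble(
    unit_id = ids, role = role,
    MAT = round(mat, 2),
    MAP = round(runif(k, min(ref$MAP), max(ref$MAP)), 2),
    MWMT = round(mat + runif(k, min(wo), max(wo)), 2),
    MCMT = round(mat - runif(k, min(co), max(co)), 2),
    lat = round(runif(k, min(ref$lat), max(ref$lat)), 2),
    lon = round(runif(k, min(ref$lon), max(ref$lon)), 2)
  )
}

# restore the caller's RNG stream after seeded generation
restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
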