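#' Summer heat:moisture index
#'
#' `SHM = MWMT / (MSP / 1000)`: mean warmest-month temperature (degC) over
#' May--September precipitation (mm) scaled to meters. Higher values indicate
#' drier long-term growing conditions at the location.
#'
#' @param MWMT Mean warmest-month temperature, degC.
#' @param MSP May--September precipitation, mm (`> 0`).
#' @return The SHM index (vectorized).
#' @examples
#' compute_shm(20, 500) # 40
#' @export
compute_shm <- function(MWMT, MSP) {
  if (any(MSP <= 0)) {
    abort("MSP must be positive", class = "provtrial_domain_error")
  }
  MWMT / (MSP / 1000)
}

# Hagen-Poiseuille constant: pi * rho_w / (128 eta) with water at 20 degC
# (rho_w = 998.2 kg/m3, eta = 1.002e-3 Pa s)
hp_constant <- function() pi * 998.2 / (128 * 1.002e-3)

#' Theoretical xylem hydraulic conductivity (Hagen--Poiseuille)
#'
#' `Kh = (pi rho_w / 128 eta) * VD * Dh^4` with water density
#' `rho_w = 998.2 kg/m3` and viscosity `eta = 1.002e-3 Pa s` (20 degC),
#' vessel density `VD` in vessels per m2 of cross-section, and hydraulic
#' diameter `Dh = (sum(D^4) / n)^(1/4)` where each vessel's `D` is the mean
#' of its minor and major axis diameters. With zero vessels `Kh = 0`.
#'
#' The fourth-root hydraulic mean is the dimensionally consistent form;
#' `literal_dh = TRUE` switches to the alternative `(sum(D^4)/n)/4`
#' convention, kept selectable for comparison with sources that print it
#' that way.
#'
#' @param vessels Tibble of individual vessels with columns `minor` and
#'   `major` (axis diameters, um). May have zero rows.
#' @param section_area_mm2 Sampled cross-section area in mm2 (`> 0`).
#' @param literal_dh Use the literal `(sum(D^4)/n)/4` in place of the
#'   fourth root (default `FALSE`).
#' @return `Kh` in SI units (kg m / (s MPa) equivalent:
#'   kg m^-1 s^-1 Pa^-1 x m2).
#' @examples
#' v <- tibble::tibble(minor = 50, major = 50)
#' compute_kh(v, section_area_mm2 = 0.01) # one 50-um vessel at VD = 1e8 m-2
#' @export
compute_kh <- function(vessels, section_area_mm2, literal_dh = FALSE) {
  if (section_area_mm2 <= 0) {
    abort("section area must be positive", class = "provtrial_domain_error")
  }
  if (nrow(vessels) == 0) return(0)
  if (any(vessels$minor < 0 | vessels$major < 0)) {
    abort("vessel diameters must be non-negative", class = "provtrial_domain_error")
  }
  if (any(vessels$major < vessels$minor)) {
    abort("major axis must be >= minor axis", class = "provtrial_domain_error")
  }
  d_m <- (vessels$minor + vessels$major) / 2 * 1e-6 # um -> m
  n <- length(d_m)
  vd_m2 <- n / (section_area_mm2 * 1e-6) # vessels per m2
  dh4 <- if (literal_dh) (sum(d_m^4) / n / 4)^4 else sum(d_m^4) / n
  hp_constant() * vd_m2 * dh4
}

#' Leaf traits from mass and area primitives
#'
#' Specific leaf area by this study's convention, `SLA = dry mass / area`
#' (g/cm2 -- the reciprocal of the more common area/mass definition; the
#' column is named `SLA_mass_per_area` to make the convention explicit), and
#' leaf dry matter content `LDMC = dry mass / saturated mass` (g/g).
#'
#' @param dry_mass Leaf dry mass, g (`> 0`).
#' @param saturated_mass Water-saturated leaf mass, g (`>= dry_mass`).
#' @param leaf_area One-sided leaf area, cm2 (`> 0`).
#' @return A tibble with columns `SLA_mass_per_area` and `LDMC` (vectorized).
#' @examples
#' leaf_traits(dry_mass = 1, saturated_mass = 2.5, leaf_area = 100)
#' @export
leaf_traits <- function(dry_mass, saturated_mass, leaf_area) {
  if (any(dry_mass <= 0) || any(saturated_mass <= 0) || any(leaf_area <= 0)) {
    abort("masses and areas must be positive", class = "provtrial_domain_error")
  }
  if (any(dry_mass > saturated_mass)) {
    abort("dry mass cannot exceed saturated mass",
          class = "provtrial_domain_error")
  }
  tibble::tibble(SLA_mass_per_area = dry_mass / leaf_area,
                 LDMC = dry_mass / saturated_mass)
}

#' Vessel summary statistics for one cross-section
#'
#' Mean vessel lumen area (`VA`, um2), its 95% quantile (`VA_max`, linear
#' interpolation between order statistics, the default "type 7" convention),
#' vessel lumen fraction (`F`, total lumen area over section area) and vessel
#' density (`VD`, vessels per mm2). A lumen fraction above 1 indicates
#' inconsistent measurements and is raised as an error.
#'
#' @param vessels Tibble with a column `area` (lumen areas, um2, `> 0`), at
#'   least one row.
#' @param section_area_mm2 Sampled cross-section area in mm2 (`> 0`).
#' @return A one-row tibble: `VA`, `VA_max`, `F`, `VD`, `n_vessels`.
#' @export
vessel_summary <- function(vessels, section_area_mm2) {
  if (nrow(vessels) < 1) {
    abort("need at least one vessel", class = "provtrial_domain_error")
  }
  if (any(vessels$area <= 0)) {
    abort("vessel areas must be positive", class = "provtrial_domain_error")
  }
  if (section_area_mm2 <= 0) {
    abort("section area must be positive", class = "provtrial_domain_error")
  }
  lumen_mm2 <- sum(vessels$area) * 1e-6 # um2 -> mm2
  f <- lumen_mm2 / section_area_mm2
  if (f > 1) {
    abort("vessel lumen fraction exceeds 1: inconsistent measurements",
          class = "provtrial_measurement_error")
  }
  tibble::tibble(
    VA = mean(vessels$area),
    VA_max = unname(quantile(vessels$area, 0.95, type = 7)),
    F = f,
    VD = nrow(vessels) / section_area_mm2,
    n_vessels = nrow(vessels)
  )
}

#' Per-tree vessel traits from a long vessel table
#'
#' Convenience wrapper applying [vessel_summary()] and [compute_kh()] per
#' tree to a long table of individual vessels.
#'
#' @param data Tibble with columns `tree_id`, `area` (um2), `minor`, `major`
#'   (um) and `section_area_mm2` (constant within tree).
#' @return One row per tree: `tree_id`, `VA`, `VA_max`, `F`, `VD`,
#'   `n_vessels`, `Kh`.
#' @export
vessel_traits <- function(data) {
  data |>
    dplyr::group_by(.data$tree_id) |>
    dplyr::group_modify(function(d, key) {
      sa <- d$section_area_mm2[1]
      dplyr::bind_cols(vessel_summary(d, sa),
                       tibble::tibble(Kh = compute_kh(d, sa)))
    }) |>
    dplyr::ungroup()
}

#' Benjamini--Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment: adjusted values are monotone in
#' the input ranks and capped at 1.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order as the input.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.04)) # 0.03 0.03 0.04
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    abort("p-values must lie in [0, 1]", class = "provtrial_domain_error")
  }
  p.adjust(p, method = "BH")
}

#' Provenance-level trait--climate regressions per site
#'
#' For each site and each trait: averages the trait to provenance level,
#' regresses the provenance means on a climate variable at seed origin
#' (default the summer heat:moisture index, computed from `MWMT` and `MSP`
#' when not already present), and tests the slope two-sided. p-values are
#' Benjamini--Hochberg adjusted within site across the trait family.
#'
#' @param data Tree-level tibble with `provenance_id`, `site_id` and the
#'   trait columns.
#' @param traits Character vector of trait columns to regress.
#' @param climate Climate tibble with provenance rows carrying the climate
#'   variable (or `MWMT` + `MSP` when `climate_var = "SHM"`).
#' @param climate_var Climate variable at seed origin (default `"SHM"`).
#' @return A tibble: `site`, `trait`, `slope`, `intercept`, `r_squared`,
#'   `n_prov`, `p_value`, `p_adjusted`.
#' @export
trait_climate_regression <- function(data, traits, climate,
                                     climate_var = "SHM") {
  prov <- climate[climate$role == "provenance", , drop = FALSE]
  if (climate_var == "SHM" && !"SHM" %in% names(prov)) {
    if (!all(c("MWMT", "MSP") %in% names(prov))) {
      abort("computing SHM needs MWMT and MSP in the climate table",
            class = "provtrial_spec_error")
    }
    prov$SHM <- compute_shm(prov$MWMT, prov$MSP)
  }
  if (!climate_var %in% names(prov)) {
    abort(paste0("climate variable '", climate_var, "' not found"),
          class = "provtrial_spec_error")
  }
  clim <- tibble::tibble(provenance_id = prov$unit_id, x = prov[[climate_var]])
  means <- data |>
    tidyr::pivot_longer(dplyr::all_of(traits), names_to = "trait",
                        values_to = "value") |>
    dplyr::group_by(.data$site_id, .data$trait, .data$provenance_id) |>
    dplyr::summarise(value = mean(.data$value, na.rm = TRUE), .groups = "drop") |>
    dplyr::inner_join(clim, by = "provenance_id")
  out <- means |>
    dplyr::group_by(site = .data$site_id, trait = .data$trait) |>
    dplyr::group_modify(function(d, key) {
      if (sum(stats::complete.cases(d[, c("value", "x")])) < 3) {
        abort("need at least 3 provenances per regression",
              class = "provtrial_spec_error")
      }
      m <- summary(lm(value ~ x, data = d))
      tibble::tibble(slope = m$coefficients[2, 1],
                     intercept = m$coefficients[1, 1],
                     r_squared = m$r.squared,
                     n_prov = nrow(d),
                     p_value = m$coefficients[2, 4])
    }) |>
    dplyr::ungroup()
  # one BH family per site, across the trait set tested there
  out |>
    dplyr::group_by(.data$site) |>
    dplyr::mutate(p_adjusted = bh_adjust(.data$p_value)) |>
    dplyr::ungroup()
}

#' Trait--growth Pearson correlations
#'
#' Pearson product-moment correlations between functional traits and growth
#' traits, at the individual-tree level or between provenance-mean traits and
#' provenance-mean growth, per site and pooled across sites.
#'
#' @param data Tree-level tibble with `provenance_id`, `site_id`, the trait
#'   and the growth columns.
#' @param traits Character vector of trait columns.
#' @param growth Character vector of growth columns (e.g. height, dbh).
#' @param level `"tree"` (default) or `"provenance"` for provenance means.
#' @param by_site Also return per-site correlations (default `TRUE`); the
#'   pooled rows carry `site = "pooled"`.
#' @return A tibble: `site`, `trait`, `growth`, `r`, `n`, `p_value`.
#' @export
trait_growth_correlation <- function(data, traits, growth,
                                     level = c("tree", "provenance"),
                                     by_site = TRUE) {
  level <- match.arg(level)
  scopes <- if (by_site) c("pooled", unique(data$site_id)) else "pooled"
  purrr::map_dfr(scopes, function(sc) {
    d <- if (sc == "pooled") data else data[data$site_id == sc, , drop = FALSE]
    if (level == "provenance") {
      d <- d |>
        dplyr::group_by(.data$provenance_id) |>
        dplyr::summarise(dplyr::across(dplyr::all_of(c(traits, growth)),
                                       ~mean(.x, na.rm = TRUE)),
                         .groups = "drop")
    }
    tidyr::expand_grid(trait = traits, growth = growth) |>
      purrr::pmap_dfr(function(trait, growth) {
        ok <- stats::complete.cases(d[[trait]], d[[growth]])
        x <- d[[trait]][ok]; y <- d[[growth]][ok]
        if (length(x) < 3) {
          abort("need at least 3 paired observations",
                class = "provtrial_spec_error")
        }
        if (sd(x) == 0 || sd(y) == 0) {
          abort("correlation undefined for a constant vector",
                class = "provtrial_domain_error")
        }
        ct <- cor.test(x, y)
        tibble::tibble(site = sc, trait = trait, growth = growth,
                       r = unname(ct$estimate), n = length(x),
                       p_value = ct$p.value)
      })
  })
}
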