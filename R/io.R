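#' Read a common-garden trial table
#'
#' Reads one row per planted tree: design factors (site, block nested in site,
#' provenance, mother/family nested in provenance), the two growth traits
#' (height and dbh, both in cm) and survival status. The table is validated
#' against the design invariants before it is returned: every block must occur
#' in exactly one site, every mother in exactly one provenance, growth traits
#' must be positive where present, and dead trees must carry missing growth
#' traits (mortality bookkeeping is kept separate from estimation; records for
#' dead trees are retained but never enter model design matrices).
#'
#' The expected CSV dialect is comma-separated UTF-8 with `.` as the decimal
#' mark and empty cells for missing values. Files whose columns are named
#' differently can be mapped with `col_map`.
#'
#' @param path Path to a CSV file.
#' @param col_map Optional mapping from the canonical column names
#'   (`tree_id`, `site_id`, `block_id`, `provenance_id`, `mother_id`,
#'   `height`, `dbh`, `alive`) to the names used in the file. Either a named
#'   character vector (`c(height = "h10", ...)`) or the path to a YAML file of
#'   `canonical: actual` pairs.
#' @return A tibble with the canonical columns, one row per tree.
#' @seealso [simulate_garden()] to generate such tables with known truth.
#' @export
read_trial <- function(path, col_map = NULL) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  x <- apply_col_map(x, col_map)
  need <- c("tree_id", "site_id", "block_id", "provenance_id", "mother_id",
            "height", "dbh", "alive")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    abort(paste0("trial table is missing column(s): ", toString(miss)),
          class = "provtrial_schema_error")
  }
  x <- dplyr::mutate(
    x,
    dplyr::across(dplyr::all_of(c("tree_id", "site_id", "block_id",
                                  "provenance_id", "mother_id")), as.character),
    height = as.numeric(.data$height),
    dbh    = as.numeric(.data$dbh),
    alive  = parse_logical_col(.data$alive)
  )
  validate_trial(x)
  pt_log("read_trial: ", nrow(x), " trees from ", path)
  tibble::as_tibble(x[, c(need, setdiff(names(x), need))])
}

#' Validate trial-table invariants
#'
#' Checks the design invariants of a trial table (see [read_trial()]) and
#' errors if any is violated. Returns the input invisibly so it can be used in
#' a pipe.
#'
#' @param trees A trial tibble with the canonical columns.
#' @return `trees`, invisibly.
#' @export
validate_trial <- function(trees) {
  if (anyDuplicated(trees$tree_id)) {
    abort("duplicate tree_id values in trial table",
          class = "provtrial_schema_error")
  }
  bad_block <- trees |>
    dplyr::distinct(.data$block_id, .data$site_id) |>
    dplyr::count(.data$block_id) |>
    dplyr::filter(.data$n > 1)
  if (nrow(bad_block) > 0) {
    abort(paste0("block(s) appear in more than one site: ",
                 toString(bad_block$block_id)),
          class = "provtrial_nesting_error")
  }
  bad_mother <- trees |>
    dplyr::distinct(.data$mother_id, .data$provenance_id) |>
    dplyr::count(.data$mother_id) |>
    dplyr::filter(.data$n > 1)
  if (nrow(bad_mother) > 0) {
    abort(paste0("mother(s) appear in more than one provenance: ",
                 toString(bad_mother$mother_id)),
          class = "provtrial_nesting_error")
  }
  for (v in c("height", "dbh")) {
    if (any(trees[[v]] <= 0, na.rm = TRUE)) {
      abort(paste0("non-positive ", v, " values present"),
            class = "provtrial_invariant_error")
    }
    if (any(!trees$alive & !is.na(trees[[v]]))) {
      abort(paste0("dead trees must have missing ", v),
            class = "provtrial_invariant_error")
    }
  }
  invisible(trees)
}

#' Read a pedigree table
#'
#' A maternal half-sib pedigree: founder mothers have no recorded parents and
#' every offspring points to its mother; fathers are unknown throughout
#' (open-pollinated design). Validates that the pedigree is acyclic and that
#' every referenced mother is itself listed.
#'
#' @param path Path to a CSV file with columns `individual_id`, `mother_id`
#'   (empty for founders) and optionally `father_id` (must be empty).
#' @return A tibble with columns `individual_id`, `mother_id`, `father_id`.
#' @export
read_pedigree <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                       col_types = readr::cols(.default = readr::col_character()))
  if (!all(c("individual_id", "mother_id") %in% names(x))) {
    abort("pedigree needs columns individual_id and mother_id",
          class = "provtrial_schema_error")
  }
  if (!"father_id" %in% names(x)) x$father_id <- NA_character_
  validate_pedigree(x)
  tibble::as_tibble(x[, c("individual_id", "mother_id", "father_id")])
}

#' Read a long-term climate table
#'
#' One row per climate unit (a provenance seed origin or a trial site) with
#' long-term climate normals. Enforces the physical invariants
#' `MWMT >= MAT >= MCMT`, `MAP > 0` and, when May--September precipitation is
#' present, `MSP <= MAP`.
#'
#' @param path Path to a CSV file with columns `unit_id`, `role`
#'   (`"provenance"` or `"site"`), `MAT`, `MAP`, `MWMT`, `MCMT` and optionally
#'   `MSP`, `lat`, `lon` and further variables.
#' @return A validated tibble.
#' @export
read_climate <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("unit_id", "role", "MAT", "MAP", "MWMT", "MCMT")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    abort(paste0("climate table is missing column(s): ", toString(miss)),
          class = "provtrial_schema_error")
  }
  x$unit_id <- as.character(x$unit_id)
  validate_climate(x)
  tibble::as_tibble(x)
}

#' @rdname read_climate
#' @param climate A climate tibble to validate.
#' @export
validate_climate <- function(climate) {
  if (!all(climate$role %in% c("provenance", "site"))) {
    abort("climate role must be 'provenance' or 'site'",
          class = "provtrial_schema_error")
  }
  ok_order <- climate$MWMT >= climate$MAT & climate$MAT >= climate$MCMT
  if (any(!ok_order, na.rm = TRUE)) {
    abort("climate rows violate MWMT >= MAT >= MCMT",
          class = "provtrial_invariant_error")
  }
  if (any(climate$MAP <= 0, na.rm = TRUE)) {
    abort("MAP must be positive", class = "provtrial_invariant_error")
  }
  if ("MSP" %in% names(climate) &&
      any(climate$MSP > climate$MAP, na.rm = TRUE)) {
    abort("MSP cannot exceed MAP", class = "provtrial_invariant_error")
  }
  invisible(climate)
}

#' Read a per-tree functional-trait table
#'
#' Leaf and wood functional traits measured on a subset of trees: specific
#' leaf area (`SLA`, g/cm2 -- note this study's convention is mass/area, the
#' reciprocal of the usual leaf area/mass), leaf dry matter content
#' (`LDMC`, g/g), carbon isotope ratio (`delta13C`, permil vs VPDB), stomatal
#' density (per mm2), vein density (mm/mm2), mean and 95th-percentile vessel
#' lumen area (`VA`, `VA_max`, um2), vessel lumen fraction `F` and theoretical
#' hydraulic conductivity `Kh`. Only `tree_id` is required; any subset of the
#' trait columns may be present. Invariants checked where the columns exist:
#' `0 <= F <= 1`, `0 < LDMC <= 1`, `VA_max >= VA`, densities non-negative.
#'
#' @param path Path to a CSV file.
#' @return A validated tibble.
#' @export
read_traits <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!"tree_id" %in% names(x)) {
    abort("trait table needs a tree_id column", class = "provtrial_schema_error")
  }
  x$tree_id <- as.character(x$tree_id)
  chk <- function(cond, msg) {
    if (any(!cond, na.rm = TRUE)) abort(msg, class = "provtrial_invariant_error")
  }
  if ("F" %in% names(x)) chk(x$F >= 0 & x$F <= 1, "F must lie in [0, 1]")
  if ("LDMC" %in% names(x)) chk(x$LDMC > 0 & x$LDMC <= 1, "LDMC must lie in (0, 1]")
  if (all(c("VA", "VA_max") %in% names(x))) chk(x$VA_max >= x$VA, "VA_max must be >= VA")
  for (v in intersect(c("stomatal_density", "vein_density"), names(x))) {
    chk(x[[v]] >= 0, paste0(v, " must be non-negative"))
  }
  tibble::as_tibble(x)
}

#' Write a simulated garden to disk
#'
#' Writes the trial, pedigree and climate tables of a [simulate_garden()]
#' result as CSV files, plus the generative ground truth as a JSON sidecar,
#' into `dir`.
#'
#' @param sim A `garden_sim` object.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_garden <- function(sim, dir) {
  stopifnot(inherits(sim, "garden_sim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(sim$trees, file.path(dir, "trial.csv"))
  readr::write_csv(sim$pedigree, file.path(dir, "pedigree.csv"))
  readr::write_csv(sim$climate, file.path(dir, "climate.csv"))
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(as.list(truth_report(sim) |> tibble::deframe()),
                         file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  pt_log("write_garden: wrote ", nrow(sim$trees), " trees to ", dir)
  invisible(dir)
}

#' Survival rate as a percentage
#'
#' @param n_alive Number of living trees, `0 <= n_alive <= n_planted`.
#' @param n_planted Number of trees planted, `> 0`.
#' @return `100 * n_alive / n_planted`.
#' @examples
#' survival_rate(9306, 9900) # 94
#' @export
survival_rate <- function(n_alive, n_planted) {
  if (any(n_planted <= 0)) {
    abort("n_planted must be positive", class = "provtrial_domain_error")
  }
  if (any(n_alive < 0 | n_alive > n_planted)) {
    abort("need 0 <= n_alive <= n_planted", class = "provtrial_domain_error")
  }
  100 * n_alive / n_planted
}

#' Reference climate table for ten pedunculate oak provenances
#'
#' Long-term climate normals (MAT, MAP, MWMT, MCMT), coordinates and published
#' climatic-cluster assignments for the ten Quercus robur provenances of a
#' 10-year, three-site Central European provenance trial. Shipped as a
#' plain-text fixture and used as the default provenance climate by
#' [simulate_garden()].
#'
#' @param as_climate_table If `TRUE`, return in the generic climate-table
#'   shape used by [read_climate()] (`unit_id`, `role = "provenance"`, ...)
#'   instead of the provenance-labelled original.
#' @return A tibble with 10 rows.
#' @examples
#' oak_provenance_climate()
#' @export
oak_provenance_climate <- function(as_climate_table = FALSE) {
  path <- system.file("extdata", "oak_provenance_climate.csv",
                      package = "provtrial", mustWork = TRUE)
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  x$provenance_id <- as.character(x$provenance_id)
  if (as_climate_table) {
    x <- x |>
      dplyr::transmute(unit_id = .data$provenance_id, role = "provenance",
                       MAT = .data$MAT, MAP = .data$MAP, MWMT = .data$MWMT,
                       MCMT = .data$MCMT, lat = .data$lat, lon = .data$lon)
    validate_climate(x)
  }
  tibble::as_tibble(x)
}

#' Reference growth variance components
#'
#' Published REML variance components (with standard errors) for tree height
#' and dbh from the full multi-site model of a 10-year three-site pedunculate
#' oak provenance trial: site, provenance, family, block, provenance-by-site,
#' family-by-site and residual terms. Useful as input for
#' [variance_percentages()] and as a realistic scale reference for
#' [sim_config()].
#'
#' @return A tibble with columns `trait`, `term`, `variance`, `se`.
#' @examples
#' oak_growth_varcomp() |>
#'   dplyr::filter(trait == "height") |>
#'   variance_percentages()
#' @export
oak_growth_varcomp <- function() {
  path <- system.file("extdata", "oak_growth_varcomp.csv",
                      package = "provtrial", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

# --- internal helpers --------------------------------------------------------

apply_col_map <- function(x, col_map) {
  if (is.null(col_map)) return(x)
  if (is.character(col_map) && length(col_map) == 1 && is.null(names(col_map))) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      abort("reading a YAML column map requires the yaml package")
    }
    col_map <- unlist(yaml::read_yaml(col_map))
  }
  for (canon in names(col_map)) {
    actual <- col_map[[canon]]
    if (!actual %in% names(x)) {
      abort(paste0("mapped column '", actual, "' not found in file"),
            class = "provtrial_schema_error")
    }
    names(x)[names(x) == actual] <- canon
  }
  x
}

parse_logical_col <- function(v) {
  if (is.logical(v)) return(v)
  if (is.numeric(v)) return(v != 0)
  tolower(as.character(v)) %in% c("true", "t", "1", "yes", "alive")
}

# Appends to the file in option 'provtrial.log_file' when set; otherwise no-op.
pt_log <- function(...) {
  f <- getOption("provtrial.log_file", NULL)
  if (!is.null(f)) {
    cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), ..., "\n",
        file = f, sep = "", append = TRUE)
  }
  invisible(NULL)
}
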