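#' Climatic transfer distance
#'
#' `D = climate at provenance origin - climate at planting site`, so positive
#' values mean the provenance was moved to a colder/drier site than its
#' origin and negative values to a warmer/wetter one.
#'
#' @param climate_prov Climate value(s) at the provenance origin.
#' @param climate_site Climate value(s) at the site, same variable and units.
#' @param variable_prov,variable_site Optional variable labels; if both are
#'   given and differ, an error is raised to guard against mixing variables.
#' @return `climate_prov - climate_site`.
#' @examples
#' transfer_distance(10.85, 8.90) # +1.95: moved to a colder site
#' @export
transfer_distance <- function(climate_prov, climate_site,
                              variable_prov = NULL, variable_site = NULL) {
  if (!is.null(variable_prov) && !is.null(variable_site) &&
      !identical(variable_prov, variable_site)) {
    abort(paste0("transfer distance mixes variables: ", variable_prov,
                 " vs ", variable_site), class = "provtrial_unit_error")
  }
  climate_prov - climate_site
}

#' Fit the quadratic climatic transfer model at one site
#'
#' Ordinary least squares of individual-tree growth on the transfer distance
#' `D` and its square, `Y = b0 + b1 D + b2 D^2 + e`, fitted separately per
#' site. `D` is computed per provenance as the provenance's climate value
#' minus the site's, for the chosen climate variable. A concave response
#' (`b2 < 0`) has its maximum at the vertex `D* = -b1 / (2 b2)`: the climatic
#' distance at which transferred material grows best.
#'
#' @param trees Trial tibble (see [read_trial()]).
#' @param climate Climate tibble with provenance and site rows
#'   (see [read_climate()]).
#' @param site Site id (must exist as a `role = "site"` row in `climate`).
#' @param variable Climate variable, e.g. `"MAT"` (degC) or `"MAP"` (mm).
#' @param trait Response column, default `"height"`.
#' @return A `transfer_fit` object; `tidy()` gives the coefficient table
#'   (estimate, t, p per coefficient), `glance()` the fit summary including
#'   `r_squared` and the vertex, `autoplot()` the provenance-mean response
#'   curve.
#' @export
fit_transfer <- function(trees, climate, site, variable = "MAT",
                         trait = "height") {
  if (!variable %in% names(climate)) {
    abort(paste0("climate variable '", variable, "' not found"),
          class = "provtrial_spec_error")
  }
  site_row <- climate[climate$role == "site" & climate$unit_id == site, ]
  if (nrow(site_row) != 1) {
    abort(paste0("site '", site, "' not found in climate table"),
          class = "provtrial_spec_error")
  }
  prov_clim <- climate[climate$role == "provenance", ]
  d <- trees |>
    dplyr::filter(.data$site_id == site) |>
    dplyr::left_join(
      tibble::tibble(provenance_id = prov_clim$unit_id,
                     .clim = prov_clim[[variable]]),
      by = "provenance_id") |>
    dplyr::mutate(D = transfer_distance(.data$.clim, site_row[[variable]])) |>
    dplyr::filter(!is.na(.data[[trait]]), !is.na(.data$D))
  if (dplyr::n_distinct(d$D) < 3) {
    abort("need at least 3 distinct transfer distances",
          class = "provtrial_spec_error")
  }
  fml <- stats::as.formula(paste(trait, "~ D + I(D^2)"))
  m <- lm(fml, data = d)
  sm <- summary(m)
  co <- sm$coefficients
  coefs <- tibble::tibble(
    coefficient = c("intercept", "D", "D2"),
    estimate = unname(co[, 1]), std_error = unname(co[, 2]),
    t_value = unname(co[, 3]), p_value = unname(co[, 4])
  )
  b1 <- coefs$estimate[2]; b2 <- coefs$estimate[3]
  structure(list(
    model = m, coefficients = coefs, r_squared = sm$r.squared,
    vertex = if (b2 < 0) -b1 / (2 * b2) else NA_real_,
    has_maximum = b2 < 0,
    variable = variable, site = site, trait = trait, n = nrow(d),
    prov_means = d |>
      dplyr::group_by(.data$provenance_id, .data$D) |>
      dplyr::summarise(mean = mean(.data[[trait]]),
                       se = sd(.data[[trait]]) / sqrt(dplyr::n()),
                       .groups = "drop")
  ), class = "transfer_fit")
}

#' Optimum of a fitted transfer response
#'
#' The vertex `D* = -b1 / (2 b2)` of the quadratic transfer model: the
#' transfer distance of maximal expected growth. Only defined for a concave
#' response (`b2 < 0`); otherwise the fit has no interior maximum and `NA` is
#' returned with a warning.
#'
#' @param fit A `transfer_fit` object (see [fit_transfer()]).
#' @return The vertex `D*`, or `NA` when `b2 >= 0`.
#' @export
vertex <- function(fit) {
  stopifnot(inherits(fit, "transfer_fit"))
  if (!fit$has_maximum) {
    warn("response is not concave (b2 >= 0): no interior maximum")
    return(NA_real_)
  }
  fit$vertex
}

#' @describeIn fit_transfer Coefficient table.
#' @param x A `transfer_fit`.
#' @param ... Unused.
#' @method tidy transfer_fit
#' @export
tidy.transfer_fit <- function(x, ...) x$coefficients

#' @describeIn fit_transfer One-row fit summary.
#' @method glance transfer_fit
#' @export
glance.transfer_fit <- function(x, ...) {
  tibble::tibble(trait = x$trait, site = x$site, variable = x$variable,
                 r_squared = x$r_squared, vertex = x$vertex,
                 has_maximum = x$has_maximum, n = x$n)
}

#' @export
print.transfer_fit <- function(x, ...) {
  cat("Quadratic transfer model:", x$trait, "~", x$variable,
      "distance at site", x$site, "\n")
  print(x$coefficients)
  cat(sprintf("R2 = %.4f; vertex D* = %s\n", x$r_squared,
              ifelse(x$has_maximum, sprintf("%.3f", x$vertex), "none (b2 >= 0)")))
  invisible(x)
}

#' @describeIn fit_transfer Provenance means against transfer distance with
#'   the fitted quadratic.
#' @param object A `transfer_fit`.
#' @method autoplot transfer_fit
#' @export
autoplot.transfer_fit <- function(object, ...) {
  pm <- object$prov_means
  rng <- range(pm$D)
  curve_d <- tibble::tibble(D = seq(rng[1], rng[2], length.out = 200))
  b <- object$coefficients$estimate
  curve_d$fit <- b[1] + b[2] * curve_d$D + b[3] * curve_d$D^2
  ggplot2::ggplot(pm, ggplot2::aes(x = .data$D, y = .data$mean)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$se,
                                        ymax = .data$mean + .data$se),
                           width = 0, colour = "grey55") +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = curve_d, ggplot2::aes(y = .data$fit),
                       colour = "firebrick") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(
      x = paste0("Transfer distance D (", object$variable,
                 ", provenance - site)"),
      y = paste("Provenance mean", object$trait),
      title = paste("Climatic transfer response at site", object$site)
    )
}
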