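#' Partition phenotypic variance across the full multi-site model
#'
#' Fits the all-random multi-site decomposition by REML: site, provenance,
#' family (nested in provenance), block (nested in site), provenance-by-site
#' and family-by-site interactions, plus residual. The two interaction terms
#' are the genotype-by-environment components. All terms are expressed as
#' percentages of the total phenotypic variance.
#'
#' @param trees Trial tibble with at least 2 sites and families replicated
#'   across sites.
#' @param trait Response column, default `"height"`.
#' @return A `gxe_fit` object; `tidy()` gives the component table with a
#'   `pct` column, `glance()` the fit summary including the combined GxE
#'   share, and [ecovalence_from_blups()] consumes the family-by-site BLUPs.
#' @export
fit_gxe <- function(trees, trait = "height") {
  if (dplyr::n_distinct(trees$site_id) < 2) {
    abort("GxE decomposition needs at least 2 sites",
          class = "provtrial_spec_error")
  }
  d <- trees |>
    dplyr::mutate(
      family = .data$mother_id,
      prov_x_site = paste(.data$provenance_id, .data$site_id, sep = ":"),
      fam_x_site = paste(.data$mother_id, .data$site_id, sep = ":")
    )
  fit <- reml_fit(d, trait,
                  random = c("site_id", "provenance_id", "family",
                             "block_id", "prov_x_site", "fam_x_site"))
  labels <- c(site_id = "site", provenance_id = "provenance",
              family = "family", block_id = "block",
              prov_x_site = "prov_x_site", fam_x_site = "fam_x_site",
              residual = "residual")
  vc <- fit$varcomp |>
    dplyr::mutate(term = unname(labels[.data$term])) |>
    variance_percentages()
  structure(list(fit = fit, varcomp = vc, trait = trait), class = "gxe_fit")
}

#' @describeIn fit_gxe Component table with percentages of total variance.
#' @param x A `gxe_fit`.
#' @param ... Unused.
#' @method tidy gxe_fit
#' @export
tidy.gxe_fit <- function(x, ...) x$varcomp

#' @describeIn fit_gxe One-row summary with the combined GxE share.
#' @method glance gxe_fit
#' @export
glance.gxe_fit <- function(x, ...) {
  tibble::tibble(trait = x$trait, gxe_pct = gxe_share(x),
                 logLik = x$fit$loglik, converged = x$fit$converged,
                 n = x$fit$n)
}

#' @export
print.gxe_fit <- function(x, ...) {
  cat("Multi-site variance decomposition for", x$trait, "\n")
  print(x$varcomp, n = Inf)
  cat(sprintf("combined GxE share: %.2f%%\n", gxe_share(x)))
  invisible(x)
}

#' Combined genotype-by-environment variance share
#'
#' The summed percentage of total phenotypic variance attributed to the
#' provenance-by-site and family-by-site interaction terms.
#'
#' @param x A `gxe_fit` or a component tibble with `term` and `variance`
#'   columns (a `pct` column is recomputed if absent).
#' @return A percentage.
#' @examples
#' oak_growth_varcomp() |>
#'   dplyr::filter(trait == "height") |>
#'   gxe_share() # 4.0
#' @export
gxe_share <- function(x) {
  tab <- if (inherits(x, "gxe_fit")) x$varcomp else variance_percentages(x)
  sum(tab$pct[tab$term %in% c("prov_x_site", "fam_x_site")])
}

#' Wricke's ecovalence from a family-by-environment table
#'
#' Double-centers the family-by-site matrix `X` and sums squared deviations
#' per family: `W2_i = sum_j (X_ij - Xbar_i. - Xbar_.j + Xbar_..)^2`. Each
#' family's share of the total interaction sum of squares,
#' `ratio_i = W2_i / sum(W2)`, measures how much of the GxE instability that
#' family contributes; families above `threshold` are flagged as
#' extraordinarily plastic.
#'
#' If the table carries no interaction at all (`sum(W2) = 0`, e.g. a purely
#' additive row + column structure), ratios are reported as 0 and the result
#' is marked degenerate instead of dividing by zero.
#'
#' @param x A numeric matrix (families in rows, environments in columns, row
#'   names = family ids) or a long data frame with columns `family`, `site`,
#'   `value`. Every family must be observed in every environment.
#' @param threshold Flagging threshold on the ratio scale (default 0.05).
#' @return A tibble: `family`, `w2`, `ratio`, `plastic`, with attribute
#'   `"degenerate"`.
#' @examples
#' ecovalence(matrix(c(1, 0, 0, 1), 2, 2,
#'                   dimnames = list(c("f1", "f2"), NULL)))
#' @export
ecovalence <- function(x, threshold = 0.05) {
  if (is.data.frame(x)) {
    need <- c("family", "site", "value")
    if (!all(need %in% names(x))) {
      abort("long ecovalence input needs columns family, site, value",
            class = "provtrial_spec_error")
    }
    wide <- tidyr::pivot_wider(x[, need], names_from = "site",
                               values_from = "value")
    m <- as.matrix(wide[, -1]); rownames(m) <- wide$family
    x <- m
  }
  if (!is.matrix(x) || !is.numeric(x)) {
    abort("ecovalence needs a numeric matrix", class = "provtrial_spec_error")
  }
  if (anyNA(x)) {
    abort("ecovalence needs a complete family-by-site table (no missing cells)",
          class = "provtrial_spec_error")
  }
  if (nrow(x) < 2 || ncol(x) < 2) {
    abort("ecovalence needs at least 2 families and 2 environments",
          class = "provtrial_spec_error")
  }
  centered <- sweep(sweep(x, 1, rowMeans(x)), 2, colMeans(x)) + mean(x)
  w2 <- rowSums(centered^2)
  total <- sum(w2)
  degenerate <- total <= 0
  ratio <- if (degenerate) rep(0, length(w2)) else w2 / total
  out <- tibble::tibble(
    family = rownames(x) %||% as.character(seq_len(nrow(x))),
    w2 = unname(w2), ratio = unname(ratio),
    plastic = !degenerate & unname(ratio) > threshold
  )
  attr(out, "degenerate") <- degenerate
  attr(out, "threshold") <- threshold
  out
}

#' Ecovalence of families from fitted GxE BLUPs
#'
#' Assembles the family-by-site matrix of BLUPs of the family-by-site
#' interaction term from a [fit_gxe()] result and applies [ecovalence()].
#' Working on BLUPs (shrunken predictions) rather than raw cell means damps
#' sampling noise in family-site cells. A family unobserved at a site gets
#' the BLUP of an unobserved level, 0, and a message is emitted.
#'
#' @param x A `gxe_fit` object.
#' @param threshold Flagging threshold, see [ecovalence()].
#' @return A tibble as from [ecovalence()].
#' @export
ecovalence_from_blups <- function(x, threshold = 0.05) {
  stopifnot(inherits(x, "gxe_fit"))
  b <- x$fit$blup |>
    dplyr::filter(.data$term == "fam_x_site") |>
    tidyr::separate_wider_delim("level", delim = ":",
                                names = c("family", "site"))
  full <- tidyr::expand_grid(family = unique(b$family),
                             site = unique(b$site)) |>
    dplyr::left_join(b, by = c("family", "site"))
  n_missing <- sum(is.na(full$blup))
  if (n_missing > 0) {
    inform(paste0(n_missing,
                  " family-site combination(s) unobserved; BLUP imputed as 0"))
    full$blup[is.na(full$blup)] <- 0
  }
  ecovalence(dplyr::transmute(full, family = .data$family, site = .data$site,
                              value = .data$blup),
             threshold = threshold)
}

#' @describeIn ecovalence Histogram of ecovalence ratios across families.
#' @param object An ecovalence tibble.
#' @param ... Unused.
#' @export
plot_ecovalence <- function(object, ...) {
  thr <- attr(object, "threshold") %||% 0.05
  ggplot2::ggplot(object, ggplot2::aes(x = .data$ratio)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey40") +
    ggplot2::geom_vline(xintercept = thr, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::labs(x = "ecovalence ratio (family share of GxE sum of squares)",
                  y = "families")
}
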