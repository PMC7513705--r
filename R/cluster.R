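#' Principal components of a standardized climate table
#'
#' Standardizes the chosen climate variables to z-scores (they mix degC and
#' mm) and computes principal components. Constant variables are dropped with
#' a warning. Explained-variance fractions are non-increasing and sum to 1.
#'
#' @param climate Climate tibble (provenance rows are used; a plain tibble
#'   with an id column also works).
#' @param variables Character vector of climate columns (default: all numeric
#'   climate variables found among `MAT`, `MAP`, `MWMT`, `MCMT`, `MSP` plus
#'   any extra numeric columns except coordinates).
#' @param id_col Column holding the unit labels (default `unit_id`, falling
#'   back to `provenance_id`).
#' @return A `climate_pca` object: `scores` (tibble, one row per unit),
#'   `explained` (fractions per component), `loadings`, and the underlying
#'   `prcomp` fit.
#' @export
climate_pca <- function(climate, variables = NULL, id_col = NULL) {
  x <- climate
  if ("role" %in% names(x)) x <- x[x$role == "provenance", , drop = FALSE]
  id_col <- id_col %||% intersect(c("unit_id", "provenance_id"), names(x))[1]
  if (is.na(id_col)) abort("no id column found", class = "provtrial_spec_error")
  if (is.null(variables)) {
    drop <- c(id_col, "role", "lat", "lon", "cluster", "name", "region")
    variables <- names(x)[vapply(x, is.numeric, logical(1))]
    variables <- setdiff(variables, drop)
  }
  if (nrow(x) < 2 || length(variables) < 2) {
    abort("need at least 2 units and 2 variables", class = "provtrial_spec_error")
  }
  m <- as.matrix(x[, variables])
  const <- apply(m, 2, function(v) sd(v) == 0)
  if (any(const)) {
    warn(paste0("dropping constant variable(s): ",
                toString(variables[const])))
    m <- m[, !const, drop = FALSE]
    if (ncol(m) < 2) {
      abort("fewer than 2 non-constant variables", class = "provtrial_spec_error")
    }
  }
  pc <- prcomp(m, center = TRUE, scale. = TRUE)
  explained <- pc$sdev^2 / sum(pc$sdev^2)
  scores <- tibble::as_tibble(pc$x)
  scores <- dplyr::bind_cols(tibble::tibble(unit_id = as.character(x[[id_col]])),
                             scores)
  structure(list(scores = scores, explained = explained,
                 loadings = pc$rotation, prcomp = pc),
            class = "climate_pca")
}

#' @export
print.climate_pca <- function(x, ...) {
  cat("Climate PCA:", nrow(x$scores), "units,",
      length(x$explained), "components\n")
  cat("explained variance:",
      paste0(sprintf("%.1f%%", 100 * head(x$explained, 5)), collapse = ", "),
      "\n")
  invisible(x)
}

#' Assign provenances to climatic clusters from PCA scores
#'
#' Centroid-based partitioning (k-means, 25 restarts, seeded) of the
#' principal-component scores. `k = "elbow"` automates the screeplot elbow:
#' the within-cluster sum of squares is computed for `k = 1..max_k` and the
#' chosen k maximizes its second difference (the sharpest bend). A fixed
#' integer k can be forced instead -- useful to mirror an externally chosen
#' cluster count.
#'
#' @param x A `climate_pca` object (see [climate_pca()]) or a tibble of
#'   scores with a `unit_id` column.
#' @param k `"elbow"` (default) or an integer number of clusters
#'   (`<=` number of units).
#' @param n_components Number of leading components to cluster on (default:
#'   enough to explain 95% of variance; ignored for plain score input).
#' @param max_k Largest k scanned by the elbow rule (default
#'   `min(n - 1, 8)`).
#' @param seed Seed for the k-means restarts.
#' @return A tibble `unit_id`, `cluster` (factor), with attributes
#'   `"k"` and `"explained"` (when available).
#' @export
assign_clusters <- function(x, k = "elbow", n_components = NULL,
                            max_k = NULL, seed = 1) {
  if (inherits(x, "climate_pca")) {
    if (is.null(n_components)) {
      n_components <- max(2, which(cumsum(x$explained) >= 0.95)[1])
      n_components <- min(n_components, length(x$explained))
    }
    scores <- as.matrix(x$scores[, paste0("PC", seq_len(n_components))])
    ids <- x$scores$unit_id
    explained <- x$explained
  } else {
    ids <- as.character(x$unit_id)
    scores <- as.matrix(x[, setdiff(names(x), "unit_id")])
    explained <- NULL
  }
  n <- nrow(scores)
  old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(seed)

  wss_for <- function(kk) {
    if (kk == 1) return(sum(scale(scores, scale = FALSE)^2))
    if (kk >= n) return(0)
    kmeans(scores, centers = kk, nstart = 25, iter.max = 50)$tot.withinss
  }
  if (identical(k, "elbow")) {
    if (all(dist(scores) < 1e-12)) {
      k <- 1L
    } else {
      max_k <- max_k %||% min(n - 1L, 8L)
      ks <- seq_len(max_k)
      wss <- vapply(ks, wss_for, numeric(1))
      if (length(ks) < 3) {
        k <- length(ks)
      } else {
        # sharpest bend: largest second difference of the WSS curve
        d2 <- wss[ks[-c(1, length(ks))] - 1] - 2 * wss[ks[-c(1, length(ks))]] +
          wss[ks[-c(1, length(ks))] + 1]
        k <- ks[-c(1, length(ks))][which.max(d2)]
      }
    }
  }
  k <- as.integer(k)
  if (k > n) abort("k cannot exceed the number of units",
                   class = "provtrial_spec_error")
  cl <- if (k == 1) {
    rep(1L, n)
  } else if (k == n) {
    seq_len(n)
  } else {
    kmeans(scores, centers = k, nstart = 25, iter.max = 50)$cluster
  }
  out <- tibble::tibble(unit_id = ids, cluster = factor(cl))
  attr(out, "k") <- k
  attr(out, "explained") <- explained
  out
}

#' @describeIn climate_pca Screeplot of explained-variance fractions.
#' @param object A `climate_pca`.
#' @param ... Unused.
#' @method autoplot climate_pca
#' @export
autoplot.climate_pca <- function(object, ...) {
  d <- tibble::tibble(component = seq_along(object$explained),
                      explained = object$explained)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$component, y = .data$explained)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::scale_x_continuous(breaks = d$component) +
    ggplot2::labs(x = "principal component", y = "explained variance fraction")
}
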