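#' REML fit of a Gaussian mixed model with i.i.d. and pedigree random terms
#'
#' Estimates variance components, fixed effects and BLUPs for models of the
#' form `y = X b + sum_k Z_k u_k + e`, where each random term `u_k` is either
#' i.i.d. (`u_k ~ N(0, s2_k I)`) or pedigree-structured
#' (`a ~ N(0, s2_a A)`, the individual-tree "animal" term with A the additive
#' relationship matrix), and `e ~ N(0, s2_e I)`.
#'
#' The restricted likelihood is profiled over the residual variance and
#' evaluated through the sparse mixed-model equations (one CHOLMOD
#' factorization update per evaluation), then maximized over the log variance
#' ratios with a bounded quasi-Newton optimizer. Standard errors of the
#' variance components come from the inverse average-information matrix
#' evaluated at the optimum; BLUPs and fixed-effect estimates are the
#' solutions of Henderson's equations at the estimates.
#'
#' Rows with a missing response or missing grouping values are dropped before
#' fitting. Variance ratios are constrained to `[1e-8, 1e8]` times the
#' residual variance; an estimate pinned at the lower bound is reported as a
#' boundary estimate with `NA` standard error. Non-convergence is flagged in
#' the result, not raised as an error.
#'
#' @param data A data frame with the response and grouping columns.
#' @param response Name of the response column (character).
#' @param random Character vector of grouping-factor columns that receive
#'   i.i.d. random effects. Interaction terms are passed as pre-built columns
#'   (e.g. `paste(site, provenance)`).
#' @param genetic Optional name of the column holding individual ids for the
#'   pedigree-structured additive term.
#' @param pedigree Pedigree tibble covering every id in `data[[genetic]]`
#'   (see [validate_pedigree()]). Required when `genetic` is given.
#' @param fixed One-sided formula for the fixed part; default intercept only.
#' @param start Optional named numeric vector of starting variances (terms
#'   plus `"residual"`). Default splits the phenotypic variance equally.
#' @param max_iter Maximum optimizer iterations.
#' @param pev_terms Terms for which prediction-error variances of the BLUPs
#'   are computed (costs one sparse solve per level; off by default).
#' @return An object of class `reml_fit` with components `varcomp` (tibble:
#'   term, variance, se, ratio, boundary), `fixef`, `blup`, `loglik`,
#'   `converged`, `iterations`, `n`, `vcov_theta` (asymptotic covariance of
#'   the variance estimates). Methods: [tidy.reml_fit()], [glance.reml_fit()],
#'   `print`.
#' @examples
#' set.seed(1)
#' d <- tibble::tibble(g = rep(letters[1:10], each = 5),
#'                     y = rnorm(50, rep(rnorm(10, sd = 2), each = 5)))
#' fit <- reml_fit(d, "y", random = "g")
#' tidy(fit)
#' @export
reml_fit <- function(data, response, random = character(), genetic = NULL,
                     pedigree = NULL, fixed = ~1, start = NULL,
                     max_iter = 200, pev_terms = NULL) {
  stopifnot(is.character(response), length(response) == 1)
  if (!response %in% names(data)) {
    abort(paste0("response column '", response, "' not found"),
          class = "provtrial_spec_error")
  }
  for (v in random) {
    if (!v %in% names(data)) {
      abort(paste0("random term column '", v, "' not found"),
            class = "provtrial_spec_error")
    }
  }
  if (!is.null(genetic) && is.null(pedigree)) {
    abort("a pedigree is required for the genetic term",
          class = "provtrial_spec_error")
  }

  keep_cols <- c(response, random, genetic)
  cc <- stats::complete.cases(data[, keep_cols, drop = FALSE])
  n_dropped <- sum(!cc)
  d <- data[cc, , drop = FALSE]
  y <- as.numeric(d[[response]])
  n <- length(y)
  if (n < 2) abort("fewer than 2 usable observations", class = "provtrial_spec_error")

  X <- stats::model.matrix(fixed, data = as.data.frame(d))
  p <- ncol(X)
  Xs <- methods::as(Matrix::Matrix(X, sparse = TRUE), "CsparseMatrix")

  terms <- list() # per term: name, kind, Z (n x q), penalty (q x q sparse), q, levels
  for (v in random) {
    f <- factor(as.character(d[[v]]))
    if (nlevels(f) < 2) {
      abort(paste0("random factor '", v, "' has fewer than 2 levels"),
            class = "provtrial_spec_error")
    }
    Z <- Matrix::sparseMatrix(i = seq_len(n), j = as.integer(f),
                              x = 1, dims = c(n, nlevels(f)))
    terms[[v]] <- list(name = v, kind = "iid", Z = Z,
                       penalty = Matrix::Diagonal(nlevels(f)),
                       q = nlevels(f), levels = levels(f), logdetG = 0)
  }
  if (!is.null(genetic)) {
    validate_pedigree(pedigree)
    ids <- as.character(pedigree$individual_id)
    gi <- match(as.character(d[[genetic]]), ids)
    if (anyNA(gi)) {
      abort("pedigree does not cover every individual in the data",
            class = "provtrial_spec_error")
    }
    Z <- Matrix::sparseMatrix(i = seq_len(n), j = gi, x = 1,
                              dims = c(n, length(ids)))
    terms[[genetic]] <- list(name = genetic, kind = "pedigree", Z = Z,
                             penalty = amatrix_inverse(pedigree),
                             q = length(ids), levels = ids,
                             logdetG = logdet_amatrix(pedigree))
  }
  K <- length(terms)
  if (K == 0) {
    return(reml_fixed_only(d, y, X, response, fixed, n_dropped))
  }

  W <- do.call(cbind, c(list(Xs), lapply(terms, function(t) t$Z)))
  WtW <- Matrix::forceSymmetric(Matrix::crossprod(W))
  Wty <- as.numeric(Matrix::crossprod(W, y))
  yty <- sum(y^2)
  qs <- vapply(terms, function(t) t$q, numeric(1))
  offs <- p + c(0, cumsum(qs))[seq_len(K)] # 0-based column offset per term
  ntot <- p + sum(qs)
  logdetG <- sum(vapply(terms, function(t) t$logdetG, numeric(1)))

  # penalty matrices embedded in full (ntot x ntot) coordinates
  pens <- vector("list", K)
  for (k in seq_len(K)) {
    Pk <- methods::as(methods::as(terms[[k]]$penalty, "generalMatrix"), "TsparseMatrix")
    pens[[k]] <- Matrix::sparseMatrix(i = Pk@i + 1L + offs[k],
                                      j = Pk@j + 1L + offs[k], x = Pk@x,
                                      dims = c(ntot, ntot))
  }

  # assemble the coefficient-matrix template once; per evaluation only the
  # numeric slot changes (the sparsity pattern is gamma-invariant)
  tmpl <- WtW
  for (k in seq_len(K)) tmpl <- tmpl + pens[[k]]
  tmpl <- methods::as(Matrix::forceSymmetric(tmpl), "CsparseMatrix")
  sp_keys <- function(M) M@i + rep.int(seq_len(ncol(M)), diff(M@p)) * nrow(M)
  tkey <- sp_keys(tmpl)
  map_into <- function(M) {
    M <- methods::as(Matrix::forceSymmetric(M), "CsparseMatrix")
    list(idx = match(sp_keys(M), tkey), x = M@x)
  }
  base_map <- map_into(WtW)
  pen_maps <- lapply(pens, map_into)
  x_zero <- numeric(length(tmpl@x))
  make_C <- function(gamma) {
    xv <- x_zero
    xv[base_map$idx] <- base_map$x
    for (k in seq_len(K)) {
      idx <- pen_maps[[k]]$idx
      xv[idx] <- xv[idx] + pen_maps[[k]]$x / gamma[k]
    }
    tmpl@x <- xv
    tmpl
  }
  ch0 <- Matrix::Cholesky(make_C(rep(1, K)), LDL = FALSE, perm = TRUE)
  n_eval <- 0L

  eval_fit <- function(loggamma) {
    gamma <- exp(loggamma)
    C <- make_C(gamma)
    ch <- tryCatch(Matrix::update(ch0, C, mult = 0), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    sol <- as.numeric(Matrix::solve(ch, Wty, system = "A"))
    yPy <- yty - sum(Wty * sol)
    if (!is.finite(yPy) || yPy <= 0) return(NULL)
    s2e <- yPy / (n - p)
    ldC <- 2 * Matrix::determinant(ch, sqrt = TRUE)$modulus
    dev <- (n - p) * (log(2 * pi * s2e) + 1) + sum(qs * loggamma) +
      logdetG + as.numeric(ldC)
    list(dev = dev, s2e = s2e, sol = sol, ch = ch, gamma = gamma)
  }
  objective <- function(loggamma) {
    n_eval <<- n_eval + 1L
    f <- eval_fit(loggamma)
    if (is.null(f)) return(1e12)
    f$dev
  }

  vy <- var(y)
  if (is.null(start)) {
    # sequential method-of-moments starts: sweep group means out of the
    # response from the coarsest factor inward, so nested factors (block in
    # site, family-by-site in family) are not credited with their parents'
    # variance; the individual-level additive term gets a broad prior share
    s0 <- setNames(numeric(K), names(terms))
    r <- y - mean(y)
    ord <- order(qs)
    for (k in ord) {
      t_k <- terms[[k]]
      if (t_k$kind == "pedigree") { s0[k] <- 0.4 * vy; next }
      f <- factor(as.character(d[[t_k$name]]))
      gm <- tapply(r, f, mean)
      nb <- length(r) / nlevels(f)
      s0[k] <- max(var(gm) - var(r) / nb, 0.02 * vy)
      r <- r - gm[f]
    }
    s_res <- max(var(r), 0.2 * vy)
    par0 <- log(s0 / s_res)
  } else {
    s_res <- start[["residual"]]
    par0 <- log(vapply(names(terms), function(nm) start[[nm]] / s_res, numeric(1)))
  }
  lo <- rep(log(1e-8), K); hi <- rep(log(1e8), K)
  par0 <- pmin(pmax(par0, lo), hi)
  clamped <- function(lg) objective(pmin(pmax(lg, lo), hi))
  run_from <- function(p) {
    o <- optim(p, clamped, method = "Nelder-Mead",
               control = list(maxit = 20 * max_iter, reltol = 1e-8))
    o$par <- pmin(pmax(o$par, lo), hi)
    polish <- tryCatch(
      optim(o$par, objective, method = "L-BFGS-B", lower = lo, upper = hi,
            control = list(maxit = max_iter, factr = 1e7)),
      error = function(e) NULL)
    if (!is.null(polish) && polish$value <= o$value) o <- polish
    o
  }
  if (K == 1) {
    o1 <- stats::optimize(objective, c(lo, hi), tol = 1e-9)
    opt <- list(par = o1$minimum, value = o1$objective, convergence = 0L)
  } else {
    # simplex search from a method-of-moments start and an equal-split start
    # (multi-start guards against local traps in weakly identified corners),
    # each followed by a bounded quasi-Newton polish
    starts <- list(par0)
    if (is.null(start)) starts <- c(starts, list(rep(0, K)))
    runs <- lapply(starts, run_from)
    opt <- runs[[which.min(vapply(runs, function(o) o$value, numeric(1)))]]
    # a component pinned at the bound can mark a saddle where a nested or
    # crossed term absorbed its variance; retry once from the interior
    pinned <- opt$par <= lo + 1e-3
    if (any(pinned)) {
      p2 <- opt$par; p2[pinned] <- 0
      o2 <- run_from(p2)
      if (o2$value < opt$value - 1e-6) opt <- o2
    }
  }
  converged <- identical(opt$convergence, 0L) || identical(opt$convergence, 0)
  fit <- eval_fit(opt$par)
  if (is.null(fit)) {
    abort("restricted likelihood is degenerate at the optimum",
          class = "provtrial_fit_error")
  }
  gamma <- fit$gamma
  s2e <- fit$s2e
  sigma2 <- gamma * s2e
  boundary <- opt$par <= lo + 1e-3
  loglik <- -0.5 * fit$dev

  # --- average information matrix at the optimum (theta = sigma2 terms, s2e)
  pfun <- function(v) { # P_H v = v - W C^-1 W'v  (H-scale projection)
    s <- Matrix::solve(fit$ch, as.numeric(Matrix::crossprod(W, v)), system = "A")
    as.numeric(v - as.numeric(W %*% s))
  }
  r <- pfun(y) / s2e # P y
  fvecs <- vector("list", K + 1)
  for (k in seq_len(K)) {
    t_k <- terms[[k]]
    u <- as.numeric(Matrix::crossprod(t_k$Z, r))
    if (t_k$kind == "pedigree") {
      Gmult <- get_amatrix_cached(pedigree)
      u <- as.numeric(Gmult %*% u)
    }
    fvecs[[k]] <- as.numeric(t_k$Z %*% u)
  }
  fvecs[[K + 1]] <- r
  AI <- matrix(0, K + 1, K + 1)
  hvecs <- lapply(fvecs, function(f) pfun(f) / s2e)
  for (a in seq_len(K + 1)) {
    for (b in a:(K + 1)) {
      AI[a, b] <- AI[b, a] <- 0.5 * sum(fvecs[[a]] * hvecs[[b]])
    }
  }
  vcov_theta <- tryCatch(solve(AI), error = function(e) matrix(NA_real_, K + 1, K + 1))
  term_names <- vapply(terms, function(t) t$name, character(1))
  dimnames(vcov_theta) <- list(c(term_names, "residual"),
                               c(term_names, "residual"))
  se <- sqrt(pmax(diag(vcov_theta), 0))
  se[seq_len(K)][boundary] <- NA_real_

  # --- solutions
  sol <- fit$sol
  fixef <- tibble::tibble(term = colnames(X), estimate = sol[seq_len(p)])
  blup <- purrr::map2_dfr(terms, seq_len(K), function(t_k, k) {
    idx <- offs[k] + seq_len(t_k$q)
    tibble::tibble(term = t_k$name, level = t_k$levels, blup = sol[idx])
  })
  if (!is.null(pev_terms)) {
    pevs <- compute_pev(fit$ch, terms, offs, ntot, s2e, pev_terms)
    blup <- dplyr::left_join(blup, pevs, by = c("term", "level"))
  }

  varcomp <- tibble::tibble(
    term = unname(c(term_names, "residual")),
    variance = unname(c(sigma2, s2e)),
    se = unname(se),
    ratio = unname(c(gamma, 1)),
    boundary = unname(c(boundary, FALSE))
  )
  structure(list(
    varcomp = varcomp, fixef = fixef, blup = blup,
    loglik = loglik, deviance = fit$dev, converged = converged,
    iterations = n_eval, n = n, n_dropped = n_dropped,
    vcov_theta = vcov_theta, response = response,
    random = random, genetic = genetic, fixed = fixed,
    phenotypic_var = vy
  ), class = "reml_fit")
}

# OLS reduction when no random terms are given
reml_fixed_only <- function(d, y, X, response, fixed, n_dropped) {
  fit <- stats::lm.fit(X, y)
  n <- length(y); p <- fit$rank
  s2e <- sum(fit$residuals^2) / (n - p)
  structure(list(
    varcomp = tibble::tibble(term = "residual", variance = s2e,
                             se = s2e * sqrt(2 / (n - p)), ratio = 1,
                             boundary = FALSE),
    fixef = tibble::tibble(term = colnames(X), estimate = unname(fit$coefficients)),
    blup = tibble::tibble(term = character(), level = character(), blup = numeric()),
    loglik = NA_real_, deviance = NA_real_, converged = TRUE, iterations = 0L,
    n = n, n_dropped = n_dropped, vcov_theta = NULL, response = response,
    random = character(), genetic = NULL, fixed = fixed,
    phenotypic_var = var(y)
  ), class = "reml_fit")
}

compute_pev <- function(ch, terms, offs, ntot, s2e, pev_terms) {
  out <- list()
  for (k in seq_along(terms)) {
    t_k <- terms[[k]]
    if (!t_k$name %in% pev_terms) next
    idx <- offs[k] + seq_len(t_k$q)
    S <- Matrix::sparseMatrix(i = idx, j = seq_along(idx), x = 1,
                              dims = c(ntot, t_k$q))
    E <- Matrix::solve(ch, S, system = "A")
    pev <- s2e * Matrix::colSums(S * E)
    out[[t_k$name]] <- tibble::tibble(term = t_k$name, level = t_k$levels,
                                      pev = as.numeric(pev))
  }
  dplyr::bind_rows(out)
}

# cache A per pedigree within a session (used for AI working vectors)
amatrix_cache <- new.env(parent = emptyenv())
get_amatrix_cached <- function(pedigree) {
  key <- digest_ped(pedigree)
  if (is.null(amatrix_cache[[key]])) {
    if (length(ls(amatrix_cache)) > 8) rm(list = ls(amatrix_cache), envir = amatrix_cache)
    amatrix_cache[[key]] <- build_amatrix(pedigree)
  }
  amatrix_cache[[key]]
}
digest_ped <- function(pedigree) {
  paste0("p", nrow(pedigree), "_",
         sum(cumsum(utf8ToInt(paste(substr(paste0(pedigree$individual_id,
           pedigree$mother_id), 1, 3), collapse = "")))) %% 1e9)
}

#' @describeIn reml_fit Tidy the variance components of a fit.
#' @param x A `reml_fit` object.
#' @param ... Unused.
#' @method tidy reml_fit
#' @export
tidy.reml_fit <- function(x, ...) x$varcomp

#' @describeIn reml_fit One-row model summary.
#' @method glance reml_fit
#' @export
glance.reml_fit <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, converged = x$converged,
                 iterations = x$iterations, n = x$n,
                 n_dropped = x$n_dropped,
                 total_variance = sum(x$varcomp$variance))
}

#' @export
print.reml_fit <- function(x, ...) {
  cat("REML fit for response '", x$response, "' (n = ", x$n, ")\n", sep = "")
  cat("converged:", x$converged, " evaluations:", x$iterations, "\n")
  print(variance_percentages(x), n = Inf)
  invisible(x)
}

#' Variance components as percentages of total phenotypic variance
#'
#' Expresses each variance component (residual included) as
#' `100 * s2_term / sum(s2)`. Accepts a [reml_fit()] object or any tibble with
#' `term` and `variance` columns, so published component tables can be
#' recomputed directly.
#'
#' @param x A `reml_fit` or a tibble with columns `term` and `variance`.
#' @return The component tibble with a `pct` column added; percentages sum
#'   to 100.
#' @examples
#' oak_growth_varcomp() |>
#'   dplyr::filter(trait == "height") |>
#'   variance_percentages()
#' @export
variance_percentages <- function(x) {
  tab <- if (inherits(x, "reml_fit")) x$varcomp else tibble::as_tibble(x)
  if (!all(c("term", "variance") %in% names(tab))) {
    abort("need columns 'term' and 'variance'", class = "provtrial_spec_error")
  }
  total <- sum(tab$variance)
  if (!is.finite(total) || total <= 0) {
    abort("total variance must be positive", class = "provtrial_domain_error")
  }
  dplyr::mutate(tab, pct = 100 * .data$variance / total)
}

# Dense-matrix restricted log-likelihood, used as an independent oracle in
# tests: builds V explicitly and evaluates the textbook REML criterion.
dense_reml_loglik <- function(y, X, Zs, Gs, sigma2, s2e) {
  n <- length(y); p <- qr(X)$rank
  V <- diag(s2e, n)
  for (k in seq_along(Zs)) {
    V <- V + sigma2[k] * as.matrix(Zs[[k]] %*% Gs[[k]] %*% Matrix::t(Zs[[k]]))
  }
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(XtViX, t(X) %*% Vi)
  as.numeric(-0.5 * (determinant(V)$modulus + determinant(XtViX)$modulus +
                       t(y) %*% P %*% y + (n - p) * log(2 * pi)))
}
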