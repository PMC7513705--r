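#' Validate a maternal half-sib pedigree
#'
#' Checks that individual ids are unique, that every recorded mother is itself
#' listed as an individual, that fathers are unrecorded (open-pollinated
#' design) and that no individual is its own ancestor.
#'
#' @param pedigree Tibble with columns `individual_id`, `mother_id`
#'   (`NA` for founders) and optionally `father_id` (all `NA`).
#' @return The pedigree, invisibly.
#' @export
validate_pedigree <- function(pedigree) {
  id <- as.character(pedigree$individual_id)
  mom <- as.character(pedigree$mother_id)
  mom[!is.na(mom) & mom == ""] <- NA_character_
  if (anyDuplicated(id)) {
    abort("duplicate individual_id in pedigree", class = "provtrial_pedigree_error")
  }
  if ("father_id" %in% names(pedigree)) {
    f <- as.character(pedigree$father_id)
    if (any(!is.na(f) & f != "")) {
      abort("fathers must be unknown in a maternal half-sib pedigree",
            class = "provtrial_pedigree_error")
    }
  }
  known <- !is.na(mom)
  if (any(!mom[known] %in% id)) {
    abort("pedigree references mothers that are not listed as individuals",
          class = "provtrial_pedigree_error")
  }
  # cycle check: follow maternal links from each individual
  midx <- match(mom, id)
  for (i in seq_along(id)) {
    j <- midx[i]; steps <- 0L
    while (!is.na(j)) {
      if (j == i) {
        abort("pedigree contains a cycle", class = "provtrial_pedigree_error")
      }
      j <- midx[j]; steps <- steps + 1L
      if (steps > length(id)) {
        abort("pedigree contains a cycle", class = "provtrial_pedigree_error")
      }
    }
  }
  invisible(pedigree)
}

#' Build a pedigree table from a trial table
#'
#' Mothers enter as founders with unknown parents; every tree points to its
#' mother. Mothers have no phenotype of their own in this design, they exist
#' only to carry the half-sib covariance structure.
#'
#' @param trees A trial tibble (see [read_trial()]).
#' @return A pedigree tibble (`individual_id`, `mother_id`, `father_id`).
#' @export
pedigree_from_trees <- function(trees) {
  mothers <- sort(unique(as.character(trees$mother_id)))
  tibble::tibble(
    individual_id = c(mothers, as.character(trees$tree_id)),
    mother_id = c(rep(NA_character_, length(mothers)),
                  as.character(trees$mother_id)),
    father_id = NA_character_
  )
}

#' Additive (numerator) relationship matrix A
#'
#' Builds A by the tabular method for a maternal pedigree with unknown
#' fathers: founders are unrelated and non-inbred (diagonal 1), an offspring's
#' relationship to any older individual is half its mother's, so maternal
#' half-sibs get 0.25 and mother--offspring pairs 0.5. With unrelated mothers
#' A is block-diagonal by maternal family, and the result is stored sparse.
#'
#' @param pedigree A pedigree tibble (see [validate_pedigree()]).
#' @return A symmetric sparse `Matrix` with dimnames equal to
#'   `individual_id`, in pedigree order.
#' @examples
#' ped <- tibble::tibble(individual_id = c("M1", "o1", "o2"),
#'                       mother_id = c(NA, "M1", "M1"))
#' build_amatrix(ped)["o1", "o2"] # 0.25
#' @export
build_amatrix <- function(pedigree) {
  validate_pedigree(pedigree)
  ord <- pedigree_topo_order(pedigree)
  id <- as.character(pedigree$individual_id)[ord]
  mom <- normalize_mother(pedigree)[ord]
  n <- length(id)
  midx <- match(mom, id) # positions of mothers, < i by topological order
  # connected components under maternal links (union-find)
  parent <- seq_len(n)
  findp <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (i in seq_len(n)) if (!is.na(midx[i])) {
    a <- findp(i); b <- findp(midx[i]); if (a != b) parent[a] <- b
  }
  comp <- vapply(seq_len(n), findp, integer(1))
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (cc in unique(comp)) {
    members <- which(comp == cc) # ascending, topological within component
    m <- length(members)
    Ab <- matrix(0, m, m)
    loc <- match(seq_len(n), members) # global -> local
    for (a in seq_len(m)) {
      g <- members[a]
      if (is.na(midx[g])) {
        Ab[a, a] <- 1
      } else {
        ml <- loc[midx[g]]
        if (a > 1) {
          prev <- seq_len(a - 1L)
          Ab[a, prev] <- 0.5 * Ab[ml, prev]
          Ab[prev, a] <- Ab[a, prev]
        }
        Ab[a, a] <- 1 # father unknown, mother non-inbred: no inbreeding
      }
    }
    nz <- which(Ab != 0, arr.ind = TRUE)
    ii <- c(ii, members[nz[, 1]]); jj <- c(jj, members[nz[, 2]])
    xx <- c(xx, Ab[nz])
  }
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                            dimnames = list(id, id))
  # return in original pedigree order
  orig <- as.character(pedigree$individual_id)
  A <- A[orig, orig, drop = FALSE]
  Matrix::forceSymmetric(A)
}

#' Sparse inverse of the additive relationship matrix
#'
#' For a pedigree with unknown fathers the inverse of A is assembled directly
#' from the pedigree in one pass: each individual contributes `1/d_i` to its
#' own diagonal, `-1/(2 d_i)` to the mother cross terms and `1/(4 d_i)` to the
#' mother diagonal, where `d_i` is the Mendelian sampling variance (1 for
#' founders, 3/4 with a known non-inbred mother). Alternatively an explicit
#' relationship matrix can be inverted, with an optional ridge for
#' numerically singular input.
#'
#' @param x A pedigree tibble or a (sparse or dense) relationship matrix.
#' @param ridge Non-negative value added to the diagonal before inverting a
#'   matrix that is not positive definite. Ignored for pedigree input.
#' @return A symmetric sparse `Matrix`, the inverse of `build_amatrix(x)`.
#' @export
amatrix_inverse <- function(x, ridge = 0) {
  if (is.data.frame(x)) {
    validate_pedigree(x)
    id <- as.character(x$individual_id)
    mom <- normalize_mother(x)
    midx <- match(mom, id)
    n <- length(id)
    has_mom <- !is.na(midx)
    d <- ifelse(has_mom, 0.75, 1)
    alpha <- 1 / d
    ii <- seq_len(n); jj <- seq_len(n); xx <- alpha
    hm <- which(has_mom)
    ii <- c(ii, hm, midx[hm], midx[hm])
    jj <- c(jj, midx[hm], hm, midx[hm])
    xx <- c(xx, -alpha[hm] / 2, -alpha[hm] / 2, alpha[hm] / 4)
    Ainv <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                                 dimnames = list(id, id))
    return(Matrix::forceSymmetric(Ainv))
  }
  A <- methods::as(methods::as(x, "generalMatrix"), "CsparseMatrix")
  ch <- tryCatch(Matrix::Cholesky(Matrix::forceSymmetric(A), LDL = FALSE),
                 error = function(e) NULL)
  if (is.null(ch)) {
    if (ridge <= 0) {
      abort("relationship matrix is singular; supply a positive ridge",
            class = "provtrial_pedigree_error")
    }
    A <- A + Matrix::Diagonal(nrow(A), ridge)
    ch <- Matrix::Cholesky(Matrix::forceSymmetric(A), LDL = FALSE)
  }
  Ainv <- Matrix::solve(ch, Matrix::Diagonal(nrow(A)))
  dimnames(Ainv) <- dimnames(A)
  Matrix::forceSymmetric(methods::as(Ainv, "CsparseMatrix"))
}

# log det A = sum log d_i over the pedigree (founders d = 1, known mother 3/4)
logdet_amatrix <- function(pedigree) {
  mom <- normalize_mother(pedigree)
  sum(log(ifelse(is.na(mom), 1, 0.75)))
}

normalize_mother <- function(pedigree) {
  mom <- as.character(pedigree$mother_id)
  mom[!is.na(mom) & mom == ""] <- NA_character_
  mom
}

# indices ordering parents before offspring
pedigree_topo_order <- function(pedigree) {
  id <- as.character(pedigree$individual_id)
  mom <- normalize_mother(pedigree)
  midx <- match(mom, id)
  depth <- integer(length(id))
  for (i in seq_along(id)) {
    j <- midx[i]; d <- 0L
    while (!is.na(j)) { d <- d + 1L; j <- midx[j] }
    depth[i] <- d
  }
  order(depth, seq_along(id))
}
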