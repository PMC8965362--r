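# Pedigree numerator relationship matrix A (tabular method, with
# inbreeding), its inverse, and the VanRaden (method 1) genomic relationship
# matrix G, plus blending for guaranteed invertibility.

# Topological sort of a pedigree so parents precede offspring; cycles abort.
pedigree_order <- function(pedigree) {
  ids <- pedigree$id
  if (anyDuplicated(ids)) {
    stop_input(sprintf("duplicate pedigree id(s): %s",
                       paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  idx <- seq_along(ids)
  names(idx) <- ids
  mo <- idx[pedigree$mother]
  fa <- idx[pedigree$father]
  placed <- rep(FALSE, length(ids))
  order_out <- integer(0)
  repeat {
    ready <- !placed &
      (is.na(mo) | placed[ifelse(is.na(mo), 1L, mo)]) &
      (is.na(fa) | placed[ifelse(is.na(fa), 1L, fa)])
    if (!any(ready)) break
    order_out <- c(order_out, which(ready))
    placed[ready] <- TRUE
  }
  if (!all(placed)) {
    stop_input(sprintf("pedigree contains a cycle involving: %s",
                       paste(ids[!placed], collapse = ", ")))
  }
  order_out
}

#' Pedigree numerator relationship matrix (A)
#'
#' Tabular method with inbreeding: `a(i,i) = 1 + a(m_i, f_i)/2` and
#' `a(i,j) = (a(j, m_i) + a(j, f_i))/2`, with unknown parents treated as
#' unrelated non-inbred founders. Parents referenced but absent from the id
#' column are added as founders.
#'
#' @param pedigree Tibble with columns `id`, `mother`, `father` (`NA` for
#'   unknown parents). Any ordering is accepted; rows are sorted internally so
#'   parents precede offspring.
#' @return Symmetric relationship matrix with the pedigree ids as dimnames;
#'   per-individual inbreeding `F = diag(A) - 1` in attribute `"inbreeding"`.
#' @export
build_A <- function(pedigree) {
  check_columns(pedigree, c("id", "mother", "father"), "pedigree")
  pedigree <- as_tibble(pedigree)[, c("id", "mother", "father")]
  implicit <- setdiff(unique(c(pedigree$mother, pedigree$father)),
                      c(pedigree$id, NA))
  if (length(implicit) > 0L) {
    pedigree <- dplyr::bind_rows(
      tibble(id = implicit, mother = NA_character_, father = NA_character_),
      pedigree
    )
  }
  ord <- pedigree_order(pedigree)
  ped <- pedigree[ord, ]
  n <- nrow(ped)
  pos <- seq_len(n)
  names(pos) <- ped$id
  mo <- pos[ped$mother]
  fa <- pos[ped$father]
  a <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    prev <- seq_len(i - 1L)
    am <- if (!is.na(mo[i])) a[mo[i], prev] else numeric(i - 1L)
    af <- if (!is.na(fa[i])) a[fa[i], prev] else numeric(i - 1L)
    if (i > 1L) {
      row_i <- 0.5 * (am + af)
      a[i, prev] <- row_i
      a[prev, i] <- row_i
    }
    amf <- if (!is.na(mo[i]) && !is.na(fa[i])) a[mo[i], fa[i]] else 0
    a[i, i] <- 1 + 0.5 * amf
  }
  a <- a[pedigree$id, pedigree$id, drop = FALSE]
  attr(a, "inbreeding") <- setNames(diag(a) - 1, rownames(a))
  attr(a, "kind") <- "A"
  a
}

#' Inverse of the pedigree relationship matrix
#'
#' Computed by Cholesky inversion of [build_A()]'s output; the contract is
#' that `A %*% build_A_inverse(ped)` equals the identity to high accuracy.
#'
#' @inheritParams build_A
#' @return Inverse numerator relationship matrix.
#' @export
build_A_inverse <- function(pedigree) {
  a <- build_A(pedigree)
  ch <- try(chol(a), silent = TRUE)
  if (!inherits(ch, "matrix")) {
    stop_input("A matrix is singular (duplicate identities or degenerate pedigree)")
  }
  ainv <- chol2inv(ch)
  dimnames(ainv) <- dimnames(a)
  attr(ainv, "kind") <- "A_inverse"
  ainv
}

#' VanRaden genomic relationship matrix (method 1)
#'
#' `G = Z Z' / (2 sum p_k (1 - p_k))` with `Z = M - 2p`, allele frequencies
#' `p` estimated from the genotyped sample itself. Missing dosages are
#' mean-imputed per SNP before centering; monomorphic SNPs and SNPs below
#' `maf_min` are excluded (count reported via a message).
#'
#' @param genotypes Dosage matrix (individuals x SNPs, values 0/1/2 or `NA`).
#' @param maf_min Minimum minor allele frequency retained.
#' @return Genomic relationship matrix with `F = diag(G) - 1` in attribute
#'   `"inbreeding"`.
#' @export
build_G <- function(genotypes, maf_min = 0.01) {
  if (!is.matrix(genotypes) || nrow(genotypes) < 2L) {
    stop_input("genotypes must be a matrix with >= 2 individuals")
  }
  p <- colMeans(genotypes, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  keep <- is.finite(maf) & maf >= maf_min & maf > 0
  n_dropped <- sum(!keep)
  if (!any(keep)) stop_input("all SNPs are monomorphic or below maf_min")
  if (n_dropped > 0L) {
    inform(sprintf("build_G: excluded %d SNP(s) (monomorphic or MAF < %g)",
                   n_dropped, maf_min))
  }
  m <- genotypes[, keep, drop = FALSE]
  p <- p[keep]
  if (anyNA(m)) {
    for (j in seq_len(ncol(m))) {
      nas <- is.na(m[, j])
      if (any(nas)) m[nas, j] <- 2 * p[j]
    }
  }
  z <- sweep(m, 2L, 2 * p)
  g <- tcrossprod(z) / (2 * sum(p * (1 - p)))
  attr(g, "inbreeding") <- setNames(diag(g) - 1, rownames(g))
  attr(g, "kind") <- "G"
  g
}

#' Blend a relationship matrix towards a positive-definite target
#'
#' `(1 - w) K + w T` with `T` the identity (default) or a supplied matrix
#' (e.g. the matching A submatrix). Positive definiteness of the result is
#' verified by Cholesky factorization.
#'
#' @param K Relationship matrix.
#' @param weight Blending weight in `[0, 1]`.
#' @param target `"identity"` or a matrix conformable with `K`.
#' @return Blended matrix (attribute `"kind"` = `"G_blended"`).
#' @export
blend_K <- function(K, weight = 0.01, target = "identity") {
  if (weight < 0 || weight > 1) stop_input("weight must lie in [0, 1]")
  t_mat <- if (is.character(target) && identical(target, "identity")) {
    diag(nrow(K))
  } else if (is.matrix(target)) {
    if (!all(dim(target) == dim(K))) stop_input("target must match dim(K)")
    target
  } else {
    stop_input("target must be \"identity\" or a matrix")
  }
  out <- (1 - weight) * K + weight * t_mat
  dimnames(out) <- dimnames(K)
  if (!is_positive_definite(out)) {
    stop_input("blended matrix still not positive definite; increase `weight`")
  }
  attr(out, "inbreeding") <- attr(K, "inbreeding")
  attr(out, "kind") <- "G_blended"
  out
}

#' Inbreeding coefficients from a relationship matrix
#'
#' @param K Relationship matrix (A or G); `F = diag(K) - 1`.
#' @return Named numeric vector of inbreeding coefficients.
#' @export
inbreeding_from_K <- function(K) {
  setNames(diag(K) - 1, rownames(K))
}
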