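#' Genomic relationship matrix (GCTA convention)
#'
#' G_jk = mean over polymorphic autosomal SNPs of
#' (x_j - 2p)(x_k - 2p) / (2p(1-p)). Missing calls are handled by
#' pairwise-complete SNP sets: a missing call contributes nothing to the
#' cross-product and the pair's denominator counts only SNPs observed in
#' both individuals.
#'
#' @param gm a [genotype_matrix()].
#' @return symmetric numeric matrix of class `grm` with sample-id
#'   dimnames.
#' @export
compute_grm <- function(gm) {
  vi <- which(!gm$variants$is_sex_linked)
  calls <- gm$calls[, vi, drop = FALSE]
  p <- colSums(calls, na.rm = TRUE) / (2 * colSums(!is.na(calls)))
  poly <- is.finite(p) & p > 0 & p < 1
  if (!any(poly)) stop("no polymorphic autosomal SNPs")
  calls <- calls[, poly, drop = FALSE]
  p <- p[poly]
  z <- sweep(calls, 2, 2 * p)
  z <- sweep(z, 2, sqrt(2 * p * (1 - p)), `/`)
  obs <- !is.na(z)
  z[!obs] <- 0
  num <- tcrossprod(z)
  den <- tcrossprod(obs * 1)
  g <- num / den
  dimnames(g) <- list(gm$samples$sample_id, gm$samples$sample_id)
  class(g) <- c("grm", class(g))
  g
}

#' PCA from a genomic relationship matrix
#'
#' Eigendecomposition of the GRM; components are ordered by eigenvalue
#' and the per-component variance proportion is eigenvalue / trace. Sign
#' convention: each component is flipped so its largest-magnitude loading
#' is positive, making coordinates reproducible across platforms.
#'
#' @param grm a [compute_grm()] result (or any symmetric matrix).
#' @param n_components number of components to return (default 2).
#' @return list of class `grm_pca`: `coords` (samples x components),
#'   `var_prop`, `eigenvalues`.
#' @export
pca_from_grm <- function(grm, n_components = 2) {
  g <- unclass(grm)
  if (any(!is.finite(g))) stop("non-finite GRM entries")
  e <- eigen(g, symmetric = TRUE)
  k <- min(n_components, ncol(g))
  vec <- e$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i_max <- which.max(abs(vec[, j]))
    if (vec[i_max, j] < 0) vec[, j] <- -vec[, j]
  }
  coords <- sweep(vec, 2, sqrt(pmax(e$values[seq_len(k)], 0)), `*`)
  dimnames(coords) <- list(rownames(g), paste0("PC", seq_len(k)))
  structure(list(coords = coords,
                 var_prop = e$values[seq_len(k)] / sum(diag(g)),
                 eigenvalues = e$values), class = "grm_pca")
}

#' @export
print.grm_pca <- function(x, ...) {
  cat("GRM PCA:", nrow(x$coords), "samples\n")
  cat("  variance proportions:",
      paste(sprintf("%.1f%%", 100 * x$var_prop), collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.grm_pca <- function(x, groups = NULL, ...) {
  col <- if (is.null(groups)) 1 else as.integer(factor(groups))
  graphics::plot(x$coords[, 1], x$coords[, 2], col = col,
                 xlab = sprintf("PC1 (%.1f%%)", 100 * x$var_prop[1]),
                 ylab = sprintf("PC2 (%.1f%%)", 100 * x$var_prop[2]), ...)
  invisible(x)
}

#' Allele-sharing distance matrix
#'
#' d(j,k) = 1 - IBS(j,k), where IBS is the mean shared-allele fraction
#' (1, 0.5, or 0 per SNP for dosage differences 0, 1, 2) over SNPs
#' non-missing in both individuals. A pair with no shared non-missing
#' SNP is an error.
#'
#' @param gm a [genotype_matrix()].
#' @param by_population if TRUE, return the matrix of mean
#'   inter-individual distances between (and within) populations instead
#'   of the individual-level matrix.
#' @return symmetric `dist`-convertible matrix with zero diagonal.
#' @export
allele_sharing_distance <- function(gm, by_population = FALSE) {
  calls <- gm$calls
  a <- lapply(0:2, function(g) {
    m <- calls == g
    m[is.na(m)] <- FALSE
    m * 1
  })
  # sum over SNPs of |x_j - x_k| and of jointly observed SNPs
  absdiff <- tcrossprod(a[[1]], a[[2]]) + tcrossprod(a[[2]], a[[1]]) +
    tcrossprod(a[[2]], a[[3]]) + tcrossprod(a[[3]], a[[2]]) +
    2 * (tcrossprod(a[[1]], a[[3]]) + tcrossprod(a[[3]], a[[1]]))
  obs <- a[[1]] + a[[2]] + a[[3]]
  shared <- tcrossprod(obs)
  if (any(shared == 0 & row(shared) != col(shared)))
    stop("sample pair(s) with no shared non-missing SNPs")
  d <- absdiff / (2 * shared)
  diag(d) <- 0
  dimnames(d) <- list(gm$samples$sample_id, gm$samples$sample_id)
  if (!by_population) return(d)
  pops <- unique(gm$samples$population)
  pd <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  for (i in seq_along(pops)) for (j in seq_along(pops)) {
    ii <- gm$samples$population == pops[i]
    jj <- gm$samples$population == pops[j]
    block <- d[ii, jj, drop = FALSE]
    if (i == j) {
      pd[i, j] <- if (sum(ii) > 1) mean(block[upper.tri(block)]) else 0
    } else pd[i, j] <- mean(block)
  }
  diag(pd) <- 0
  pd
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration (via ape) on a symmetric distance matrix,
#' with newick serialization at full precision. Negative branch lengths,
#' which NJ can produce, are preserved and flagged with a warning rather
#' than zeroed.
#'
#' @param distances symmetric numeric matrix with zero diagonal (e.g.
#'   from [allele_sharing_distance()]).
#' @return an ape `phylo` object with attribute `newick` (the serialized
#'   tree string).
#' @export
nj_tree <- function(distances) {
  distances <- as.matrix(distances)
  if (!isSymmetric(unname(distances), tol = 1e-8))
    stop("distance matrix must be symmetric")
  if (nrow(distances) < 3) stop("need >= 3 labels for NJ")
  tree <- ape::nj(stats::as.dist(distances))
  if (any(tree$edge.length < 0))
    warning(sum(tree$edge.length < 0),
            " negative NJ branch length(s) preserved")
  attr(tree, "newick") <- ape::write.tree(tree, digits = 15)
  tree
}
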