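#' EM estimate of two-locus haplotype frequencies
#'
#' Maximum-likelihood haplotype frequencies for two biallelic loci from
#' unphased genotype counts, by expectation-maximization over the phase of
#' double heterozygotes. The iteration starts from linkage equilibrium
#' (the product of the observed allele frequencies) and stops when the
#' largest frequency change is below `tol` or after `max_iter` iterations.
#' An all-double-heterozygote table is a degenerate case whose likelihood
#' is symmetric about D = 0: the LE start is already stationary and is
#' returned with `degenerate = TRUE`.
#'
#' Allele "A"/"B" denotes the alternate allele at each locus (dosage
#' counts), "a"/"b" the reference.
#'
#' @param counts 3x3 matrix of genotype counts: rows = dosage 0/1/2 at
#'   locus 1, columns = dosage 0/1/2 at locus 2.
#' @param tol convergence tolerance on haplotype frequencies.
#' @param max_iter iteration cap.
#' @param trace if TRUE, attach the per-iteration log-likelihood.
#' @return list of class `haplotype_freqs` with `p_AB`, `p_Ab`, `p_aB`,
#'   `p_ab`, `n_iter`, `converged`, `degenerate`.
#' @export
em_haplotype_freqs <- function(counts, tol = 1e-10, max_iter = 1000,
                               trace = FALSE) {
  counts <- as.matrix(counts)
  stopifnot(all(dim(counts) == c(3, 3)), all(counts >= 0),
            sum(counts) >= 1)
  cvec <- matrix(as.vector(counts), nrow = 1)  # column-major: (g1, g2) pairs
  fit <- em_haplo_core(cvec, tol = tol, max_iter = max_iter,
                       trace = trace)
  f <- unname(fit$f)
  out <- list(p_AB = f[1, 1], p_Ab = f[1, 2], p_aB = f[1, 3],
              p_ab = f[1, 4], n_iter = fit$n_iter,
              converged = fit$converged[1], degenerate = fit$degenerate[1])
  if (trace) out$loglik_trace <- fit$loglik_trace
  class(out) <- "haplotype_freqs"
  out
}

#' @export
print.haplotype_freqs <- function(x, ...) {
  cat(sprintf("haplotype frequencies: AB=%.4f Ab=%.4f aB=%.4f ab=%.4f\n",
              x$p_AB, x$p_Ab, x$p_aB, x$p_ab))
  cat(sprintf("  (%d EM iterations, converged=%s%s)\n", x$n_iter,
              x$converged, if (x$degenerate) ", degenerate" else ""))
  invisible(x)
}

# Vectorized EM over many locus pairs. `cmat` is n_pairs x 9, column k+1
# holding the count of (g1, g2) with code g1 + 3*g2 = k (column-major
# order of the 3x3 table: (0,0),(1,0),(2,0),(0,1),...,(2,2)).
# Returns f: n_pairs x 4 (AB, Ab, aB, ab), with NA rows where a locus is
# monomorphic (undefined LD).
em_haplo_core <- function(cmat, tol = 1e-10, max_iter = 1000,
                          trace = FALSE) {
  g1 <- rep(0:2, 3)
  g2 <- rep(0:2, each = 3)
  n2 <- 2 * rowSums(cmat)                       # chromosomes
  pA <- as.vector(cmat %*% g1) / n2
  pB <- as.vector(cmat %*% g2) / n2
  mono <- pA <= 0 | pA >= 1 | pB <= 0 | pB >= 1

  # fixed haplotype contributions from phase-known genotype pairs
  # (count of AB, Ab, aB, ab per individual for each of the 9 codes;
  #  code 5 = double het contributes via the E step)
  kAB <- c(0, 0, 0, 0, NA, 1, 0, 1, 2)
  kAb <- c(0, 1, 2, 0, NA, 1, 0, 0, 0)
  kaB <- c(0, 0, 0, 1, NA, 0, 2, 1, 0)
  kab <- c(2, 1, 0, 1, NA, 0, 0, 0, 0)
  dh <- cmat[, 5]                               # double-het count
  fixAB <- as.vector(cmat[, -5, drop = FALSE] %*% kAB[-5])
  fixAb <- as.vector(cmat[, -5, drop = FALSE] %*% kAb[-5])
  fixaB <- as.vector(cmat[, -5, drop = FALSE] %*% kaB[-5])
  fixab <- as.vector(cmat[, -5, drop = FALSE] %*% kab[-5])

  f <- cbind(AB = pA * pB, Ab = pA * (1 - pB),
             aB = (1 - pA) * pB, ab = (1 - pA) * (1 - pB))
  converged <- rep(FALSE, nrow(cmat))
  n_iter <- 0L
  ll <- NULL
  loglik <- function(f) {
    # genotype-pair probabilities under random union of gametes
    pr <- cbind(f[, 4]^2, 2 * f[, 2] * f[, 4], f[, 2]^2,
                2 * f[, 3] * f[, 4],
                2 * (f[, 1] * f[, 4] + f[, 2] * f[, 3]),
                2 * f[, 1] * f[, 2], f[, 3]^2, 2 * f[, 1] * f[, 3],
                f[, 1]^2)
    rowSums(cmat * log(pmax(pr, 1e-300)))
  }
  repeat {
    n_iter <- n_iter + 1L
    prod_cis <- f[, 1] * f[, 4]
    prod_trans <- f[, 2] * f[, 3]
    w <- ifelse(prod_cis + prod_trans > 0,
                prod_cis / (prod_cis + prod_trans), 0.5)
    new_f <- cbind(fixAB + dh * w, fixAb + dh * (1 - w),
                   fixaB + dh * (1 - w), fixab + dh * w) / n2
    ad <- abs(new_f - f)
    delta <- pmax(ad[, 1], ad[, 2], ad[, 3], ad[, 4])
    f <- new_f
    if (trace) ll <- c(ll, loglik(f))
    converged <- delta < tol
    if (all(converged | mono) || n_iter >= max_iter) break
  }
  f[mono, ] <- NA_real_
  degenerate <- !mono & dh == rowSums(cmat)
  list(f = f, n_iter = n_iter, converged = converged,
       degenerate = degenerate, loglik_trace = ll, p_A = pA, p_B = pB)
}

#' r-squared from two-locus haplotype frequencies
#'
#' r2 = (p_AB p_ab - p_Ab p_aB)^2 / (P_A P_a P_B P_b), with the allele
#' frequencies taken as the haplotype marginals.
#'
#' @param haps a `haplotype_freqs` object (or list with the four
#'   frequencies).
#' @return r-squared in \[0, 1\].
#' @export
r2_from_haplotypes <- function(haps) {
  pA <- haps$p_AB + haps$p_Ab
  pB <- haps$p_AB + haps$p_aB
  denom <- pA * (1 - pA) * pB * (1 - pB)
  if (!is.finite(denom) || denom <= 0)
    stop("r2 undefined: a locus is monomorphic")
  d <- haps$p_AB * haps$p_ab - haps$p_Ab * haps$p_aB
  min(1, d^2 / denom)
}

# r2 for many pairs at once from a dosage matrix (samples x variants).
# `pairs` is a 2-column index matrix. Returns numeric vector (NA where a
# locus is monomorphic in the subset).
ld_r2_pairs <- function(calls, pairs) {
  pairs <- matrix(as.integer(pairs), ncol = 2)
  ind <- lapply(0:2, function(g) {
    m <- calls == g
    m[is.na(m)] <- FALSE
    m
  })
  n_pairs <- nrow(pairs)
  cmat <- matrix(0, n_pairs, 9)
  k <- 0L
  for (j2 in 0:2) for (j1 in 0:2) {
    k <- k + 1L
    cmat[, k] <- colSums(ind[[j1 + 1]][, pairs[, 1], drop = FALSE] *
                         ind[[j2 + 1]][, pairs[, 2], drop = FALSE])
  }
  # drop individuals missing at either locus: counts only include jointly
  # observed calls by construction of the indicator product
  fit <- em_haplo_core(cmat)
  f <- fit$f
  pA <- f[, 1] + f[, 2]
  pB <- f[, 1] + f[, 3]
  denom <- pA * (1 - pA) * pB * (1 - pB)
  d <- f[, 1] * f[, 4] - f[, 2] * f[, 3]
  r2 <- ifelse(is.na(denom) | denom <= 0, NA_real_, pmin(1, d^2 / denom))
  r2
}

#' Population LD-decay curve
#'
#' Mean EM-based r-squared in physical-distance bins, over all
#' intra-chromosome autosomal SNP pairs closer than `max_dist_bp`,
#' computed on a seeded random subsample of individuals (the small-sample
#' design keeps curves comparable across populations of very different
#' size). Bins are half-open `(start, end]` of width `bin_bp`. Pairs where
#' either locus is monomorphic in the subsample are dropped.
#'
#' @param gm a [genotype_matrix()].
#' @param population population label (or sample subset).
#' @param max_dist_bp maximum pair distance (default 500 kb).
#' @param bin_bp bin width (default 5 kb; use 1 to read single-distance
#'   evaluation points).
#' @param n_subsample individuals to draw (default 7); if the population
#'   is smaller, all are used with a message.
#' @param seed integer seed for the subsample.
#' @return data.frame of class `ld_decay` with columns `bin_start_bp`,
#'   `bin_end_bp`, `mean_r2`, `n_pairs`, `population`; subsampled ids and
#'   seed kept as attributes.
#' @export
ld_decay_curve <- function(gm, population, max_dist_bp = 500000,
                           bin_bp = 5000, n_subsample = 7, seed = 1) {
  idx <- resolve_samples(gm, population)
  if (length(idx) > n_subsample) {
    idx <- with_seed(seed, sort(sample(idx, n_subsample)))
  } else if (length(idx) < n_subsample) {
    message("population smaller than n_subsample: using all ",
            length(idx), " individuals")
  }
  vi <- which(!gm$variants$is_sex_linked)
  v <- gm$variants[vi, , drop = FALSE]
  calls <- gm$calls[idx, vi, drop = FALSE]

  pr <- NULL
  for (ch in unique(v$chrom)) {
    w <- which(v$chrom == ch)
    pos <- v$pos_bp[w]
    last <- findInterval(pos + max_dist_bp, pos)
    ni <- last - seq_along(w)
    if (sum(ni) == 0) next
    i1 <- rep(seq_along(w), ni)
    i2 <- sequence(ni, from = seq_along(w) + 1L)
    pr <- rbind(pr, cbind(w[i1], w[i2], pos[i2] - pos[i1]))
  }
  if (is.null(pr) || nrow(pr) == 0) stop("no eligible SNP pairs")
  r2 <- ld_r2_pairs(calls, pr[, 1:2, drop = FALSE])
  keep <- !is.na(r2)
  dist <- pr[keep, 3]
  r2 <- r2[keep]

  n_bins <- ceiling(max_dist_bp / bin_bp)
  bin <- pmin(ceiling(dist / bin_bp), n_bins)
  mean_r2 <- rep(NA_real_, n_bins)
  agg <- tapply(r2, bin, mean)
  mean_r2[as.integer(names(agg))] <- agg
  n_pairs <- integer(n_bins)
  tab <- table(bin)
  n_pairs[as.integer(names(tab))] <- as.integer(tab)

  pop_label <- if (is.character(population) && length(population) == 1)
    population else "subset"
  out <- data.frame(bin_start_bp = (seq_len(n_bins) - 1) * bin_bp,
                    bin_end_bp = pmin(seq_len(n_bins) * bin_bp, max_dist_bp),
                    mean_r2 = mean_r2, n_pairs = n_pairs,
                    population = pop_label, stringsAsFactors = FALSE)
  attr(out, "sample_ids") <- gm$samples$sample_id[idx]
  attr(out, "seed") <- seed
  class(out) <- c("ld_decay", "data.frame")
  out
}

#' @export
plot.ld_decay <- function(x, ...) {
  ok <- !is.na(x$mean_r2)
  mid <- (x$bin_start_bp + x$bin_end_bp) / 2 / 1000
  graphics::plot(mid[ok], x$mean_r2[ok], type = "l",
                 xlab = "distance (kb)", ylab = expression(mean ~ r^2),
                 main = paste("LD decay:", x$population[1]), ...)
  invisible(x)
}
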