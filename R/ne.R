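#' Sample-size adjustment of r-squared
#'
#' Subtracts the expected sampling contribution 1/n (unphased, EM-based
#' r-squared from n diploid individuals) and floors the result at zero;
#' floored entries are flagged in the `"floored"` attribute.
#'
#' @param r2 numeric vector of r-squared values.
#' @param n_individuals diploid sample size the r2 were computed from.
#' @return adjusted r-squared vector with attribute `floored`.
#' @export
adjust_r2_for_sample_size <- function(r2, n_individuals) {
  stopifnot(n_individuals >= 2)
  adj <- r2 - 1 / n_individuals
  floored <- adj <= 0
  adj[floored] <- 0
  attr(adj, "floored") <- floored
  adj
}

# physical distance (bp) -> recombination fraction, linear map capped at 0.5
dist_to_c <- function(dist_bp, rate_cm_per_mb = 1.0) {
  pmin(dist_bp * rate_cm_per_mb * 1e-8, 0.5)
}

# scalar rate, named vector, data.frame (chrom, cm_per_mb), or TSV path
# -> per-pair rate vector
resolve_map_rate <- function(map_rate, chrom) {
  if (is.character(map_rate) && length(map_rate) == 1) {
    map_rate <- utils::read.table(map_rate, header = TRUE, sep = "\t",
                                  stringsAsFactors = FALSE)
  }
  if (is.data.frame(map_rate)) {
    if (!all(c("chrom", "cm_per_mb") %in% names(map_rate)))
      stop("recombination map needs columns 'chrom' and 'cm_per_mb'")
    map_rate <- stats::setNames(map_rate$cm_per_mb,
                                as.character(map_rate$chrom))
  }
  if (length(map_rate) == 1 && is.null(names(map_rate)))
    return(as.numeric(map_rate))
  if (is.null(chrom))
    stop("per-chromosome map rates require a 'chrom' column in ld_pairs")
  rate <- unname(map_rate[as.character(chrom)])
  if (anyNA(rate))
    stop("no map rate for chromosome(s): ",
         paste(unique(chrom[is.na(rate)]), collapse = ", "))
  rate
}

#' Historical effective population size from binned LD
#'
#' Inverts the drift-recombination equilibrium relation
#' E\[r2_adj\] = 1 / (alpha + 4 N c): pairs are mapped from physical
#' distance to recombination fraction c (linear `map_rate_cm_per_mb`,
#' capped at 0.5), binned on c, and each bin yields
#' Ne(t) = (1/(4 c_bar)) * (1/mean(r2_adj) - alpha) dated at
#' t = 1/(2 c_bar) generations ago. Bins with fewer than
#' `min_pairs_per_bin` pairs are masked (`NA`).
#'
#' @param ld_pairs data.frame with columns `dist_bp` and `r2`
#'   (sample-size-adjusted r-squared; apply
#'   [adjust_r2_for_sample_size()] first, or pass `n_individuals`), and
#'   optionally `chrom` when a per-chromosome map is used.
#' @param map_rate_cm_per_mb linear genetic map rate: a single number
#'   (default 1 cM/Mb), a named vector of rates by chromosome, a
#'   data.frame with columns `chrom` and `cm_per_mb`, or the path of a
#'   two-column TSV of the same layout (then `ld_pairs$chrom` is
#'   required).
#' @param n_bins number of equal-width bins over the observed c range.
#' @param min_pairs_per_bin mask threshold (default 20).
#' @param alpha Sved relation constant: 1 (default) or 2.2 for the
#'   mutation-adjusted variant.
#' @param n_individuals if given, r2 values are first adjusted via
#'   [adjust_r2_for_sample_size()].
#' @return data.frame of class `ne_trajectory`: `generations_ago`, `ne`,
#'   `c_bin`, `n_pairs`.
#' @export
historical_ne <- function(ld_pairs, map_rate_cm_per_mb = 1.0, n_bins = 30,
                          min_pairs_per_bin = 20, alpha = 1,
                          n_individuals = NULL) {
  r2 <- ld_pairs$r2
  if (!is.null(n_individuals))
    r2 <- adjust_r2_for_sample_size(r2, n_individuals)
  rate <- resolve_map_rate(map_rate_cm_per_mb, ld_pairs$chrom)
  cc <- dist_to_c(ld_pairs$dist_bp, rate)
  ok <- is.finite(r2) & is.finite(cc) & cc > 0
  if (!any(ok)) stop("no usable pairs")
  r2 <- r2[ok]; cc <- cc[ok]
  # half-open (start, end] bins of equal width over (0, max(c)];
  # ceiling with a tiny slack keeps exact grid points on their edge
  bin <- pmin(pmax(ceiling(cc / max(cc) * n_bins - 1e-9), 1L), n_bins)
  cbar <- tapply(cc, bin, mean)
  r2bar <- tapply(r2, bin, mean)
  np <- tapply(r2, bin, length)
  out <- data.frame(c_bin = rep(NA_real_, n_bins),
                    generations_ago = NA_real_, ne = NA_real_,
                    n_pairs = 0L)
  ib <- as.integer(names(cbar))
  out$c_bin[ib] <- cbar
  out$n_pairs[ib] <- as.integer(np)
  out$generations_ago[ib] <- 1 / (2 * cbar)
  ne <- (1 / (4 * cbar)) * (1 / r2bar - alpha)
  ne[r2bar <= 0] <- NA_real_
  out$ne[ib] <- pmax(ne, 0)
  out$ne[out$n_pairs < min_pairs_per_bin] <- NA_real_
  out <- out[order(out$generations_ago), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ne_trajectory", "data.frame")
  out
}

#' @export
plot.ne_trajectory <- function(x, ...) {
  ok <- !is.na(x$ne)
  graphics::plot(x$generations_ago[ok], x$ne[ok], type = "b", log = "x",
                 xlab = "generations ago", ylab = "Ne", ...)
  invisible(x)
}

#' Contemporary effective population size from unlinked-locus LD
#'
#' Hill-type estimator on a seeded subsample of S individuals: mean
#' EM-based r-squared over pairs of loci on different chromosomes, then
#' Ne = 1 / (3 * (mean r2 - 1/S)). When mean r2 <= 1/S the estimate is
#' undefined (consistent with infinite Ne) and returned as `NA` with a
#' flag.
#'
#' @param gm a [genotype_matrix()] (QC-filtered input recommended).
#' @param population population label (or sample subset).
#' @param n_subsample individuals to draw (default 40; all if fewer).
#' @param seed integer seed for subsampling (individuals and pairs).
#' @param max_pairs cap on the number of cross-chromosome pairs (default
#'   50000, drawn uniformly at random when exceeded).
#' @return list of class `ne_point_estimate`: `ne_hat`,
#'   `mean_adjusted_r2`, `mean_r2`, `n_samples_used`, `n_pairs`,
#'   `undefined`.
#' @export
contemporary_ne <- function(gm, population = NULL, n_subsample = 40,
                            seed = 1, max_pairs = 50000) {
  idx <- resolve_samples(gm, population)
  if (length(idx) < 2) stop("need at least 2 individuals")
  if (length(idx) > n_subsample)
    idx <- with_seed(seed, sort(sample(idx, n_subsample)))
  S <- length(idx)
  vi <- which(!gm$variants$is_sex_linked)
  v <- gm$variants[vi, , drop = FALSE]
  calls <- gm$calls[idx, vi, drop = FALSE]
  chroms <- unique(v$chrom)
  if (length(chroms) < 2) stop("need >= 2 autosomes for unlinked pairs")

  # seeded uniform draw of cross-chromosome pairs without enumeration
  chrom_id <- match(v$chrom, chroms)
  pr <- with_seed(derive_seed(seed, "pairs"), {
    i <- sample.int(nrow(v), 4 * max_pairs, replace = TRUE)
    j <- sample.int(nrow(v), 4 * max_pairs, replace = TRUE)
    keep <- chrom_id[i] != chrom_id[j]
    cbind(i[keep], j[keep])[seq_len(min(max_pairs, sum(keep))), ,
                            drop = FALSE]
  })
  if (nrow(pr) == 0) stop("no eligible unlinked pairs")
  r2 <- ld_r2_pairs(calls, pr)
  r2 <- r2[!is.na(r2)]
  if (!length(r2)) stop("no eligible unlinked pairs")
  mean_r2 <- mean(r2)
  denom <- mean_r2 - 1 / S
  undefined <- denom <= 0
  structure(list(ne_hat = if (undefined) NA_real_ else 1 / (3 * denom),
                 mean_r2 = mean_r2, mean_adjusted_r2 = max(denom, 0),
                 n_samples_used = S, n_pairs = length(r2),
                 undefined = undefined),
            class = "ne_point_estimate")
}

#' @export
print.ne_point_estimate <- function(x, ...) {
  if (x$undefined)
    cat("contemporary Ne: undefined (consistent with infinite Ne)\n")
  else
    cat(sprintf("contemporary Ne = %.1f (S = %d, %d unlinked pairs, mean r2 = %.5f)\n",
                x$ne_hat, x$n_samples_used, x$n_pairs, x$mean_r2))
  invisible(x)
}
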