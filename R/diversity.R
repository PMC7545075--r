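#' Observed heterozygosity per individual
#'
#' Ho = (number of heterozygous calls) / (number of non-missing calls),
#' the complement of observed homozygosity.
#'
#' @param gm a [genotype_matrix()].
#' @param samples sample subset (indices, ids, or population label).
#' @param autosomal_only restrict to autosomal variants (default TRUE).
#' @return named numeric vector, one Ho per individual.
#' @export
observed_heterozygosity <- function(gm, samples = NULL,
                                    autosomal_only = TRUE) {
  idx <- resolve_samples(gm, samples)
  vi <- if (autosomal_only) !gm$variants$is_sex_linked else
    rep(TRUE, ncol(gm$calls))
  calls <- gm$calls[idx, vi, drop = FALSE]
  n_obs <- rowSums(!is.na(calls))
  if (any(n_obs == 0)) stop("sample(s) with no non-missing calls")
  rowSums(calls == 1L, na.rm = TRUE) / n_obs
}

# unbiased per-variant expected heterozygosity 2p(1-p) * m/(m-1),
# m = non-missing allele count
he_per_variant <- function(calls) {
  n_obs <- colSums(!is.na(calls))
  m <- 2 * n_obs
  p <- colSums(calls, na.rm = TRUE) / m
  ifelse(m >= 2, 2 * p * (1 - p) * m / (m - 1), NA_real_)
}

#' Expected heterozygosity per individual and per variant
#'
#' Per-variant He is the unbiased estimator 2p(1-p) * m/(m-1) with m the
#' number of non-missing alleles in the population. The per-individual
#' value averages the per-variant He over that individual's non-missing
#' variants (the array-toolkit convention, which makes He reportable with
#' an across-individual spread like Ho).
#'
#' @param gm a [genotype_matrix()].
#' @param population population label (or sample subset) defining the
#'   allele frequencies.
#' @param autosomal_only restrict to autosomal variants (default TRUE).
#' @return list with `per_individual` (named vector), `per_variant`
#'   (vector), and `mean` (average over variants).
#' @export
expected_heterozygosity <- function(gm, population = NULL,
                                    autosomal_only = TRUE) {
  idx <- resolve_samples(gm, population)
  vi <- if (autosomal_only) which(!gm$variants$is_sex_linked) else
    seq_len(ncol(gm$calls))
  calls <- gm$calls[idx, vi, drop = FALSE]
  he_v <- he_per_variant(calls)
  obs <- !is.na(calls)
  he_vv <- ifelse(is.na(he_v), 0, he_v)
  per_ind <- as.vector(obs %*% he_vv) / rowSums(obs)
  names(per_ind) <- gm$samples$sample_id[idx]
  list(per_individual = per_ind, per_variant = he_v,
       mean = mean(he_v, na.rm = TRUE))
}

#' SNP-ascertained nucleotide diversity
#'
#' Per-site pi for a biallelic site with non-missing allele counts n_ref
#' and n_alt (N = n_ref + n_alt) is n_ref * n_alt / choose(N, 2): the
#' average number of pairwise allelic differences. The mean is over
#' retained SNP sites (SNP-ascertained pi, not per-bp). Sites with N < 2
#' are skipped with a message.
#'
#' @inheritParams expected_heterozygosity
#' @return list with `per_site` vector and `mean` and `sd` over sites.
#' @export
nucleotide_diversity <- function(gm, population = NULL,
                                 autosomal_only = TRUE) {
  idx <- resolve_samples(gm, population)
  vi <- if (autosomal_only) which(!gm$variants$is_sex_linked) else
    seq_len(ncol(gm$calls))
  calls <- gm$calls[idx, vi, drop = FALSE]
  n_obs <- colSums(!is.na(calls))
  N <- 2 * n_obs
  n_alt <- colSums(calls, na.rm = TRUE)
  n_ref <- N - n_alt
  skip <- N < 2
  if (any(skip))
    message(sum(skip), " site(s) with < 2 alleles skipped")
  pi_site <- ifelse(skip, NA_real_, n_ref * n_alt / choose(N, 2))
  list(per_site = pi_site, mean = mean(pi_site, na.rm = TRUE),
       sd = stats::sd(pi_site, na.rm = TRUE))
}

#' Per-population diversity summary
#'
#' Ho and He are computed per individual and summarized as mean and sd
#' across individuals; He sd across variants is reported alongside (the
#' two spreads answer different questions and are labelled).
#'
#' @param gm a [genotype_matrix()].
#' @param populations labels to summarize (default: all).
#' @return data.frame of class `diversity_summary`.
#' @export
diversity_summary <- function(gm, populations = NULL) {
  if (is.null(populations)) populations <- unique(gm$samples$population)
  rows <- lapply(populations, function(pop) {
    ho <- observed_heterozygosity(gm, samples = pop)
    he <- expected_heterozygosity(gm, population = pop)
    pv <- nucleotide_diversity(gm, population = pop)
    data.frame(population = pop, n_samples = length(ho),
               ho_mean = mean(ho), ho_sd = stats::sd(ho),
               he_mean = mean(he$per_individual),
               he_sd_individuals = stats::sd(he$per_individual),
               he_sd_snps = stats::sd(he$per_variant, na.rm = TRUE),
               pi_mean = pv$mean, pi_sd = pv$sd,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("diversity_summary", "data.frame")
  out
}

#' @export
print.diversity_summary <- function(x, ...) {
  df <- as.data.frame(x)
  df$Ho <- sprintf("%.3f ± %.3f", df$ho_mean, df$ho_sd)
  df$He <- sprintf("%.3f ± %.3f", df$he_mean, df$he_sd_individuals)
  df$pi <- sprintf("%.3f ± %.3f", df$pi_mean, df$pi_sd)
  print(df[, c("population", "n_samples", "Ho", "He", "pi")],
        row.names = FALSE)
  invisible(x)
}

# WC84 two-population variance components per locus.
# Returns matrix with columns a, b, c (NA where undefined).
wc_components <- function(callsA, callsB) {
  r <- 2
  nA <- colSums(!is.na(callsA)); nB <- colSums(!is.na(callsB))
  pA <- colSums(callsA, na.rm = TRUE) / (2 * nA)
  pB <- colSums(callsB, na.rm = TRUE) / (2 * nB)
  hA <- colSums(callsA == 1L, na.rm = TRUE) / nA
  hB <- colSums(callsB == 1L, na.rm = TRUE) / nB

  nbar <- (nA + nB) / 2
  nc <- (r * nbar - (nA^2 + nB^2) / (r * nbar)) / (r - 1)
  pbar <- (nA * pA + nB * pB) / (r * nbar)
  s2 <- (nA * (pA - pbar)^2 + nB * (pB - pbar)^2) / ((r - 1) * nbar)
  hbar <- (nA * hA + nB * hB) / (r * nbar)

  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2

  bad <- nA < 1 | nB < 1 | nbar <= 1 | nc <= 0
  a[bad] <- b[bad] <- cc[bad] <- NA_real_
  cbind(a = a, b = b, c = cc)
}

#' Weir-Cockerham multi-locus FST between two populations
#'
#' The full two-population 1984 estimator including the
#' observed-heterozygosity component: per-locus variance components a
#' (among populations), b (among individuals within populations), and c
#' (within individuals), combined as sum(a) / sum(a + b + c) over loci
#' with a defined, non-zero denominator. The estimate is reported as
#' computed and may be negative (the parameter, not the estimator, lives
#' in \[0, 1\]). Loci monomorphic across both populations drop out
#' (denominator 0).
#'
#' @param gm a [genotype_matrix()].
#' @param pop_a,pop_b population labels (or sample index vectors).
#' @param autosomal_only restrict to autosomal variants (default TRUE).
#' @return list of class `fst_estimate`: `fst`, `n_loci_used`, and the
#'   per-locus component matrix.
#' @export
fst_weir_cockerham <- function(gm, pop_a, pop_b, autosomal_only = TRUE) {
  ia <- resolve_samples(gm, pop_a)
  ib <- resolve_samples(gm, pop_b)
  vi <- if (autosomal_only) !gm$variants$is_sex_linked else
    rep(TRUE, ncol(gm$calls))
  comp <- wc_components(gm$calls[ia, vi, drop = FALSE],
                        gm$calls[ib, vi, drop = FALSE])
  denom <- rowSums(comp)
  use <- !is.na(denom) & denom > 0
  if (!any(use)) stop("no usable loci for FST")
  structure(list(fst = sum(comp[use, "a"]) / sum(denom[use]),
                 n_loci_used = sum(use), components = comp),
            class = "fst_estimate")
}

#' @export
print.fst_estimate <- function(x, ...) {
  cat(sprintf("Weir-Cockerham FST = %.4f (%s; %d loci)\n", x$fst,
              classify_fst(x$fst), x$n_loci_used))
  invisible(x)
}

#' Classify an FST value into four differentiation levels
#'
#' Low (< 0.05, including negative estimates), medium (0.05 to < 0.15),
#' high (0.15 to 0.25 inclusive), extreme (> 0.25).
#'
#' @param value numeric FST value(s).
#' @return character vector of levels.
#' @export
classify_fst <- function(value) {
  stopifnot(all(is.finite(value)))
  out <- character(length(value))
  out[value < 0.05] <- "low"
  out[value >= 0.05 & value < 0.15] <- "medium"
  out[value >= 0.15 & value <= 0.25] <- "high"
  out[value > 0.25] <- "extreme"
  out
}

#' Pairwise FST matrix across all populations
#'
#' @param gm a [genotype_matrix()].
#' @param populations labels (default: all in `gm`).
#' @return object of class `fst_matrix`: symmetric `values` matrix (zero
#'   diagonal), matching `levels` matrix, and a long-form data.frame.
#' @export
fst_matrix <- function(gm, populations = NULL) {
  if (is.null(populations)) populations <- unique(gm$samples$population)
  k <- length(populations)
  vals <- matrix(0, k, k, dimnames = list(populations, populations))
  long <- NULL
  if (k >= 2) {
    for (i in seq_len(k - 1)) for (j in seq.int(i + 1, k)) {
      est <- fst_weir_cockerham(gm, populations[i], populations[j])
      vals[i, j] <- vals[j, i] <- est$fst
      long <- rbind(long, data.frame(pop_a = populations[i],
                                     pop_b = populations[j], fst = est$fst,
                                     level = classify_fst(est$fst),
                                     stringsAsFactors = FALSE))
    }
  }
  lev <- matrix(classify_fst(pmax(vals, 0)), k, k,
                dimnames = dimnames(vals))
  structure(list(populations = populations, values = vals, levels = lev,
                 pairs = long), class = "fst_matrix")
}

#' @export
print.fst_matrix <- function(x, ...) {
  cat("Pairwise Weir-Cockerham FST:\n")
  print(round(x$values, 4))
  invisible(x)
}
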