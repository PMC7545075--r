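# Brute-force reference implementations and fixture builders shared across
# the suite. Oracles deliberately use naive loops / direct formulas so they
# stay independent of the package's vectorized code paths.

make_gm <- function(calls, chrom = NULL, pos = NULL, population = NULL,
                    sex = NULL) {
  calls <- rbind(calls)
  n <- nrow(calls); L <- ncol(calls)
  if (is.null(chrom)) chrom <- rep("1", L)
  if (is.null(pos)) pos <- seq_len(L) * 1000L
  samples <- data.frame(sample_id = sprintf("s%03d", seq_len(n)),
                        population = if (is.null(population)) "pop1"
                        else population,
                        stringsAsFactors = FALSE)
  if (!is.null(sex)) samples$sex <- sex
  genotype_matrix(calls, data.frame(chrom = chrom, pos_bp = pos,
                                    stringsAsFactors = FALSE), samples)
}

random_gm <- function(seed, n = 20, L = 50, miss = 0.05, n_chrom = 2,
                      population = NULL) {
  set.seed(seed)
  p <- runif(L, 0.05, 0.95)
  calls <- matrix(rbinom(n * L, 2, rep(p, each = n)), n, L)
  calls[matrix(runif(n * L) < miss, n, L)] <- NA
  chrom <- as.character(rep_len(seq_len(n_chrom), L))
  pos <- unlist(lapply(split(seq_len(L), chrom), seq_along))
  # regroup positions per chromosome in variant order
  pos <- ave(seq_len(L), chrom, FUN = seq_along) * 1000L
  make_gm(calls, chrom = chrom, pos = pos, population = population)
}

oracle_allele_freq <- function(calls) {
  out <- numeric(ncol(calls))
  for (j in seq_len(ncol(calls))) {
    s <- 0; m <- 0
    for (i in seq_len(nrow(calls))) {
      if (!is.na(calls[i, j])) { s <- s + calls[i, j]; m <- m + 1 }
    }
    out[j] <- s / (2 * m)
  }
  out
}

# direct log-factorial enumeration of the HWE conditional distribution
oracle_hwe <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  nA <- 2 * n0 + n1
  nB <- 2 * n2 + n1
  lp <- function(h) {
    hr <- (nA - h) / 2; ha <- (nB - h) / 2
    lgamma(n + 1) - lgamma(hr + 1) - lgamma(h + 1) - lgamma(ha + 1) +
      h * log(2) - (lgamma(2 * n + 1) - lgamma(nA + 1) - lgamma(nB + 1))
  }
  hs <- seq(min(nA, nB) %% 2, min(nA, nB), by = 2)
  pr <- exp(sapply(hs, lp))
  pr <- pr / sum(pr)
  p_obs <- pr[match(n1, hs)]
  min(1, sum(pr[pr <= p_obs * (1 + 1e-12)]))
}

# haplotype counting for phase-unambiguous tables (no double heterozygotes)
oracle_hap_counting <- function(counts) {
  stopifnot(counts[2, 2] == 0)
  hap <- c(AB = 0, Ab = 0, aB = 0, ab = 0)
  for (g1 in 0:2) for (g2 in 0:2) {
    nn <- counts[g1 + 1, g2 + 1]
    if (nn == 0) next
    # resolve phase: at most one locus heterozygous
    a1 <- c(g1 >= 1, g1 == 2)   # locus-1 alleles on hap 1, 2 (A = TRUE)
    a2 <- c(g2 >= 1, g2 == 2)
    if (g1 == 1) a1 <- c(TRUE, FALSE)
    if (g2 == 1) a2 <- c(TRUE, FALSE)
    for (k in 1:2) {
      nm <- paste0(if (a1[k]) "A" else "a", if (a2[k]) "B" else "b")
      hap[nm] <- hap[nm] + nn
    }
  }
  hap / sum(hap)
}

oracle_roh <- function(dosage, pos, p) {
  L <- length(dosage); W <- p$window_snps
  nW <- L - W + 1L
  pass <- if (nW >= 1) vapply(seq_len(nW), function(w) {
    win <- dosage[w:(w + W - 1)]
    sum(win == 1, na.rm = TRUE) <= p$max_het_per_window &&
      sum(is.na(win)) <= p$max_missing_per_window
  }, TRUE) else logical(0)
  cand <- vapply(seq_len(L), function(k) {
    if (nW < 1) return(FALSE)
    ws <- max(1L, k - W + 1L):min(k, nW)
    ws <- ws[ws >= 1 & ws <= nW]
    length(ws) > 0 && mean(pass[ws]) >= p$window_hit_threshold
  }, TRUE)
  segs <- NULL
  k <- 1L
  while (k <= L) {
    if (!cand[k]) { k <- k + 1L; next }
    j <- k
    while (j + 1L <= L && cand[j + 1L] &&
           (pos[j + 1L] - pos[j]) <= p$max_gap_kb * 1000) j <- j + 1L
    len_kb <- (pos[j] - pos[k] + 1) / 1000
    n_snp <- j - k + 1L
    if (len_kb >= p$min_length_kb && n_snp >= p$min_snps_per_segment &&
        len_kb / n_snp <= p$min_density_kb_per_snp)
      segs <- rbind(segs, data.frame(start_bp = pos[k], end_bp = pos[j],
                                     n_snps = n_snp, length_kb = len_kb))
    k <- j + 1L
  }
  segs
}

oracle_incidence <- function(segments, pos, chrom, ids) {
  out <- numeric(length(pos))
  for (k in seq_along(pos)) {
    cov <- 0
    for (id in ids) {
      s <- segments[segments$sample_id == id &
                    segments$chrom == chrom[k], , drop = FALSE]
      hit <- FALSE
      for (r in seq_len(nrow(s)))
        if (pos[k] >= s$start_bp[r] && pos[k] <= s$end_bp[r]) hit <- TRUE
      cov <- cov + hit
    }
    out[k] <- cov / length(ids)
  }
  out
}

oracle_pi_site <- function(calls_col) {
  alleles <- NULL
  for (d in calls_col[!is.na(calls_col)])
    alleles <- c(alleles, c(d >= 1, d == 2))
  N <- length(alleles)
  if (N < 2) return(NA_real_)
  diff <- 0
  for (i in 1:(N - 1)) for (j in (i + 1):N)
    diff <- diff + (alleles[i] != alleles[j])
  diff / choose(N, 2)
}

# single-locus two-allele WF drift of allele frequencies (no linkage):
# an independent route for frequency-only oracles
drift_freqs <- function(p0, ne, t) {
  p <- p0
  for (g in seq_len(t)) p <- rbinom(length(p), 2 * ne, p) / (2 * ne)
  p
}
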