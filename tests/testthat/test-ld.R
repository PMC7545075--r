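counts_from_pairs <- function(g1, g2) {
  tab <- matrix(0, 3, 3)
  for (i in seq_along(g1)) tab[g1[i] + 1, g2[i] + 1] <-
      tab[g1[i] + 1, g2[i] + 1] + 1
  tab
}

test_that("EM resolves phase-unambiguous tables and the double-het degenerate case", {
  # 50/50 split of AABB and aabb individuals
  tab <- matrix(0, 3, 3); tab[3, 3] <- 25; tab[1, 1] <- 25
  h <- em_haplotype_freqs(tab)
  expect_equal(h$p_AB, 0.5, tolerance = 1e-9)
  expect_equal(h$p_ab, 0.5, tolerance = 1e-9)
  expect_equal(h$p_Ab + h$p_aB, 0, tolerance = 1e-9)
  expect_false(h$degenerate)

  # all double heterozygotes: symmetric likelihood, LE start stays at D=0
  tab2 <- matrix(0, 3, 3); tab2[2, 2] <- 30
  h2 <- em_haplotype_freqs(tab2)
  expect_true(h2$degenerate)
  expect_equal(h2$p_AB * h2$p_ab - h2$p_Ab * h2$p_aB, 0, tolerance = 1e-12)

  expect_error(em_haplotype_freqs(matrix(c(10, 0, 0, 5, 0, 0, 3, 0, 0),
                                         3, 3)) |> r2_from_haplotypes(),
               "monomorphic")
})

test_that("EM equals direct haplotype counting on random phase-unambiguous tables", {
  set.seed(101)
  for (rep in 1:200) {
    # build genotypes from explicit haplotype pairs -> no phase ambiguity
    # unless a double het arises; redraw those individuals' second locus
    n <- sample(10:40, 1)
    hap_p <- as.vector(stats::rmultinom(1, 20, rep(0.25, 4))) / 20
    hcode <- sample.int(4, 2 * n, replace = TRUE, prob = hap_p + 1e-9)
    a <- as.integer(hcode <= 2)            # A allele (haps 1,2 = AB, Ab)
    b <- as.integer(hcode %% 2 == 1)       # B allele (haps 1,3 = AB, aB)
    g1 <- a[seq_len(n)] + a[n + seq_len(n)]
    g2 <- b[seq_len(n)] + b[n + seq_len(n)]
    dh <- g1 == 1 & g2 == 1
    g2[dh] <- 0                            # break double hets
    b[seq_len(n)][dh] <- b[n + seq_len(n)][dh] <- 0L
    tab <- counts_from_pairs(g1, g2)
    if (sum(g1) %in% c(0, 2 * n) || sum(g2) %in% c(0, 2 * n)) next
    h <- em_haplotype_freqs(tab)
    truth <- c(sum(a & b), sum(a & !b), sum(!a & b), sum(!a & !b)) / (2 * n)
    expect_equal(c(h$p_AB, h$p_Ab, h$p_aB, h$p_ab), unname(truth),
                 tolerance = 1e-7)
  }
})

test_that("EM log-likelihood is non-decreasing", {
  set.seed(55)
  for (rep in 1:20) {
    tab <- matrix(stats::rpois(9, 4), 3, 3)
    if (sum(tab) == 0) next
    p1 <- sum(tab * rep(0:2, 3)) / (2 * sum(tab))
    p2 <- sum(tab * rep(0:2, each = 3)) / (2 * sum(tab))
    if (p1 %in% c(0, 1) || p2 %in% c(0, 1)) next
    h <- em_haplotype_freqs(tab, trace = TRUE)
    ll <- h$loglik_trace
    expect_true(all(diff(ll) >= -1e-8))
  }
})

test_that("r2 formula reproduces anchor values and label-swap invariance", {
  expect_equal(r2_from_haplotypes(list(p_AB = 0.5, p_Ab = 0, p_aB = 0,
                                       p_ab = 0.5)), 1)
  expect_equal(r2_from_haplotypes(list(p_AB = 0.35, p_Ab = 0.35,
                                       p_aB = 0.15, p_ab = 0.15)), 0)
  expect_equal(r2_from_haplotypes(list(p_AB = 0.4, p_Ab = 0.1,
                                       p_aB = 0.2, p_ab = 0.3)),
               0.01 / 0.06, tolerance = 1e-12)

  set.seed(77)
  for (rep in 1:50) {
    f <- as.vector(stats::rmultinom(1, 40, c(0.3, 0.25, 0.25, 0.2))) / 40
    if (any(c(f[1] + f[2], f[3] + f[4], f[1] + f[3], f[2] + f[4]) %in%
            c(0, 1))) next
    base <- r2_from_haplotypes(list(p_AB = f[1], p_Ab = f[2], p_aB = f[3],
                                    p_ab = f[4]))
    # swap alleles at locus 1: AB<->aB, Ab<->ab
    sw1 <- r2_from_haplotypes(list(p_AB = f[3], p_Ab = f[4], p_aB = f[1],
                                   p_ab = f[2]))
    # swap alleles at locus 2
    sw2 <- r2_from_haplotypes(list(p_AB = f[2], p_Ab = f[1], p_aB = f[4],
                                   p_ab = f[3]))
    expect_equal(base, sw1, tolerance = 1e-12)
    expect_equal(base, sw2, tolerance = 1e-12)
  }
})

test_that("decay curve: perfectly correlated SNP pair fills one bin with r2 = 1", {
  calls <- cbind(c(0, 0, 1, 1, 2, 2, 0), c(0, 0, 1, 1, 2, 2, 0))
  gm <- make_gm(calls, chrom = c("1", "1"), pos = c(1000, 11000))
  curve <- ld_decay_curve(gm, "pop1", max_dist_bp = 50000, bin_bp = 5000,
                          n_subsample = 7, seed = 1)
  expect_equal(curve$n_pairs[2], 1)           # 10 kb -> bin (5000, 10000]
  expect_equal(curve$mean_r2[2], 1)
  expect_equal(sum(curve$n_pairs), 1)
})

test_that("decay curve is deterministic in the seed and non-increasing in simulation", {
  sim <- wf_simulate(sim_config(n_females = 15, n_males = 15,
                                generations = 40, n_autosomes = 2,
                                snps_per_chrom = 250,
                                chrom_length_bp = 2e7,
                                sex_chrom = "none", seed = 99))
  gm <- apply_qc(sim$genotypes)$genotypes
  c1 <- ld_decay_curve(gm, "pop1", max_dist_bp = 2e6, bin_bp = 2e5,
                       seed = 5)
  c2 <- ld_decay_curve(gm, "pop1", max_dist_bp = 2e6, bin_bp = 2e5,
                       seed = 5)
  c3 <- ld_decay_curve(gm, "pop1", max_dist_bp = 2e6, bin_bp = 2e5,
                       seed = 6)
  expect_identical(c1, c2)
  expect_false(identical(attr(c1, "sample_ids"), attr(c3, "sample_ids")))

  # monotone decay trend: early bins exceed late bins on average
  ok <- !is.na(c1$mean_r2)
  early <- mean(c1$mean_r2[ok][1:3])
  late <- mean(rev(c1$mean_r2[ok])[1:3])
  expect_gt(early, late)
})

test_that("short-distance LD increases as simulated Ne decreases", {
  mean_short_r2 <- sapply(c(10, 40, 150), function(N) {
    sim <- wf_simulate(sim_config(n_females = N / 2, n_males = N / 2,
                                  generations = 30, n_autosomes = 1,
                                  snps_per_chrom = 150,
                                  chrom_length_bp = 5e6,
                                  sex_chrom = "none", seed = 300 + N))
    gm <- apply_qc(sim$genotypes)$genotypes
    cv <- ld_decay_curve(gm, "pop1", max_dist_bp = 5e5, bin_bp = 5e5,
                         n_subsample = 10, seed = 1)
    cv$mean_r2[1]
  })
  expect_true(all(diff(mean_short_r2) < 0))
})
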