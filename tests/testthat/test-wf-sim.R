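test_that("no drift at t = 0 and bitwise determinism given the seed", {
  cfg <- sim_config(n_populations = 2, n_females = 8, n_males = 8,
                    generations = 0, n_autosomes = 1, snps_per_chrom = 200,
                    snps_on_sex_chrom = 100, seed = 1)
  sim <- wf_simulate(cfg)
  expect_equal(sim$truth$per_population$expected_fst, c(0, 0))
  expect_equal(sim$truth$per_population$epsilon, c(0.5, 0.5))
  gm <- sim$genotypes
  pa <- allele_frequency(gm, samples = "pop1")
  pb <- allele_frequency(gm, samples = "pop2")
  # founders of both populations are draws from the same ancestral pool
  expect_lt(mean(abs(pa - pb)), 0.2)
  est <- fst_weir_cockerham(gm, "pop1", "pop2")
  expect_lt(abs(est$fst), 0.05)

  sim2 <- wf_simulate(cfg)
  expect_identical(sim$genotypes$calls, sim2$genotypes$calls)
  sim3 <- wf_simulate(sim_config(n_populations = 2, n_females = 8,
                                 n_males = 8, generations = 0,
                                 n_autosomes = 1, snps_per_chrom = 200,
                                 snps_on_sex_chrom = 100, seed = 2))
  expect_false(identical(sim$genotypes$calls, sim3$genotypes$calls))
})

test_that("zero recombination collapses a chromosome into one haplotype block", {
  mean_r2 <- sapply(c(0, 3), function(rate) {
    sim <- wf_simulate(sim_config(n_females = 8, n_males = 8,
                                  generations = 25, n_autosomes = 1,
                                  snps_per_chrom = 20,
                                  recomb_cm_per_mb = rate,
                                  sex_chrom = "none",
                                  ancestral_freq_range = c(0.5, 0.5),
                                  seed = 31))
    calls <- sim$genotypes$calls
    pr <- cbind(seq_len(ncol(calls) - 1), seq_len(ncol(calls) - 1) + 1L)
    mean(popgenarray:::ld_r2_pairs(calls, pr), na.rm = TRUE)
  })
  # without crossovers every surviving chromosome is an intact founder
  # haplotype: adjacent-pair r2 is maximal
  expect_equal(mean_r2[1], 1, tolerance = 1e-9)
  expect_lt(mean_r2[2], 0.6)
})

test_that("Mendelian consistency: offspring dosages lie in the parental span", {
  sim <- wf_simulate(sim_config(n_females = 6, n_males = 6,
                                generations = 3, n_autosomes = 2,
                                snps_per_chrom = 100, sex_chrom = "none",
                                keep_parents = TRUE, seed = 47))
  kids <- sim$genotypes$calls
  parents <- sim$parent_genotypes[[1]]
  ped <- sim$parents[[1]]
  for (i in seq_len(nrow(kids))) {
    dd <- parents[ped$dam[i], ]
    ss <- parents[ped$sire[i], ]
    lo <- (dd > 0) * 0 + (dd == 2) + (ss == 2)       # min gametes
    hi <- (dd >= 1) + (ss >= 1)                      # max gametes
    expect_true(all(kids[i, ] >= lo & kids[i, ] <= hi),
                label = paste("offspring", i))
  }
})

test_that("allele-frequency drift variance matches p(1-p) t/(2Ne) at small t", {
  # 200 replicate populations, one locus class, small t
  ne <- 20; t <- 4
  p0 <- 0.5
  set.seed(9)
  seeds <- sample.int(1e6, 200)
  pt <- unlist(lapply(seeds, function(s) {
    sim <- wf_simulate(sim_config(n_females = 10, n_males = 10,
                                  generations = t, n_autosomes = 1,
                                  snps_per_chrom = 4,
                                  ancestral_freq_range = c(p0, p0),
                                  sex_chrom = "none", drop_fixed = FALSE,
                                  seed = s))
    unname(allele_frequency(sim$genotypes))
  }))
  v_obs <- stats::var(pt)
  # frequencies of the census are one binomial draw noisier than the
  # breeding-pool expectation; accept the theory value within MC error
  v_theory <- p0 * (1 - p0) * (1 - (1 - 1 / (2 * ne))^t)
  expect_lt(abs(v_obs - v_theory) / v_theory, 0.45)
})

test_that("heterozygosity decays like (1 - 1/(2Ne))^t", {
  ne <- 16
  ts <- c(5, 15, 30)
  hets <- sapply(ts, function(t) {
    mean(sapply(1:3, function(s) {
      sim <- wf_simulate(sim_config(n_females = 8, n_males = 8,
                                    generations = t, n_autosomes = 2,
                                    snps_per_chrom = 400,
                                    sex_chrom = "none",
                                    drop_fixed = FALSE,
                                    seed = 600 + 10 * t + s))
      mean(expected_heterozygosity(sim$genotypes)$per_variant)
    }))
  })
  slope <- stats::coef(stats::lm(log(hets) ~ ts))[2]
  expect_equal(unname(slope), log(1 - 1 / (2 * ne)), tolerance = 0.35)
})

test_that("sex-linked drift outpaces autosomal drift when males are scarce", {
  # ZW with few males: Ne(Z) = 9 Nf Nm / (4 Nf + 2 Nm) << Ne(A)
  ratio <- sapply(1:6, function(s) {
    sim <- wf_simulate(sim_config(n_females = 24, n_males = 3,
                                  generations = 12, n_autosomes = 1,
                                  snps_per_chrom = 500,
                                  snps_on_sex_chrom = 500,
                                  drop_fixed = FALSE, seed = 7100 + s))
    gm <- sim$genotypes
    anc <- sim$truth$ancestral_freqs
    fa <- sex_aware_allele_freq(gm, sex_linked = FALSE)
    fs <- sex_aware_allele_freq(gm, sex_linked = TRUE)
    da <- mean((fa$freq - anc$autosomal)^2 /
                 (anc$autosomal * (1 - anc$autosomal)))
    ds <- mean((fs$freq - anc$sex_linked)^2 /
                 (anc$sex_linked * (1 - anc$sex_linked)))
    ds / da
  })
  ne_a <- 4 * 24 * 3 / 27
  ne_z <- 9 * 24 * 3 / (4 * 24 + 2 * 3)
  expect_gt(ne_a / ne_z, 1.5)       # regime really is Z-accelerated
  expect_gt(median(ratio), 1.2)     # and the simulator shows it
})

test_that("pedigree inbreeding truth ranks mating schemes", {
  f_final <- sapply(c("random", "half_sib", "full_sib"), function(sch) {
    mean(sapply(1:5, function(s) {
      sim <- wf_simulate(sim_config(n_females = 8, n_males = 8,
                                    generations = 10, n_autosomes = 1,
                                    snps_per_chrom = 10,
                                    sex_chrom = "none", mating = sch,
                                    drop_fixed = FALSE, seed = 880 + s))
      tail(sim$truth$mean_pedigree_f[1, ], 1)
    }))
  })
  expect_lt(f_final["random"], f_final["half_sib"])
  expect_lt(f_final["half_sib"], f_final["full_sib"])
})

test_that("fixture suite writes VCFs, truth, and a checksummed manifest", {
  dir <- withr::local_tempdir()
  scenarios <- list(
    tiny_balanced = sim_config(n_females = 5, n_males = 5,
                               generations = 5, n_autosomes = 1,
                               snps_per_chrom = 60,
                               snps_on_sex_chrom = 40, seed = 11),
    tiny_skewed = sim_config(n_females = 8, n_males = 2, generations = 5,
                             n_autosomes = 1, snps_per_chrom = 60,
                             snps_on_sex_chrom = 40, seed = 12))
  man <- write_fixture_suite(dir, scenarios)
  expect_true(all(file.exists(file.path(dir, man$file))))
  expect_equal(sort(unique(man$scenario)),
               c("tiny_balanced", "tiny_skewed"))
  # checksums in the manifest match the files on disk
  md5 <- tools::md5sum(file.path(dir, man$file))
  expect_equal(unname(md5), man$md5)
  # truth values match the config arithmetic
  tr <- read.table(file.path(dir, "tiny_skewed.truth.tsv"), header = TRUE,
                   sep = "\t")
  expect_equal(tr$epsilon, 0.8)
  expect_equal(tr$ne_auto, 4 * 8 * 2 / 10)

  # same seed -> byte-identical outputs
  dir2 <- withr::local_tempdir()
  man2 <- write_fixture_suite(dir2, scenarios)
  expect_equal(man$md5, man2$md5)

  # a genotype matrix read back from the fixture VCF round trips
  gm <- read_vcf(file.path(dir, "tiny_balanced.vcf"),
                 sample_sheet = read.table(
                   file.path(dir, "tiny_balanced.samples.tsv"),
                   header = TRUE, sep = "\t"))
  expect_equal(sort(unique(gm$samples$population)), "pop1")
})
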