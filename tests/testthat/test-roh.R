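test_that("ROH detector finds a long homozygous tract and honors the length floor", {
  # 200 homozygous SNPs spanning ~2 Mb at 10 kb spacing -> one segment
  pos <- seq(10000, by = 10000, length.out = 200)
  gm <- make_gm(rbind(rep(0L, 200)), chrom = rep("1", 200), pos = pos)
  segs <- detect_roh(gm, 1)
  expect_equal(nrow(segs), 1)
  expect_equal(segs$start_bp, pos[1])
  expect_equal(segs$end_bp, pos[200])
  expect_equal(segs$n_snps, 200)
  expect_equal(segs$length_kb, (pos[200] - pos[1] + 1) / 1000)

  # 30 homozygous SNPs spanning 90 kb -> below the 100 kb floor
  pos2 <- seq(3000, by = 3000, length.out = 30)
  gm2 <- make_gm(rbind(rep(2L, 30)), chrom = rep("1", 30), pos = pos2)
  p2 <- roh_params(window_snps = 10)
  expect_equal(nrow(detect_roh(gm2, 1, p2)), 0)
})

test_that("detector equals the brute-force oracle on random instances", {
  set.seed(500)
  pars <- roh_params(window_snps = 20, max_het_per_window = 1,
                     max_missing_per_window = 2, min_length_kb = 50,
                     min_density_kb_per_snp = 20, max_gap_kb = 100,
                     min_snps_per_segment = 10)
  for (rep in 1:60) {
    L <- sample(30:400, 1)
    pos <- sort(sample.int(L * 8000, L))
    # blocks of homozygosity with sprinkled hets and missing
    base <- sample(c(0L, 2L), L, replace = TRUE)
    het_rate <- runif(1, 0.005, 0.2)
    base[runif(L) < het_rate] <- 1L
    base[runif(L) < 0.03] <- NA
    gm <- make_gm(rbind(base), chrom = rep("1", L), pos = pos)
    segs <- detect_roh(gm, 1, pars)
    orc <- oracle_roh(base, pos, pars)
    if (is.null(orc)) {
      expect_equal(nrow(segs), 0, label = paste("rep", rep))
    } else {
      expect_equal(segs[, c("start_bp", "end_bp", "n_snps")],
                   orc[, c("start_bp", "end_bp", "n_snps")],
                   ignore_attr = TRUE, label = paste("rep", rep))
    }
  }
})

test_that("detected segments always satisfy every parameter constraint", {
  set.seed(901)
  pars <- roh_params(window_snps = 15, min_length_kb = 40,
                     min_density_kb_per_snp = 30, max_gap_kb = 200,
                     min_snps_per_segment = 8)
  for (rep in 1:20) {
    L <- 300
    pos <- sort(sample.int(3e6, L))
    base <- sample(c(0L, 0L, 2L, 2L, 1L), L, replace = TRUE)
    gm <- make_gm(rbind(base), chrom = rep("1", L), pos = pos)
    segs <- detect_roh(gm, 1, pars)
    if (nrow(segs) == 0) next
    expect_true(all(segs$length_kb >= pars$min_length_kb))
    expect_true(all(segs$n_snps >= pars$min_snps_per_segment))
    expect_true(all(segs$length_kb / segs$n_snps <=
                    pars$min_density_kb_per_snp))
    segs <- segs[order(segs$start_bp), ]
    if (nrow(segs) > 1)
      expect_true(all(segs$start_bp[-1] > segs$end_bp[-nrow(segs)]))
  }
})

test_that("F_ROH is segment length over autosomal length", {
  segs <- data.frame(sample_id = "s1", chrom = c("1", "2"),
                     start_bp = c(1, 1), end_bp = c(50000000, 45209000),
                     n_snps = c(100, 100),
                     length_kb = c(50000, 45209))
  expect_equal(f_roh(segs), 95209 / 952090)
  expect_equal(f_roh(segs[0, ]), 0)
  # full coverage of a map-derived denominator gives 1
  expect_equal(f_roh(segs, l_auto_kb = sum(segs$length_kb)), 1)
  over <- rbind(segs, data.frame(sample_id = "s1", chrom = "1",
                                 start_bp = 100, end_bp = 200,
                                 n_snps = 5, length_kb = 0.101))
  expect_error(f_roh(over), "overlapping")
  two <- segs; two$sample_id <- c("a", "b")
  expect_error(f_roh(two), "single individual")
})

test_that("per-SNP incidence matches the interval-stabbing oracle", {
  gm <- random_gm(33, n = 10, L = 60, miss = 0)
  segs <- data.frame(
    sample_id = c("s001", "s001", "s002", "s005"),
    chrom = c("1", "2", "1", "1"),
    start_bp = c(2000, 5000, 10000, 1000),
    end_bp = c(9000, 20000, 25000, 30000),
    n_snps = 5, length_kb = 1, stringsAsFactors = FALSE)
  inc <- snp_roh_incidence(segs, gm)
  orc <- oracle_incidence(segs, inc$pos_bp, inc$chrom,
                          gm$samples$sample_id)
  expect_equal(inc$incidence, orc)
  # no segments at all -> all zero
  inc0 <- snp_roh_incidence(segs[0, ], gm)
  expect_true(all(inc0$incidence == 0))
})

test_that("ROH islands select the top-incidence SNPs and merge adjacency", {
  n <- 1000
  chrom <- rep("1", n)
  pos <- seq_len(n) * 1000L
  incidence <- rep(0.1, n)
  incidence[101:110] <- 0.9
  inc <- structure(data.frame(chrom = chrom, pos_bp = pos,
                              id = paste0("v", seq_len(n)),
                              incidence = incidence,
                              stringsAsFactors = FALSE),
                   class = c("roh_incidence", "data.frame"))
  isl <- roh_islands(inc, top_fraction = 0.01)
  expect_equal(nrow(isl), 1)
  expect_equal(isl$start_bp, 101000)
  expect_equal(isl$end_bp, 110000)
  expect_equal(isl$n_snps, 10)
  expect_equal(isl$peak_incidence, 0.9)

  # all equal and positive: tie case, one island per chromosome
  inc2 <- inc; inc2$incidence <- 0.3
  inc2$chrom <- rep(c("1", "2"), each = n / 2)
  inc2$pos_bp <- rep(seq_len(n / 2) * 1000L, 2)
  expect_warning(isl2 <- roh_islands(inc2), "degenerate")
  expect_equal(nrow(isl2), 2)

  inc3 <- inc; inc3$incidence <- 0
  expect_equal(nrow(roh_islands(inc3)), 0)
})

test_that("quantile-then-merge oracle agrees on random incidence fields", {
  set.seed(71)
  for (rep in 1:10) {
    n <- 400
    inc <- structure(data.frame(chrom = rep(c("1", "2"), each = n / 2),
                                pos_bp = rep(seq_len(n / 2) * 500L, 2),
                                id = paste0("v", seq_len(n)),
                                incidence = round(runif(n), 2),
                                stringsAsFactors = FALSE),
                     class = c("roh_incidence", "data.frame"))
    isl <- roh_islands(inc, top_fraction = 0.05)
    thr <- quantile(inc$incidence, 0.95, names = FALSE)
    sel <- inc$incidence >= thr & inc$incidence > 0
    # oracle: walk the rows, opening an island at each selected SNP whose
    # predecessor is unselected or on another chromosome
    n_isl <- 0; covered <- 0
    for (k in seq_len(n)) {
      if (!sel[k]) next
      covered <- covered + 1
      if (k == 1 || !sel[k - 1] || inc$chrom[k] != inc$chrom[k - 1])
        n_isl <- n_isl + 1
    }
    expect_equal(nrow(isl), n_isl)
    expect_equal(sum(isl$n_snps), covered)
  }
})

test_that("inbred mating schemes rank mean F_ROH as random < half_sib < full_sib", {
  mean_froh <- sapply(c("random", "half_sib", "full_sib"), function(scheme) {
    vals <- sapply(1:4, function(s) {
      sim <- wf_simulate(sim_config(
        n_females = 8, n_males = 8, generations = 12, n_autosomes = 1,
        snps_per_chrom = 600, chrom_length_bp = 6e6, sex_chrom = "none",
        mating = scheme, drop_fixed = FALSE, seed = 7000 + s))
      gm <- sim$genotypes
      segs <- detect_roh_all(gm, roh_params(window_snps = 25,
                                            min_snps_per_segment = 15))
      l_auto <- l_auto_from_map(gm)
      mean(vapply(gm$samples$sample_id, function(id)
        f_roh(segs[segs$sample_id == id, , drop = FALSE], l_auto), 0))
    })
    mean(vals)
  })
  expect_lt(mean_froh["random"], mean_froh["half_sib"])
  expect_lt(mean_froh["half_sib"], mean_froh["full_sib"])
})
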