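test_that("GRM matches a direct double-loop oracle and flags duplicates", {
  gm <- random_gm(41, n = 8, L = 40, miss = 0.05)
  g <- compute_grm(gm)
  calls <- gm$calls
  p <- oracle_allele_freq(calls)
  poly <- p > 0 & p < 1
  oracle <- matrix(0, 8, 8)
  for (i in 1:8) for (j in 1:8) {
    num <- den <- 0
    for (k in which(poly)) {
      xi <- calls[i, k]; xj <- calls[j, k]
      if (is.na(xi) || is.na(xj)) next
      num <- num + (xi - 2 * p[k]) * (xj - 2 * p[k]) / (2 * p[k] * (1 - p[k]))
      den <- den + 1
    }
    oracle[i, j] <- num / den
  }
  expect_equal(unclass(unname(g)), oracle, tolerance = 1e-12,
               ignore_attr = TRUE)

  # duplicated individual: off-diagonal close to the diagonal entries
  calls2 <- rbind(calls, calls[1, ])
  gm2 <- make_gm(calls2, chrom = gm$variants$chrom,
                 pos = gm$variants$pos_bp)
  g2 <- compute_grm(gm2)
  expect_equal(g2[1, 9], g2[1, 1], tolerance = 1e-9)
})

test_that("unrelated simulated individuals have near-zero off-diagonals", {
  set.seed(63)
  p <- runif(3000, 0.1, 0.9)
  calls <- matrix(rbinom(12 * 3000, 2, rep(p, each = 12)), 12, 3000)
  g <- compute_grm(make_gm(calls, chrom = rep("1", 3000)))
  off <- g[upper.tri(g)]
  # centering on sample-estimated frequencies makes the expected
  # off-diagonal -1/(n-1), not 0; spread shrinks as 1/sqrt(L)
  expect_equal(mean(off), -1 / 11, tolerance = 0.25)
  expect_lt(max(abs(off - mean(off))), 0.1)
  expect_equal(mean(diag(g)), 1, tolerance = 0.05)
})

test_that("PCA orders components, fixes signs, and separates diverged populations", {
  g <- diag(6)
  class(g) <- c("grm", class(g))
  dimnames(g) <- list(letters[1:6], letters[1:6])
  pca <- pca_from_grm(g, n_components = 6)
  expect_equal(pca$var_prop, rep(1 / 6, 6))

  sim <- wf_simulate(sim_config(n_populations = 2, n_females = 10,
                                n_males = 10, generations = 40,
                                n_autosomes = 2, snps_per_chrom = 400,
                                sex_chrom = "none", seed = 17))
  gm <- apply_qc(sim$genotypes)$genotypes
  pca2 <- pca_from_grm(compute_grm(gm))
  pc1 <- pca2$coords[, 1]
  a <- pc1[gm$samples$population == "pop1"]
  b <- pc1[gm$samples$population == "pop2"]
  gap <- abs(mean(a) - mean(b))
  spread <- max(stats::sd(a), stats::sd(b))
  expect_gt(gap, spread)

  # variance proportions non-increasing and summing to <= 1
  expect_true(all(diff(pca2$var_prop) <= 1e-12))
  expect_lte(sum(pca2$var_prop), 1 + 1e-9)

  # invariance (up to sign already fixed) to sample permutation
  perm <- rev(seq_len(nrow(gm$calls)))
  gmp <- subset_genotypes(gm, samples = perm)
  pca3 <- pca_from_grm(compute_grm(gmp))
  expect_equal(abs(pca3$coords[rownames(pca2$coords), 1]), abs(pc1),
               tolerance = 1e-6)
})

test_that("allele-sharing distance matches the counting oracle and axioms", {
  gm <- random_gm(88, n = 6, L = 30, miss = 0.1)
  d <- allele_sharing_distance(gm)
  calls <- gm$calls
  for (i in 1:5) for (j in (i + 1):6) {
    num <- den <- 0
    for (k in seq_len(ncol(calls))) {
      xi <- calls[i, k]; xj <- calls[j, k]
      if (is.na(xi) || is.na(xj)) next
      num <- num + abs(xi - xj) / 2
      den <- den + 1
    }
    expect_equal(d[i, j], num / den, tolerance = 1e-12)
    expect_equal(d[i, j], d[j, i])
  }
  expect_true(all(diag(d) == 0))

  same <- make_gm(rbind(c(0, 1, 2), c(0, 1, 2)))
  expect_equal(allele_sharing_distance(same)[1, 2], 0)
  opp <- make_gm(rbind(c(0, 0, 0), c(2, 2, 2)))
  expect_equal(allele_sharing_distance(opp)[1, 2], 1)
})

test_that("NJ recovers additive distances exactly and handles 3 taxa", {
  # fixed 4-taxon additive tree: ((a:1,b:2):1.5,(c:3,d:1));
  dm <- rbind(c(0, 3, 5.5, 3.5),
              c(3, 0, 6.5, 4.5),
              c(5.5, 6.5, 0, 4),
              c(3.5, 4.5, 4, 0))
  dimnames(dm) <- list(letters[1:4], letters[1:4])
  tree <- nj_tree(dm)
  expect_equal(sort(tree$tip.label), letters[1:4])
  # recovered tree reproduces the input distances exactly
  expect_equal(as.matrix(stats::cophenetic(tree))[letters[1:4], letters[1:4]],
               dm, tolerance = 1e-9)

  d3 <- rbind(c(0, 2, 3), c(2, 0, 4.2), c(3, 4.2, 0))
  dimnames(d3) <- list(c("x", "y", "z"), c("x", "y", "z"))
  t3 <- nj_tree(d3)
  # unique star: branch lengths solve the three pairwise equations
  expect_equal(as.matrix(stats::cophenetic(t3))[c("x", "y", "z"),
                                                c("x", "y", "z")],
               d3, tolerance = 1e-9)

  bad <- dm; bad[1, 2] <- 99
  expect_error(nj_tree(bad), "symmetric")
  expect_error(nj_tree(dm[1:2, 1:2]), ">= 3")
})

test_that("NJ recovers random additive trees (topology and lengths)", {
  set.seed(12)
  for (rep in 1:30) {
    n_tip <- sample(4:12, 1)
    ref <- ape::rtree(n_tip, rooted = FALSE,
                      br = function(n) runif(n, 0.1, 2))
    dm <- as.matrix(stats::cophenetic(ref))
    tree <- nj_tree(dm)
    expect_equal(ape::dist.topo(ape::unroot(ref), ape::unroot(tree)), 0,
                 ignore_attr = TRUE)
    expect_equal(as.matrix(stats::cophenetic(tree))[rownames(dm), colnames(dm)],
                 dm, tolerance = 1e-8)
  }
})

test_that("population-level distances feed a labelled NJ tree", {
  sim <- wf_simulate(sim_config(n_populations = 4, n_females = 6,
                                n_males = 6, generations = 15,
                                n_autosomes = 2, snps_per_chrom = 150,
                                sex_chrom = "none", seed = 23))
  pd <- allele_sharing_distance(sim$genotypes, by_population = TRUE)
  expect_equal(dim(pd), c(4, 4))
  tree <- nj_tree(pd)
  expect_setequal(tree$tip.label, paste0("pop", 1:4))
  expect_match(attr(tree, "newick"), "^\\(.*;$")
})
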