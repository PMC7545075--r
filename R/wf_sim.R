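#' Configuration for the two-sex Wright-Fisher simulator
#'
#' Discrete non-overlapping generations; each population keeps a constant
#' census of `n_females` breeding females and `n_males` breeding males and
#' descends independently from a shared ancestral gene pool in linkage
#' equilibrium with allele frequencies drawn from
#' `Uniform(ancestral_freq_range)`. Autosomal gametes recombine with
#' Poisson crossover counts on a linear genetic map; the sex chromosome
#' follows ZW transmission by default (male homogametic, as in birds) or
#' XY under the flag. Mating schemes: `random` draws a dam and sire
#' uniformly per offspring; `half_sib` uses a single sire per generation;
#' `full_sib` a single sire and single dam.
#'
#' @param n_populations number of populations.
#' @param n_females,n_males breeders per sex (scalar or per-population
#'   vector).
#' @param generations generations since the common ancestor.
#' @param n_autosomes,snps_per_chrom,chrom_length_bp autosomal map.
#' @param recomb_cm_per_mb linear recombination rate (3 cM/Mb default,
#'   macrochromosome-like).
#' @param sex_chrom `"Z"` to include one sex chromosome, `"none"` to omit.
#' @param snps_on_sex_chrom,sex_chrom_length_bp sex-chromosome map.
#' @param heterogamety `"ZW"` (default) or `"XY"`.
#' @param ancestral_freq_range range of the uniform ancestral frequency
#'   distribution (default `c(0.05, 0.95)`).
#' @param mating `"random"`, `"half_sib"`, or `"full_sib"`.
#' @param mutation_rate per-site per-gamete flip probability (default 0
#'   so drift-only truth stays exact).
#' @param drop_fixed drop sites fixed in the final combined sample
#'   (array-like polymorphism ascertainment; default TRUE).
#' @param keep_parents also return the penultimate generation's genotypes
#'   and the parent indices of the final one (for Mendelian checks).
#' @param pop_names population labels (default "pop1", "pop2", ...).
#' @param seed mandatory integer seed.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_populations = 1, n_females = 50, n_males = 50,
                       generations = 50, n_autosomes = 5,
                       snps_per_chrom = 1000, chrom_length_bp = 5e7,
                       recomb_cm_per_mb = 3, sex_chrom = c("Z", "none"),
                       snps_on_sex_chrom = 1000,
                       sex_chrom_length_bp = 8e7,
                       heterogamety = c("ZW", "XY"),
                       ancestral_freq_range = c(0.05, 0.95),
                       mating = c("random", "half_sib", "full_sib"),
                       mutation_rate = 0, drop_fixed = TRUE,
                       keep_parents = FALSE, pop_names = NULL, seed) {
  sex_chrom <- match.arg(sex_chrom)
  heterogamety <- match.arg(heterogamety)
  mating <- match.arg(mating)
  if (missing(seed)) stop("seed is mandatory")
  n_females <- rep_len(n_females, n_populations)
  n_males <- rep_len(n_males, n_populations)
  stopifnot(all(n_females >= 1), all(n_males >= 1), generations >= 0,
            n_autosomes >= 1, snps_per_chrom >= 1, chrom_length_bp >= 1,
            recomb_cm_per_mb >= 0, mutation_rate >= 0)
  if (is.null(pop_names)) pop_names <- paste0("pop", seq_len(n_populations))
  structure(list(n_populations = n_populations, n_females = n_females,
                 n_males = n_males, generations = generations,
                 n_autosomes = n_autosomes,
                 snps_per_chrom = snps_per_chrom,
                 chrom_length_bp = chrom_length_bp,
                 recomb_cm_per_mb = recomb_cm_per_mb,
                 sex_chrom = sex_chrom,
                 snps_on_sex_chrom = snps_on_sex_chrom,
                 sex_chrom_length_bp = sex_chrom_length_bp,
                 heterogamety = heterogamety,
                 ancestral_freq_range = ancestral_freq_range,
                 mating = mating, mutation_rate = mutation_rate,
                 drop_fixed = drop_fixed, keep_parents = keep_parents,
                 pop_names = pop_names, seed = as.integer(seed)),
            class = "sim_config")
}

#' Pure-drift FST expectation
#'
#' Expected fixation index after `t` generations of drift at effective
#' size `ne`: 1 - (1 - 1/(2 ne))^t.
#'
#' @param ne effective population size (> 0).
#' @param t generations (>= 0).
#' @export
expected_fst <- function(ne, t) {
  stopifnot(all(ne > 0), all(t >= 0))
  1 - (1 - 1 / (2 * ne))^t
}

# one recombinant gamete from haplotype rows i1, i2 of H
wf_gamete <- function(H, i1, i2, pos_m, len_m) {
  k <- stats::rpois(1, len_m)
  start <- stats::runif(1) < 0.5
  if (k == 0L) return(if (start) H[i2, ] else H[i1, ])
  br <- sort(stats::runif(k, 0, len_m))
  ph <- (findInterval(pos_m, br) + start) %% 2
  h <- H[i1, ]
  sel <- ph == 1
  h[sel] <- H[i2, sel]
  h
}

wf_mutate <- function(h, mu) {
  if (mu <= 0) return(h)
  k <- stats::rbinom(1, length(h), mu)
  if (k > 0) {
    i <- sample.int(length(h), k)
    h[i] <- 1L - h[i]
  }
  h
}

#' Run the two-sex Wright-Fisher forward simulation
#'
#' Simulates every population of a [sim_config()] forward from the shared
#' ancestor and emits the final generation as a [genotype_matrix()] with
#' sexes, population labels, and a fully populated ground-truth record
#' (see Details). Hemizygous sex-chromosome genotypes are encoded as
#' homozygous 0/2 dosages. Bitwise reproducible given the seed.
#'
#' Ground truth per population: breeder counts, true epsilon
#' N_f/(N_f+N_m), autosomal Ne = 4 N_f N_m/(N_f+N_m), sex-chromosome Ne
#' (9 N_f N_m/(4 N_f + 2 N_m) under ZW, sexes swapped under XY), drift
#' branch lengths tau = t/(2 Ne) per marker class, the pure-drift FST
#' expectation versus the ancestor, and the mean pedigree inbreeding
#' coefficient per generation (from the kinship recursion). Global truth:
#' the ancestral allele frequencies of the emitted (post-ascertainment)
#' variants.
#'
#' @param config a [sim_config()].
#' @return list of class `wf_sim`: `genotypes` (a `genotype_matrix`),
#'   `truth` (list, see Details), and when `keep_parents` is set,
#'   `parents` (dam/sire indices) plus `parent_genotypes`.
#' @export
wf_simulate <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cf <- config
  with_seed(cf$seed, {
    rate_m_per_bp <- cf$recomb_cm_per_mb * 1e-8
    has_sex <- cf$sex_chrom != "none"
    chrom_names <- c(as.character(seq_len(cf$n_autosomes)),
                     if (has_sex) "Z")
    n_chrom_tot <- length(chrom_names)
    pos <- vector("list", n_chrom_tot)
    for (a in seq_len(cf$n_autosomes))
      pos[[a]] <- sort(sample.int(cf$chrom_length_bp, cf$snps_per_chrom))
    if (has_sex)
      pos[[n_chrom_tot]] <- sort(sample.int(cf$sex_chrom_length_bp,
                                            cf$snps_on_sex_chrom))
    pos_m <- lapply(seq_len(n_chrom_tot), function(ci)
      pos[[ci]] * rate_m_per_bp)
    len_m <- vapply(seq_len(n_chrom_tot), function(ci)
      (if (ci <= cf$n_autosomes) cf$chrom_length_bp else
         cf$sex_chrom_length_bp) * rate_m_per_bp, 0)
    anc <- lapply(pos, function(p)
      stats::runif(length(p), cf$ancestral_freq_range[1],
                   cf$ancestral_freq_range[2]))

    # homogametic sex carries two copies of the sex chromosome
    homog_sex <- if (cf$heterogamety == "ZW") "male" else "female"

    sim_one_pop <- function(pop_i) {
      Nf <- cf$n_females[pop_i]; Nm <- cf$n_males[pop_i]
      N <- Nf + Nm
      sexes <- rep(c("female", "male"), c(Nf, Nm))
      H <- lapply(seq_len(n_chrom_tot), function(ci) {
        L <- length(pos[[ci]])
        matrix(stats::rbinom(2 * N * L, 1L, rep(anc[[ci]], each = 2 * N)),
               2 * N, L)
      })
      K <- diag(0.5, N)                  # kinship among current generation
      mean_F <- numeric(cf$generations)
      dams <- sires <- NULL
      females <- which(sexes == "female"); males <- which(sexes == "male")

      for (g in seq_len(cf$generations)) {
        dams <- switch(cf$mating,
          random = females[sample.int(Nf, N, replace = TRUE)],
          half_sib = females[sample.int(Nf, N, replace = TRUE)],
          full_sib = rep(females[sample.int(Nf, 1)], N))
        sires <- switch(cf$mating,
          random = males[sample.int(Nm, N, replace = TRUE)],
          half_sib = rep(males[sample.int(Nm, 1)], N),
          full_sib = rep(males[sample.int(Nm, 1)], N))
        if (cf$keep_parents && g == cf$generations) H_prev <- H

        newH <- vector("list", n_chrom_tot)
        for (ci in seq_len(n_chrom_tot)) {
          L <- length(pos[[ci]])
          M <- matrix(0L, 2 * N, L)
          if (ci <= cf$n_autosomes) {
            for (i in seq_len(N)) {
              d <- dams[i]; s <- sires[i]
              M[2 * i - 1, ] <- wf_mutate(
                wf_gamete(H[[ci]], 2 * d - 1, 2 * d, pos_m[[ci]],
                          len_m[ci]), cf$mutation_rate)
              M[2 * i, ] <- wf_mutate(
                wf_gamete(H[[ci]], 2 * s - 1, 2 * s, pos_m[[ci]],
                          len_m[ci]), cf$mutation_rate)
            }
          } else {
            for (i in seq_len(N)) {
              d <- dams[i]; s <- sires[i]
              homog_parent <- if (homog_sex == "male") s else d
              heterog_parent <- if (homog_sex == "male") d else s
              rec <- wf_mutate(
                wf_gamete(H[[ci]], 2 * homog_parent - 1, 2 * homog_parent,
                          pos_m[[ci]], len_m[ci]), cf$mutation_rate)
              if (sexes[i] == homog_sex) {
                M[2 * i - 1, ] <- rec
                M[2 * i, ] <- wf_mutate(H[[ci]][2 * heterog_parent - 1, ],
                                        cf$mutation_rate)
              } else {
                M[2 * i - 1, ] <- rec
                M[2 * i, ] <- rec       # hemizygous: single copy duplicated
              }
            }
          }
          newH[[ci]] <- M
        }
        H <- newH
        F_off <- K[cbind(dams, sires)]
        mean_F[g] <- mean(F_off)
        Knew <- 0.25 * (K[dams, dams] + K[dams, sires] +
                        K[sires, dams] + K[sires, sires])
        diag(Knew) <- 0.5 * (1 + F_off)
        K <- Knew
      }
      out <- list(H = H, sexes = sexes, mean_F = mean_F)
      if (cf$keep_parents) {
        out$dams <- dams; out$sires <- sires
        out$H_prev <- if (cf$generations > 0) H_prev else H
      }
      out
    }

    pops <- lapply(seq_len(cf$n_populations), sim_one_pop)

    dosage_of <- function(H) {
      do.call(cbind, lapply(H, function(M) {
        n <- nrow(M) / 2
        M[2 * seq_len(n) - 1, , drop = FALSE] +
          M[2 * seq_len(n), , drop = FALSE]
      }))
    }
    calls <- do.call(rbind, lapply(pops, function(p) dosage_of(p$H)))
    variants <- data.frame(
      chrom = rep(chrom_names, lengths(pos)),
      pos_bp = unlist(pos),
      ancestral_freq = unlist(anc),   # travels with any later subsetting
      stringsAsFactors = FALSE)
    samples <- data.frame(
      sample_id = unlist(lapply(seq_len(cf$n_populations), function(i)
        sprintf("%s_i%03d", cf$pop_names[i],
                seq_len(cf$n_females[i] + cf$n_males[i])))),
      population = rep(cf$pop_names, cf$n_females + cf$n_males),
      sex = unlist(lapply(pops, `[[`, "sexes")),
      stringsAsFactors = FALSE)

    keep <- rep(TRUE, ncol(calls))
    if (cf$drop_fixed) {
      cs <- colSums(calls)
      keep <- cs > 0 & cs < 2 * nrow(calls)
      if (!any(keep))
        stop("every site fixed in the final sample; ",
             "reduce drift (larger sizes / fewer generations) or set ",
             "drop_fixed = FALSE")
    }
    gm <- genotype_matrix(calls[, keep, drop = FALSE],
                          variants[keep, , drop = FALSE], samples,
                          sex_chroms = "Z")
    # genotype_matrix resorts variants; the ancestral_freq column
    # travels with them
    ord <- order(variants$chrom[keep], variants$pos_bp[keep])
    v_sorted <- gm$variants
    anc_all <- v_sorted$ancestral_freq

    ne_auto <- 4 * cf$n_females * cf$n_males / (cf$n_females + cf$n_males)
    ne_sex <- if (cf$heterogamety == "ZW")
      9 * cf$n_females * cf$n_males / (4 * cf$n_females + 2 * cf$n_males)
    else
      9 * cf$n_females * cf$n_males / (4 * cf$n_males + 2 * cf$n_females)
    truth <- list(
      per_population = data.frame(
        population = cf$pop_names, n_females = cf$n_females,
        n_males = cf$n_males,
        epsilon = cf$n_females / (cf$n_females + cf$n_males),
        ne_auto = ne_auto, ne_sex = ne_sex,
        generations = cf$generations,
        tau_auto = cf$generations / (2 * ne_auto),
        tau_sex = cf$generations / (2 * ne_sex),
        expected_fst = expected_fst(ne_auto, cf$generations),
        stringsAsFactors = FALSE),
      mean_pedigree_f = do.call(rbind, lapply(pops, `[[`, "mean_F")),
      ancestral_freqs = list(
        autosomal = anc_all[!v_sorted$is_sex_linked],
        sex_linked = anc_all[v_sorted$is_sex_linked]),
      heterogamety = cf$heterogamety, mating = cf$mating,
      seed = cf$seed)

    out <- list(genotypes = gm, truth = truth, config = cf)
    if (cf$keep_parents) {
      out$parents <- lapply(pops, function(p)
        data.frame(dam = p$dams, sire = p$sires))
      out$parent_genotypes <- lapply(pops, function(p)
        dosage_of(p$H_prev)[, keep, drop = FALSE][, ord, drop = FALSE])
    }
    class(out) <- "wf_sim"
    out
  })
}

#' @export
print.wf_sim <- function(x, ...) {
  cat("two-sex Wright-Fisher simulation (", x$truth$heterogamety, ", ",
      x$truth$mating, " mating, t = ", x$config$generations, ")\n",
      sep = "")
  print(x$truth$per_population, row.names = FALSE)
  print(x$genotypes)
  invisible(x)
}

#' Write the standard simulated test scenarios to disk
#'
#' Emits a reduced-scale scenario suite (balanced and skewed sex ratios,
#' three drift intensities, three mating schemes, and a 15-population
#' star) as plain-text VCFs with sample-sheet and truth TSVs, plus a
#' manifest listing every file with its MD5 checksum and seed. Scenario
#' sizes are desk-scale so the suite writes in seconds.
#'
#' @param output_dir writable directory (created if absent).
#' @param scenarios named list of [sim_config()] objects; `NULL` selects
#'   the standard set derived from `seed`.
#' @param seed integer seed used to derive per-scenario seeds.
#' @return data.frame manifest (file, md5, scenario, seed), also written
#'   to `manifest.tsv`.
#' @export
write_fixture_suite <- function(output_dir, scenarios = NULL, seed = 1) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(scenarios)) {
    sc <- function(label, ...) sim_config(..., seed = derive_seed(seed, label))
    scenarios <- list(
      balanced = sc("balanced", n_females = 25, n_males = 25,
                    generations = 20, n_autosomes = 2,
                    snps_per_chrom = 300, snps_on_sex_chrom = 300),
      skewed = sc("skewed", n_females = 40, n_males = 10,
                  generations = 20, n_autosomes = 2, snps_per_chrom = 300,
                  snps_on_sex_chrom = 300),
      ne_small = sc("ne_small", n_females = 10, n_males = 10,
                    generations = 20, n_autosomes = 2,
                    snps_per_chrom = 300, sex_chrom = "none"),
      ne_medium = sc("ne_medium", n_females = 25, n_males = 25,
                     generations = 20, n_autosomes = 2,
                     snps_per_chrom = 300, sex_chrom = "none"),
      ne_large = sc("ne_large", n_females = 50, n_males = 50,
                    generations = 20, n_autosomes = 2,
                    snps_per_chrom = 300, sex_chrom = "none"),
      mating_random = sc("mating_random", n_females = 10, n_males = 10,
                         generations = 10, n_autosomes = 1,
                         snps_per_chrom = 300, sex_chrom = "none"),
      mating_half_sib = sc("mating_half_sib", n_females = 10,
                           n_males = 10, generations = 10,
                           n_autosomes = 1, snps_per_chrom = 300,
                           sex_chrom = "none", mating = "half_sib"),
      mating_full_sib = sc("mating_full_sib", n_females = 10,
                           n_males = 10, generations = 10,
                           n_autosomes = 1, snps_per_chrom = 300,
                           sex_chrom = "none", mating = "full_sib"),
      star15 = sc("star15", n_populations = 15, n_females = 5,
                  n_males = 5, generations = 15, n_autosomes = 2,
                  snps_per_chrom = 200, snps_on_sex_chrom = 200))
  }
  manifest <- NULL
  for (nm in names(scenarios)) {
    sim <- wf_simulate(scenarios[[nm]])
    files <- file.path(output_dir, paste0(nm, c(".vcf", ".samples.tsv",
                                                ".truth.tsv")))
    write_vcf(sim$genotypes, files[1])
    write_sample_sheet(sim$genotypes, files[2])
    utils::write.table(sim$truth$per_population, files[3], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    md5 <- tools::md5sum(files)
    manifest <- rbind(manifest, data.frame(
      file = basename(files), md5 = unname(md5), scenario = nm,
      seed = scenarios[[nm]]$seed, stringsAsFactors = FALSE))
  }
  utils::write.table(manifest, file.path(output_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest
}
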