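#' Effective-sex-ratio estimation configuration
#'
#' Pseudo-replication and MCMC schedule for the ESR estimator: each
#' replicate draws `n_autosomal_snps` autosomal and `n_sex_snps`
#' sex-linked SNPs at random (with replacement when fewer are available)
#' and produces one tau pair and one epsilon.
#'
#' @param n_replicates number of pseudo-replicated datasets (default 50).
#' @param n_autosomal_snps,n_sex_snps SNPs drawn per replicate (5000 each).
#' @param pilot_runs,pilot_iters MCMC step-size adaptation schedule
#'   (20 runs of 500 iterations).
#' @param iters,thin,burn_in main MCMC schedule (20000 iterations, thin
#'   20, burn-in 10000).
#' @param seed integer seed.
#' @return object of class `esr_config`.
#' @export
esr_config <- function(n_replicates = 50, n_autosomal_snps = 5000,
                       n_sex_snps = 5000, pilot_runs = 20,
                       pilot_iters = 500, iters = 20000, thin = 20,
                       burn_in = 10000, seed = 1) {
  stopifnot(n_replicates >= 1, n_autosomal_snps >= 1, n_sex_snps >= 1,
            pilot_runs >= 1, pilot_iters >= 1, iters > burn_in,
            thin >= 1, burn_in >= 0)
  structure(list(n_replicates = n_replicates,
                 n_autosomal_snps = n_autosomal_snps,
                 n_sex_snps = n_sex_snps,
                 mcmc = list(pilot_runs = pilot_runs,
                             pilot_iters = pilot_iters, iters = iters,
                             thin = thin, burn_in = burn_in),
                 seed = seed), class = "esr_config")
}

#' Moment estimator of the drift branch length tau
#'
#' For each SNP with current sample frequency p-hat (from m chromosomes)
#' and ancestral/reference frequency pi, the drift fraction
#' F = 1 - (1 - 1/(2Ne))^t satisfies
#' E\[(p-hat - pi)^2 - p-hat (1 - p-hat)/(m - 1)\] = pi (1 - pi) F, so F
#' is estimated by averaging that ratio over SNPs and tau = t/(2 Ne) by
#' -log(1 - F-hat) (exact under pure drift up to O(1/Ne)). SNPs with pi
#' fixed (0 or 1) are excluded. When `pi` is the pooled mean of K
#' population frequencies rather than a known outgroup/ancestral value,
#' pass `n_pops_pooled = K` to apply the K/(K-1) bias correction for
#' estimating pi from the populations themselves.
#'
#' @param pop_freqs per-SNP sample allele frequencies of the population.
#' @param ancestral_freqs per-SNP ancestral/reference frequencies pi.
#' @param n_chrom chromosomes sampled per SNP (scalar or vector): 2n for
#'   autosomes; 2 n_homogametic + n_heterogametic for sex-linked markers.
#' @param n_pops_pooled number of populations pooled to form pi (default
#'   1 = pi known externally, no correction).
#' @return list of class `tau_estimate`: `tau`, `se` (delta-method moment
#'   SE), `drift_fraction`, `n_snps_used`, `method = "moments"`.
#' @export
estimate_tau_moments <- function(pop_freqs, ancestral_freqs, n_chrom,
                                 n_pops_pooled = 1) {
  stopifnot(length(pop_freqs) == length(ancestral_freqs))
  m <- rep_len(n_chrom, length(pop_freqs))
  use <- is.finite(pop_freqs) & is.finite(ancestral_freqs) &
    ancestral_freqs > 0 & ancestral_freqs < 1 & m >= 2
  if (sum(use) == 0) stop("no usable SNPs for tau estimation")
  if (sum(use) < 100)
    warning("fewer than 100 usable SNPs: tau estimate will be noisy")
  p <- pop_freqs[use]; pi0 <- ancestral_freqs[use]; m <- m[use]
  num <- (p - pi0)^2 - p * (1 - p) / (m - 1)
  ratio <- num / (pi0 * (1 - pi0))
  if (n_pops_pooled > 1) ratio <- ratio * n_pops_pooled / (n_pops_pooled - 1)
  f_hat <- mean(ratio)
  se_f <- stats::sd(ratio) / sqrt(length(ratio))
  if (f_hat >= 1)
    warning("estimated drift fraction >= 1: tau is off-scale ",
            "(check that ancestral frequencies match these SNPs)")
  f_hat <- min(max(f_hat, 0), 1 - 1e-12)
  tau <- -log(1 - f_hat)
  structure(list(tau = tau, se = se_f / (1 - f_hat),
                 drift_fraction = f_hat, n_snps_used = length(ratio),
                 method = "moments"), class = "tau_estimate")
}

#' @export
print.tau_estimate <- function(x, ...) {
  cat(sprintf("tau = %.4f (se %.4f, %d SNPs, %s)\n", x$tau, x$se,
              x$n_snps_used, x$method))
  invisible(x)
}

# log density of truncated Normal(mu, sd) on (0,1), vectorized
ltnorm <- function(x, mu, sd) {
  stats::dnorm(x, mu, sd, log = TRUE) -
    log(pmax(stats::pnorm(1, mu, sd) - stats::pnorm(0, mu, sd), 1e-300))
}

#' Bayesian (MCMC) estimator of the drift branch length tau
#'
#' Hierarchical star-tree model with a truncated-normal approximation to
#' time-dependent drift: for population k and SNP l,
#' p_kl ~ TruncNormal(pi_l, tau_k pi_l (1 - pi_l)) on (0, 1), the observed
#' alternate-allele count x_kl ~ Binomial(m_kl, p_kl), pi_l ~ Uniform(0,1)
#' (shared across populations), and log tau_k ~ Uniform. Random-walk
#' Metropolis with per-block step sizes adapted during pilot runs to an
#' acceptance rate in (0.25, 0.45); a population whose pilot acceptance
#' never enters that window is flagged. SNP-level updates are vectorized,
#' so chains are cheap even for thousands of SNPs.
#'
#' @param counts matrix (K populations x L SNPs) of alternate-allele
#'   counts.
#' @param n_chrom matrix (K x L) or vector of chromosomes sampled.
#' @param config an [esr_config()] (MCMC schedule + seed).
#' @param ancestral_freqs optional known pi vector; when supplied pi is
#'   held fixed (useful with K = 1).
#' @return list of class `tau_mcmc`: `tau` (posterior means, length K),
#'   `sd` (posterior sds), `samples` (draws x K), `accept` rates,
#'   `converged` flags, `method = "mcmc"`.
#' @export
estimate_tau_mcmc <- function(counts, n_chrom, config = esr_config(),
                              ancestral_freqs = NULL) {
  counts <- rbind(counts)
  K <- nrow(counts); L <- ncol(counts)
  if (is.null(ancestral_freqs) && K < 2)
    stop("need >= 2 populations to estimate pi jointly; supply ancestral_freqs for K = 1")
  m <- if (is.matrix(n_chrom)) n_chrom else
    matrix(rep_len(n_chrom, L), K, L, byrow = TRUE)
  fixed_pi <- !is.null(ancestral_freqs)
  sched <- config$mcmc

  with_seed(derive_seed(config$seed, "tau_mcmc"), {
    pi0 <- if (fixed_pi) pmin(pmax(ancestral_freqs, 1e-4), 1 - 1e-4) else
      pmin(pmax(colSums(counts) / colSums(m), 1e-4), 1 - 1e-4)
    p <- pmin(pmax(counts / m, 1e-4), 1 - 1e-4)
    ltau <- rep(log(0.05), K)

    lp_p <- function(p, pi0, ltau) {       # K x L matrix of log posterior terms in p
      sd <- sqrt(pmax(exp(ltau) %o% (pi0 * (1 - pi0)), 1e-12))
      ltnorm(p, matrix(pi0, K, L, byrow = TRUE), sd) +
        counts * log(p) + (m - counts) * log(1 - p)
    }
    step_p <- matrix(0.05, K, 1); step_pi <- 0.05; step_tau <- rep(0.5, K)

    run_block <- function(n_iter, adapt) {
      acc_p <- numeric(K); acc_pi <- 0; acc_tau <- numeric(K)
      for (it in seq_len(n_iter)) {
        # p updates (reflected random walk), vectorized over K x L
        prop <- p + matrix(stats::rnorm(K * L), K, L) *
          matrix(step_p, K, L)
        prop <- abs(prop); prop <- 1 - abs(1 - prop)   # reflect into (0,1)
        prop <- pmin(pmax(prop, 1e-6), 1 - 1e-6)
        cur_lp <- lp_p(p, pi0, ltau)
        new_lp <- lp_p(prop, pi0, ltau)
        acc <- log(matrix(stats::runif(K * L), K, L)) < new_lp - cur_lp
        p[acc] <<- prop[acc]
        acc_p <- acc_p + rowMeans(acc)
        # pi updates, vectorized over L
        if (!fixed_pi) {
          prop_pi <- pi0 + stats::rnorm(L) * step_pi
          prop_pi <- abs(prop_pi); prop_pi <- 1 - abs(1 - prop_pi)
          prop_pi <- pmin(pmax(prop_pi, 1e-6), 1 - 1e-6)
          cur <- colSums(lp_p(p, pi0, ltau))
          new <- colSums(lp_p(p, prop_pi, ltau))
          accpi <- log(stats::runif(L)) < new - cur
          pi0[accpi] <<- prop_pi[accpi]
          acc_pi <- acc_pi + mean(accpi)
        }
        # tau updates (one scalar per population; log-uniform prior is
        # flat in log tau)
        prop_lt <- ltau + stats::rnorm(K) * step_tau
        cur <- rowSums(lp_p(p, pi0, ltau))
        new <- rowSums(lp_p(p, pi0, prop_lt))
        acctau <- log(stats::runif(K)) < new - cur
        ltau[acctau] <<- prop_lt[acctau]
        acc_tau <- acc_tau + acctau
        if (adapt && it %% 50 == 0) {
          tune <- function(step, rate) {
            step * ifelse(rate > 0.45, 1.3, ifelse(rate < 0.25, 1 / 1.3, 1))
          }
          step_p <<- tune(step_p, acc_p / it)
          step_pi <<- tune(step_pi, acc_pi / it)
          step_tau <<- tune(step_tau, acc_tau / it)
        }
      }
      list(acc_p = acc_p / n_iter, acc_pi = acc_pi / n_iter,
           acc_tau = acc_tau / n_iter)
    }

    pilot_acc <- rep(FALSE, K)
    for (r in seq_len(sched$pilot_runs)) {
      a <- run_block(sched$pilot_iters, adapt = TRUE)
      pilot_acc <- pilot_acc | (a$acc_tau > 0.25 & a$acc_tau < 0.45)
    }
    draws <- matrix(NA_real_, 0, K)
    acc_main <- run_block(sched$burn_in, adapt = FALSE)
    n_keep <- (sched$iters - sched$burn_in) %/% sched$thin
    samples <- matrix(NA_real_, n_keep, K)
    for (s in seq_len(n_keep)) {
      run_block(sched$thin, adapt = FALSE)
      samples[s, ] <- exp(ltau)
    }
    structure(list(tau = colMeans(samples),
                   sd = apply(samples, 2, stats::sd), samples = samples,
                   accept = acc_main$acc_tau, converged = pilot_acc,
                   method = "mcmc"), class = "tau_mcmc")
  })
}

#' @export
print.tau_mcmc <- function(x, ...) {
  cat("posterior tau (mean ± sd):\n")
  for (k in seq_along(x$tau))
    cat(sprintf("  pop %d: %.4f ± %.4f%s\n", k, x$tau[k], x$sd[k],
                if (!x$converged[k]) "  [pilot acceptance never in (0.25,0.45)]"
                else ""))
  invisible(x)
}

#' Effective sex ratio from tau estimates
#'
#' epsilon = 2 - (9/8) * tau_sex / tau_auto. Under XY heterogamety (the
#' algebra the formula is written for) this is the proportion of females
#' in the effective population; under ZW data the identical algebra
#' yields the proportion of males — the `heterogamety` argument only
#' controls the interpretation label attached to the result. Estimator
#' noise can push values outside \[0, 1\]; they are returned as computed
#' with an `out_of_range` flag.
#'
#' @param tau_sex,tau_auto drift branch lengths of the sex-linked and
#'   autosomal marker classes (`tau_auto > 0`).
#' @param heterogamety "XY" or "ZW" (label only).
#' @return numeric epsilon with attributes `out_of_range` and `label`.
#' @export
esr_from_tau <- function(tau_sex, tau_auto, heterogamety = c("XY", "ZW")) {
  heterogamety <- match.arg(heterogamety)
  if (any(tau_auto <= 0)) stop("tau_auto must be positive")
  eps <- 2 - (9 / 8) * tau_sex / tau_auto
  attr(eps, "out_of_range") <- eps < 0 | eps > 1
  attr(eps, "label") <- if (heterogamety == "XY")
    "proportion of females" else "proportion of males"
  eps
}

#' Pseudo-replicated effective-sex-ratio estimate
#'
#' For each of `config$n_replicates` replicates: draw a seeded random set
#' of autosomal and sex-linked SNPs (with replacement when fewer are
#' available than requested, with a message), estimate tau for each
#' marker class by the moment estimator (sex-aware allele frequencies and
#' chromosome counts), and convert to epsilon. The replicate distribution
#' is the boxplot-ready result; its mean is the headline estimate.
#'
#' @param gm a [genotype_matrix()] (QC-filtered input recommended).
#' @param populations labels to estimate (default: all).
#' @param config an [esr_config()].
#' @param ancestral_freqs optional list with vectors `autosomal` and
#'   `sex_linked` of per-SNP ancestral frequencies (aligned with the
#'   autosomal / sex-linked variant subsets of `gm`; lengths are
#'   checked). When `NULL`, an `ancestral_freq` column in
#'   `gm$variants` (as written by [wf_simulate()], surviving any
#'   subsetting) is used if present; otherwise pi falls back to the
#'   across-population pooled mean frequency with the pooled-K moment
#'   correction (requires >= 2 populations, and assumes comparable
#'   drift across them — strongly heterogeneous populations leak drift
#'   into each other's tau through the pooled mean).
#' @param heterogamety "XY" or "ZW" (interpretation label; see
#'   [esr_from_tau()]).
#' @return object of class `esr_estimate`: long data.frame `replicates`
#'   (population, replicate, tau_auto, tau_sex, epsilon) plus a `summary`
#'   data.frame with means and sds.
#' @export
pseudo_replicate_esr <- function(gm, populations = NULL,
                                 config = esr_config(),
                                 ancestral_freqs = NULL,
                                 heterogamety = c("XY", "ZW")) {
  heterogamety <- match.arg(heterogamety)
  if (is.null(populations)) populations <- unique(gm$samples$population)
  auto_idx <- which(!gm$variants$is_sex_linked)
  sex_idx <- which(gm$variants$is_sex_linked)
  if (length(sex_idx) == 0) stop("no sex-linked SNPs")
  K <- length(populations)
  if (is.null(ancestral_freqs) && !is.null(gm$variants$ancestral_freq))
    ancestral_freqs <- list(
      autosomal = gm$variants$ancestral_freq[auto_idx],
      sex_linked = gm$variants$ancestral_freq[sex_idx])
  pooled <- is.null(ancestral_freqs)
  if (pooled && K < 2)
    stop("pooled ancestral frequencies need >= 2 populations; supply ancestral_freqs")
  if (!pooled &&
      (length(ancestral_freqs$autosomal) != length(auto_idx) ||
       length(ancestral_freqs$sex_linked) != length(sex_idx)))
    stop("ancestral_freqs lengths do not match the variant subsets of gm ",
         "(were the genotypes filtered after the frequencies were taken?)")

  # per-population sex-aware frequencies and chromosome counts, both classes
  freq <- lapply(populations, function(pop) {
    a <- sex_aware_allele_freq(gm, samples = pop, sex_linked = FALSE,
                               heterogamety = heterogamety)
    s <- sex_aware_allele_freq(gm, samples = pop, sex_linked = TRUE,
                               heterogamety = heterogamety)
    list(auto = a, sex = s)
  })
  names(freq) <- populations
  pi_auto <- if (pooled)
    rowMeans(vapply(freq, function(f) f$auto$freq, numeric(length(auto_idx))))
  else ancestral_freqs$autosomal
  pi_sex <- if (pooled)
    rowMeans(vapply(freq, function(f) f$sex$freq, numeric(length(sex_idx))))
  else ancestral_freqs$sex_linked
  n_pool <- if (pooled) K else 1

  n_a <- config$n_autosomal_snps
  n_s <- config$n_sex_snps
  if (length(auto_idx) < n_a || length(sex_idx) < n_s)
    message("fewer SNPs than requested: sampling with replacement")

  rows <- NULL
  for (r in seq_len(config$n_replicates)) {
    sa <- with_seed(derive_seed(config$seed, paste0("esr_auto_", r)),
                    sample.int(length(auto_idx), n_a,
                               replace = length(auto_idx) < n_a))
    ss <- with_seed(derive_seed(config$seed, paste0("esr_sex_", r)),
                    sample.int(length(sex_idx), n_s,
                               replace = length(sex_idx) < n_s))
    for (pop in populations) {
      fa <- freq[[pop]]$auto; fs <- freq[[pop]]$sex
      ta <- estimate_tau_moments(fa$freq[sa], pi_auto[sa], fa$n_chrom[sa],
                                 n_pops_pooled = n_pool)
      ts <- estimate_tau_moments(fs$freq[ss], pi_sex[ss], fs$n_chrom[ss],
                                 n_pops_pooled = n_pool)
      eps <- if (ta$tau > 0)
        as.numeric(esr_from_tau(ts$tau, ta$tau, heterogamety)) else NA_real_
      rows <- rbind(rows, data.frame(population = pop, replicate = r,
                                     tau_auto = ta$tau, tau_sex = ts$tau,
                                     epsilon = eps, stringsAsFactors = FALSE))
    }
  }
  summ <- do.call(rbind, lapply(split(rows, rows$population), function(d)
    data.frame(population = d$population[1], n_replicates = nrow(d),
               epsilon_mean = mean(d$epsilon, na.rm = TRUE),
               epsilon_sd = stats::sd(d$epsilon, na.rm = TRUE),
               tau_auto_mean = mean(d$tau_auto),
               tau_sex_mean = mean(d$tau_sex),
               n_out_of_range = sum(d$epsilon < 0 | d$epsilon > 1,
                                    na.rm = TRUE),
               stringsAsFactors = FALSE)))
  rownames(summ) <- NULL
  structure(list(replicates = rows, summary = summ,
                 label = if (heterogamety == "XY") "proportion of females"
                 else "proportion of males",
                 heterogamety = heterogamety, config = config),
            class = "esr_estimate")
}

#' @export
print.esr_estimate <- function(x, ...) {
  cat(sprintf("effective sex ratio (%s; %d replicates):\n", x$label,
              x$config$n_replicates))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' @export
plot.esr_estimate <- function(x, ...) {
  graphics::boxplot(epsilon ~ population, data = x$replicates,
                    ylab = paste("epsilon (", x$label, ")"), ...)
  graphics::abline(h = 0.5, lty = 3)
  invisible(x)
}
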