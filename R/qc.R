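#' Quality-control configuration
#'
#' Thresholds for the standard array QC filter: variants are retained when
#' minor allele frequency >= `min_maf`, call rate >= `min_call_rate`, and
#' the Hardy-Weinberg exact p-value >= `hwe_p_floor`.
#'
#' @param min_maf minimum minor allele frequency (default 0.05).
#' @param min_call_rate minimum fraction of non-missing calls (default 0.90).
#' @param hwe_p_floor minimum HWE exact p-value (default 1e-6).
#' @param per_population if `TRUE`, MAF and HWE are evaluated within each
#'   population and a variant fails when it fails in any population;
#'   default `FALSE` evaluates the pooled dataset once.
#' @param hwe_on_sex_linked include sex-linked variants in the HWE filter
#'   (default `FALSE`: the heterogametic sex breaks HWE assumptions).
#' @return an object of class `qc_config`.
#' @export
qc_config <- function(min_maf = 0.05, min_call_rate = 0.90,
                      hwe_p_floor = 1e-6, per_population = FALSE,
                      hwe_on_sex_linked = FALSE) {
  stopifnot(min_maf >= 0, min_maf <= 0.5,
            min_call_rate >= 0, min_call_rate <= 1,
            hwe_p_floor > 0, hwe_p_floor < 1)
  structure(list(min_maf = min_maf, min_call_rate = min_call_rate,
                 hwe_p_floor = hwe_p_floor, per_population = per_population,
                 hwe_on_sex_linked = hwe_on_sex_linked),
            class = "qc_config")
}

#' Hardy-Weinberg conditional exact test
#'
#' Two-sided exact test conditioning on the observed allele counts: the
#' p-value is the sum of the probabilities of every heterozygote count no
#' more probable than the observed one (plain p, not mid-p). Probabilities
#' are evaluated by the stable recurrence over heterozygote counts of the
#' same parity, started at the modal count.
#'
#' @param n_hom_ref,n_het,n_hom_alt genotype counts.
#' @return exact p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_hom_ref, n_het, n_hom_alt) {
  if (n_hom_ref < 0 || n_het < 0 || n_hom_alt < 0)
    stop("genotype counts must be non-negative")
  n <- n_hom_ref + n_het + n_hom_alt
  if (n < 1) stop("at least one genotype required")
  n_rare <- min(2 * n_hom_ref + n_het, 2 * n_hom_alt + n_het)
  if (n_rare == 0) return(1)          # monomorphic: single configuration

  # feasible het counts share the parity of the rare allele count
  het_lo <- n_rare %% 2L
  hets <- seq.int(het_lo, n_rare, by = 2L)
  probs <- numeric(length(hets))

  # unnormalized recurrence: P(h+2)/P(h) = 4*hr(h)*ha(h) / ((h+2)*(h+1)),
  # where hr, ha are the homozygote counts implied by h
  mid <- n_rare * (2 * n - n_rare) / (2 * n)      # modal het count, approx
  mid <- het_lo + 2 * round((mid - het_lo) / 2)
  mid <- min(max(mid, het_lo), n_rare)
  i_mid <- match(mid, hets)
  probs[i_mid] <- 1
  if (i_mid < length(hets)) {
    for (i in seq.int(i_mid, length(hets) - 1L)) {
      h <- hets[i]
      hr <- (n_rare - h) / 2
      ha <- n - hr - h
      probs[i + 1L] <- probs[i] * 4 * hr * ha / ((h + 2) * (h + 1))
    }
  }
  if (i_mid > 1) {
    for (i in seq.int(i_mid, 2L)) {
      h <- hets[i]
      hr <- (n_rare - h) / 2
      ha <- n - hr - h
      probs[i - 1L] <- probs[i] * h * (h - 1) / (4 * (hr + 1) * (ha + 1))
    }
  }
  probs <- probs / sum(probs)
  p_obs <- probs[match(n_het, hets)]
  if (is.na(p_obs)) stop("observed het count infeasible for allele counts")
  min(1, sum(probs[probs <= p_obs * (1 + 1e-12)]))
}

hwe_pvalues <- function(gm, samples = NULL) {
  idx <- resolve_samples(gm, samples)
  calls <- gm$calls[idx, , drop = FALSE]
  n0 <- colSums(calls == 0L, na.rm = TRUE)
  n1 <- colSums(calls == 1L, na.rm = TRUE)
  n2 <- colSums(calls == 2L, na.rm = TRUE)
  p <- rep(1, ncol(calls))
  tot <- n0 + n1 + n2
  for (j in which(tot > 0))
    p[j] <- hwe_exact_test(n0[j], n1[j], n2[j])
  p
}

#' Apply the array QC filter
#'
#' Removes variants failing MAF, call rate, or the HWE exact test; all
#' samples are retained. For reporting, each removed variant is assigned a
#' single reason by the precedence MAF, then call rate, then HWE; the
#' retained set itself is independent of that order. Sex-linked variants
#' are exempt from the HWE filter unless `hwe_on_sex_linked` is set.
#'
#' @param gm a [genotype_matrix()].
#' @param config a [qc_config()].
#' @return list with elements `genotypes` (filtered matrix) and `report`
#'   (class `qc_report`).
#' @export
apply_qc <- function(gm, config = qc_config()) {
  if (ncol(gm$calls) == 0) stop("empty genotype matrix")
  pops <- if (config$per_population) unique(gm$samples$population) else NULL

  fail_of <- function(samples) {
    m <- maf(gm, samples = samples)
    cr <- call_rate(gm, samples = samples)
    hw <- hwe_pvalues(gm, samples = samples)
    hwe_fail <- hw < config$hwe_p_floor
    if (!config$hwe_on_sex_linked) hwe_fail[gm$variants$is_sex_linked] <- FALSE
    list(maf = is.na(m) | m < config$min_maf,
         cr = cr < config$min_call_rate,
         hwe = hwe_fail)
  }
  if (is.null(pops)) {
    f <- fail_of(NULL)
  } else {
    per <- lapply(pops, fail_of)
    f <- list(maf = Reduce(`|`, lapply(per, `[[`, "maf")),
              cr = Reduce(`|`, lapply(per, `[[`, "cr")),
              hwe = Reduce(`|`, lapply(per, `[[`, "hwe")))
    f$cr <- f$cr | call_rate(gm) < config$min_call_rate
  }

  reason <- rep(NA_character_, ncol(gm$calls))
  reason[f$hwe] <- "hwe"
  reason[f$cr] <- "call_rate"
  reason[f$maf] <- "maf"          # precedence: maf > call_rate > hwe
  keep <- is.na(reason)

  ids <- gm$variants$id
  report <- structure(list(
    n_input = length(keep),
    n_removed_maf = sum(reason == "maf", na.rm = TRUE),
    n_removed_callrate = sum(reason == "call_rate", na.rm = TRUE),
    n_removed_hwe = sum(reason == "hwe", na.rm = TRUE),
    n_retained = sum(keep),
    removed_maf = ids[!is.na(reason) & reason == "maf"],
    removed_callrate = ids[!is.na(reason) & reason == "call_rate"],
    removed_hwe = ids[!is.na(reason) & reason == "hwe"],
    config = config), class = "qc_report")
  list(genotypes = subset_genotypes(gm, variants = keep), report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report:", x$n_input, "variants in\n")
  cat(sprintf("  removed: %d MAF < %.3g, %d call rate < %.3g, %d HWE p < %.3g\n",
              x$n_removed_maf, x$config$min_maf,
              x$n_removed_callrate, x$config$min_call_rate,
              x$n_removed_hwe, x$config$hwe_p_floor))
  cat("  retained:", x$n_retained, "\n")
  invisible(x)
}

#' Write a QC report as TSV
#'
#' One row per removed variant (id, reason) preceded by comment lines with
#' the counts.
#'
#' @param report a `qc_report`.
#' @param path output path.
#' @export
write_qc_report <- function(report, path) {
  hdr <- sprintf("# n_input=%d n_removed_maf=%d n_removed_callrate=%d n_removed_hwe=%d n_retained=%d",
                 report$n_input, report$n_removed_maf,
                 report$n_removed_callrate, report$n_removed_hwe,
                 report$n_retained)
  df <- data.frame(
    id = c(report$removed_maf, report$removed_callrate, report$removed_hwe),
    reason = rep(c("maf", "call_rate", "hwe"),
                 c(length(report$removed_maf), length(report$removed_callrate),
                   length(report$removed_hwe))))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(hdr, "id\treason"), con)
  if (nrow(df))
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  invisible(path)
}
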