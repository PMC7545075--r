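#' Multi-population SNP genotype matrix
#'
#' Container for diploid biallelic genotypes: an integer matrix of
#' alternate-allele dosages (samples in rows, variants in columns, values
#' 0/1/2 with `NA` for missing calls), a variant table with genomic
#' coordinates, and a sample table with population labels and sexes.
#' Variants are stored sorted by chromosome then position; positions are
#' 1-based and strictly increasing within a chromosome.
#'
#' Sex-linked markers (chromosome label in `sex_chroms`) are flagged in the
#' variant table. Hemizygous genotypes in the heterogametic sex are encoded
#' like homozygous diploid calls (dosage 0 or 2), the usual array
#' convention; downstream sex-aware code divides their contribution by two.
#'
#' @param calls integer matrix, samples x variants, values in {0,1,2,NA}.
#' @param variants data.frame with columns `chrom`, `pos_bp`, and optionally
#'   `id`, `ref_allele`, `alt_allele`, `is_sex_linked`.
#' @param samples data.frame with columns `sample_id` and optionally
#'   `population`, `sex` (one of "male","female","unknown").
#' @param sex_chroms chromosome labels treated as sex-linked when the
#'   variant table does not provide `is_sex_linked`.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, variants, samples,
                            sex_chroms = c("Z", "X")) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)

  if (!all(c("chrom", "pos_bp") %in% names(variants)))
    stop("variants must have columns 'chrom' and 'pos_bp'")
  if (!"sample_id" %in% names(samples))
    stop("samples must have a 'sample_id' column")
  if (nrow(samples) != nrow(calls) || nrow(variants) != ncol(calls))
    stop("dimension mismatch between calls, variants and samples")
  if (anyDuplicated(samples$sample_id))
    stop("sample_id must be unique")

  variants$chrom <- as.character(variants$chrom)
  variants$pos_bp <- as.integer(variants$pos_bp)
  if (any(variants$pos_bp < 1L)) stop("pos_bp must be >= 1")
  if (is.null(variants$id))
    variants$id <- if (nrow(variants))
      paste0(variants$chrom, "_", variants$pos_bp) else character(0)
  if (is.null(variants$ref_allele)) variants$ref_allele <- "A"
  if (is.null(variants$alt_allele)) variants$alt_allele <- "B"
  if (any(variants$ref_allele == variants$alt_allele))
    stop("ref_allele and alt_allele must differ")
  if (is.null(variants$is_sex_linked))
    variants$is_sex_linked <- variants$chrom %in% sex_chroms

  if (is.null(samples$population)) samples$population <- "pop1"
  samples$population <- as.character(samples$population)
  if (is.null(samples$sex)) samples$sex <- "unknown"
  if (!all(samples$sex %in% c("male", "female", "unknown")))
    stop("sex must be 'male', 'female' or 'unknown'")

  bad <- calls[!is.na(calls)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L))
    stop("calls must be 0, 1, 2 or NA")

  ord <- order(variants$chrom, variants$pos_bp)
  variants <- variants[ord, , drop = FALSE]
  calls <- calls[, ord, drop = FALSE]
  rownames(variants) <- NULL

  dup <- unlist(tapply(variants$pos_bp, variants$chrom,
                       function(p) duplicated(p)))
  if (any(dup))
    stop("pos_bp must be strictly increasing within each chromosome")

  dimnames(calls) <- list(samples$sample_id, variants$id)
  structure(list(calls = calls, variants = variants, samples = samples),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$calls), "samples x",
      ncol(x$calls), "variants\n")
  cat("  chromosomes:", paste(unique(x$variants$chrom), collapse = ", "),
      sprintf(" (%d sex-linked variants)\n", sum(x$variants$is_sex_linked)))
  pops <- table(x$samples$population)
  cat("  populations:",
      paste(sprintf("%s (n=%d)", names(pops), as.integer(pops)),
            collapse = ", "), "\n")
  miss <- mean(is.na(x$calls))
  cat(sprintf("  missing calls: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' @export
summary.genotype_matrix <- function(object, ...) {
  maf_v <- maf(object)
  out <- list(
    n_samples = nrow(object$calls),
    n_variants = ncol(object$calls),
    n_autosomal = sum(!object$variants$is_sex_linked),
    populations = table(object$samples$population),
    maf_quartiles = stats::quantile(maf_v, c(0.25, 0.5, 0.75), na.rm = TRUE),
    call_rate_mean = mean(call_rate(object)))
  class(out) <- "summary.genotype_matrix"
  out
}

#' @export
print.summary.genotype_matrix <- function(x, ...) {
  cat(sprintf("%d samples, %d variants (%d autosomal)\n",
              x$n_samples, x$n_variants, x$n_autosomal))
  cat(sprintf("mean call rate %.3f; MAF quartiles %.3f/%.3f/%.3f\n",
              x$call_rate_mean, x$maf_quartiles[1], x$maf_quartiles[2],
              x$maf_quartiles[3]))
  invisible(x)
}

resolve_samples <- function(gm, samples) {
  if (is.null(samples)) return(seq_len(nrow(gm$calls)))
  if (is.character(samples) && length(samples) == 1 &&
      samples %in% gm$samples$population)
    return(which(gm$samples$population == samples))
  if (is.character(samples)) {
    idx <- match(samples, gm$samples$sample_id)
    if (anyNA(idx)) stop("unknown sample id(s): ",
                         paste(samples[is.na(idx)], collapse = ", "))
    return(idx)
  }
  as.integer(samples)
}

#' Alternate-allele frequency per variant
#'
#' Frequency of the alternate allele, `sum(dosage) / (2 * n_non_missing)`,
#' over an optional sample subset. Variants with no non-missing call in the
#' subset yield `NaN` (the "no data" signal).
#'
#' Note this treats every sample as diploid; for sex-linked markers with
#' recorded sexes use [sex_aware_allele_freq()].
#'
#' @param gm a [genotype_matrix()].
#' @param variants optional variant indices (default all).
#' @param samples optional sample subset: indices, sample ids, or a single
#'   population label.
#' @return numeric vector of frequencies in `[0, 1]` (or `NaN`).
#' @export
allele_frequency <- function(gm, variants = NULL, samples = NULL) {
  idx <- resolve_samples(gm, samples)
  calls <- gm$calls[idx, , drop = FALSE]
  if (!is.null(variants)) calls <- calls[, variants, drop = FALSE]
  n_obs <- colSums(!is.na(calls))
  colSums(calls, na.rm = TRUE) / (2 * n_obs)
}

#' Per-variant call rate
#'
#' @inheritParams allele_frequency
#' @return fraction of non-missing calls per variant.
#' @export
call_rate <- function(gm, samples = NULL) {
  idx <- resolve_samples(gm, samples)
  colMeans(!is.na(gm$calls[idx, , drop = FALSE]))
}

#' Per-variant minor allele frequency
#'
#' @inheritParams allele_frequency
#' @export
maf <- function(gm, samples = NULL) {
  p <- allele_frequency(gm, samples = samples)
  pmin(p, 1 - p)
}

#' Subset a genotype matrix
#'
#' @param gm a [genotype_matrix()].
#' @param variants variant indices or logical mask to keep.
#' @param samples sample indices, ids, or a population label to keep.
#' @return a new `genotype_matrix`.
#' @export
subset_genotypes <- function(gm, variants = NULL, samples = NULL) {
  vi <- if (is.null(variants)) seq_len(ncol(gm$calls)) else variants
  si <- resolve_samples(gm, samples)
  genotype_matrix(gm$calls[si, vi, drop = FALSE],
                  gm$variants[vi, , drop = FALSE],
                  gm$samples[si, , drop = FALSE])
}

#' Assign population labels (and optionally sexes) from a sample sheet
#'
#' @param gm a [genotype_matrix()].
#' @param sheet data.frame with columns `sample_id`, `population` and
#'   optionally `sex`.
#' @return the updated `genotype_matrix`.
#' @export
assign_populations <- function(gm, sheet) {
  sheet <- as.data.frame(sheet, stringsAsFactors = FALSE)
  idx <- match(gm$samples$sample_id, sheet$sample_id)
  if (anyNA(idx))
    stop("sample sheet is missing ids: ",
         paste(gm$samples$sample_id[is.na(idx)], collapse = ", "))
  gm$samples$population <- as.character(sheet$population[idx])
  if (!is.null(sheet$sex)) gm$samples$sex <- as.character(sheet$sex[idx])
  gm
}

#' Sex-aware allele frequency for one marker class
#'
#' For autosomal markers every individual contributes two chromosomes. For
#' sex-linked markers the heterogametic sex (females under ZW, males under
#' XY) carries a single copy, encoded as a homozygous-like 0/2 dosage, and
#' contributes one chromosome (dosage / 2). Individuals of unknown sex are
#' classified from their own sex-linked heterozygosity (any heterozygous
#' sex-linked call implies homogametic), a crude fallback that is flagged
#' with a warning.
#'
#' @param gm a [genotype_matrix()].
#' @param samples sample subset (indices, ids, or population label).
#' @param sex_linked logical: compute over sex-linked (TRUE) or autosomal
#'   (FALSE) variants.
#' @param heterogamety "ZW" (female heterogametic, e.g. birds) or "XY".
#' @return list with `freq` (per-variant frequency), `n_chrom` (chromosomes
#'   sampled per variant) and `variant_index`.
#' @export
sex_aware_allele_freq <- function(gm, samples = NULL, sex_linked = FALSE,
                                  heterogamety = c("ZW", "XY")) {
  heterogamety <- match.arg(heterogamety)
  idx <- resolve_samples(gm, samples)
  vi <- which(gm$variants$is_sex_linked == sex_linked)
  calls <- gm$calls[idx, vi, drop = FALSE]
  if (!sex_linked) {
    n_obs <- colSums(!is.na(calls))
    return(list(freq = colSums(calls, na.rm = TRUE) / (2 * n_obs),
                n_chrom = 2 * n_obs, variant_index = vi))
  }
  het_sex <- if (heterogamety == "ZW") "female" else "male"
  sex <- gm$samples$sex[idx]
  if (any(sex == "unknown")) {
    warning("unknown sexes classified from sex-linked heterozygosity")
    any_het <- rowSums(calls == 1L, na.rm = TRUE) > 0
    sex[sex == "unknown"] <- ifelse(any_het[sex == "unknown"],
                                    setdiff(c("male", "female"), het_sex),
                                    het_sex)
  }
  hemi <- sex == het_sex
  w <- ifelse(hemi, 0.5, 1)          # chromosome weight per individual
  obs <- !is.na(calls)
  n_chrom <- 2 * colSums(obs * w)
  cnt <- colSums(calls * w, na.rm = TRUE)
  list(freq = cnt / n_chrom, n_chrom = n_chrom, variant_index = vi)
}
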