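#' Read a VCF file into a genotype matrix
#'
#' Reads GT fields from a VCF (plain or bgzipped) via vcfR and converts
#' them to alternate-allele dosages. Multiallelic records are skipped with
#' a warning. Missing genotypes (`./.` or `.`) become `NA`. Haploid GT
#' fields ("0"/"1") are encoded as homozygous dosages 0/2.
#'
#' @param path VCF file path.
#' @param sample_sheet optional data.frame (`sample_id`, `population`,
#'   `sex`) applied via [assign_populations()].
#' @param sex_chroms chromosome labels flagged as sex-linked.
#' @return a [genotype_matrix()].
#' @export
read_vcf <- function(path, sample_sheet = NULL, sex_chroms = c("Z", "X")) {
  if (!file.exists(path)) stop("cannot read VCF: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  if (nrow(v@fix) == 0) stop("no records in VCF: ", path)
  bi <- vcfR::is.biallelic(v)
  if (any(!bi))
    warning(sum(!bi), " non-biallelic record(s) skipped")
  if (!any(bi)) stop("no biallelic records in VCF: ", path)
  v <- v[bi, ]
  fix <- v@fix
  gt <- vcfR::extract.gt(v, element = "GT")

  dose <- gt_to_dosage(gt)                      # variants x samples
  variants <- data.frame(chrom = fix[, "CHROM"],
                         pos_bp = as.integer(fix[, "POS"]),
                         id = ifelse(is.na(fix[, "ID"]) | fix[, "ID"] == ".",
                                     paste0(fix[, "CHROM"], "_", fix[, "POS"]),
                                     fix[, "ID"]),
                         ref_allele = fix[, "REF"],
                         alt_allele = fix[, "ALT"],
                         stringsAsFactors = FALSE)
  samples <- data.frame(sample_id = colnames(gt), stringsAsFactors = FALSE)
  gm <- genotype_matrix(t(dose), variants, samples, sex_chroms = sex_chroms)
  if (!is.null(sample_sheet)) gm <- assign_populations(gm, sample_sheet)
  gm
}

gt_to_dosage <- function(gt) {
  d <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  # strip phase, keep first field
  gt <- sub(":.*$", "", gt)
  gt <- gsub("|", "/", gt, fixed = TRUE)
  d[gt %in% c("0/0")] <- 0L
  d[gt %in% c("0/1", "1/0")] <- 1L
  d[gt %in% c("1/1")] <- 2L
  d[gt %in% c("0")] <- 0L   # haploid calls
  d[gt %in% c("1")] <- 2L
  d
}

#' Write a genotype matrix as VCF
#'
#' Emits a minimal VCFv4.2 with contig headers and GT-only genotype
#' columns. Coordinates are written 1-based as stored.
#'
#' @param gm a [genotype_matrix()].
#' @param path output path (plain text).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  v <- gm$variants
  chroms <- unique(v$chrom)
  clen <- vapply(chroms, function(ch) max(v$pos_bp[v$chrom == ch]), 0L)
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##source=popgenarray_%s",
                   as.character(utils::packageVersion("popgenarray"))),
           sprintf("##contig=<ID=%s,length=%d>", chroms, clen),
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", gm$samples$sample_id), collapse = "\t"))
  code <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow(gm$calls), ncol(gm$calls))
  ok <- !is.na(gm$calls)
  gt[ok] <- code[gm$calls[ok] + 1L]
  body <- paste(v$chrom, v$pos_bp, v$id, v$ref_allele, v$alt_allele,
                ".", "PASS", ".", "GT",
                apply(gt, 2, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read PLINK text files (.ped/.map) into a genotype matrix
#'
#' Allele pairs are converted to dosages against a per-marker reference
#' assignment: the reference allele is the first allele seen at the marker
#' (scanning samples in file order), the alternate is the first-seen other
#' allele; "0 0" entries are missing. Markers with more than two alleles
#' are an error. The .ped `FID` column becomes the population label and
#' column 5 the sex (1 = male, 2 = female).
#'
#' @param ped_path path to the .ped file.
#' @param map_path path to the .map file (chrom, id, cM, bp).
#' @param sex_chroms chromosome labels flagged as sex-linked.
#' @return a [genotype_matrix()].
#' @export
read_plink_text <- function(ped_path, map_path, sex_chroms = c("Z", "X")) {
  map <- utils::read.table(map_path, header = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(map) < 4) stop("malformed .map: expected 4 columns")
  names(map)[1:4] <- c("chrom", "id", "cm", "pos_bp")
  ped <- utils::read.table(ped_path, header = FALSE,
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  n_mark <- nrow(map)
  if (ncol(ped) != 6 + 2 * n_mark)
    stop("marker count mismatch: .map has ", n_mark, " markers but .ped has ",
         (ncol(ped) - 6) / 2)
  n <- nrow(ped)
  calls <- matrix(NA_integer_, n, n_mark)
  ref <- alt <- character(n_mark)
  for (j in seq_len(n_mark)) {
    a1 <- ped[[6 + 2 * j - 1]]
    a2 <- ped[[6 + 2 * j]]
    miss <- a1 == "0" | a2 == "0"
    alleles <- setdiff(unique(c(a1[!miss], a2[!miss])), character(0))
    if (length(alleles) > 2)
      stop("marker ", map$id[j], " has >2 alleles")
    ref[j] <- if (length(alleles)) alleles[1] else "A"
    alt[j] <- if (length(alleles) > 1) alleles[2] else
      setdiff(c("A", "B"), ref[j])[1]
    d <- (a1 == alt[j]) + (a2 == alt[j])
    d[miss] <- NA_integer_
    calls[, j] <- d
  }
  variants <- data.frame(chrom = as.character(map$chrom),
                         pos_bp = as.integer(map$pos_bp), id = map$id,
                         ref_allele = ref, alt_allele = alt,
                         stringsAsFactors = FALSE)
  sex <- c("1" = "male", "2" = "female")[ped[[5]]]
  sex[is.na(sex)] <- "unknown"
  samples <- data.frame(sample_id = ped[[2]], population = ped[[1]],
                        sex = unname(sex), stringsAsFactors = FALSE)
  genotype_matrix(calls, variants, samples, sex_chroms = sex_chroms)
}

#' Write a sample sheet TSV (sample_id, population, sex)
#'
#' @param gm a [genotype_matrix()].
#' @param path output path.
#' @export
write_sample_sheet <- function(gm, path) {
  utils::write.table(gm$samples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
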