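#' Runs-of-homozygosity detection parameters
#'
#' PLINK-style scanning-window parameters: a window of `window_snps`
#' consecutive SNPs "passes" when it holds at most `max_het_per_window`
#' heterozygotes and `max_missing_per_window` missing calls; a SNP becomes
#' a run candidate when the fraction of passing windows among those
#' overlapping it reaches `window_hit_threshold`. Candidate runs are split
#' at inter-SNP gaps above `max_gap_kb` and kept when they span at least
#' `min_length_kb`, contain at least `min_snps_per_segment` SNPs, and have
#' at most `min_density_kb_per_snp` kb per SNP. The window thresholds mean
#' a reported segment may contain isolated heterozygous or missing calls.
#'
#' @param window_snps window size in SNPs (50).
#' @param max_het_per_window heterozygotes allowed per window (1).
#' @param max_missing_per_window missing calls allowed per window (5).
#' @param min_length_kb minimum segment span (100 kb).
#' @param min_density_kb_per_snp maximum kb per SNP in a segment (50).
#' @param max_gap_kb maximum gap between consecutive segment SNPs (1000 kb).
#' @param window_hit_threshold passing-window fraction making a SNP a
#'   candidate (0.05).
#' @param min_snps_per_segment minimum SNPs per final segment (25).
#' @return object of class `roh_params`.
#' @export
roh_params <- function(window_snps = 50, max_het_per_window = 1,
                       max_missing_per_window = 5, min_length_kb = 100,
                       min_density_kb_per_snp = 50, max_gap_kb = 1000,
                       window_hit_threshold = 0.05,
                       min_snps_per_segment = 25) {
  stopifnot(window_snps >= 1, max_het_per_window >= 0,
            max_missing_per_window >= 0, min_length_kb > 0,
            min_density_kb_per_snp > 0, max_gap_kb > 0,
            window_hit_threshold > 0, window_hit_threshold <= 1,
            min_snps_per_segment >= 1)
  structure(list(window_snps = window_snps,
                 max_het_per_window = max_het_per_window,
                 max_missing_per_window = max_missing_per_window,
                 min_length_kb = min_length_kb,
                 min_density_kb_per_snp = min_density_kb_per_snp,
                 max_gap_kb = max_gap_kb,
                 window_hit_threshold = window_hit_threshold,
                 min_snps_per_segment = min_snps_per_segment),
            class = "roh_params")
}

roh_one_chrom <- function(dosage, pos, chrom, sample_id, p) {
  L <- length(dosage)
  het <- !is.na(dosage) & dosage == 1L
  mis <- is.na(dosage)
  W <- p$window_snps
  nW <- L - W + 1L
  cand <- logical(L)
  if (nW >= 1) {
    csh <- c(0, cumsum(het))
    csm <- c(0, cumsum(mis))
    pass <- (csh[(W + 1):(L + 1)] - csh[1:nW]) <= p$max_het_per_window &
      (csm[(W + 1):(L + 1)] - csm[1:nW]) <= p$max_missing_per_window
    # windows overlapping SNP k: start indices max(1, k-W+1) .. min(k, nW)
    cp <- c(0, cumsum(pass))
    lo <- pmax(1L, seq_len(L) - W + 1L)
    hi <- pmin(seq_len(L), nW)
    n_over <- pmax(hi - lo + 1L, 0L)
    n_pass <- ifelse(n_over > 0, cp[hi + 1L] - cp[lo], 0L)
    cand <- n_over > 0 & n_pass / pmax(n_over, 1L) >= p$window_hit_threshold
  }
  if (!any(cand)) return(NULL)
  # maximal candidate runs, split at large gaps
  idx <- which(cand)
  brk <- c(TRUE, diff(idx) > 1L |
             diff(pos[idx]) > p$max_gap_kb * 1000)
  run <- cumsum(brk)
  segs <- lapply(split(idx, run), function(ii) {
    len_kb <- (pos[ii[length(ii)]] - pos[ii[1]] + 1) / 1000
    n <- length(ii)
    if (len_kb < p$min_length_kb || n < p$min_snps_per_segment ||
        len_kb / n > p$min_density_kb_per_snp) return(NULL)
    data.frame(sample_id = sample_id, chrom = chrom,
               start_bp = pos[ii[1]], end_bp = pos[ii[length(ii)]],
               n_snps = n, length_kb = len_kb, stringsAsFactors = FALSE)
  })
  do.call(rbind, segs)
}

#' Detect runs of homozygosity for one individual
#'
#' Two-stage sliding-window scan over sorted autosomal SNPs (see
#' [roh_params()] for the algorithm contract). Segments are reported with
#' 1-based inclusive coordinates and `length_kb = (end - start + 1)/1000`.
#'
#' @param gm a [genotype_matrix()].
#' @param sample sample id or index.
#' @param params a [roh_params()].
#' @return data.frame of class `roh_segments` (possibly 0 rows) with
#'   columns `sample_id`, `chrom`, `start_bp`, `end_bp`, `n_snps`,
#'   `length_kb`.
#' @export
detect_roh <- function(gm, sample, params = roh_params()) {
  si <- resolve_samples(gm, sample)
  stopifnot(length(si) == 1)
  vi <- which(!gm$variants$is_sex_linked)
  v <- gm$variants[vi, , drop = FALSE]
  dos <- gm$calls[si, vi]
  out <- NULL
  for (ch in unique(v$chrom)) {
    w <- which(v$chrom == ch)
    out <- rbind(out, roh_one_chrom(dos[w], v$pos_bp[w], ch,
                                    gm$samples$sample_id[si], params))
  }
  if (is.null(out))
    out <- data.frame(sample_id = character(), chrom = character(),
                      start_bp = integer(), end_bp = integer(),
                      n_snps = integer(), length_kb = numeric(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("roh_segments", "data.frame")
  out
}

#' Detect ROH for every individual
#'
#' @param gm a [genotype_matrix()].
#' @param params a [roh_params()].
#' @return a single `roh_segments` data.frame over all samples.
#' @export
detect_roh_all <- function(gm, params = roh_params()) {
  segs <- lapply(seq_len(nrow(gm$calls)),
                 function(i) detect_roh(gm, i, params))
  out <- do.call(rbind, segs)
  class(out) <- c("roh_segments", "data.frame")
  out
}

#' Genomic inbreeding coefficient from ROH
#'
#' F_ROH = sum of ROH segment lengths (kb) / autosomal genome length (kb).
#' The default denominator is the 952,090 kb autosomal span of the
#' chicken 600K array map; pass `l_auto_kb = l_auto_from_map(gm)` to use
#' the span of the typed SNPs instead.
#'
#' @param segments `roh_segments` for one individual.
#' @param l_auto_kb autosomal length in kb (default 952090).
#' @return F_ROH in \[0, 1\].
#' @export
f_roh <- function(segments, l_auto_kb = 952090) {
  if (nrow(segments) == 0) return(0)
  if (length(unique(segments$sample_id)) > 1)
    stop("f_roh expects segments from a single individual")
  for (ch in unique(segments$chrom)) {
    s <- segments[segments$chrom == ch, , drop = FALSE]
    s <- s[order(s$start_bp), , drop = FALSE]
    if (nrow(s) > 1 && any(s$start_bp[-1] <= s$end_bp[-nrow(s)]))
      stop("overlapping ROH segments on chromosome ", ch)
  }
  sum(segments$length_kb) / l_auto_kb
}

#' Autosomal map length spanned by typed SNPs
#'
#' Sum over autosomes of (max position - min position + 1), in kb.
#'
#' @param gm a [genotype_matrix()].
#' @export
l_auto_from_map <- function(gm) {
  v <- gm$variants[!gm$variants$is_sex_linked, , drop = FALSE]
  spans <- tapply(v$pos_bp, v$chrom, function(p) max(p) - min(p) + 1)
  sum(spans) / 1000
}

#' Per-SNP ROH incidence within a group
#'
#' For every autosomal SNP, the fraction of the group's individuals whose
#' detected ROH cover its position (denominator = group size).
#'
#' @param segments a `roh_segments` data.frame (all individuals).
#' @param gm a [genotype_matrix()].
#' @param group population label (or sample subset) defining the group.
#' @return data.frame of class `roh_incidence`: `chrom`, `pos_bp`, `id`,
#'   `incidence`.
#' @export
snp_roh_incidence <- function(segments, gm, group = NULL) {
  idx <- resolve_samples(gm, group)
  ids <- gm$samples$sample_id[idx]
  if (length(ids) == 0) stop("empty group")
  vi <- which(!gm$variants$is_sex_linked)
  v <- gm$variants[vi, , drop = FALSE]
  cnt <- numeric(nrow(v))
  segs <- segments[segments$sample_id %in% ids, , drop = FALSE]
  if (nrow(segs)) {
    for (ch in unique(segs$chrom)) {
      w <- which(v$chrom == ch)
      if (!length(w)) next
      s <- segs[segs$chrom == ch, , drop = FALSE]
      for (k in seq_len(nrow(s)))
        cnt[w] <- cnt[w] + (v$pos_bp[w] >= s$start_bp[k] &
                            v$pos_bp[w] <= s$end_bp[k])
    }
  }
  out <- data.frame(chrom = v$chrom, pos_bp = v$pos_bp, id = v$id,
                    incidence = cnt / length(ids),
                    stringsAsFactors = FALSE)
  attr(out, "group_size") <- length(ids)
  class(out) <- c("roh_incidence", "data.frame")
  out
}

#' ROH islands from per-SNP incidence
#'
#' Selects SNPs at or above the empirical `1 - top_fraction` incidence
#' quantile (and with incidence > 0) and merges runs of adjacent selected
#' SNPs (no unselected SNP between, same chromosome) into islands. When
#' all incidences are equal the threshold equals that value and whole
#' chromosomes merge into single islands; this degenerate case is flagged
#' with a warning.
#'
#' @param incidence a `roh_incidence` data.frame.
#' @param top_fraction fraction of SNPs defining the threshold (0.01).
#' @return data.frame of class `roh_islands`: `chrom`, `start_bp`,
#'   `end_bp`, `n_snps`, `peak_incidence`; threshold kept as attribute.
#' @export
roh_islands <- function(incidence, top_fraction = 0.01) {
  x <- incidence$incidence
  if (all(x == 0)) {
    out <- data.frame(chrom = character(), start_bp = integer(),
                      end_bp = integer(), n_snps = integer(),
                      peak_incidence = numeric(), stringsAsFactors = FALSE)
    class(out) <- c("roh_islands", "data.frame")
    attr(out, "threshold") <- NA_real_
    return(out)
  }
  thr <- stats::quantile(x, 1 - top_fraction, names = FALSE)
  if (length(unique(x)) == 1)
    warning("all incidences equal: degenerate tie case, one island per chromosome")
  sel <- x >= thr & x > 0
  idx <- which(sel)
  brk <- c(TRUE, diff(idx) > 1L |
             incidence$chrom[idx[-1]] != incidence$chrom[idx[-length(idx)]])
  run <- cumsum(brk)
  isl <- lapply(split(idx, run), function(ii)
    data.frame(chrom = incidence$chrom[ii[1]],
               start_bp = incidence$pos_bp[ii[1]],
               end_bp = incidence$pos_bp[ii[length(ii)]],
               n_snps = length(ii), peak_incidence = max(x[ii]),
               stringsAsFactors = FALSE))
  out <- do.call(rbind, isl)
  rownames(out) <- NULL
  attr(out, "threshold") <- thr
  class(out) <- c("roh_islands", "data.frame")
  out
}

#' Write ROH segments in PLINK .hom-like TSV layout
#'
#' @param segments a `roh_segments` data.frame.
#' @param path output path.
#' @export
write_roh_segments <- function(segments, path) {
  df <- data.frame(IID = segments$sample_id, CHR = segments$chrom,
                   POS1 = segments$start_bp, POS2 = segments$end_bp,
                   KB = segments$length_kb, NSNP = segments$n_snps)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write ROH islands as BED (0-based half-open) plus TSV
#'
#' @param islands a `roh_islands` data.frame.
#' @param bed_path,tsv_path output paths.
#' @export
write_roh_islands <- function(islands, bed_path, tsv_path) {
  bed <- data.frame(chrom = islands$chrom, start = islands$start_bp - 1L,
                    end = islands$end_bp)
  utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(as.data.frame(islands), tsv_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(tsv_path)
}
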