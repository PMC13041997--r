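# SV quality-control stage: region-based exclusion, carrier rates by
# diagnostic group, read-evidence metrics, SNP linkage-disequilibrium
# annotation, and the low-confidence filter.

#' Remove SVs overlapping masked regions and the sex chromosomes
#'
#' An SV is removed when its query span (for insertions: the single
#' breakpoint base) overlaps any mask interval by at least 1 bp, or when it
#' lies on chrX/chrY. Masks use BED half-open coordinates.
#'
#' @param svs SV table.
#' @param masks Interval `data.frame` (`chrom`, `start`, `end`), merged or
#'   not (they are reduced internally).
#' @return `list(kept, removed)`; `removed` carries a `rule` column
#'   (`"masked"`, `"sex_chromosome"`).
#' @export
exclude_regions <- function(svs, masks) {
  sex <- svs$chrom %in% c("chrX", "chrY", "X", "Y")
  masked <- logical(nrow(svs))
  if (!is.null(masks) && nrow(masks)) {
    gr_m <- GenomicRanges::reduce(intervals_to_granges(masks))
    hits <- GenomicRanges::countOverlaps(sv_query_granges(svs), gr_m,
                                         minoverlap = 1L)
    masked <- hits > 0L
  }
  rule <- ifelse(sex & masked, "masked,sex_chromosome",
                 ifelse(sex, "sex_chromosome", "masked"))
  drop <- sex | masked
  list(kept = svs[!drop, , drop = FALSE],
       removed = data.frame(id = svs$id[drop], rule = rule[drop],
                            stringsAsFactors = FALSE))
}

#' Carrier identification and case/control rates
#'
#' Carriers are samples with dosage 1 or 2 (both HET and HOM ALT). HC is
#' the control group; ILBD and PD together form the case group.
#'
#' @param sv_gt Named genotype-string vector for one SV (names = samples),
#'   or one row of an SV table's `gt` matrix.
#' @param panel A [cohort_panel()].
#' @return `list(carriers = list(HC=, ILBD=, PD=), case_rate, control_rate)`.
#' @export
annotate_carriers <- function(sv_gt, panel) {
  dos <- gt_dosage(sv_gt[panel$sample])
  carrier <- !is.na(dos) & dos >= 1L
  carriers <- split(panel$sample[carrier], factor(panel$diagnosis[carrier],
                                                 levels = c("HC", "ILBD", "PD")))
  n_hc <- sum(panel$diagnosis == "HC")
  n_case <- sum(panel$diagnosis %in% c("ILBD", "PD"))
  list(carriers = carriers,
       case_rate = if (n_case) (length(carriers$ILBD) + length(carriers$PD)) / n_case else NA_real_,
       control_rate = if (n_hc) length(carriers$HC) / n_hc else NA_real_)
}

#' Read-evidence metrics over carrier samples
#'
#' Counts non-supplementary reads from carrier samples whose alignment span
#' overlaps the SV query interval (span types: the SV interval with >= 1 bp
#' overlap; insertions: the read must fully contain the breakpoint base).
#'
#' @param sv One-row SV table (or a list with `chrom`, `pos`, `end`,
#'   `svtype`).
#' @param reads Read-evidence `data.frame` with columns `read_id`, `chrom`,
#'   `start`, `end` (0-based half-open), `mapq`, `supplementary`, `sample`.
#' @param carriers Character vector of carrier samples.
#' @return `list(total_reads, avg_reads_per_sample, avg_map_quality,
#'   flagged)`; all zero and `flagged = TRUE` when there are no carriers or
#'   no overlapping reads.
#' @export
read_support_metrics <- function(sv, reads, carriers) {
  if (length(carriers) == 0L) {
    return(list(total_reads = 0L, avg_reads_per_sample = 0,
                avg_map_quality = 0, flagged = TRUE))
  }
  q <- sv_query_interval(as.data.frame(sv[1, , drop = FALSE]))
  r <- reads[!reads$supplementary & reads$sample %in% carriers &
               reads$chrom == q$chrom, , drop = FALSE]
  if (sv$svtype[1] == "INS") {
    hit <- r$start <= q$start & r$end >= q$end  # fully contains breakpoint base
  } else {
    hit <- r$start < q$end & r$end > q$start
  }
  r <- r[hit, , drop = FALSE]
  total <- nrow(r)
  list(total_reads = total,
       avg_reads_per_sample = total / length(carriers),
       avg_map_quality = if (total) mean(r$mapq) else 0,
       flagged = total == 0L)
}

#' Linkage-disequilibrium metrics between an SV and nearby SNPs
#'
#' Candidate SNPs lie within `flank` bp of either SV breakpoint (`pos` or
#' `end`). For each, r-squared is the squared Pearson correlation between
#' SNP and SV dosage vectors over samples non-missing in both. SNPs with a
#' zero-variance dosage vector have undefined r2: they are excluded from
#' the high-LD count but included in `total_snps_nearby`.
#'
#' @param sv_dosages Named numeric dosage vector for the SV.
#' @param snps SNP table (`chrom`, `pos`, matrix column `gt`) as from
#'   [read_snp_vcf()], or a list with `chrom`, `pos` and a numeric dosage
#'   matrix `dosage` (SNP x sample).
#' @param sv One-row SV table.
#' @param flank Flanking distance in bp (default 10 kb).
#' @param r2_threshold High-LD threshold (default 0.7).
#' @return `list(total_snps_nearby, ld_snps_count, ld_snp_rate, r2)`.
#' @export
ld_metrics <- function(sv_dosages, snps, sv, flank = 10000, r2_threshold = 0.7) {
  near <- snps$chrom == sv$chrom[1] &
    (abs(snps$pos - sv$pos[1]) <= flank | abs(snps$pos - sv$end[1]) <= flank)
  idx <- which(near)
  total <- length(idx)
  if (total == 0L) {
    return(list(total_snps_nearby = 0L, ld_snps_count = 0L,
                ld_snp_rate = NA_real_, r2 = numeric()))
  }
  dos <- if (!is.null(snps$dosage)) snps$dosage else gt_dosage(snps$gt)
  samples <- intersect(colnames(dos), names(sv_dosages))
  sv_d <- sv_dosages[samples]
  r2 <- vapply(idx, function(i) {
    x <- as.numeric(dos[i, samples])
    ok <- !is.na(x) & !is.na(sv_d)
    if (sum(ok) < 2L) return(NA_real_)
    if (sd(x[ok]) == 0 || sd(sv_d[ok]) == 0) return(NA_real_)
    cor(x[ok], sv_d[ok])^2
  }, 1)
  count <- sum(!is.na(r2) & r2 >= r2_threshold)
  list(total_snps_nearby = total, ld_snps_count = count,
       ld_snp_rate = count / total, r2 = r2)
}

#' Annotate a cohort callset with all QC metrics
#'
#' Convenience wrapper attaching `CASE_RATE`, `CONTROL_RATE`, carrier
#' lists, `TOTAL_READS`, `AVG_READS_PER_SAMPLE`, `AVG_MAP_QUALITY`,
#' `TOTAL_SNPS_NEARBY`, `LD_SNPS_COUNT` and `LD_SNP_RATE` columns to the SV
#' table (they are serialized into INFO by [write_sv_vcf()] when exported
#' via [qc_columns_to_info()]).
#'
#' @param svs SV table with genotypes.
#' @param panel [cohort_panel()].
#' @param reads Read-evidence `data.frame` (see [read_support_metrics()]).
#' @param snps SNP table (see [ld_metrics()]); `NULL` skips LD annotation.
#' @param flank LD flank in bp.
#' @return Annotated SV table.
#' @export
annotate_sv_qc <- function(svs, panel, reads, snps = NULL, flank = 10000) {
  n <- nrow(svs)
  svs$CASE_RATE <- svs$CONTROL_RATE <- numeric(n)
  svs$HC_CARRIERS <- svs$ILBD_CARRIERS <- svs$PD_CARRIERS <- character(n)
  svs$TOTAL_READS <- integer(n)
  svs$AVG_READS_PER_SAMPLE <- svs$AVG_MAP_QUALITY <- numeric(n)
  svs$TOTAL_SNPS_NEARBY <- svs$LD_SNPS_COUNT <- integer(n)
  svs$LD_SNP_RATE <- rep(NA_real_, n)
  dos <- sv_dosage_matrix(svs)
  snp_dos <- if (!is.null(snps)) {
    if (!is.null(snps$dosage)) snps else { snps$dosage <- gt_dosage(snps$gt); snps }
  }
  for (i in seq_len(n)) {
    car <- annotate_carriers(svs$gt[i, ], panel)
    svs$CASE_RATE[i] <- car$case_rate
    svs$CONTROL_RATE[i] <- car$control_rate
    svs$HC_CARRIERS[i] <- paste(car$carriers$HC, collapse = ",")
    svs$ILBD_CARRIERS[i] <- paste(car$carriers$ILBD, collapse = ",")
    svs$PD_CARRIERS[i] <- paste(car$carriers$PD, collapse = ",")
    all_car <- unlist(car$carriers, use.names = FALSE)
    rm_ <- read_support_metrics(svs[i, , drop = FALSE], reads, all_car)
    svs$TOTAL_READS[i] <- rm_$total_reads
    svs$AVG_READS_PER_SAMPLE[i] <- rm_$avg_reads_per_sample
    svs$AVG_MAP_QUALITY[i] <- rm_$avg_map_quality
    if (!is.null(snp_dos)) {
      ld <- ld_metrics(dos[i, ], snp_dos, svs[i, , drop = FALSE], flank = flank)
      svs$TOTAL_SNPS_NEARBY[i] <- ld$total_snps_nearby
      svs$LD_SNPS_COUNT[i] <- ld$ld_snps_count
      svs$LD_SNP_RATE[i] <- ld$ld_snp_rate
    }
  }
  svs
}

#' Copy QC annotation columns into the INFO list column
#'
#' @param svs Annotated SV table (from [annotate_sv_qc()]).
#' @return SV table whose `info` column carries the QC keys, ready for
#'   [write_sv_vcf()].
#' @export
qc_columns_to_info <- function(svs) {
  keys <- c("CASE_RATE", "CONTROL_RATE", "HC_CARRIERS", "ILBD_CARRIERS",
            "PD_CARRIERS", "TOTAL_READS", "AVG_READS_PER_SAMPLE",
            "AVG_MAP_QUALITY", "TOTAL_SNPS_NEARBY", "LD_SNPS_COUNT",
            "LD_SNP_RATE")
  keys <- intersect(keys, names(svs))
  if (is.null(svs$info)) svs$info <- rep(list(NULL), nrow(svs))
  for (i in seq_len(nrow(svs))) {
    kv <- vapply(keys, function(k) as.character(svs[[k]][i]), "")
    svs$info[[i]] <- c(svs$info[[i]], setNames(kv, keys))
  }
  svs
}

#' Low-confidence SV filter
#'
#' Removes SVs failing any of: `TOTAL_READS >= 5`,
#' `AVG_READS_PER_SAMPLE >= 5`, `AVG_MAP_QUALITY >= 20` (Phred), cohort
#' alternate-allele count `>= 1`. All thresholds are strict less-than
#' removals, so exact boundary values are kept. An SV lacking annotation is
#' removed with reason `"unannotated"`. An SV may carry several reasons.
#'
#' @param svs Annotated SV table (see [annotate_sv_qc()]).
#' @return `list(kept, removed, counts)`; `removed$rule` is a
#'   comma-separated reason list and `counts` gives per-rule removals.
#' @export
apply_confidence_filter <- function(svs) {
  n <- nrow(svs)
  need <- c("TOTAL_READS", "AVG_READS_PER_SAMPLE", "AVG_MAP_QUALITY")
  unann <- if (all(need %in% names(svs))) {
    is.na(svs$TOTAL_READS) | is.na(svs$AVG_READS_PER_SAMPLE) | is.na(svs$AVG_MAP_QUALITY)
  } else rep(TRUE, n)
  ac <- rowSums(sv_dosage_matrix(svs), na.rm = TRUE)
  reasons <- vector("list", n)
  for (i in seq_len(n)) {
    r <- character()
    if (unann[i]) {
      r <- "unannotated"
    } else {
      if (svs$TOTAL_READS[i] < 5) r <- c(r, "total_reads_lt_5")
      if (svs$AVG_READS_PER_SAMPLE[i] < 5) r <- c(r, "avg_reads_lt_5")
      if (svs$AVG_MAP_QUALITY[i] < 20) r <- c(r, "avg_mapq_lt_20")
    }
    if (ac[i] < 1) r <- c(r, "alt_allele_count_lt_1")
    reasons[[i]] <- r
  }
  drop <- lengths(reasons) > 0L
  all_rules <- c("unannotated", "total_reads_lt_5", "avg_reads_lt_5",
                 "avg_mapq_lt_20", "alt_allele_count_lt_1")
  counts <- vapply(all_rules, function(rule)
    sum(vapply(reasons, function(r) rule %in% r, TRUE)), 1L)
  list(kept = svs[!drop, , drop = FALSE],
       removed = data.frame(
         id = svs$id[drop],
         rule = vapply(reasons[drop], paste, "", collapse = ","),
         stringsAsFactors = FALSE),
       counts = counts)
}
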