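# Haplotype partitioning of long reads at phased heterozygous SNPs and
# phased SV genotyping: reads are assigned to allele 1 / allele 2 / an
# uncertain pool, SV presence is tested on each allele's reads, and the
# two per-allele calls are combined into a phased genotype.

#' Phased heterozygous SNP table
#'
#' @param chrom,pos SNP coordinates (1-based).
#' @param hap1_base,hap2_base Bases carried by haplotype 1 and 2 (must
#'   differ: heterozygous sites only).
#' @return `data.frame` of phased SNPs.
#' @export
phased_snps <- function(chrom, pos, hap1_base, hap2_base) {
  stopifnot(all(hap1_base != hap2_base))
  data.frame(chrom = as.character(chrom), pos = as.integer(pos),
             hap1_base = as.character(hap1_base),
             hap2_base = as.character(hap2_base), stringsAsFactors = FALSE)
}

# per-read haplotype match counts over informative sites (base calls that
# match either haplotype base); optionally ignoring SNPs within
# `bp_exclude` bp of SV breakpoints (indel-adjacent calls are unreliable)
read_hap_counts <- function(reads, base_calls, snps, sv_breakpoints = NULL,
                            bp_exclude = 5L) {
  key <- paste(base_calls$chrom, base_calls$pos)
  skey <- paste(snps$chrom, snps$pos)
  m <- match(key, skey)
  ok <- !is.na(m)
  if (!is.null(sv_breakpoints) && length(sv_breakpoints)) {
    near <- vapply(base_calls$pos, function(p)
      any(abs(p - sv_breakpoints) <= bp_exclude), TRUE)
    ok <- ok & !near
  }
  bc <- base_calls[ok, , drop = FALSE]
  m <- m[ok]
  is1 <- bc$base == snps$hap1_base[m]
  is2 <- bc$base == snps$hap2_base[m]
  rid <- factor(bc$read_id, levels = reads$read_id)
  n1 <- tapply(is1, rid, sum, default = 0L)
  n2 <- tapply(is2, rid, sum, default = 0L)
  data.frame(read_id = reads$read_id,
             n_match_hap1 = as.integer(n1[reads$read_id]),
             n_match_hap2 = as.integer(n2[reads$read_id]),
             stringsAsFactors = FALSE)
}

#' Classify one read to a haplotype
#'
#' Over SNPs inside the read whose called base matches either haplotype
#' base, the read is assigned HAP1 when more than 95% of informative sites
#' match haplotype 1, HAP2 when fewer than 5% do, and is otherwise
#' UNASSIGNED (including reads covering zero informative sites). A read
#' matching exactly 95% is UNASSIGNED (the threshold is strict).
#' Supplementary alignments are rejected.
#'
#' @param read One-row read-evidence `data.frame`.
#' @param base_calls `data.frame(read_id, chrom, pos, base)` for this read.
#' @param snps A [phased_snps()] table.
#' @param frac Assignment threshold (default 0.95).
#' @return `list(class, n_match_hap1, n_match_hap2)` with `class` one of
#'   `"HAP1"`, `"HAP2"`, `"UNASSIGNED"`.
#' @export
classify_read <- function(read, base_calls, snps, frac = 0.95) {
  if (isTRUE(read$supplementary)) stop("supplementary reads are not classified")
  cnt <- read_hap_counts(read, base_calls[base_calls$read_id == read$read_id, ,
                                          drop = FALSE], snps)
  n1 <- cnt$n_match_hap1; n2 <- cnt$n_match_hap2
  cls <- if (n1 + n2 == 0L) "UNASSIGNED"
  else if (n1 / (n1 + n2) > frac) "HAP1"
  else if (n1 / (n1 + n2) < 1 - frac) "HAP2"
  else "UNASSIGNED"
  list(class = cls, n_match_hap1 = n1, n_match_hap2 = n2)
}

#' Partition reads into allele-1, allele-2 and uncertain sets
#'
#' Applies [classify_read()] to every non-supplementary read, then retains
#' a read in an allele set only when its allele-match SNP counter exceeds
#' `min_counter` (default 3); reads failing the counter filter join the
#' uncertain pool.
#'
#' @param reads Read-evidence `data.frame` (`read_id`, `chrom`, `start`,
#'   `end`, `mapq`, `supplementary`, `sample`).
#' @param base_calls `data.frame(read_id, chrom, pos, base)`.
#' @param snps A [phased_snps()] table.
#' @param min_counter Allele-match counter threshold (retained when
#'   strictly greater).
#' @param frac Assignment threshold passed to the classifier.
#' @param sv_breakpoints Optional positions near which SNP calls are
#'   ignored.
#' @return `list(hap1, hap2, uncertain)` of read-evidence frames; each
#'   carries `n_match_hap1`/`n_match_hap2` columns.
#' @export
partition_reads <- function(reads, base_calls, snps, min_counter = 3L,
                            frac = 0.95, sv_breakpoints = NULL) {
  reads <- reads[!reads$supplementary, , drop = FALSE]
  cnt <- read_hap_counts(reads, base_calls, snps, sv_breakpoints)
  reads$n_match_hap1 <- cnt$n_match_hap1
  reads$n_match_hap2 <- cnt$n_match_hap2
  tot <- reads$n_match_hap1 + reads$n_match_hap2
  f1 <- ifelse(tot > 0, reads$n_match_hap1 / tot, NA_real_)
  cls <- rep("UNASSIGNED", nrow(reads))
  cls[!is.na(f1) & f1 > frac] <- "HAP1"
  cls[!is.na(f1) & f1 < 1 - frac] <- "HAP2"
  keep1 <- cls == "HAP1" & reads$n_match_hap1 > min_counter
  keep2 <- cls == "HAP2" & reads$n_match_hap2 > min_counter
  list(hap1 = reads[keep1, , drop = FALSE],
       hap2 = reads[keep2, , drop = FALSE],
       uncertain = reads[!(keep1 | keep2), , drop = FALSE])
}

#' Test SV presence on one allele's reads
#'
#' Among reads fully spanning the SV query interval, counts those carrying
#' the SV signature. PRESENT requires at least `min_support` supporting
#' reads and a supporting fraction of at least `min_fraction`; ABSENT
#' requires at least `min_support` spanning reads with supporting fraction
#' below `1 - min_fraction`; anything else (including zero spanning reads)
#' is AMBIGUOUS.
#'
#' @param allele_reads Read-evidence frame for one allele.
#' @param sv One-row SV table.
#' @param supporting_reads Character vector of read ids carrying this SV's
#'   signature (from tabular read evidence or alignment inspection).
#' @param min_support,min_fraction Presence thresholds.
#' @return One of `"PRESENT"`, `"ABSENT"`, `"AMBIGUOUS"`.
#' @export
genotype_sv_on_allele <- function(allele_reads, sv, supporting_reads,
                                  min_support = 2L, min_fraction = 0.5) {
  q <- sv_query_interval(sv[1, , drop = FALSE])
  span <- allele_reads$chrom == q$chrom &
    allele_reads$start <= q$start & allele_reads$end >= q$end
  n_span <- sum(span)
  if (n_span == 0L) return("AMBIGUOUS")
  n_sup <- sum(allele_reads$read_id[span] %in% supporting_reads)
  frac <- n_sup / n_span
  if (n_sup >= min_support && frac >= min_fraction) return("PRESENT")
  if (n_span >= min_support && frac < 1 - min_fraction) return("ABSENT")
  "AMBIGUOUS"
}

#' Combine per-allele SV calls into a phased genotype
#'
#' `(ABSENT, PRESENT)` yields `"0|1"`, `(PRESENT, ABSENT)` yields `"1|0"`;
#' every other combination (including any AMBIGUOUS call) is unphaseable
#' and yields `"./."`.
#'
#' @param g1,g2 Allele-1 and allele-2 status from
#'   [genotype_sv_on_allele()].
#' @return Genotype string.
#' @export
combine_allele_genotypes <- function(g1, g2) {
  if (g1 == "ABSENT" && g2 == "PRESENT") return("0|1")
  if (g1 == "PRESENT" && g2 == "ABSENT") return("1|0")
  "./."
}

#' Phase all SVs of one sample from its reads
#'
#' Partitions the sample's reads by haplotype, genotypes each SV on each
#' allele's reads, and combines the calls into phased genotypes.
#'
#' @param svs SV table for the loci to phase.
#' @param reads,base_calls,snps Sample-level read evidence, per-read base
#'   calls and phased heterozygous SNPs.
#' @param read_support `data.frame(read_id, sv_id)` listing which reads
#'   carry which SV signature.
#' @param min_counter,frac Passed to [partition_reads()].
#' @param min_support,min_fraction Passed to [genotype_sv_on_allele()].
#' @return Named character vector of phased genotypes (`"0|1"`, `"1|0"`,
#'   `"./."`) indexed by SV id.
#' @export
phase_sample <- function(svs, reads, base_calls, snps, read_support,
                         min_counter = 3L, frac = 0.95,
                         min_support = 2L, min_fraction = 0.5) {
  parts <- partition_reads(reads, base_calls, snps, min_counter = min_counter,
                           frac = frac)
  out <- setNames(character(nrow(svs)), svs$id)
  for (i in seq_len(nrow(svs))) {
    sup <- read_support$read_id[read_support$sv_id == svs$id[i]]
    g1 <- genotype_sv_on_allele(parts$hap1, svs[i, , drop = FALSE], sup,
                                min_support, min_fraction)
    g2 <- genotype_sv_on_allele(parts$hap2, svs[i, , drop = FALSE], sup,
                                min_support, min_fraction)
    out[i] <- combine_allele_genotypes(g1, g2)
  }
  out
}
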