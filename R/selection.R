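# Restriction of the cohort callset to SVs near eGenes and the
# cohort-frequency filters that define the functional-analysis set.

#' eGene table constructor
#'
#' @param gene_id,symbol Gene identifiers.
#' @param chrom,start,end Gene span in BED half-open coordinates.
#' @return `data.frame` of eGenes.
#' @export
egene_table <- function(gene_id, symbol = gene_id, chrom, start, end) {
  stopifnot(all(start < end))
  data.frame(gene_id = as.character(gene_id), symbol = as.character(symbol),
             chrom = as.character(chrom), start = as.integer(start),
             end = as.integer(end), stringsAsFactors = FALSE)
}

#' Candidate SV-gene pairs within a window of eGenes
#'
#' An SV is paired with a gene when its query span (insertions: the
#' breakpoint base) overlaps the gene span expanded by `window` bp on both
#' sides; SVs overlapping the gene body itself are included.
#'
#' @param svs SV table.
#' @param egenes [egene_table()].
#' @param window Flank in bp (default 100 kb).
#' @return `data.frame(sv_id, gene_id, distance)` with `distance` the gap
#'   between SV span and gene span (0 when overlapping).
#' @export
select_near_egenes <- function(svs, egenes, window = 100000) {
  if (nrow(svs) == 0L || nrow(egenes) == 0L || window < 0) {
    return(data.frame(sv_id = character(), gene_id = character(),
                      distance = integer(), stringsAsFactors = FALSE))
  }
  gr_sv <- sv_query_granges(svs)
  gene_gr <- intervals_to_granges(egenes)
  expanded <- GenomicRanges::resize(gene_gr,
                                    GenomicRanges::width(gene_gr) + 2 * window,
                                    fix = "center")
  hits <- GenomicRanges::findOverlaps(gr_sv, expanded, minoverlap = 1L)
  i <- S4Vectors::queryHits(hits); j <- S4Vectors::subjectHits(hits)
  dist <- GenomicRanges::distance(gr_sv[i], gene_gr[j])
  data.frame(sv_id = svs$id[i], gene_id = egenes$gene_id[j],
             distance = as.integer(dist), stringsAsFactors = FALSE)
}

#' Cohort-frequency filters for the functional-analysis set
#'
#' Keeps SVs satisfying all of: fraction of missing genotypes `<= 0.95`
#' (i.e. valid genotype calls in at least 5 of 100 samples), cohort allele
#' frequency `< 0.99` over non-missing alleles, and at least 2 alternate
#' alleles among PD samples or among ILBD samples (which removes SVs
#' present only in healthy controls).
#'
#' @param svs SV table with genotypes.
#' @param panel [cohort_panel()].
#' @param max_missing Maximum fraction of missing genotypes.
#' @param max_af Allele-frequency ceiling.
#' @return `list(kept, removed, counts)` with per-rule removal counts.
#' @export
apply_cohort_filters <- function(svs, panel, max_missing = 0.95, max_af = 0.99) {
  dos <- sv_dosage_matrix(svs)[, panel$sample, drop = FALSE]
  n_samp <- ncol(dos)
  f_missing <- rowSums(is.na(dos)) / n_samp
  af <- rowSums(dos, na.rm = TRUE) / (2 * rowSums(!is.na(dos)))
  ac_pd <- rowSums(dos[, panel$diagnosis == "PD", drop = FALSE], na.rm = TRUE)
  ac_ilbd <- rowSums(dos[, panel$diagnosis == "ILBD", drop = FALSE], na.rm = TRUE)
  fail_miss <- f_missing > max_missing
  fail_af <- is.nan(af) | af >= max_af
  fail_group <- !(ac_pd > 1 | ac_ilbd > 1)
  drop <- fail_miss | fail_af | fail_group
  rule <- vapply(seq_len(nrow(svs)), function(i) {
    paste(c(if (fail_miss[i]) "missingness", if (fail_af[i]) "high_af",
            if (fail_group[i]) "no_case_group_ac"), collapse = ",")
  }, "")
  list(kept = svs[!drop, , drop = FALSE],
       removed = data.frame(id = svs$id[drop], rule = rule[drop],
                            stringsAsFactors = FALSE),
       counts = c(missingness = sum(fail_miss), high_af = sum(fail_af),
                  no_case_group_ac = sum(fail_group)))
}
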