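# End-to-end orchestration: ensemble merge -> QC -> functional selection
# -> expression processing -> association, with a per-stage record ledger
# and a reproducible run manifest.

#' Pipeline configuration
#'
#' All thresholds default to the pipeline's canonical values (merge
#' distance 1 kb, minimum size 50 bp, initial filter 40 bp, confidence
#' thresholds 5 reads / 5 per carrier / MAPQ 20, LD flank 10 kb with r2
#' 0.7, eGene window 100 kb, BH cutoff 0.05).
#'
#' @param seed Integer seed for any stochastic stage.
#' @param merge [merge_params()].
#' @param egene_window Candidate-pair window in bp.
#' @param ld_flank LD annotation flank in bp.
#' @param bh_alpha Significance cutoff on adjusted p.
#' @param region Region label attached to association results.
#' @param out_dir Optional directory for stage outputs (VCF/TSV).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, merge = merge_params(),
                            egene_window = 100000, ld_flank = 10000,
                            bh_alpha = 0.05, region = "region1",
                            out_dir = NULL) {
  structure(list(seed = seed, merge = merge, egene_window = egene_window,
                 ld_flank = ld_flank, bh_alpha = bh_alpha, region = region,
                 out_dir = out_dir), class = "pipeline_config")
}

#' Run the full pipeline on prepared inputs
#'
#' Executes merge, QC, selection, expression processing and association in
#' order, accumulating a per-stage SV count ledger. Stages whose inputs
#' are absent (e.g. no expression data) are skipped and recorded as such.
#'
#' @param inputs A list with elements `callsets` (list of SV tables),
#'   `panel` ([cohort_panel()]), and optionally `masks`, `reads`, `snps`,
#'   `egenes`, `cells` (`list(counts, meta)`), `dosage_override`,
#'   `phased_umis` plus `phased_gt`.
#' @param config A [pipeline_config()].
#' @return `list(svs, candidate_pairs, expression, eqtl, ase, counts,
#'   manifest)`.
#' @export
run_pipeline <- function(inputs, config = pipeline_config()) {
  counts <- list()
  mg <- ensemble_merge(inputs$callsets, config$merge)
  svs <- mg$svs
  counts$merge <- mg$counts

  if (!is.null(inputs$masks)) {
    ex <- exclude_regions(svs, inputs$masks)
    counts$exclude <- c(kept = nrow(ex$kept), removed = nrow(ex$removed))
    svs <- ex$kept
  }
  if (!is.null(inputs$reads)) {
    svs <- annotate_sv_qc(svs, inputs$panel, inputs$reads, inputs$snps,
                          flank = config$ld_flank)
    cf <- apply_confidence_filter(svs)
    counts$confidence <- c(kept = nrow(cf$kept), cf$counts)
    svs <- cf$kept
  }

  pairs <- NULL
  if (!is.null(inputs$egenes)) {
    pairs <- select_near_egenes(svs, inputs$egenes, config$egene_window)
    svs <- svs[svs$id %in% pairs$sv_id | nrow(pairs) == 0L, , drop = FALSE]
    ch <- apply_cohort_filters(svs, inputs$panel)
    counts$cohort_filters <- c(kept = nrow(ch$kept), ch$counts)
    svs <- ch$kept
    pairs <- pairs[pairs$sv_id %in% svs$id, , drop = FALSE]
  }

  expr <- NULL; eqtl <- NULL; ase <- NULL
  if (!is.null(inputs$cells)) {
    norm <- lognormalize_cells(inputs$cells$counts)
    pbs <- pseudobulk_means(norm, inputs$cells$counts, inputs$cells$meta,
                            samples = inputs$panel$sample)
    scaled <- lapply(pbs, function(pb)
      scale_genes(adjust_covariates(pb, inputs$panel)))
    expr <- list(pseudobulk = pbs, scaled = scaled,
                 binary_expr = binary_expression_matrix(pbs),
                 cell_count_ok = cell_count_screen(pbs))
    if (!is.null(pairs) && nrow(pairs)) {
      dos <- if (!is.null(inputs$dosage_override)) inputs$dosage_override else
        sv_dosage_matrix(svs)
      eqtl <- do.call(rbind, lapply(names(scaled), function(ct)
        cis_eqtl_scan(dos, scaled[[ct]]$values, pairs, cell_type = ct,
                      region = config$region)))
      if (!is.null(eqtl) && nrow(eqtl)) {
        eqtl <- bh_adjust(eqtl, alpha = config$bh_alpha)
      }
    }
    if (!is.null(inputs$phased_umis) && !is.null(inputs$phased_gt) &&
        !is.null(pairs) && nrow(pairs)) {
      ac <- aggregate_ase_counts(inputs$phased_umis, inputs$phased_gt,
                                 inputs$cells$meta)
      ac <- merge(ac, pairs, by.x = "gene", by.y = "gene_id")
      ase <- ase_scan(ac, region = config$region)
      if (nrow(ase)) ase <- bh_adjust(ase, alpha = config$bh_alpha)
    }
  }

  manifest <- list(seed = config$seed, config_hash = config_hash(config),
                   n_svs = nrow(svs),
                   package_version = as.character(utils::packageVersion("svcellreg")))
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_sv_vcf(qc_columns_to_info(svs),
                 file.path(config$out_dir, "cohort_svs.vcf"))
    if (!is.null(eqtl)) {
      write.table(eqtl, file.path(config$out_dir, "eqtl_results.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(ase)) {
      write.table(ase, file.path(config$out_dir, "ase_results.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  list(svs = svs, candidate_pairs = pairs, expression = expr, eqtl = eqtl,
       ase = ase, counts = counts, manifest = manifest)
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(config[setdiff(names(config), "out_dir")]), f)
  unname(tools::md5sum(f))
}
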