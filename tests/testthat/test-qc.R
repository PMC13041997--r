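test_that("region exclusion removes masked and sex-chromosome SVs exactly", {
  # 50 SVs: 12 planted inside masks, 3 on chrX, rest clear
  set.seed(3)
  pos_clear <- seq(100000L, by = 50000L, length.out = 35L)
  pos_masked <- seq(2000000L, by = 10000L, length.out = 12L)
  svs <- rbind(
    mk_svs(pos_clear, svlen = -100L),
    mk_svs(pos_masked, svlen = -100L),
    mk_svs(c(500L, 600L, 700L), chrom = "chrX", svlen = -100L))
  masks <- data.frame(chrom = "chr1", start = 1999000L, end = 2200000L)
  res <- exclude_regions(svs, masks)
  expect_identical(nrow(res$kept), 35L)
  expect_identical(nrow(res$kept) + nrow(res$removed), nrow(svs))
  # per-record oracle: no survivor overlaps the mask
  expect_true(all(res$kept$end < 1999000L | res$kept$pos - 1L >= 2200000L))

  # 1 bp edge overlap removes; INS breakpoint just outside is kept
  edge <- mk_svs(1998901L, svlen = -100L)           # span [1998900, 1999001)
  expect_identical(nrow(exclude_regions(edge, masks)$kept), 0L)
  ins_out <- mk_svs(1998991L, svtype = "INS", svlen = 60L) # base [1998990,1998991)
  expect_identical(nrow(exclude_regions(ins_out, masks)$kept), 1L)
})

test_that("carrier annotation computes group rates from dosages", {
  panel <- cohort_panel(paste0("S", 1:6),
                        c("HC", "HC", "ILBD", "ILBD", "PD", "PD"))
  gt <- setNames(c("0/1", "0/0", "0/0", "0/0", "1/1", "0|1"), panel$sample)
  car <- annotate_carriers(gt, panel)
  expect_identical(car$control_rate, 0.5)
  expect_identical(car$case_rate, 0.5)
  expect_identical(car$carriers$PD, c("S5", "S6"))

  # all-reference genotypes
  ref <- setNames(rep("0/0", 6), panel$sample)
  car0 <- annotate_carriers(ref, panel)
  expect_identical(car0$case_rate, 0)
  expect_identical(unname(lengths(car0$carriers)), c(0L, 0L, 0L))

  # missing genotype: not a carrier, but stays in the denominator
  mis <- setNames(c("./.", "0/0", "0/0", "0/0", "0/0", "0/0"), panel$sample)
  expect_identical(annotate_carriers(mis, panel)$control_rate, 0)
})

test_that("read support counts primary overlapping reads over carriers", {
  sv <- mk_svs(1001L, svlen = -200L)  # span [1000, 1201)
  reads <- data.frame(
    read_id = sprintf("r%02d", 1:12),
    chrom = "chr1",
    start = c(rep(900L, 6), rep(1100L, 4), 900L, 5000L),
    end = c(rep(1500L, 6), rep(1600L, 4), 1500L, 6000L),
    mapq = 60L,
    supplementary = c(rep(FALSE, 10), TRUE, FALSE),
    sample = c(rep("A", 6), rep("B", 4), "A", "A"))
  m <- read_support_metrics(sv, reads, carriers = c("A", "B"))
  expect_identical(m$total_reads, 10L)
  expect_identical(m$avg_reads_per_sample, 5)
  expect_identical(m$avg_map_quality, 60)

  # supplementary-only evidence counts zero
  supp_only <- reads[reads$supplementary, , drop = FALSE]
  expect_identical(read_support_metrics(sv, supp_only, "A")$total_reads, 0L)

  # zero carriers flags the SV
  expect_true(read_support_metrics(sv, reads, character())$flagged)

  # INS breakpoint must be fully contained
  ins <- mk_svs(1000L, svtype = "INS", svlen = 60L)
  tight <- data.frame(read_id = "r1", chrom = "chr1", start = 999L, end = 1000L,
                      mapq = 60L, supplementary = FALSE, sample = "A")
  expect_identical(read_support_metrics(ins, tight, "A")$total_reads, 1L)
  off <- transform(tight, start = 1000L, end = 1100L)
  expect_identical(read_support_metrics(ins, off, "A")$total_reads, 0L)
})

test_that("LD r2 matches an independent Pearson implementation", {
  sv <- mk_svs(50000L, svlen = -100L)
  samples <- paste0("S", 1:6)
  sv_dos <- setNames(c(0, 1, 2, 1, 0, 2), samples)
  snp_dos <- rbind(c(0, 1, 1, 1, 0, 2))
  colnames(snp_dos) <- samples
  snps <- list(chrom = "chr1", pos = 50500L, dosage = snp_dos)
  ld <- ld_metrics(sv_dos, snps, sv)
  expect_equal(ld$r2, oracle_pearson_r2(sv_dos, snp_dos[1, ]), tolerance = 1e-12)

  # twenty random dosage pairs against the closed form
  set.seed(21)
  for (k in 1:20) {
    x <- setNames(sample(0:2, 30, replace = TRUE), paste0("S", 1:30))
    y <- matrix(sample(0:2, 30, replace = TRUE), 1,
                dimnames = list(NULL, names(x)))
    ld_k <- ld_metrics(x, list(chrom = "chr1", pos = 50100L, dosage = y), sv)
    expect_equal(ld_k$r2, oracle_pearson_r2(x, y[1, ]), tolerance = 1e-12)
    expect_true(is.na(ld_k$r2) || (ld_k$r2 >= -1e-12 && ld_k$r2 <= 1 + 1e-12))
  }
})

test_that("r2 is invariant under allele complement and self-correlation is 1", {
  sv <- mk_svs(50000L, svlen = -100L)
  samples <- paste0("S", 1:8)
  sv_dos <- setNames(c(0, 1, 2, 1, 0, 2, 1, 1), samples)
  self <- matrix(sv_dos, 1, dimnames = list(NULL, samples))
  flip <- matrix(2 - sv_dos, 1, dimnames = list(NULL, samples))
  expect_equal(ld_metrics(sv_dos, list(chrom = "chr1", pos = 50100L, dosage = self), sv)$r2,
               1, tolerance = 1e-12)
  expect_equal(ld_metrics(sv_dos, list(chrom = "chr1", pos = 50100L, dosage = flip), sv)$r2,
               1, tolerance = 1e-12)
})

test_that("zero-variance SNPs stay in the nearby total but not the LD count", {
  sv <- mk_svs(50000L, svlen = -100L)
  samples <- paste0("S", 1:6)
  sv_dos <- setNames(c(0, 1, 2, 1, 0, 2), samples)
  dos <- rbind(rep(1, 6), sv_dos)
  colnames(dos) <- samples
  ld <- ld_metrics(sv_dos, list(chrom = "chr1", pos = c(50100L, 50200L),
                                dosage = dos), sv)
  expect_identical(ld$total_snps_nearby, 2L)
  expect_identical(ld$ld_snps_count, 1L)
  expect_identical(ld$ld_snp_rate, 0.5)
})

test_that("the flank window measures from both breakpoints", {
  sv <- mk_svs(50000L, svlen = -30000L)  # end = 80000
  samples <- paste0("S", 1:4)
  sv_dos <- setNames(c(0, 1, 2, 1), samples)
  dos <- matrix(rep(c(0, 1, 2, 1), 3), 3, byrow = TRUE,
                dimnames = list(NULL, samples))
  snps <- list(chrom = rep("chr1", 3),
               pos = c(41000L, 89000L, 65000L),  # near pos, near end, interior
               dosage = dos)
  ld <- ld_metrics(sv_dos, snps, sv, flank = 10000)
  expect_identical(ld$total_snps_nearby, 2L)
})

test_that("confidence filter applies the strict less-than thresholds", {
  gt <- mk_gt(c("0/1", "0/0"), c("0/1", "0/0"), c("0/1", "0/0"),
              c("0/0", "0/0"))
  svs <- mk_svs(c(1L, 2L, 3L, 4L) * 1000L, svlen = -100L, gt = gt)
  svs$TOTAL_READS <- c(5L, 4L, 5L, 5L)
  svs$AVG_READS_PER_SAMPLE <- c(5, 5, 4.9, 5)
  svs$AVG_MAP_QUALITY <- c(20, 20, 20, 20)
  res <- apply_confidence_filter(svs)
  # boundary record (5, 5.0, 20.0, AC=1) is kept
  expect_identical(res$kept$pos, 1000L)
  expect_identical(unname(res$counts["total_reads_lt_5"]), 1L)
  expect_identical(unname(res$counts["avg_reads_lt_5"]), 1L)
  expect_identical(unname(res$counts["alt_allele_count_lt_1"]), 1L)
})

test_that("confidence filter removal set equals the rule-by-rule oracle", {
  set.seed(5)
  n <- 200L
  gt <- matrix(sample(c("0/1", "0/0"), n * 4, replace = TRUE, prob = c(0.8, 0.2)),
               n, 4, dimnames = list(NULL, paste0("S", 1:4)))
  svs <- mk_svs(seq_len(n) * 1000L, svlen = -100L, gt = gt)
  svs$TOTAL_READS <- sample(c(4L, 5L, 30L), n, replace = TRUE)
  svs$AVG_READS_PER_SAMPLE <- sample(c(4.5, 5, 12), n, replace = TRUE)
  svs$AVG_MAP_QUALITY <- sample(c(19.9, 20, 60), n, replace = TRUE)
  ac <- rowSums(gt_dosage(gt))
  oracle_drop <- svs$TOTAL_READS < 5 | svs$AVG_READS_PER_SAMPLE < 5 |
    svs$AVG_MAP_QUALITY < 20 | ac < 1
  res <- apply_confidence_filter(svs)
  expect_identical(sort(res$removed$id), sort(svs$id[oracle_drop]))
  # per-rule counts conserved against independent scans
  expect_identical(unname(res$counts["total_reads_lt_5"]), sum(svs$TOTAL_READS < 5))
  expect_identical(unname(res$counts["avg_mapq_lt_20"]), sum(svs$AVG_MAP_QUALITY < 20))
  # unannotated records are removed with that reason
  svs2 <- svs[1:3, , drop = FALSE]
  svs2$TOTAL_READS <- NA_integer_
  expect_true(all(grepl("unannotated", apply_confidence_filter(svs2)$removed$rule)))
})

test_that("full QC annotation wraps carriers, reads and LD per SV", {
  panel <- cohort_panel(paste0("S", 1:4), c("HC", "HC", "PD", "PD"))
  gt <- mk_gt(c("0/0", "0/1", "1/1", "0/0"), samples = panel$sample)
  svs <- mk_svs(5000L, svlen = -100L, gt = gt)
  reads <- data.frame(read_id = sprintf("r%d", 1:8), chrom = "chr1",
                      start = 4800L, end = 5400L, mapq = 60L,
                      supplementary = FALSE,
                      sample = rep(c("S2", "S3"), each = 4))
  dos <- matrix(gt_dosage(gt[1, ]), 1, dimnames = list(NULL, panel$sample))
  snps <- list(chrom = "chr1", pos = 6000L, dosage = dos)
  ann <- annotate_sv_qc(svs, panel, reads, snps)
  expect_identical(ann$TOTAL_READS, 8L)
  expect_identical(ann$AVG_READS_PER_SAMPLE, 4)
  expect_identical(ann$CASE_RATE, 0.5)
  expect_identical(ann$CONTROL_RATE, 0.5)
  expect_identical(ann$LD_SNPS_COUNT, 1L)
  expect_identical(ann$LD_SNP_RATE, 1)
})
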