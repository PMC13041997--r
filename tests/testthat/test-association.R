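test_that("eQTL slopes equal the normal-equations oracle", {
  set.seed(51)
  samples <- sprintf("S%03d", 1:6)
  dos <- matrix(c(0, 0, 1, 1, 2, 2), 1, dimnames = list("sv1", samples))
  expr <- matrix(c(0.1, -0.1, 0.5, 0.6, 1.0, 1.1), 1,
                 dimnames = list("g1", samples))
  res <- cis_eqtl_scan(dos, expr, data.frame(sv_id = "sv1", gene_id = "g1"))
  expect_equal(res$effect_size, oracle_ols_slope(expr[1, ], dos[1, ]),
               tolerance = 1e-10)
  expect_identical(res$n_used, 6L)

  # with covariates, against the multi-column normal equations
  for (k in 1:5) {
    n <- 10L
    x <- sample(0:2, n, replace = TRUE)
    cv <- matrix(rnorm(2 * n), n, dimnames = list(sprintf("S%03d", 1:n), NULL))
    y <- 0.4 * x + cv %*% c(0.5, -0.3) + rnorm(n, 0, 0.1)
    d2 <- matrix(x, 1, dimnames = list("sv1", rownames(cv)))
    e2 <- matrix(as.numeric(y), 1, dimnames = list("g1", rownames(cv)))
    got <- cis_eqtl_scan(d2, e2, data.frame(sv_id = "sv1", gene_id = "g1"),
                         covariates = cv)
    expect_equal(got$effect_size, oracle_ols_slope(as.numeric(y), x, cv),
                 tolerance = 1e-10)
  }
})

test_that("a perfect dosage-expression fit gives a vanishing p-value", {
  samples <- sprintf("S%03d", 1:100)
  x <- rep(0:2, length.out = 100)
  dos <- matrix(x, 1, dimnames = list("sv1", samples))
  expr <- matrix(x + rnorm(100, 0, 1e-8), 1, dimnames = list("g1", samples))
  res <- cis_eqtl_scan(dos, expr, data.frame(sv_id = "sv1", gene_id = "g1"))
  expect_lt(res$p_value, 1e-10)
})

test_that("monomorphic dosages and missing values are handled pairwise", {
  samples <- sprintf("S%03d", 1:10)
  dos <- matrix(c(rep(1, 10), c(NA, 0:2, rep(1, 6))), 2, byrow = TRUE,
                dimnames = list(c("svA", "svB"), samples))
  expr <- matrix(rnorm(10), 1, dimnames = list("g1", samples))
  pairs <- data.frame(sv_id = c("svA", "svB"), gene_id = "g1")
  res <- cis_eqtl_scan(dos, expr, pairs)
  expect_identical(res$sv_id, "svB")     # monomorphic svA skipped
  expect_identical(res$n_used, 9L)       # one missing dosage dropped
})

test_that("BH adjustment follows the step-up formula within scope groups", {
  res <- data.frame(region = "r1", test = "eQTL",
                    p_value = c(0.01, 0.02, 0.03, 0.9))
  adj <- bh_adjust(res)
  expect_equal(adj$p_adj, c(0.04, 0.04, 0.04, 0.9))
  expect_true(all(adj$p_adj >= adj$p_value))
  one <- bh_adjust(data.frame(region = "r1", test = "eQTL", p_value = 0.2))
  expect_identical(one$p_adj, 0.2)
  all1 <- bh_adjust(data.frame(region = "r1", test = "ASE",
                               p_value = rep(1, 5)))
  expect_true(all(all1$p_adj == 1))
  # grouping is per region x test
  two <- bh_adjust(data.frame(region = c("r1", "r2"), test = "eQTL",
                              p_value = c(0.04, 0.04)))
  expect_equal(two$p_adj, c(0.04, 0.04))
  # BH is monotone: sorted p implies sorted p_adj
  set.seed(8)
  p <- sort(runif(50))
  m <- bh_adjust(data.frame(region = "r", test = "t", p_value = p))
  expect_false(is.unsorted(m$p_adj))
})

test_that("ASE aggregation orients alternate counts by the phased genotype", {
  meta <- data.frame(cell = c("c1", "c2", "c3"), sample = c("A", "A", "B"),
                     cell_type = "ct1")
  umis <- data.frame(cell = c("c1", "c2", "c3"), gene = "g1",
                     hap1_umis = c(4, 3, 7), hap2_umis = c(2, 1, 3))
  gt <- c(A = "0|1", B = "1|0")
  agg <- aggregate_ase_counts(umis, gt, meta)
  # A: 0|1, alt on hap2: alt = 2+1 = 3, total = 10
  expect_identical(agg$alt_umis[agg$sample == "A"], 3)
  expect_identical(agg$total_umis[agg$sample == "A"], 10)
  # B: 1|0, alt on hap1: alt = 7
  expect_identical(agg$alt_umis[agg$sample == "B"], 7)
  # unphased samples are excluded
  gt2 <- c(A = "0|1", B = "./.")
  expect_identical(unique(aggregate_ase_counts(umis, gt2, meta)$sample), "A")
})

test_that("balanced counts give effect 0 and p near 1", {
  counts <- data.frame(alt_umis = rep(10, 5), total_umis = rep(20, 5))
  t <- beta_binomial_imbalance_test(counts)
  expect_equal(t$effect_size, 0, tolerance = 1e-4)
  expect_gt(t$p_value, 0.9)
})

test_that("fully imbalanced counts are strongly significant", {
  # under the free-overdispersion null the likelihood ratio grows roughly
  # linearly in the number of consistently imbalanced samples (the null can
  # place half its mass at each extreme, costing ~log 2 per sample)
  t5 <- beta_binomial_imbalance_test(
    data.frame(alt_umis = rep(20, 5), total_umis = rep(20, 5)))
  expect_lt(t5$p_value, 0.01)
  expect_true(t5$boundary)
  expect_gt(t5$effect_size, 0)
  t20 <- beta_binomial_imbalance_test(
    data.frame(alt_umis = rep(20, 20), total_umis = rep(20, 20)))
  expect_lt(t20$p_value, 1e-6)
  expect_lt(t20$p_value, t5$p_value)
})

test_that("the test respects its sample and depth preconditions", {
  expect_null(beta_binomial_imbalance_test(
    data.frame(alt_umis = 3, total_umis = 6)))       # one sample
  expect_null(beta_binomial_imbalance_test(
    data.frame(alt_umis = c(1, 1), total_umis = c(4, 4))))  # pooled < 10
  expect_null(beta_binomial_imbalance_test(
    data.frame(alt_umis = c(0, 0), total_umis = c(0, 0))))
})

test_that("flipping phased genotypes negates ASE effects, p unchanged", {
  set.seed(61)
  meta <- data.frame(cell = sprintf("c%02d", 1:20),
                     sample = rep(sprintf("S%d", 1:5), each = 4),
                     cell_type = "ct1")
  umis <- data.frame(cell = meta$cell, gene = "g1",
                     hap1_umis = rbinom(20, 30, 0.75),
                     hap2_umis = rbinom(20, 30, 0.25))
  gt <- setNames(rep("0|1", 5), unique(meta$sample))
  flip <- setNames(rep("1|0", 5), unique(meta$sample))
  t1 <- beta_binomial_imbalance_test(aggregate_ase_counts(umis, gt, meta))
  t2 <- beta_binomial_imbalance_test(aggregate_ase_counts(umis, flip, meta))
  expect_equal(t1$effect_size, -t2$effect_size, tolerance = 1e-3)
  expect_equal(t1$p_value, t2$p_value, tolerance = 1e-6)
})

test_that("specificity classification matches the four-way truth table", {
  cts <- c("sig", "o1", "o2")
  screen <- function(expr_o1, expr_o2, cells_o1, cells_o2) {
    be <- matrix(c(TRUE, expr_o1, expr_o2), 1,
                 dimnames = list("g1", cts))
    cc <- c(sig = TRUE, o1 = cells_o1, o2 = cells_o2)
    classify_cell_type_specificity("sig", "g1", be, cc)
  }
  # enumerate all realizable combinations and compare to the mapping
  for (e1 in c(TRUE, FALSE)) for (e2 in c(TRUE, FALSE))
    for (c1 in c(TRUE, FALSE)) for (c2 in c(TRUE, FALSE)) {
      got <- screen(e1, e2, c1, c2)
      E <- c("o1", "o2")[c(e1, e2)]
      C <- c("o1", "o2")[c(c1, c2)]
      want <- if (length(intersect(E, C))) "potential_regulatory_specificity"
      else if (length(E) == 0 && length(C) > 0) "low_expression"
      else if (length(E) > 0) "low_cell_number"
      else "low_expression_and_cell_number"
      expect_identical(got, want)
    }
})

test_that("genotype PCs separate planted ancestry clusters and prune LD", {
  set.seed(71)
  n_snp <- 120L; n_samp <- 60L
  grp <- rep(c(0, 1), each = n_samp / 2)
  af1 <- runif(n_snp, 0.2, 0.5)
  af2 <- pmin(0.95, af1 + 0.3)
  dos <- t(vapply(seq_len(n_snp), function(i)
    rbinom(n_samp, 2, ifelse(grp == 1, af2[i], af1[i])), numeric(n_samp)))
  colnames(dos) <- sprintf("S%02d", 1:n_samp)
  pcs <- compute_genotype_pcs(dos, chrom = rep("chr1", n_snp),
                              pos = seq_len(n_snp) * 1000L, n_pcs = 2)
  # silhouette-style check: PC1 separates the two groups
  m1 <- mean(pcs[grp == 0, 1]); m2 <- mean(pcs[grp == 1, 1])
  s <- sd(c(pcs[grp == 0, 1] - m1, pcs[grp == 1, 1] - m2))
  expect_gt(abs(m1 - m2) / s, 2)

  # duplicated SNP columns: one of each pair pruned (|r| = 1)
  # duplicated SNP columns (|r| = 1): one of each pair pruned; build from
  # unstructured genotypes so no other pair correlates above the threshold
  iid <- t(vapply(1:10, function(i) rbinom(200, 2, 0.5), numeric(200)))
  colnames(iid) <- sprintf("T%03d", 1:200)
  dup <- rbind(iid, iid)
  expect_warning(
    pcs2 <- compute_genotype_pcs(dup, chrom = rep("chr1", 20),
                                 pos = seq_len(20) * 100L, n_pcs = 15),
    "PC")
  expect_identical(ncol(pcs2), 10L)
})

test_that("effect-size correlations recover planted MAF dependence", {
  set.seed(81)
  n <- 60L
  maf <- runif(n, 0.05, 0.5)
  eff <- 1 / sqrt(maf) * 0.2 * (1 + rnorm(n, 0, 0.1))
  res <- data.frame(sv_id = sprintf("chr1_%d_DEL_-100", seq_len(n) * 1000L),
                    gene_id = "g1", cell_type = "ct1", region = "r1",
                    test = "eQTL", effect_size = eff,
                    p_value = runif(n), n_used = 50L)
  names(maf) <- res$sv_id
  svlen <- setNames(rep(-100, n), res$sv_id)
  pc <- sv_property_correlations(res, maf, svlen)
  row <- pc$property_correlations
  expect_lt(row$r[row$property == "maf"], 0)
  # exact linear dependence gives |r| = 1
  res2 <- res
  res2$effect_size <- 2 * maf + 1
  pc2 <- sv_property_correlations(res2, maf, svlen)
  expect_equal(abs(pc2$property_correlations$r[1]), 1, tolerance = 1e-12)
})

test_that("eQTL and ASE effect concordance is summarized over significant pairs", {
  base <- data.frame(sv_id = sprintf("chr1_%d_INS_60", 1:10), gene_id = "g1",
                     cell_type = "ct1", region = "r1", stringsAsFactors = FALSE)
  eq <- transform(base, test = "eQTL", effect_size = seq(-1, 1, length.out = 10),
                  p_value = 0.001, n_used = 50L, significant = TRUE)
  as_ <- transform(base, test = "ASE", effect_size = seq(-1, 1, length.out = 10) +
                     rnorm(10, 0, 0.01), p_value = 0.001, n_used = 5L,
                   significant = TRUE)
  res <- rbind(eq, as_)
  maf <- setNames(runif(10, 0.1, 0.4), base$sv_id)
  svlen <- setNames(rep(60, 10), base$sv_id)
  out <- sv_property_correlations(res, maf, svlen)
  expect_gt(out$concordance$r, 0.99)
  expect_gte(out$concordance$sign_agreement, 0.9)
})
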