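test_that("log-normalization follows the closed form and is scale-invariant", {
  counts <- Matrix::Matrix(matrix(c(100, 9900, 0, 0, 50, 50), nrow = 3,
                                  dimnames = list(paste0("g", 1:3),
                                                  c("c1", "c2"))),
                           sparse = TRUE)
  norm <- lognormalize_cells(counts)
  expect_equal(norm["g1", "c1"], log(101))  # 100 / 10000 * 1e4 = 100
  expect_equal(norm["g3", "c1"], 0)         # count 0 -> ln(1) = 0
  doubled <- lognormalize_cells(counts * 2)
  expect_equal(as.matrix(doubled), as.matrix(norm))
  with_zero <- cbind(counts, c3 = c(0, 0, 0))
  expect_warning(lognormalize_cells(with_zero), "all-zero")
})

test_that("pseudobulk means equal a naive group-by-mean oracle", {
  set.seed(41)
  n_genes <- 20L; n_cells <- 500L
  counts <- Matrix::Matrix(matrix(rpois(n_genes * n_cells, 3), n_genes,
                                  dimnames = list(sprintf("g%02d", 1:n_genes),
                                                  sprintf("c%03d", 1:n_cells))),
                           sparse = TRUE)
  meta <- data.frame(cell = colnames(counts),
                     sample = sample(paste0("S", 1:5), n_cells, replace = TRUE),
                     cell_type = sample(c("ctA", "ctB"), n_cells, replace = TRUE))
  norm <- lognormalize_cells(counts)
  pb <- pseudobulk_means(norm, counts, meta)
  dense <- as.matrix(norm)
  for (ct in c("ctA", "ctB")) {
    for (s in paste0("S", 1:5)) {
      cols <- meta$cell[meta$sample == s & meta$cell_type == ct]
      want <- rowMeans(dense[, cols, drop = FALSE])
      expect_equal(pb[[ct]]$values[, s], want, tolerance = 1e-12)
      expect_identical(unname(pb[[ct]]$cells_per_sample[s]), length(cols))
    }
  }
  # single cell: pseudobulk equals that cell
  one <- meta[1, , drop = FALSE]
  pb1 <- pseudobulk_means(norm[, one$cell, drop = FALSE],
                          counts[, one$cell, drop = FALSE], one)
  expect_equal(pb1[[one$cell_type]]$values[, one$sample], dense[, one$cell])
})

test_that("samples with zero cells of a type get missing columns", {
  counts <- Matrix::Matrix(matrix(1:6, 2, dimnames = list(c("g1", "g2"),
                                                          c("c1", "c2", "c3"))),
                           sparse = TRUE)
  meta <- data.frame(cell = c("c1", "c2", "c3"),
                     sample = c("S1", "S1", "S2"),
                     cell_type = c("A", "A", "B"))
  pb <- pseudobulk_means(lognormalize_cells(counts), counts, meta,
                         samples = c("S1", "S2"))
  expect_true(all(is.na(pb$A$values[, "S2"])))
  expect_true(all(is.na(pb$B$values[, "S1"])))
})

simulate_pb <- function(n_samples = 40, n_genes = 30, batch_shift = 0,
                        seed = 1) {
  set.seed(seed)
  panel <- cohort_panel(sprintf("S%02d", 1:n_samples),
                        sample(c("HC", "ILBD", "PD"), n_samples, TRUE),
                        batch = rep(c("b1", "b2"), length.out = n_samples),
                        age = rnorm(n_samples, 78, 6),
                        sex = sample(c("M", "F"), n_samples, TRUE),
                        pmi = rnorm(n_samples, 6, 2),
                        rin = rnorm(n_samples, 7, 1))
  vals <- matrix(rnorm(n_genes * n_samples), n_genes, n_samples,
                 dimnames = list(sprintf("g%02d", 1:n_genes), panel$sample))
  vals[, panel$batch == "b2"] <- vals[, panel$batch == "b2"] + batch_shift
  list(pb = list(values = vals, stage = "lognorm_mean",
                 cells_per_sample = setNames(rep(10L, n_samples), panel$sample)),
       panel = panel)
}

test_that("batch adjustment removes planted additive batch shifts", {
  sim <- simulate_pb(batch_shift = 2, seed = 2)
  adj <- adjust_covariates(sim$pb, sim$panel, k_sva = 5)
  b2 <- sim$panel$batch == "b2"
  var_explained <- function(m) {
    mean(apply(m, 1, function(v) {
      f <- summary(lm(v ~ b2))$r.squared
      f
    }))
  }
  expect_lt(var_explained(adj$values), 0.05 * var_explained(sim$pb$values))
  expect_identical(adj$stage, "covariate_adjusted")
})

test_that("adjusted expression is orthogonal to covariates and surrogates", {
  sim <- simulate_pb(seed = 3)
  adj <- adjust_covariates(sim$pb, sim$panel, k_sva = 5)
  res <- t(adj$values)
  for (j in seq_len(ncol(adj$covariates))) {
    expect_lt(max(abs(cor(res, adj$covariates[, j]))), 1e-8)
  }
  for (j in seq_len(ncol(adj$sv))) {
    expect_lt(max(abs(cor(res, adj$sv[, j]))), 1e-8)
  }
})

test_that("with no batch or covariate structure adjustment is centering", {
  set.seed(4)
  n <- 40L
  panel <- cohort_panel(sprintf("S%02d", 1:n),
                        sample(c("HC", "PD"), n, TRUE), batch = "b1")
  vals <- matrix(rnorm(30 * n), 30, n,
                 dimnames = list(sprintf("g%02d", 1:30), panel$sample))
  pb <- list(values = vals, stage = "lognorm_mean",
             cells_per_sample = setNames(rep(10L, n), panel$sample))
  adj <- adjust_covariates(pb, panel, k_sva = 0)
  centered <- vals - rowMeans(vals)
  cors <- vapply(seq_len(nrow(centered)), function(i)
    cor(adj$values[i, ], centered[i, ]), 1)
  expect_gt(min(cors), 0.99)
  # with null covariates present, the adjusted data stay highly correlated
  sim <- simulate_pb(seed = 4)
  adj2 <- adjust_covariates(sim$pb, sim$panel, k_sva = 0)
  centered2 <- sim$pb$values - rowMeans(sim$pb$values)
  cors2 <- vapply(seq_len(nrow(centered2)), function(i)
    cor(adj2$values[i, ], centered2[i, ]), 1)
  expect_gt(min(cors2), 0.7)
})

test_that("gene scaling yields zero mean, unit variance, and is idempotent", {
  sim <- simulate_pb(seed = 5)
  adj <- adjust_covariates(sim$pb, sim$panel, k_sva = 3)
  sc <- scale_genes(adj)
  expect_lt(max(abs(rowMeans(sc$values))), 1e-12)
  expect_lt(max(abs(apply(sc$values, 1, sd) - 1)), 1e-9)
  expect_equal((1:3 - 2) / sd(1:3), scale(1:3)[, 1])
  again <- scale_genes(sc)
  expect_equal(again$values, sc$values, tolerance = 1e-9)
  # constant gene flattens to zero and is flagged
  adj$values[1, ] <- 5
  sc2 <- scale_genes(adj)
  expect_true(all(sc2$values[1, ] == 0))
  expect_true("g01" %in% attr(sc2, "zero_variance"))
})

test_that("binary expression uses strict >0.1 UMI and >50% sample rules", {
  mk_pb <- function(mean_umi, n_cells = 10L) {
    samples <- sprintf("S%03d", seq_along(mean_umi))
    list(values = NULL,
         raw_mean_umi = matrix(mean_umi, 1, dimnames = list("g1", samples)),
         cells_per_sample = setNames(rep(n_cells, length(mean_umi)), samples))
  }
  # 51 of 100 above threshold: TRUE
  expect_true(binary_expression_matrix(
    list(ct = mk_pb(c(rep(0.2, 51), rep(0, 49)))))["g1", "ct"])
  # exactly 50 of 100: FALSE
  expect_false(binary_expression_matrix(
    list(ct = mk_pb(c(rep(0.2, 50), rep(0, 50)))))["g1", "ct"])
  # mean UMI exactly 0.1 does not count
  expect_false(binary_expression_matrix(
    list(ct = mk_pb(rep(0.1, 10))))["g1", "ct"])
})

test_that("cell-count screen takes the median across individuals", {
  mk <- function(counts) list(cells_per_sample = counts)
  expect_true(cell_count_screen(list(a = mk(c(9, 9, 9))))[["a"]])
  expect_false(cell_count_screen(list(a = mk(c(1, 2, 100))))[["a"]])
  expect_true(cell_count_screen(list(a = mk(c(8, 9, 10))))[["a"]])
})
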