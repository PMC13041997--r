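# Cell-level normalization, per-cell-type pseudobulk aggregation,
# covariate adjustment with surrogate variables, gene scaling, and the
# expression / cell-count screens used by the specificity classifier.

#' Log-normalize a cell-level count matrix
#'
#' Per cell: `ln(1 + count / cell_total * scale_factor)` (scale factor
#' 10,000). All-zero cells are dropped with a warning.
#'
#' @param counts Gene x cell matrix (dense or `Matrix` sparse) of UMI
#'   counts.
#' @param scale_factor Library-size target (default 1e4).
#' @return Normalized matrix of the same class, possibly with fewer
#'   columns.
#' @export
lognormalize_cells <- function(counts, scale_factor = 10000) {
  totals <- Matrix::colSums(counts)
  if (any(totals == 0)) {
    warning(sum(totals == 0), " all-zero cell(s) dropped")
    counts <- counts[, totals > 0, drop = FALSE]
    totals <- totals[totals > 0]
  }
  norm <- counts %*% Matrix::Diagonal(x = scale_factor / totals)
  colnames(norm) <- colnames(counts)
  log1p(norm)
}

#' Per-cell-type pseudobulk means
#'
#' For every cell type and sample, the mean over that sample's cells of
#' that type (gene-wise). Samples with zero cells of a type get `NA`
#' columns. Returns both the normalized-mean matrices and a raw mean-UMI
#' companion (used by the binary expression screen).
#'
#' @param norm Normalized gene x cell matrix ([lognormalize_cells()]).
#' @param raw_counts Raw gene x cell UMI matrix (same cells).
#' @param meta Cell metadata `data.frame(cell, sample, cell_type, ...)`;
#'   rows must cover the matrix columns.
#' @param samples Ordered sample universe (columns of the output).
#' @return A list per cell type, each
#'   `list(values, raw_mean_umi, stage = "lognorm_mean", cells_per_sample)`.
#' @export
pseudobulk_means <- function(norm, raw_counts, meta, samples = NULL) {
  meta <- meta[match(colnames(norm), meta$cell), , drop = FALSE]
  if (is.null(samples)) samples <- sort(unique(meta$sample))
  out <- list()
  for (ct in sort(unique(meta$cell_type))) {
    in_ct <- meta$cell_type == ct
    values <- matrix(NA_real_, nrow(norm), length(samples),
                     dimnames = list(rownames(norm), samples))
    rawm <- values
    cps <- setNames(integer(length(samples)), samples)
    for (s in samples) {
      cols <- which(in_ct & meta$sample == s)
      cps[s] <- length(cols)
      if (length(cols)) {
        values[, s] <- Matrix::rowMeans(norm[, cols, drop = FALSE])
        rawm[, s] <- Matrix::rowMeans(raw_counts[, cols, drop = FALSE])
      }
    }
    out[[ct]] <- list(values = values, raw_mean_umi = rawm,
                      stage = "lognorm_mean", cells_per_sample = cps)
  }
  out
}

# residualize columns of y (samples x genes) on design X (with intercept)
residualize <- function(y, X) {
  X <- cbind(Intercept = 1, X)
  qrX <- qr(X)
  keep <- qrX$pivot[seq_len(qrX$rank)]
  if (qrX$rank < ncol(X)) {
    warning("rank-deficient design: dropping ", ncol(X) - qrX$rank,
            " collinear column(s)")
    qrX <- qr(X[, keep, drop = FALSE])
  }
  qr.resid(qrX, y)
}

#' Adjust pseudobulk expression for batch, known and hidden covariates
#'
#' Three stages, all deterministic: (1) per gene and batch, mean-center
#' and rescale to the pooled variance (location/scale batch adjustment; no
#' empirical-Bayes shrinkage); (2) residualize on the known covariates and
#' take the top `k = min(k_sva, n - p - 1)` principal components of the
#' residual matrix as surrogate variables; (3) residualize expression on
#' known covariates plus surrogate variables. `NA` sample columns (zero
#' cells) are carried through untouched.
#'
#' @param pb One cell type's pseudobulk entry from [pseudobulk_means()]
#'   (or any list with a gene x sample `values` matrix).
#' @param panel [cohort_panel()] supplying `batch`, `age`, `sex`, `pmi`,
#'   `rin` per sample.
#' @param k_sva Number of surrogate dimensions requested (default 30).
#' @return The input list with `values` replaced by the adjusted matrix,
#'   `stage = "covariate_adjusted"`, and the surrogate variables in `sv`.
#' @export
adjust_covariates <- function(pb, panel, k_sva = 30) {
  vals <- pb$values
  use <- colnames(vals)[colSums(is.na(vals)) < nrow(vals)]
  x <- t(vals[, use, drop = FALSE])          # samples x genes
  p <- panel[match(use, panel$sample), , drop = FALSE]

  batch <- as.factor(p$batch)
  if (nlevels(batch) > 1L) {
    for (g in seq_len(ncol(x))) {
      v <- x[, g]
      mu_b <- tapply(v, batch, mean)
      sd_b <- tapply(v, batch, sd)
      pooled_sd <- sd(v - mu_b[batch])
      z <- v - mu_b[batch]
      scale_ok <- !is.na(sd_b[batch]) & sd_b[batch] > 0 & pooled_sd > 0
      z[scale_ok] <- z[scale_ok] / sd_b[batch][scale_ok] * pooled_sd
      x[, g] <- z + mean(v)
    }
  } else {
    x <- scale(x, center = TRUE, scale = FALSE)
  }

  covars <- covariate_design(p)
  res <- residualize(x, covars)
  k <- max(0L, min(k_sva, nrow(x) - ncol(covars) - 2L))
  sv <- NULL
  if (k > 0L) {
    pc <- prcomp(res, center = TRUE, scale. = FALSE)
    k <- min(k, ncol(pc$x))
    sv <- pc$x[, seq_len(k), drop = FALSE]
    # deterministic orientation: largest-magnitude loading positive
    for (j in seq_len(k)) {
      l <- pc$rotation[, j]
      if (l[which.max(abs(l))] < 0) sv[, j] <- -sv[, j]
    }
    colnames(sv) <- paste0("SV", seq_len(k))
  }
  adj <- residualize(x, cbind(covars, sv))
  vals[, use] <- t(adj)
  out <- pb
  out$values <- vals
  out$stage <- "covariate_adjusted"
  out$sv <- sv
  out$covariates <- covars
  out
}

# numeric design matrix of known covariates (age, sex, PMI, RIN)
covariate_design <- function(p) {
  sex_num <- if (is.numeric(p$sex)) p$sex else as.numeric(factor(p$sex))
  m <- cbind(age = as.numeric(p$age), sex = sex_num,
             pmi = as.numeric(p$pmi), rin = as.numeric(p$rin))
  m[, colSums(is.na(m)) == 0 & apply(m, 2, sd) > 0, drop = FALSE]
}

#' Scale genes to zero mean and unit variance across samples
#'
#' Zero-variance genes are left at 0 and flagged in attribute
#' `"zero_variance"`.
#'
#' @param pb Pseudobulk entry at stage `covariate_adjusted`.
#' @return The entry with `values` row-scaled, `stage = "scaled"`.
#' @export
scale_genes <- function(pb) {
  vals <- pb$values
  use <- colSums(is.na(vals)) < nrow(vals)
  m <- vals[, use, drop = FALSE]
  mu <- rowMeans(m)
  sdv <- apply(m, 1, sd)
  zero <- sdv == 0 | is.na(sdv)
  scaled <- (m - mu) / ifelse(zero, 1, sdv)
  scaled[zero, ] <- 0
  vals[, use] <- scaled
  out <- pb
  out$values <- vals
  out$stage <- "scaled"
  attr(out, "zero_variance") <- rownames(m)[zero]
  out
}

#' Binary confident-expression matrix
#'
#' A gene is confidently expressed in a cell type when strictly more than
#' `frac` of samples (among samples with at least one cell of the type)
#' have mean UMI strictly greater than `umi_threshold`.
#'
#' @param pb_list Output of [pseudobulk_means()] (uses `raw_mean_umi`).
#' @param umi_threshold Mean-UMI threshold (default 0.1).
#' @param frac Sample-fraction threshold (default 0.5).
#' @return Gene x cell-type logical matrix.
#' @export
binary_expression_matrix <- function(pb_list, umi_threshold = 0.1, frac = 0.5) {
  cts <- names(pb_list)
  genes <- rownames(pb_list[[1]]$raw_mean_umi)
  out <- matrix(FALSE, length(genes), length(cts),
                dimnames = list(genes, cts))
  for (ct in cts) {
    m <- pb_list[[ct]]$raw_mean_umi
    m <- m[, pb_list[[ct]]$cells_per_sample[colnames(m)] > 0, drop = FALSE]
    if (ncol(m) == 0L) next
    out[, ct] <- rowMeans(m > umi_threshold) > frac
  }
  out
}

#' Cell-count screen per cell type
#'
#' A cell type passes when the median cell count across individuals is at
#' least `min_median` (default 9; the boundary is inclusive).
#'
#' @param pb_list Output of [pseudobulk_means()] (uses
#'   `cells_per_sample`).
#' @param min_median Minimum median cell count.
#' @return Named logical vector per cell type.
#' @export
cell_count_screen <- function(pb_list, min_median = 9) {
  vapply(pb_list, function(pb) median(pb$cells_per_sample) >= min_median, TRUE)
}
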