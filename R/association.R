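# cis-SV-eQTL regression, genotype principal components, allele-specific
# expression aggregation and beta-binomial imbalance testing, BH
# adjustment, cell-type-specificity classification, and effect-size
# analytics.

#' Genotype principal components
#'
#' SNPs are filtered to MAF >= `maf` and missingness <= `miss`, LD-pruned
#' greedily (a SNP is dropped when `|r|` with any retained SNP within
#' `window` bp exceeds `ld_threshold`, default `sqrt(0.1)`), mean-imputed,
#' standardized, and decomposed by PCA. Autosomal input is assumed.
#'
#' @param dosage SNP x sample numeric dosage matrix (0/1/2, NA missing).
#' @param chrom,pos SNP coordinates aligned with rows of `dosage`.
#' @param n_pcs Number of components to return (default 6).
#' @param maf,miss,ld_threshold,window Filtering/pruning parameters.
#' @return Sample x PC matrix (fewer columns, with a warning, when fewer
#'   SNPs survive pruning).
#' @export
compute_genotype_pcs <- function(dosage, chrom, pos, n_pcs = 6,
                                 maf = 0.05, miss = 0.05,
                                 ld_threshold = sqrt(0.1), window = 1e7) {
  af <- rowMeans(dosage, na.rm = TRUE) / 2
  keep <- pmin(af, 1 - af) >= maf & rowMeans(is.na(dosage)) <= miss
  dosage <- dosage[keep, , drop = FALSE]
  chrom <- chrom[keep]; pos <- pos[keep]
  ord <- order(chrom, pos)
  retained <- integer()
  for (i in ord) {
    cand <- retained[chrom[retained] == chrom[i] &
                       abs(pos[retained] - pos[i]) <= window]
    ok <- TRUE
    for (j in cand) {
      r <- suppressWarnings(cor(dosage[i, ], dosage[j, ],
                                use = "pairwise.complete.obs"))
      if (!is.na(r) && abs(r) > ld_threshold) { ok <- FALSE; break }
    }
    if (ok) retained <- c(retained, i)
  }
  m <- dosage[retained, , drop = FALSE]
  for (i in seq_len(nrow(m))) {
    m[i, is.na(m[i, ])] <- mean(m[i, ], na.rm = TRUE)
  }
  sds <- apply(m, 1, sd)
  m <- m[sds > 0, , drop = FALSE]
  z <- t(scale(t(m)))
  pc <- prcomp(t(z), center = FALSE, scale. = FALSE)
  k <- min(n_pcs, ncol(pc$x))
  if (k < n_pcs) warning("only ", k, " PC(s) available after pruning")
  out <- pc$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    l <- pc$rotation[, j]
    if (l[which.max(abs(l))] < 0) out[, j] <- -out[, j]
  }
  rownames(out) <- colnames(dosage)
  out
}

# OLS slope of y on x with optional covariates; returns slope, t p-value
ols_assoc <- function(y, x, covars = NULL) {
  X <- cbind(1, x, covars)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
    qrX <- qr(X)
  }
  beta <- qr.coef(qrX, y)
  res <- y - X %*% beta
  df <- length(y) - ncol(X)
  if (df <= 0) return(list(slope = NA_real_, p = NA_real_))
  sigma2 <- sum(res^2) / df
  xtxi <- chol2inv(qr.R(qrX))
  se <- sqrt(sigma2 * xtxi[2, 2])
  tval <- beta[2] / se
  list(slope = unname(beta[2]), p = 2 * pt(-abs(tval), df))
}

#' cis-SV-eQTL scan
#'
#' For each candidate SV-gene pair and cell type, ordinary least squares
#' of scaled pseudobulk expression on SV dosage (plus optional covariates,
#' e.g. genotype PCs). The effect size is the dosage slope; p comes from
#' its t statistic. Samples missing dosage or expression are dropped
#' pairwise; pairs monomorphic among used samples are skipped.
#'
#' @param dosages SV x sample dosage matrix (rownames = SV ids).
#' @param expression Gene x sample scaled pseudobulk matrix (a
#'   [scale_genes()] `values` matrix).
#' @param pairs `data.frame(sv_id, gene_id)` candidate pairs.
#' @param cell_type,region Labels recorded in the results.
#' @param covariates Optional sample x covariate matrix.
#' @return `data.frame` of association results (`test = "eQTL"`).
#' @export
cis_eqtl_scan <- function(dosages, expression, pairs, cell_type = NA_character_,
                          region = NA_character_, covariates = NULL) {
  res <- vector("list", nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    sv <- pairs$sv_id[k]; gene <- pairs$gene_id[k]
    if (!sv %in% rownames(dosages) || !gene %in% rownames(expression)) next
    samples <- intersect(colnames(dosages), colnames(expression))
    x <- dosages[sv, samples]
    y <- expression[gene, samples]
    ok <- !is.na(x) & !is.na(y)
    if (!is.null(covariates)) {
      cv <- covariates[samples, , drop = FALSE]
      ok <- ok & stats::complete.cases(cv)
    }
    if (sum(ok) < 3L || length(unique(x[ok])) < 2L) next
    fit <- ols_assoc(y[ok], x[ok],
                     if (!is.null(covariates)) covariates[samples, , drop = FALSE][ok, , drop = FALSE])
    res[[k]] <- data.frame(sv_id = sv, gene_id = gene, cell_type = cell_type,
                           region = region, test = "eQTL",
                           effect_size = fit$slope, p_value = fit$p,
                           n_used = sum(ok), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(sv_id = character(), gene_id = character(),
                      cell_type = character(), region = character(),
                      test = character(), effect_size = numeric(),
                      p_value = numeric(), n_used = integer(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Aggregate phased UMI counts into allele-specific expression counts
#'
#' Restricted to samples heterozygous for the SV with a phased genotype.
#' The alternate-haplotype count is the haplotype-2 UMI count for `0|1`
#' samples and the haplotype-1 count for `1|0`; totals sum both
#' haplotypes, over each sample's cells of the cell type.
#'
#' @param phased_umis `data.frame(cell, gene, hap1_umis, hap2_umis)`.
#' @param phased_gt Named vector of phased SV genotypes per sample
#'   (`"0|1"`, `"1|0"`, others excluded).
#' @param meta Cell metadata `data.frame(cell, sample, cell_type)`.
#' @return `data.frame(sample, gene, cell_type, alt_umis, total_umis)`.
#' @export
aggregate_ase_counts <- function(phased_umis, phased_gt, meta) {
  het <- names(phased_gt)[phased_gt %in% c("0|1", "1|0")]
  m <- meta[match(phased_umis$cell, meta$cell), , drop = FALSE]
  use <- m$sample %in% het
  if (!any(use)) {
    return(data.frame(sample = character(), gene = character(),
                      cell_type = character(), alt_umis = integer(),
                      total_umis = integer(), stringsAsFactors = FALSE))
  }
  d <- cbind(phased_umis[use, , drop = FALSE],
             sample = m$sample[use], cell_type = m$cell_type[use])
  alt_is_h2 <- phased_gt[d$sample] == "0|1"
  d$alt <- ifelse(alt_is_h2, d$hap2_umis, d$hap1_umis)
  d$tot <- d$hap1_umis + d$hap2_umis
  agg <- stats::aggregate(cbind(alt_umis = alt, total_umis = tot) ~
                            sample + gene + cell_type, data = d, FUN = sum)
  agg[order(agg$gene, agg$cell_type, agg$sample), , drop = FALSE]
}

# beta-binomial log-likelihood; mu mean, phi overdispersion in (0,1)
betabin_loglik <- function(alt, tot, mu, phi) {
  if (phi < 1e-8) return(sum(stats::dbinom(alt, tot, mu, log = TRUE)))
  a <- mu * (1 - phi) / phi
  b <- (1 - mu) * (1 - phi) / phi
  sum(lchoose(tot, alt) + lbeta(alt + a, tot - alt + b) - lbeta(a, b))
}

#' Beta-binomial test of allelic imbalance
#'
#' Counts for one SV-gene-cell-type trio are modelled as beta-binomial
#' with mean `mu` and overdispersion `phi` shared across samples. The null
#' fixes `mu = 0.5` with free `phi`; the alternative frees both. The
#' p-value comes from the likelihood-ratio statistic against chi-square
#' with 1 df; the effect size is `logit(mu_hat)` (clamped away from the
#' boundary using a half-count offset when `mu_hat` hits 0 or 1).
#'
#' @param counts `data.frame` with `alt_umis` and `total_umis` per sample.
#' @param min_total Minimum pooled total UMIs (default 10).
#' @param min_samples Minimum samples with nonzero totals (default 2).
#' @return `list(effect_size, mu_hat, phi_hat, p_value, n_used,
#'   boundary)`, or `NULL` when the preconditions fail.
#' @export
beta_binomial_imbalance_test <- function(counts, min_total = 10,
                                         min_samples = 2) {
  alt <- counts$alt_umis; tot <- counts$total_umis
  use <- tot >= 1
  alt <- alt[use]; tot <- tot[use]
  if (length(tot) < min_samples || sum(tot) < min_total) return(NULL)

  nll_null <- function(lphi) -betabin_loglik(alt, tot, 0.5, plogis(lphi))
  opt0 <- optimize(nll_null, c(-12, 6))
  ll0 <- -opt0$objective

  nll_alt <- function(par) -betabin_loglik(alt, tot, plogis(par[1]), plogis(par[2]))
  mu0 <- sum(alt) / sum(tot)
  mu0c <- min(max(mu0, 1 / (sum(tot) + 2)), 1 - 1 / (sum(tot) + 2))
  opt1 <- optim(c(qlogis(mu0c), opt0$minimum), nll_alt, method = "Nelder-Mead",
                control = list(maxit = 500, reltol = 1e-10))
  ll1 <- -opt1$value
  mu_hat <- plogis(opt1$par[1])
  phi_hat <- plogis(opt1$par[2])
  lrt <- max(0, 2 * (ll1 - ll0))
  boundary <- mu0 %in% c(0, 1)
  eff_mu <- if (boundary) {
    if (mu0 == 0) 0.5 / (sum(tot) + 1) else 1 - 0.5 / (sum(tot) + 1)
  } else mu_hat
  list(effect_size = qlogis(eff_mu), mu_hat = mu_hat, phi_hat = phi_hat,
       p_value = pchisq(lrt, df = 1, lower.tail = FALSE),
       n_used = length(tot), boundary = boundary)
}

#' Run the ASE test over all SV-gene-cell-type groups
#'
#' @param ase [aggregate_ase_counts()] output with an `sv_id` column.
#' @param region Region label recorded in the results.
#' @param ... Passed to [beta_binomial_imbalance_test()].
#' @return `data.frame` of association results (`test = "ASE"`).
#' @export
ase_scan <- function(ase, region = NA_character_, ...) {
  keys <- unique(ase[, c("sv_id", "gene", "cell_type")])
  res <- vector("list", nrow(keys))
  for (k in seq_len(nrow(keys))) {
    sub <- ase[ase$sv_id == keys$sv_id[k] & ase$gene == keys$gene[k] &
                 ase$cell_type == keys$cell_type[k], , drop = FALSE]
    t <- beta_binomial_imbalance_test(sub, ...)
    if (is.null(t)) next
    res[[k]] <- data.frame(sv_id = keys$sv_id[k], gene_id = keys$gene[k],
                           cell_type = keys$cell_type[k], region = region,
                           test = "ASE", effect_size = t$effect_size,
                           p_value = t$p_value, n_used = t$n_used,
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  if (is.null(out)) out <- data.frame()
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg adjustment within scope groups
#'
#' @param results Association results `data.frame` with `p_value`.
#' @param scope Character vector of grouping columns (default
#'   `c("region", "test")`, pooling cell types within each).
#' @param alpha Significance cutoff on adjusted p (default 0.05).
#' @return The results with `p_adj` and logical `significant` columns.
#' @export
bh_adjust <- function(results, scope = c("region", "test"), alpha = 0.05) {
  if (nrow(results) == 0L) {
    results$p_adj <- numeric(0); results$significant <- logical(0)
    return(results)
  }
  scope <- intersect(scope, names(results))
  grp <- if (length(scope)) interaction(results[scope], drop = TRUE) else
    factor(rep(1, nrow(results)))
  results$p_adj <- NA_real_
  for (g in levels(grp)) {
    i <- grp == g
    results$p_adj[i] <- p.adjust(results$p_value[i], method = "BH")
  }
  results$significant <- results$p_adj <= alpha
  results
}

#' Classify why a pair is significant in only one cell type
#'
#' For a pair significant in exactly one cell type S, with E the other
#' cell types where the gene is confidently expressed and C the other cell
#' types passing the cell-count screen: `potential_regulatory_specificity`
#' when some other cell type is in both E and C; `low_expression` when E
#' is empty but C is not; `low_cell_number` when E is non-empty but E and
#' C are disjoint; `low_expression_and_cell_number` when both are empty.
#'
#' @param sig_cell_type The single significant cell type.
#' @param gene_id Gene of the pair.
#' @param binary_expr Gene x cell-type logical matrix
#'   ([binary_expression_matrix()]).
#' @param cell_count_ok Named logical per cell type
#'   ([cell_count_screen()]).
#' @return One of the four category strings.
#' @export
classify_cell_type_specificity <- function(sig_cell_type, gene_id,
                                           binary_expr, cell_count_ok) {
  others <- setdiff(colnames(binary_expr), sig_cell_type)
  E <- others[binary_expr[gene_id, others]]
  C <- others[cell_count_ok[others]]
  if (length(intersect(E, C))) return("potential_regulatory_specificity")
  if (length(E) == 0L && length(C) > 0L) return("low_expression")
  if (length(E) > 0L) return("low_cell_number")
  "low_expression_and_cell_number"
}

#' Correlate SV properties with effect sizes; eQTL/ASE concordance
#'
#' Pearson correlation between absolute effect sizes and each SV property
#' (minor allele frequency, absolute length), per cell type and SV type,
#' with BH adjustment. Concordance between eQTL and ASE effect sizes is
#' summarized by Pearson r and a sign-agreement fraction over pairs
#' significant in at least one of the two tests.
#'
#' @param results Association results (with `p_adj`).
#' @param maf Named numeric vector sv_id -> minor allele frequency.
#' @param svlen Named numeric vector sv_id -> signed length.
#' @param min_n Minimum results per stratum (default 3).
#' @return `list(property_correlations, concordance)`.
#' @export
sv_property_correlations <- function(results, maf, svlen, min_n = 3) {
  eq <- results[results$test == "eQTL", , drop = FALSE]
  eq$svtype <- vapply(strsplit(eq$sv_id, "_"), `[`, "", 3L)
  strata <- unique(eq[, c("cell_type", "svtype")])
  rows <- list()
  for (k in seq_len(nrow(strata))) {
    sub <- eq[eq$cell_type == strata$cell_type[k] &
                eq$svtype == strata$svtype[k], , drop = FALSE]
    if (nrow(sub) < min_n) next
    for (prop in c("maf", "svlen")) {
      v <- if (prop == "maf") maf[sub$sv_id] else abs(svlen[sub$sv_id])
      if (sd(v, na.rm = TRUE) == 0 || sd(abs(sub$effect_size)) == 0) next
      ct <- stats::cor.test(abs(sub$effect_size), v)
      rows[[length(rows) + 1L]] <- data.frame(
        cell_type = strata$cell_type[k], svtype = strata$svtype[k],
        property = prop, r = unname(ct$estimate), p_value = ct$p.value,
        n = nrow(sub), stringsAsFactors = FALSE)
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cell_type = character(), svtype = character(),
               property = character(), r = numeric(), p_value = numeric(),
               n = integer(), stringsAsFactors = FALSE)
  if (nrow(tab)) tab$p_adj <- p.adjust(tab$p_value, method = "BH")

  concordance <- NULL
  as_ <- results[results$test == "ASE", , drop = FALSE]
  if (nrow(as_) && nrow(eq)) {
    key <- function(d) paste(d$sv_id, d$gene_id, d$cell_type)
    m <- match(key(eq), key(as_))
    ok <- !is.na(m)
    sig <- ok & (isTRUE_vec(eq$significant) | isTRUE_vec(as_$significant[m]))
    if (sum(sig) >= 2L) {
      e1 <- eq$effect_size[sig]; e2 <- as_$effect_size[m[sig]]
      concordance <- list(r = cor(e1, e2),
                          sign_agreement = mean(sign(e1) == sign(e2)),
                          n = sum(sig))
    }
  }
  list(property_correlations = tab, concordance = concordance)
}

isTRUE_vec <- function(x) if (is.null(x)) FALSE else !is.na(x) & x
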