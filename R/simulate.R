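# Synthetic-data generator: emits every pipeline input with known ground
# truth (cohort panel, truth SVs, per-caller callsets with configurable
# error profiles, phased SNPs in target LD with SVs, haplotype-tagged long
# reads, and cell-level expression with planted eQTL and allelic-imbalance
# effects). All randomness flows from the config seed.

#' Simulation configuration
#'
#' Defaults emulate the study conditions: a 100-sample cohort split
#' 34 HC / 31 ILBD / 35 PD; an SV size mixture with modes near 60, 300 and
#' 6000 bp; three callers with breakpoint jitter (sd 20 bp), 5% false
#' negatives, 5% genotype errors, and one caller that reports duplications
#' but no insertions.
#'
#' @param seed Integer master seed.
#' @param n_samples Cohort size.
#' @param diag_weights Diagnosis proportions (HC, ILBD, PD).
#' @param genome Named contig lengths in bp.
#' @param n_sv Named per-type truth SV counts.
#' @param size_mixture `list(meanlog, sdlog, weights)` of the lognormal
#'   size mixture.
#' @param af_shape1,af_shape2 Beta parameters of the allele-frequency
#'   distribution.
#' @param caller_profiles Named list of caller error profiles; each has
#'   `types`, `fn_rate`, `jitter_sd`, `len_noise`, `gt_error`,
#'   `ins_to_dup`.
#' @param n_cell_types,n_genes,cells_per_sample,nb_size Expression
#'   settings.
#' @param depth,read_len,base_error,mapq,supp_rate Read-simulation
#'   settings.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_samples = 100L,
                       diag_weights = c(HC = 34, ILBD = 31, PD = 35),
                       genome = c(chr1 = 2e7, chr2 = 2e7),
                       n_sv = c(INS = 150L, DEL = 250L, DUP = 50L, INV = 50L),
                       size_mixture = list(meanlog = log(c(60, 300, 6000)),
                                           sdlog = c(0.3, 0.3, 0.3),
                                           weights = c(0.5, 0.35, 0.15)),
                       af_shape1 = 0.8, af_shape2 = 3.2,
                       caller_profiles = list(
                         caller_a = list(types = c("DEL", "DUP", "INV"),
                                         fn_rate = 0.05, jitter_sd = 20,
                                         len_noise = 0.05, gt_error = 0.05,
                                         ins_to_dup = 0),
                         caller_b = list(types = c("INS", "DEL", "DUP", "INV"),
                                         fn_rate = 0.05, jitter_sd = 20,
                                         len_noise = 0.05, gt_error = 0.05,
                                         ins_to_dup = 0),
                         caller_c = list(types = c("INS", "DEL", "DUP", "INV"),
                                         fn_rate = 0.05, jitter_sd = 20,
                                         len_noise = 0.05, gt_error = 0.05,
                                         ins_to_dup = 0)),
                       n_cell_types = 3L, n_genes = 60L,
                       cells_per_sample = 40, nb_size = 4,
                       depth = 20, read_len = 8000, base_error = 0,
                       mapq = 60, supp_rate = 0.01) {
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a cohort panel
#'
#' Samples receive a diagnosis at the configured proportions and
#' covariates: two sequencing batches, age ~ N(78, 7), sex ~ Bernoulli,
#' post-mortem interval ~ N(6, 2) h, RIN ~ N(7, 0.8).
#'
#' @param cfg A [sim_config()].
#' @return A [cohort_panel()].
#' @export
simulate_cohort <- function(cfg) {
  set.seed(cfg$seed + 101L)
  n <- cfg$n_samples
  w <- cfg$diag_weights / sum(cfg$diag_weights)
  counts <- diff(round(cumsum(c(0, w)) * n))
  diag <- rep(names(cfg$diag_weights), counts)
  if (length(diag) < n) diag <- c(diag, rep(names(w)[length(w)], n - length(diag)))
  diag <- sample(diag[seq_len(n)])
  cohort_panel(sample = sprintf("S%03d", seq_len(n)), diagnosis = diag,
               batch = sample(c("b1", "b2"), n, replace = TRUE),
               age = round(rnorm(n, 78, 7), 1),
               sex = sample(c("M", "F"), n, replace = TRUE),
               pmi = round(pmax(1, rnorm(n, 6, 2)), 1),
               rin = round(pmin(10, pmax(4, rnorm(n, 7, 0.8))), 1))
}

draw_sizes <- function(n, mix) {
  comp <- sample.int(length(mix$weights), n, replace = TRUE, prob = mix$weights)
  pmax(50L, as.integer(round(stats::rlnorm(n, mix$meanlog[comp], mix$sdlog[comp]))))
}

#' Simulate truth SVs and per-sample, per-caller callsets
#'
#' Truth SVs are placed uniformly in the genome with sizes from the
#' configured mixture; allele frequencies come from the Beta distribution
#' and per-sample genotypes follow Hardy-Weinberg (phased haplotypes are
#' kept). Each caller's output applies its profile: undetectable types
#' dropped, Bernoulli false negatives, Gaussian breakpoint/length jitter
#' (rounded), genotype errors (het/hom swaps), and INS-to-DUP relabelling.
#'
#' @param cfg A [sim_config()].
#' @param panel A [cohort_panel()].
#' @return `list(truth, hap1, hap2, callsets, truth_map)`: the truth SV
#'   table (with phased `gt`), haplotype matrices, a list of per-(sample,
#'   caller) SV tables, and a linkage table `(caller, sample, record_id,
#'   truth_id)`.
#' @export
simulate_sv_truth_and_callers <- function(cfg, panel) {
  set.seed(cfg$seed + 202L)
  n_sv <- sum(cfg$n_sv)
  svtype <- rep(names(cfg$n_sv), cfg$n_sv)
  chrom <- sample(names(cfg$genome), n_sv, replace = TRUE,
                  prob = cfg$genome / sum(cfg$genome))
  sizes <- draw_sizes(n_sv, cfg$size_mixture)
  pos <- vapply(seq_len(n_sv), function(i) {
    as.integer(ceiling(runif(1, 1e4, cfg$genome[chrom[i]] - sizes[i] - 1e4)))
  }, 1L)
  svlen <- ifelse(svtype == "DEL", -sizes, sizes)
  af <- rbeta(n_sv, cfg$af_shape1, cfg$af_shape2)
  af <- pmin(pmax(af, 0.02), 0.8)
  ns <- nrow(panel)
  hap1 <- matrix(rbinom(n_sv * ns, 1, af), n_sv, ns,
                 dimnames = list(NULL, panel$sample))
  hap2 <- matrix(rbinom(n_sv * ns, 1, af), n_sv, ns,
                 dimnames = list(NULL, panel$sample))
  gt <- matrix(paste0(hap1, "|", hap2), n_sv, ns,
               dimnames = list(NULL, panel$sample))
  alt_seq <- ifelse(svtype == "INS",
                    vapply(sizes, function(s) paste(sample(c("A", "C", "G", "T"),
                                                           min(s, 200), replace = TRUE),
                                                    collapse = ""), ""),
                    NA_character_)
  truth <- sv_table(chrom = chrom, pos = pos, svtype = svtype, svlen = svlen,
                    alt_seq = alt_seq, strand1 = "+", strand2 = "-",
                    callers = "truth", gt = gt)
  truth$af <- af
  rownames(hap1) <- rownames(hap2) <- truth$id

  callsets <- list()
  map <- list()
  dos <- hap1 + hap2
  for (cl in names(cfg$caller_profiles)) {
    prof <- cfg$caller_profiles[[cl]]
    for (s in panel$sample) {
      idx <- which(dos[, s] >= 1L & truth$svtype %in% prof$types)
      idx <- idx[runif(length(idx)) >= prof$fn_rate]
      if (!length(idx)) next
      tp <- truth$svtype[idx]
      relab <- tp == "INS" & runif(length(idx)) < prof$ins_to_dup
      tp[relab] <- "DUP"
      jpos <- pmax(1L, truth$pos[idx] +
                     as.integer(round(rnorm(length(idx), 0, prof$jitter_sd))))
      jlen <- as.integer(round(truth$svlen[idx] *
                                 (1 + rnorm(length(idx), 0, prof$len_noise))))
      jlen[jlen == 0] <- truth$svlen[idx][jlen == 0]
      jlen <- ifelse(tp == "DEL", -abs(jlen), abs(jlen))
      g <- truth$gt[idx, s]
      d <- gt_dosage(g)
      err <- runif(length(idx)) < prof$gt_error
      d[err] <- ifelse(d[err] == 1L, 2L, 1L)
      g_out <- c("0/0", "0/1", "1/1")[d + 1L]
      gm <- matrix(g_out, ncol = 1, dimnames = list(NULL, s))
      cs <- sv_table(chrom = truth$chrom[idx], pos = jpos, svtype = tp,
                     svlen = jlen,
                     alt_seq = ifelse(tp == "INS", truth$alt_seq[idx], NA),
                     strand1 = "+", strand2 = "-", callers = cl, sample = s,
                     gt = gm)
      callsets[[paste(cl, s, sep = ".")]] <- cs
      map[[paste(cl, s, sep = ".")]] <- data.frame(
        caller = cl, sample = s, record_id = cs$id, truth_id = truth$id[idx],
        stringsAsFactors = FALSE)
    }
  }
  list(truth = truth, hap1 = hap1, hap2 = hap2, callsets = callsets,
       truth_map = do.call(rbind, c(map, list(make.row.names = FALSE))))
}

#' Simulate a phased SNP panel in target LD with the truth SVs
#'
#' Each SV receives `tags_per_sv` tag SNPs within the flank at the target
#' r-squared (constructed by copying the SV haplotypes and redrawing a
#' computed fraction), plus independent background SNPs.
#'
#' @param cfg A [sim_config()].
#' @param truth Output of [simulate_sv_truth_and_callers()].
#' @param panel A [cohort_panel()].
#' @param target_r2 Target r-squared of tag SNPs.
#' @param tags_per_sv Tag SNPs per SV.
#' @param n_background Independent background SNPs.
#' @param flank Tag placement window (bp).
#' @return `list(snps, hap1, hap2, tag_map)`; `snps` has `chrom`, `pos`,
#'   `id`, `ref`, `alt`, a phased `gt` matrix column and a `dosage`
#'   matrix.
#' @export
simulate_snp_panel <- function(cfg, truth, panel, target_r2 = 1,
                               tags_per_sv = 1L, n_background = 200L,
                               flank = 10000) {
  set.seed(cfg$seed + 303L)
  ns <- nrow(panel)
  tv <- truth$truth
  c_copy <- sqrt(target_r2)
  rows <- list(); h1 <- list(); h2 <- list(); tag <- list()
  for (i in seq_len(nrow(tv))) {
    for (t in seq_len(tags_per_sv)) {
      off <- sample(c(-1, 1), 1) * sample.int(flank - 100L, 1)
      p <- max(1L, tv$pos[i] + off)
      redraw1 <- runif(ns) > c_copy
      redraw2 <- runif(ns) > c_copy
      a1 <- ifelse(redraw1, rbinom(ns, 1, tv$af[i]), truth$hap1[i, ])
      a2 <- ifelse(redraw2, rbinom(ns, 1, tv$af[i]), truth$hap2[i, ])
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = tv$chrom[i], pos = p,
        id = sprintf("tag_%s_%d", tv$id[i], t), ref = "A", alt = "G",
        stringsAsFactors = FALSE)
      h1[[length(h1) + 1L]] <- a1
      h2[[length(h2) + 1L]] <- a2
      tag[[length(tag) + 1L]] <- data.frame(snp_id = rows[[length(rows)]]$id,
                                            sv_id = tv$id[i],
                                            stringsAsFactors = FALSE)
    }
  }
  for (b in seq_len(n_background)) {
    chrom <- sample(names(cfg$genome), 1)
    p <- sample.int(cfg$genome[[chrom]], 1)
    afb <- runif(1, 0.1, 0.5)
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = chrom, pos = p, id = sprintf("bg_%04d", b), ref = "A",
      alt = "G", stringsAsFactors = FALSE)
    h1[[length(h1) + 1L]] <- rbinom(ns, 1, afb)
    h2[[length(h2) + 1L]] <- rbinom(ns, 1, afb)
  }
  snps <- do.call(rbind, rows)
  hap1 <- do.call(rbind, h1); hap2 <- do.call(rbind, h2)
  colnames(hap1) <- colnames(hap2) <- panel$sample
  snps$gt <- matrix(paste0(hap1, "|", hap2), nrow(snps), ns,
                    dimnames = list(NULL, panel$sample))
  snps$dosage <- hap1 + hap2
  list(snps = snps, hap1 = hap1, hap2 = hap2,
       tag_map = do.call(rbind, tag))
}

#' Simulate haplotype-tagged long reads for one sample
#'
#' Reads tile each SV locus at the configured depth, drawn from a random
#' haplotype. Each read carries base calls (with error rate
#' `cfg$base_error`) at the sample's heterozygous SNP positions it spans,
#' and an SV-support flag consistent with its haplotype. The true
#' haplotype label is returned separately (hidden from the pipeline).
#'
#' @param cfg A [sim_config()].
#' @param sample_id Sample to simulate.
#' @param truth Output of [simulate_sv_truth_and_callers()].
#' @param snp_panel Output of [simulate_snp_panel()].
#' @param sv_ids SVs whose loci are covered (default: all het SVs of the
#'   sample).
#' @return `list(reads, base_calls, support, het_snps, truth_hap)`.
#' @export
simulate_reads <- function(cfg, sample_id, truth, snp_panel, sv_ids = NULL) {
  set.seed(cfg$seed + 404L + sum(utf8ToInt(sample_id)))
  tv <- truth$truth
  het <- truth$hap1[, sample_id] != truth$hap2[, sample_id]
  if (is.null(sv_ids)) sv_ids <- tv$id[het]
  svs <- tv[tv$id %in% sv_ids, , drop = FALSE]
  s_h1 <- snp_panel$hap1[, sample_id]; s_h2 <- snp_panel$hap2[, sample_id]
  het_snp <- s_h1 != s_h2
  hets <- phased_snps(chrom = snp_panel$snps$chrom[het_snp],
                      pos = snp_panel$snps$pos[het_snp],
                      hap1_base = ifelse(s_h1[het_snp] == 1,
                                         snp_panel$snps$alt[het_snp],
                                         snp_panel$snps$ref[het_snp]),
                      hap2_base = ifelse(s_h2[het_snp] == 1,
                                         snp_panel$snps$alt[het_snp],
                                         snp_panel$snps$ref[het_snp]))
  reads <- list(); calls <- list(); sup <- list(); tlab <- list()
  rid <- 0L
  bases <- c("A", "C", "G", "T")
  for (i in seq_len(nrow(svs))) {
    n_reads <- rpois(1, cfg$depth)
    if (n_reads == 0L) next
    q <- sv_query_interval(svs[i, , drop = FALSE])
    lo <- min(q$start, q$end - cfg$read_len)  # SVs longer than a read cannot be fully spanned
    starts <- as.integer(round(runif(n_reads, lo, q$start)))
    starts <- pmax(0L, starts)
    hap <- rbinom(n_reads, 1, 0.5) + 1L
    for (r in seq_len(n_reads)) {
      rid <- rid + 1L
      id <- sprintf("%s_r%05d", sample_id, rid)
      span <- c(starts[r], starts[r] + cfg$read_len)
      reads[[rid]] <- data.frame(
        read_id = id, chrom = svs$chrom[i], start = span[1], end = span[2],
        mapq = max(0, round(rnorm(1, cfg$mapq, 3))),
        supplementary = runif(1) < cfg$supp_rate, sample = sample_id,
        stringsAsFactors = FALSE)
      tlab[[rid]] <- data.frame(read_id = id, hap = hap[r],
                                stringsAsFactors = FALSE)
      cover <- hets$chrom == svs$chrom[i] & hets$pos > span[1] &
        hets$pos <= span[2]
      if (any(cover)) {
        true_base <- if (hap[r] == 1L) hets$hap1_base[cover] else hets$hap2_base[cover]
        err <- runif(sum(cover)) < cfg$base_error
        obs <- true_base
        if (any(err)) {
          obs[err] <- vapply(true_base[err], function(b)
            sample(setdiff(bases, b), 1), "")
        }
        calls[[length(calls) + 1L]] <- data.frame(
          read_id = id, chrom = svs$chrom[i], pos = hets$pos[cover],
          base = obs, stringsAsFactors = FALSE)
      }
      hap_carries <- if (hap[r] == 1L) truth$hap1[svs$id[i], sample_id] else
        truth$hap2[svs$id[i], sample_id]
      spans_sv <- span[1] <= q$start && span[2] >= q$end
      if (spans_sv && hap_carries == 1L) {
        sup[[length(sup) + 1L]] <- data.frame(read_id = id, sv_id = svs$id[i],
                                              stringsAsFactors = FALSE)
      }
    }
  }
  empty_sup <- data.frame(read_id = character(), sv_id = character(),
                          stringsAsFactors = FALSE)
  list(reads = if (length(reads)) do.call(rbind, reads) else NULL,
       base_calls = if (length(calls)) do.call(rbind, calls) else
         data.frame(read_id = character(), chrom = character(),
                    pos = integer(), base = character()),
       support = if (length(sup)) do.call(rbind, sup) else empty_sup,
       het_snps = hets,
       truth_hap = if (length(tlab)) do.call(rbind, tlab) else NULL)
}

#' Simulate cell-level expression with planted eQTL and allelic imbalance
#'
#' Per cell type and sample, the number of cells is Poisson; per-cell gene
#' UMIs are negative binomial with a log-linear mean:
#' `baseline * exp(batch + covariate + beta * dosage)`. For planted
#' SV-gene pairs in heterozygous samples, each cell's UMIs for the gene
#' are split between haplotypes with a per-sample beta-binomial alternate
#' fraction; the alternate haplotype follows the phased genotype.
#'
#' @param cfg A [sim_config()].
#' @param truth Output of [simulate_sv_truth_and_callers()].
#' @param panel A [cohort_panel()].
#' @param effects `data.frame(sv_id, gene, cell_type, beta)` of planted
#'   eQTL effects (may be empty).
#' @param ase_effects `data.frame(sv_id, gene, mu, phi)` of planted
#'   allelic-imbalance pairs (alternate-allele mean fraction `mu`).
#' @param batch_effect Additive log-scale batch-2 shift (default 0.3).
#' @return `list(counts, meta, phased_umis, baseline)`; `phased_umis` has
#'   `cell`, `gene`, `hap1_umis`, `hap2_umis` for genes in `ase_effects`.
#' @export
simulate_expression <- function(cfg, truth, panel,
                                effects = NULL, ase_effects = NULL,
                                batch_effect = 0.3) {
  set.seed(cfg$seed + 505L)
  genes <- sprintf("G%03d", seq_len(cfg$n_genes))
  cts <- paste0("ct", seq_len(cfg$n_cell_types))
  baseline <- exp(rnorm(cfg$n_genes, log(2), 0.6))
  names(baseline) <- genes
  dos <- truth$hap1 + truth$hap2
  meta <- list(); cols <- list(); phased <- list()
  cell_i <- 0L
  for (s in panel$sample) {
    b_eff <- if (panel$batch[panel$sample == s] == "b2") batch_effect else 0
    age_eff <- 0.004 * (panel$age[panel$sample == s] - 78)
    for (ct in cts) {
      n_cells <- rpois(1, cfg$cells_per_sample)
      if (n_cells == 0L) next
      mu <- baseline * exp(b_eff + age_eff)
      if (!is.null(effects) && nrow(effects)) {
        for (e in which(effects$cell_type == ct)) {
          g <- effects$gene[e]
          d <- dos[effects$sv_id[e], s]
          mu[g] <- mu[g] * exp(effects$beta[e] * d)
        }
      }
      cnt <- matrix(rnbinom(cfg$n_genes * n_cells, mu = mu, size = cfg$nb_size),
                    cfg$n_genes, n_cells)
      ids <- sprintf("c%06d", cell_i + seq_len(n_cells))
      cell_i <- cell_i + n_cells
      cols[[length(cols) + 1L]] <- cnt
      meta[[length(meta) + 1L]] <- data.frame(
        cell = ids, sample = s, cell_type = ct,
        batch = panel$batch[panel$sample == s], stringsAsFactors = FALSE)
      if (!is.null(ase_effects) && nrow(ase_effects)) {
        for (e in seq_len(nrow(ase_effects))) {
          g <- ase_effects$gene[e]
          gt_s <- truth$truth$gt[match(ase_effects$sv_id[e], truth$truth$id), s]
          if (!gt_s %in% c("0|1", "1|0")) next
          phi <- ase_effects$phi[e]
          a <- ase_effects$mu[e] * (1 - phi) / phi
          b <- (1 - ase_effects$mu[e]) * (1 - phi) / phi
          p_s <- rbeta(1, a, b)
          tot <- cnt[match(g, genes), ]
          alt <- rbinom(n_cells, tot, p_s)
          # alt haplotype is hap2 under 0|1, hap1 under 1|0
          h1 <- if (gt_s == "0|1") tot - alt else alt
          phased[[length(phased) + 1L]] <- data.frame(
            cell = ids, gene = g, hap1_umis = h1, hap2_umis = tot - h1,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  counts <- Matrix::Matrix(do.call(cbind, cols), sparse = TRUE)
  meta <- do.call(rbind, meta)
  rownames(counts) <- genes
  colnames(counts) <- meta$cell
  list(counts = counts, meta = meta,
       phased_umis = if (length(phased)) do.call(rbind, phased) else NULL,
       baseline = baseline)
}
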