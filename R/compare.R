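# SV matching under strict and lenient criteria, one-to-one benchmarking
# with precision/recall, and pairwise genotype concordance.

#' Matching parameters
#'
#' `match_params("strict")` requires near-perfect agreement (breakpoint
#' distance 1 bp; sequence, size and reciprocal-overlap similarity all
#' > 99%). `match_params("lenient")` uses the conventional relaxed regime
#' (500 bp breakpoint window, 70% similarity thresholds). Reciprocal
#' overlap is skipped for insertions (no span) and sequence similarity is
#' skipped when either record lacks a sequence.
#'
#' @param mode `"strict"`, `"lenient"`, or `"custom"`.
#' @param refdist Maximum breakpoint distance in bp.
#' @param pctseq,pctsize,pctovl Similarity thresholds in `[0, 1]`.
#' @param dup_to_ins Allow INS records to match DUP records.
#' @return A list of class `match_params`.
#' @export
match_params <- function(mode = c("lenient", "strict", "custom"),
                         refdist = NULL, pctseq = NULL, pctsize = NULL,
                         pctovl = NULL, dup_to_ins = FALSE) {
  mode <- match.arg(mode)
  def <- switch(mode,
                strict = list(refdist = 1, pct = 0.99, ovl = 0.99),
                # relaxed tool defaults: 500 bp window, 70% sequence/size
                # similarity, no reciprocal-overlap requirement
                lenient = list(refdist = 500, pct = 0.7, ovl = 0),
                custom = list(refdist = 500, pct = 0.7, ovl = 0))
  p <- list(refdist = refdist %||% def$refdist,
            pctseq = pctseq %||% def$pct,
            pctsize = pctsize %||% def$pct,
            pctovl = pctovl %||% def$ovl,
            dup_to_ins = dup_to_ins)
  stopifnot(p$refdist >= 0, p$pctseq >= 0, p$pctseq <= 1,
            p$pctsize >= 0, p$pctsize <= 1, p$pctovl >= 0, p$pctovl <= 1)
  structure(p, class = "match_params")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

types_compatible <- function(ta, tb, dup_to_ins) {
  ta == tb | (dup_to_ins & ((ta == "INS" & tb == "DUP") | (ta == "DUP" & tb == "INS")))
}

# similarity components for one pair of records (rows of SV tables)
pair_similarity <- function(a, b) {
  size_sim <- min(abs(a$svlen), abs(b$svlen)) / max(abs(a$svlen), abs(b$svlen))
  span <- a$svtype != "INS" && b$svtype != "INS"
  ovl_sim <- NA_real_
  if (span && a$chrom == b$chrom) {
    inter <- min(a$end, b$end) - max(a$pos, b$pos)
    ovl_sim <- max(0, inter) / max(a$end - a$pos, b$end - b$pos)
  } else if (span) {
    ovl_sim <- 0
  }
  seq_sim <- NA_real_
  if (!is.na(a$alt_seq) && !is.na(b$alt_seq)) {
    d <- utils::adist(a$alt_seq, b$alt_seq)[1, 1]
    seq_sim <- 1 - d / max(nchar(a$alt_seq), nchar(b$alt_seq))
  }
  c(size = size_sim, ovl = ovl_sim, seq = seq_sim)
}

#' Test whether two SV records match
#'
#' Records match when their types are compatible (equal, or INS~DUP when
#' `dup_to_ins`), breakpoints lie within `refdist`, size similarity
#' `min(|len|)/max(|len|) >= pctsize`, reciprocal overlap of the spans
#' `>= pctovl` (span types only), and edit-distance sequence similarity
#' `>= pctseq` (only when both records carry sequences). The similarity
#' triple is returned regardless of the verdict.
#'
#' @param a,b One-row SV tables.
#' @param params A [match_params()] object.
#' @return `list(match = logical, similarity = c(size, ovl, seq))`.
#' @export
sv_match <- function(a, b, params = match_params("lenient")) {
  sim <- pair_similarity(a, b)
  ok <- types_compatible(a$svtype, b$svtype, params$dup_to_ins) &&
    a$chrom == b$chrom &&
    abs(a$pos - b$pos) <= params$refdist &&
    sim["size"] >= params$pctsize &&
    (is.na(sim["ovl"]) || sim["ovl"] >= params$pctovl) &&
    (is.na(sim["seq"]) || sim["seq"] >= params$pctseq)
  list(match = unname(ok), similarity = sim)
}

# all candidate matched pairs between two callsets with mean similarity
candidate_pairs <- function(comp, base, params) {
  out <- list()
  for (i in seq_len(nrow(comp))) {
    cand <- which(base$chrom == comp$chrom[i] &
                    abs(base$pos - comp$pos[i]) <= params$refdist &
                    types_compatible(comp$svtype[i], base$svtype, params$dup_to_ins))
    for (j in cand) {
      m <- sv_match(comp[i, , drop = FALSE], base[j, , drop = FALSE], params)
      if (m$match) {
        out[[length(out) + 1L]] <- data.frame(
          comp = i, base = j, score = mean(m$similarity, na.rm = TRUE),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(comp = integer(), base = integer(), score = numeric()))
  }
  do.call(rbind, out)
}

#' Benchmark a comparison callset against a base callset
#'
#' Candidate matching pairs are scored by mean similarity and accepted
#' greedily best-first under a one-to-one constraint (ties broken by
#' position then id). Precision is the fraction of `comp` records matched;
#' recall the fraction of `base` records matched.
#'
#' @param comp,base SV tables.
#' @param params A [match_params()] object.
#' @return `list(precision, recall, pairs)` where `pairs` is a
#'   `data.frame(comp_id, base_id, score)`. `recall` is `NA` when `base`
#'   is empty.
#' @export
benchmark_callsets <- function(comp, base, params = match_params("lenient")) {
  if (nrow(base) == 0L) {
    return(list(precision = if (nrow(comp)) 0 else NA_real_, recall = NA_real_,
                pairs = data.frame(comp_id = character(), base_id = character(),
                                   score = numeric())))
  }
  cand <- candidate_pairs(comp, base, params)
  ord <- order(-cand$score, comp$pos[cand$comp], comp$id[cand$comp],
               base$pos[cand$base], base$id[cand$base])
  cand <- cand[ord, , drop = FALSE]
  used_c <- logical(nrow(comp)); used_b <- logical(nrow(base))
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    i <- cand$comp[k]; j <- cand$base[k]
    if (!used_c[i] && !used_b[j]) {
      used_c[i] <- used_b[j] <- TRUE
      keep[k] <- TRUE
    }
  }
  pairs <- data.frame(comp_id = comp$id[cand$comp[keep]],
                      base_id = base$id[cand$base[keep]],
                      score = cand$score[keep], stringsAsFactors = FALSE)
  list(precision = if (nrow(comp)) sum(used_c) / nrow(comp) else NA_real_,
       recall = sum(used_b) / nrow(base),
       pairs = pairs)
}

#' Genotype concordance between two matched callsets
#'
#' Over one-to-one matched pairs and shared samples, the fraction of
#' `(SV, sample)` entries whose unordered genotypes agree (allele order and
#' phasing are ignored; missing equals missing). Also stratified by SV
#' type.
#'
#' @param set_a,set_b SV tables with genotypes over shared samples.
#' @param params A [match_params()] object.
#' @return `list(concordance, by_type, n_pairs)`; `concordance` is `NA`
#'   when there are no matched pairs.
#' @export
genotype_concordance <- function(set_a, set_b, params = match_params("lenient")) {
  bm <- benchmark_callsets(set_a, set_b, params)
  if (nrow(bm$pairs) == 0L) {
    return(list(concordance = NA_real_, by_type = NULL, n_pairs = 0L))
  }
  samples <- intersect(colnames(set_a$gt), colnames(set_b$gt))
  ia <- match(bm$pairs$comp_id, set_a$id)
  ib <- match(bm$pairs$base_id, set_b$id)
  norm_gt <- function(g) {
    a1 <- substr(g, 1, 1); a2 <- substr(g, 3, 3)
    ifelse(a1 <= a2, paste0(a1, "/", a2), paste0(a2, "/", a1))
  }
  ga <- norm_gt(set_a$gt[ia, samples, drop = FALSE])
  gb <- norm_gt(set_b$gt[ib, samples, drop = FALSE])
  agree <- ga == gb
  per_pair_type <- set_a$svtype[ia]
  by_type <- tapply(rowMeans(matrix(agree, nrow = length(ia))), per_pair_type, mean)
  list(concordance = mean(agree), by_type = by_type, n_pairs = nrow(bm$pairs))
}
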