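# Ensemble merging of per-sample, per-caller SV callsets into a single
# cohort callset. Mirrors a SURVIVOR-style multi-stage merge: initial
# quality filter, split by SV type, single-linkage clustering within type
# under a breakpoint-distance + strand predicate, INS/DUP reconciliation,
# and a final sorted concatenation.

#' Merge parameters
#'
#' Defaults follow the cohort pipeline: maximum breakpoint distance 1 kb,
#' minimum SV size 50 bp, strand match required, minimum caller support 1.
#'
#' @param max_dist Maximum allowed breakpoint distance in bp.
#' @param min_size Minimum `|svlen|` on entry to the merge.
#' @param require_strand Require strand compatibility for linking.
#' @param min_supp Minimum caller-support count retained in the output.
#' @return A list of class `merge_params`.
#' @export
merge_params <- function(max_dist = 1000, min_size = 50,
                         require_strand = TRUE, min_supp = 1) {
  stopifnot(max_dist >= 0, min_size >= 0, min_supp >= 1)
  structure(list(max_dist = max_dist, min_size = min_size,
                 require_strand = require_strand, min_supp = min_supp),
            class = "merge_params")
}

#' Initial per-caller filter
#'
#' Removes records whose FILTER is not `PASS` and those smaller than 40 bp
#' (`|svlen| < 40`); order is preserved. Returned as `list(kept, removed)`
#' where `removed` records the rule each dropped SV violated.
#'
#' @param svs SV table.
#' @return `list(kept = SV table, removed = data.frame(id, rule))`.
#' @export
initial_filter <- function(svs) {
  not_pass <- svs$filter != "PASS"
  too_small <- abs(svs$svlen) < 40
  rule <- character(nrow(svs))
  rule[too_small] <- "size_lt_40"
  rule[not_pass] <- ifelse(too_small[not_pass], "not_pass,size_lt_40", "not_pass")
  drop <- not_pass | too_small
  list(kept = svs[!drop, , drop = FALSE],
       removed = data.frame(id = svs$id[drop], rule = rule[drop],
                            stringsAsFactors = FALSE))
}

#' Split a callset by SV type
#'
#' Partitions records into per-type lists (`INS`, `DEL`, `DUP`, `INV`).
#' Records of any other type are quarantined and reported.
#'
#' @param svs SV table.
#' @return Named list of SV tables, plus element `quarantined`.
#' @export
split_by_type <- function(svs) {
  known <- svs$svtype %in% SV_TYPES
  out <- lapply(SV_TYPES, function(tp) svs[known & svs$svtype == tp, , drop = FALSE])
  names(out) <- SV_TYPES
  out$quarantined <- svs[!known, , drop = FALSE]
  if (nrow(out$quarantined)) {
    warning(nrow(out$quarantined), " record(s) of unknown svtype quarantined")
  }
  out
}

# union-find with path compression
uf_find <- function(parent, i) {
  while (parent[i] != i) {
    parent[i] <- parent[parent[i]]
    i <- parent[i]
  }
  i
}

# single-linkage cluster ids for one svtype under the pairwise link
# predicate: same chrom, |pos difference| <= max_dist, strands compatible
cluster_links <- function(svs, params) {
  n <- nrow(svs)
  parent <- seq_len(n)
  ord <- order(svs$chrom, svs$pos)
  for (a in seq_len(n - 1L)) {
    i <- ord[a]
    for (b in (a + 1L):n) {
      j <- ord[b]
      if (svs$chrom[j] != svs$chrom[i]) break
      if (svs$pos[j] - svs$pos[i] > params$max_dist) break
      if (!params$require_strand ||
          strands_compatible(svs$strand1[i], svs$strand2[i],
                             svs$strand1[j], svs$strand2[j])) {
        ri <- uf_find(parent, i); rj <- uf_find(parent, j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  vapply(seq_len(n), function(i) uf_find(parent, i), 1L)
}

# the sorted window scan visits every pair within max_dist, so the unions
# realise the exact transitive closure of the link predicate
cluster_single_linkage <- function(svs, params) {
  cl <- cluster_links(svs, params)
  match(cl, unique(cl))
}

#' Merge same-type callsets into cluster representatives
#'
#' Single-linkage clustering on the pairwise predicate (same SV type,
#' breakpoint distance at most `max_dist`, compatible strands when
#' required); each cluster emits one representative record — the record
#' with lexicographically smallest `(pos, caller, sample)`. Callers and
#' support are unioned; per-sample genotypes are merged with priority
#' (representative's caller first, then remaining callers alphabetically),
#' taking the first non-missing call. Records with `|svlen| < min_size` are
#' excluded on entry. Output is sorted by `(chrom, pos)`.
#'
#' @param callsets A list of SV tables (or a single SV table) sharing one
#'   SV type.
#' @param params A [merge_params()] object.
#' @return Merged SV table.
#' @export
merge_within_type <- function(callsets, params = merge_params()) {
  if (is.data.frame(callsets)) callsets <- list(callsets)
  svs <- bind_sv_tables(callsets)
  if (nrow(svs) == 0L) return(svs)
  if (length(unique(svs$svtype)) > 1L) {
    stop("merge_within_type requires a single svtype; got: ",
         paste(unique(svs$svtype), collapse = ", "))
  }
  svs <- svs[abs(svs$svlen) >= params$min_size, , drop = FALSE]
  if (nrow(svs) == 0L) return(svs)
  cl <- cluster_single_linkage(svs, params)
  first_caller <- vapply(strsplit(svs$callers, ","), function(x) sort(x)[1], "")
  samp_key <- ifelse(is.na(svs$sample), "", svs$sample)
  reps <- vapply(split(seq_len(nrow(svs)), cl), function(idx) {
    idx[order(svs$pos[idx], first_caller[idx], samp_key[idx])][1L]
  }, 1L)
  out <- svs[reps, , drop = FALSE]
  clusters <- split(seq_len(nrow(svs)), cl)
  out$callers <- vapply(clusters, function(idx) {
    paste(sort(unique(unlist(strsplit(svs$callers[idx], ",")))), collapse = ",")
  }, "")
  out$supp <- vapply(strsplit(out$callers, ","), length, 1L)
  if (!is.null(svs$gt)) {
    gt <- out$gt
    for (k in seq_along(clusters)) {
      idx <- clusters[[k]]
      if (length(idx) == 1L) next
      rep_caller <- first_caller[reps[k]]
      pri <- order(first_caller[idx] != rep_caller, first_caller[idx], samp_key[idx])
      m <- svs$gt[idx[pri], , drop = FALSE]
      merged <- apply(m, 2L, function(col) {
        nm <- col[gt_known(col)]
        if (length(nm)) nm[1L] else "./."
      })
      gt[k, ] <- merged
    }
    out$gt <- gt
  }
  out$sample <- NA_character_
  out <- out[order(out$chrom, out$pos, out$svlen), , drop = FALSE]
  rownames(out) <- NULL
  out$id <- make_sv_id(out$chrom, out$pos, out$svtype, out$svlen)
  out
}

gt_known <- function(gt) {
  substr(gt, 1, 1) %in% c("0", "1") & substr(gt, 3, 3) %in% c("0", "1")
}

#' Reconcile insertions with co-located duplications
#'
#' A duplication whose breakpoint lies within `refdist` of an insertion
#' breakpoint and whose size similarity `min(|len|)/max(|len|)` is at least
#' 0.7 is linked to that insertion; linked pairs emit one insertion record
#' flagged `POSSIBLE_DUP` (INFO) with callers unioned. Unlinked records
#' pass through unchanged.
#'
#' @param ins_records,dup_records Merged INS and DUP SV tables.
#' @param refdist Maximum breakpoint distance in bp.
#' @param pctsize Size-similarity threshold (default 0.7).
#' @return SV table of insertions (flagged where duplication-supported)
#'   plus unlinked duplications.
#' @export
reconcile_ins_dup <- function(ins_records, dup_records, refdist = 500,
                              pctsize = 0.7) {
  if (is.null(dup_records) || nrow(dup_records) == 0L) return(ins_records)
  if (is.null(ins_records) || nrow(ins_records) == 0L) return(dup_records)
  linked_dup <- logical(nrow(dup_records))
  flag <- logical(nrow(ins_records))
  for (j in seq_len(nrow(dup_records))) {
    cand <- which(ins_records$chrom == dup_records$chrom[j] &
                    abs(ins_records$pos - dup_records$pos[j]) <= refdist)
    if (!length(cand)) next
    ssim <- pmin(abs(ins_records$svlen[cand]), dup_records$svlen[j]) /
      pmax(abs(ins_records$svlen[cand]), dup_records$svlen[j])
    cand <- cand[ssim >= pctsize]
    if (!length(cand)) next
    i <- cand[which.min(abs(ins_records$pos[cand] - dup_records$pos[j]))]
    linked_dup[j] <- TRUE
    flag[i] <- TRUE
    ins_records$callers[i] <- paste(sort(unique(c(
      strsplit(ins_records$callers[i], ",")[[1]],
      strsplit(dup_records$callers[j], ",")[[1]]))), collapse = ",")
  }
  ins_records$supp <- vapply(strsplit(ins_records$callers, ","), length, 1L)
  if (any(flag)) {
    if (is.null(ins_records$info)) ins_records$info <- rep(list(NULL), nrow(ins_records))
    for (i in which(flag)) {
      ins_records$info[[i]] <- c(ins_records$info[[i]], c(POSSIBLE_DUP = "1"))
    }
  }
  bind_sv_tables(list(ins_records, dup_records[!linked_dup, , drop = FALSE]))
}

#' Concatenate per-type merged callsets into the cohort callset
#'
#' Globally sorts by `(chrom, pos, svtype)`, regenerates identifiers via
#' [make_sv_id()], and disambiguates any residual ID collisions with a
#' numeric suffix (warning).
#'
#' @param per_type Named list of merged SV tables (one per SV type).
#' @return Cohort-level SV table.
#' @export
build_cohort_vcf <- function(per_type) {
  per_type <- per_type[!vapply(per_type, is.null, TRUE)]
  out <- bind_sv_tables(per_type)
  if (nrow(out) == 0L) return(out)
  out <- out[order(out$chrom, out$pos, out$svtype, out$svlen), , drop = FALSE]
  rownames(out) <- NULL
  out$id <- make_sv_id(out$chrom, out$pos, out$svtype, out$svlen)
  if (anyDuplicated(out$id)) {
    dup <- duplicated(out$id)
    warning(sum(dup), " duplicate SV id(s) disambiguated with suffixes")
    out$id <- make.unique(out$id, sep = "_dup")
  }
  out
}

#' Run the full multi-stage ensemble merge
#'
#' Applies [initial_filter()], [split_by_type()], per-type
#' [merge_within_type()] (per caller and then across callers, which
#' single-linkage clustering collapses into one pass), optional INS/DUP
#' reconciliation, and [build_cohort_vcf()].
#'
#' @param callsets List of SV tables (per sample and caller).
#' @param params A [merge_params()] object.
#' @param reconcile_dup Link duplications to co-located insertions.
#' @return `list(svs, counts)`: the cohort SV table and a per-stage record
#'   count ledger.
#' @export
ensemble_merge <- function(callsets, params = merge_params(),
                           reconcile_dup = FALSE) {
  raw <- bind_sv_tables(callsets)
  filt <- initial_filter(raw)
  by_type <- split_by_type(filt$kept)
  merged <- lapply(SV_TYPES, function(tp) merge_within_type(by_type[[tp]], params))
  names(merged) <- SV_TYPES
  if (reconcile_dup) {
    recon <- reconcile_ins_dup(merged$INS, merged$DUP)
    merged$INS <- recon[recon$svtype == "INS", , drop = FALSE]
    merged$DUP <- recon[recon$svtype == "DUP", , drop = FALSE]
  }
  svs <- build_cohort_vcf(merged)
  counts <- c(input = nrow(raw), after_initial_filter = nrow(filt$kept),
              merged = nrow(svs))
  list(svs = svs, counts = counts)
}
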