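#' @importFrom stats median na.omit optim optimize prcomp sd setNames cor
#'   pchisq pt p.adjust runif rnorm rbinom rpois rbeta rnbinom quantile
#'   plogis qlogis
#'   complete.cases lm coef ks.test var
#' @importFrom utils read.table write.table head
NULL

#' Supported structural-variant types
#'
#' Insertions, deletions, duplications and inversions; breakend records are
#' out of scope.
#' @export
SV_TYPES <- c("INS", "DEL", "DUP", "INV")

#' Construct a canonical SV identifier
#'
#' Identifiers join chromosome, 1-based breakpoint position, SV type and
#' signed length with underscores, e.g. `"chr17_46237501_DEL_-724"`.
#' Deletions carry negative lengths; insertions, duplications and inversions
#' carry positive lengths.
#'
#' @param chrom Chromosome name(s).
#' @param pos 1-based breakpoint position(s).
#' @param svtype SV type, one of `"INS"`, `"DEL"`, `"DUP"`, `"INV"`.
#' @param svlen Signed length in bp (negative for DEL).
#' @return Character vector of identifiers.
#' @examples
#' make_sv_id("chr17", 46237501, "DEL", -724)
#' @export
make_sv_id <- function(chrom, pos, svtype, svlen) {
  check_svtype(svtype)
  check_svlen_sign(svtype, svlen)
  paste(chrom, as.integer(pos), svtype, as.integer(svlen), sep = "_")
}

check_svtype <- function(svtype) {
  bad <- !svtype %in% SV_TYPES
  if (any(bad)) {
    stop("invalid svtype: ", paste(unique(svtype[bad]), collapse = ", "),
         " (must be one of ", paste(SV_TYPES, collapse = "/"), ")")
  }
  invisible(TRUE)
}

check_svlen_sign <- function(svtype, svlen) {
  bad <- (svtype == "DEL" & svlen >= 0) | (svtype != "DEL" & svlen <= 0)
  if (any(bad)) {
    stop("svlen sign inconsistent with svtype: DEL requires svlen < 0, ",
         "INS/DUP/INV require svlen > 0 (offending: ",
         paste(svtype[bad][1], svlen[bad][1]), ")")
  }
  invisible(TRUE)
}

#' Derive the END coordinate from type, position and length
#'
#' DEL/DUP/INV span `|svlen|` bases from `pos`; INS has `end = pos`.
#'
#' @inheritParams make_sv_id
#' @return Integer vector of 1-based end positions.
#' @export
sv_end <- function(pos, svtype, svlen) {
  as.integer(ifelse(svtype == "INS", pos, pos + abs(svlen)))
}

#' Assemble an SV table
#'
#' The package-wide SV container is a plain `data.frame` with one row per SV
#' and columns `chrom`, `pos`, `id`, `svtype`, `svlen`, `end`, `alt_seq`,
#' `strand1`, `strand2`, `filter`, `callers` (comma-separated labels),
#' `supp`, `sample` and an optional matrix column `gt` holding genotype
#' strings (`"0/1"`, `"0|1"`, `"./."`, ...) with one column per sample.
#' Coordinates follow VCF convention (1-based); all interval arithmetic is
#' done 0-based half-open internally, converting only at I/O boundaries.
#'
#' @param chrom,pos,svtype,svlen Per-record fields (recycled where scalar).
#' @param alt_seq Optional inserted/alternate sequence (NA when absent).
#' @param strand1,strand2 Strand pair, `"+"`, `"-"` or `"*"` for unknown
#'   (unknown matches any strand).
#' @param filter VCF FILTER value (default `"PASS"`).
#' @param callers Comma-separated caller labels supporting each record.
#' @param sample Originating sample label (NA for cohort-level records).
#' @param gt Optional character matrix of genotypes, `nrow(gt)` records by
#'   one column per sample; column names are sample identifiers.
#' @param info Optional list column of named character vectors carrying
#'   auxiliary INFO key/value annotations.
#' @return A validated SV `data.frame`.
#' @export
sv_table <- function(chrom, pos, svtype, svlen, alt_seq = NA_character_,
                     strand1 = "*", strand2 = "*", filter = "PASS",
                     callers = "unknown", sample = NA_character_,
                     gt = NULL, info = NULL) {
  n <- max(length(chrom), length(pos), length(svtype), length(svlen))
  df <- data.frame(
    chrom = rep_len(as.character(chrom), n),
    pos = rep_len(as.integer(pos), n),
    svtype = rep_len(as.character(svtype), n),
    svlen = rep_len(as.integer(svlen), n),
    alt_seq = rep_len(as.character(alt_seq), n),
    strand1 = rep_len(as.character(strand1), n),
    strand2 = rep_len(as.character(strand2), n),
    filter = rep_len(as.character(filter), n),
    callers = rep_len(as.character(callers), n),
    sample = rep_len(as.character(sample), n),
    stringsAsFactors = FALSE
  )
  df$id <- make_sv_id(df$chrom, df$pos, df$svtype, df$svlen)
  df$end <- sv_end(df$pos, df$svtype, df$svlen)
  df$supp <- vapply(strsplit(df$callers, ","), function(x) length(unique(x)), 1L)
  if (!is.null(gt)) {
    gt <- as.matrix(gt)
    stopifnot(nrow(gt) == n, !is.null(colnames(gt)))
    df$gt <- gt
  }
  if (!is.null(info)) {
    stopifnot(length(info) == n)
    df$info <- info
  }
  validate_sv_table(df)
}

#' @rdname sv_table
#' @param x An SV table to validate.
#' @export
validate_sv_table <- function(x) {
  check_svtype(x$svtype)
  check_svlen_sign(x$svtype, x$svlen)
  stopifnot(all(x$end == sv_end(x$pos, x$svtype, x$svlen)))
  x
}

# row-bind SV tables, preserving gt matrix columns (samples unioned)
bind_sv_tables <- function(lst) {
  lst <- lst[vapply(lst, nrow, 1L) > 0L]
  if (length(lst) == 0L) return(empty_sv_table())
  has_gt <- vapply(lst, function(d) !is.null(d$gt), TRUE)
  plain <- lapply(lst, function(d) d[setdiff(names(d), c("gt", "info"))])
  out <- do.call(rbind, plain)
  rownames(out) <- NULL
  if (any(has_gt)) {
    samples <- unique(unlist(lapply(lst[has_gt], function(d) colnames(d$gt))))
    gt <- do.call(rbind, lapply(lst, function(d) {
      m <- matrix("./.", nrow(d), length(samples), dimnames = list(NULL, samples))
      if (!is.null(d$gt)) m[, colnames(d$gt)] <- d$gt
      m
    }))
    out$gt <- gt
  }
  if (any(vapply(lst, function(d) !is.null(d$info), TRUE))) {
    out$info <- do.call(c, lapply(lst, function(d) {
      if (is.null(d$info)) rep(list(NULL), nrow(d)) else d$info
    }))
  }
  out
}

empty_sv_table <- function(samples = character()) {
  df <- data.frame(chrom = character(), pos = integer(), svtype = character(),
                   svlen = integer(), alt_seq = character(),
                   strand1 = character(), strand2 = character(),
                   filter = character(), callers = character(),
                   sample = character(), id = character(), end = integer(),
                   supp = integer(), stringsAsFactors = FALSE)
  df$gt <- matrix(character(), 0L, length(samples),
                  dimnames = list(NULL, samples))
  df
}

#' Genotype string to allele dosage
#'
#' Converts VCF genotype strings to alternate-allele dosage: `0/0 -> 0`,
#' `0/1` or `1/0` (phased or not) `-> 1`, `1/1 -> 2`; any missing allele
#' yields `NA`. Symmetric in allele order.
#'
#' @param gt Character vector (or matrix) of genotype strings.
#' @return Integer vector (or matrix) of dosages with `NA` for missing.
#' @examples
#' gt_dosage(c("0|1", "1/1", "./."))
#' @export
gt_dosage <- function(gt) {
  d <- dim(gt)
  a1 <- substr(gt, 1L, 1L)
  a2 <- substr(gt, 3L, 3L)
  out <- ifelse(a1 %in% c("0", "1") & a2 %in% c("0", "1"),
                (a1 == "1") + (a2 == "1"), NA_integer_)
  out <- as.integer(out)
  dim(out) <- d
  dimnames(out) <- dimnames(gt)
  out
}

# dosage matrix (svs x samples) for an sv table with genotypes
sv_dosage_matrix <- function(svs) {
  stopifnot(!is.null(svs$gt))
  m <- gt_dosage(svs$gt)
  rownames(m) <- svs$id
  m
}

#' Cohort panel constructor
#'
#' A cohort panel records the ordered sample list, each sample's diagnosis
#' (`HC` healthy control, `ILBD` incidental Lewy body disease, `PD`), and
#' covariates used downstream (sequencing batch, age, sex, post-mortem
#' interval, RNA integrity number).
#'
#' @param sample Sample identifiers.
#' @param diagnosis One of `"HC"`, `"ILBD"`, `"PD"` per sample.
#' @param batch,age,sex,pmi,rin Covariates (may be NA if unknown).
#' @return A `data.frame` with class `cohort_panel`.
#' @export
cohort_panel <- function(sample, diagnosis, batch = NA, age = NA, sex = NA,
                         pmi = NA, rin = NA) {
  stopifnot(!anyDuplicated(sample), all(diagnosis %in% c("HC", "ILBD", "PD")))
  df <- data.frame(sample = as.character(sample),
                   diagnosis = as.character(diagnosis),
                   batch = rep_len(batch, length(sample)),
                   age = rep_len(age, length(sample)),
                   sex = rep_len(sex, length(sample)),
                   pmi = rep_len(pmi, length(sample)),
                   rin = rep_len(rin, length(sample)),
                   stringsAsFactors = FALSE)
  class(df) <- c("cohort_panel", "data.frame")
  df
}

# 0-based half-open query interval of each SV: span types cover
# [pos-1, end); insertions the single breakpoint base [pos-1, pos)
sv_query_interval <- function(svs) {
  start0 <- svs$pos - 1L
  end0 <- ifelse(svs$svtype == "INS", svs$pos, svs$end)
  data.frame(chrom = svs$chrom, start = start0, end = as.integer(end0))
}

# strands compatible when equal or either unknown ("*")
strands_compatible <- function(s1a, s2a, s1b, s2b) {
  ok1 <- s1a == "*" | s1b == "*" | s1a == s1b
  ok2 <- s2a == "*" | s2b == "*" | s2a == s2b
  ok1 & ok2
}
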