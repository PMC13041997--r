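# I/O for the standard formats the pipeline consumes: SV VCF, phased SNP
# VCF, and BED interval files. Parsing goes through vcfR; the writer emits
# plain-text VCF 4.2 so that cohort outputs remain diff- and round-trip-able.

CORE_INFO_KEYS <- c("SVTYPE", "SVLEN", "END", "STRANDS", "CALLERS", "SUPP")

parse_info_field <- function(s) {
  if (is.na(s) || s == "." || s == "") return(character())
  parts <- strsplit(s, ";", fixed = TRUE)[[1]]
  kv <- regmatches(parts, regexpr("=", parts), invert = TRUE)
  keys <- vapply(kv, `[`, "", 1L)
  vals <- vapply(kv, function(x) if (length(x) == 2L) x[2L] else "", "")
  setNames(vals, keys)
}

#' Read a structural-variant VCF
#'
#' Parses a VCF 4.2 file carrying `SVTYPE` plus `SVLEN` and/or `END` in
#' INFO into the package's SV table. `END` is derived from `SVLEN` when
#' absent (and vice versa) under the type invariants; sample columns become
#' the `gt` genotype matrix. Records of span type missing both `SVLEN` and
#' `END` are dropped and reported via a warning and the `"errors"`
#' attribute.
#'
#' @param path Path to a VCF file.
#' @return An SV table (see [sv_table()]); attribute `"errors"` lists any
#'   skipped records.
#' @export
read_sv_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  n <- nrow(fix)
  samples <- colnames(v@gt)[-1]
  if (n == 0L) return(empty_sv_table(samples))
  info <- lapply(v@fix[, "INFO"], parse_info_field)
  getk <- function(k) vapply(info, function(x) if (k %in% names(x)) x[[k]] else NA_character_, "")

  svtype <- getk("SVTYPE")
  svlen <- suppressWarnings(as.integer(getk("SVLEN")))
  end <- suppressWarnings(as.integer(getk("END")))
  pos <- as.integer(fix[, "POS"])
  errors <- character()

  for (i in seq_len(n)) {
    if (is.na(svlen[i])) {
      if (svtype[i] == "INS") {
        errors <- c(errors, sprintf("record %d (%s:%d): INS without SVLEN", i, fix[i, "CHROM"], pos[i]))
      } else if (!is.na(end[i])) {
        svlen[i] <- if (svtype[i] == "DEL") -(end[i] - pos[i]) else end[i] - pos[i]
      } else {
        errors <- c(errors, sprintf("record %d (%s:%d): span SV missing both SVLEN and END", i, fix[i, "CHROM"], pos[i]))
      }
    }
  }
  keep <- !is.na(svlen)
  if (length(errors)) {
    warning(length(errors), " record(s) skipped: ", paste(errors, collapse = "; "))
  }

  strands <- getk("STRANDS")
  s1 <- ifelse(is.na(strands), "*", substr(strands, 1, 1))
  s2 <- ifelse(is.na(strands), "*", substr(strands, 2, 2))
  alt <- fix[, "ALT"]
  alt_seq <- ifelse(grepl("^<", alt), NA_character_, alt)
  callers <- getk("CALLERS")
  callers[is.na(callers)] <- "unknown"

  gt <- NULL
  if (length(samples)) {
    gtm <- v@gt[, -1, drop = FALSE]
    gt <- sub(":.*$", "", gtm)
    if (is.null(dim(gt))) gt <- matrix(gt, nrow = n, dimnames = list(NULL, samples))
    gt[is.na(gt)] <- "./."   # vcfR parses missing genotypes as NA
    gt <- gt[keep, , drop = FALSE]
  }
  extra <- lapply(info[keep], function(x) x[setdiff(names(x), CORE_INFO_KEYS)])
  out <- sv_table(chrom = fix[keep, "CHROM"], pos = pos[keep],
                  svtype = svtype[keep], svlen = svlen[keep],
                  alt_seq = alt_seq[keep], strand1 = s1[keep], strand2 = s2[keep],
                  filter = fix[keep, "FILTER"], callers = callers[keep],
                  gt = gt, info = extra)
  attr(out, "errors") <- errors
  out
}

#' Write a structural-variant VCF
#'
#' Serializes an SV table to plain-text VCF 4.2. INFO carries `SVTYPE`,
#' `SVLEN`, `END`, `STRANDS`, `CALLERS`, `SUPP` plus any keys in the `info`
#' list column; genotypes are written as a `GT` FORMAT field. A read/write
#' round trip preserves every field the pipeline uses.
#'
#' @param svs SV table.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_sv_vcf <- function(svs, path) {
  samples <- if (!is.null(svs$gt)) colnames(svs$gt) else character()
  extra_keys <- if (!is.null(svs$info)) unique(unlist(lapply(svs$info, names))) else character()
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=svcellreg",
    '##INFO=<ID=SVTYPE,Number=1,Type=String,Description="SV type">',
    '##INFO=<ID=SVLEN,Number=1,Type=Integer,Description="Signed SV length">',
    '##INFO=<ID=END,Number=1,Type=Integer,Description="1-based end position">',
    '##INFO=<ID=STRANDS,Number=1,Type=String,Description="Breakpoint strands">',
    '##INFO=<ID=CALLERS,Number=1,Type=String,Description="Supporting callers">',
    '##INFO=<ID=SUPP,Number=1,Type=Integer,Description="Caller support count">',
    sprintf('##INFO=<ID=%s,Number=1,Type=String,Description="Annotation">', extra_keys),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            if (length(samples)) c("FORMAT", samples)), collapse = "\t")
  )
  lines <- hdr
  if (nrow(svs)) {
    info_str <- vapply(seq_len(nrow(svs)), function(i) {
      kv <- c(SVTYPE = svs$svtype[i], SVLEN = as.character(svs$svlen[i]),
              END = as.character(svs$end[i]),
              STRANDS = paste0(svs$strand1[i], svs$strand2[i]),
              CALLERS = svs$callers[i], SUPP = as.character(svs$supp[i]))
      if (!is.null(svs$info) && length(svs$info[[i]])) kv <- c(kv, svs$info[[i]])
      paste(names(kv), kv, sep = "=", collapse = ";")
    }, "")
    alt <- ifelse(is.na(svs$alt_seq), paste0("<", svs$svtype, ">"), svs$alt_seq)
    body <- paste(svs$chrom, svs$pos, svs$id, "N", alt, ".", svs$filter,
                  info_str, sep = "\t")
    if (length(samples)) {
      gtcols <- apply(svs$gt, 1L, paste, collapse = "\t")
      body <- paste(body, "GT", gtcols, sep = "\t")
    }
    lines <- c(lines, body)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read phased SNP genotypes from a VCF
#'
#' Returns a SNP table with `chrom`, `pos` (1-based), `id`, `ref`, `alt`
#' and a genotype-string matrix column `gt` (one column per sample).
#'
#' @param path Path to a VCF file of biallelic SNPs.
#' @return A `data.frame` with a `gt` matrix column.
#' @export
read_snp_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  samples <- colnames(v@gt)[-1]
  out <- data.frame(chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
                    id = fix[, "ID"], ref = fix[, "REF"], alt = fix[, "ALT"],
                    stringsAsFactors = FALSE)
  gt <- sub(":.*$", "", v@gt[, -1, drop = FALSE])
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(out), dimnames = list(NULL, samples))
  gt[is.na(gt)] <- "./."
  out$gt <- gt
  out
}

#' Write a minimal phased SNP VCF
#'
#' @param snps SNP table as returned by [read_snp_vcf()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_snp_vcf <- function(snps, path) {
  samples <- colnames(snps$gt)
  hdr <- c("##fileformat=VCFv4.2", "##source=svcellreg",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  body <- paste(snps$chrom, snps$pos, snps$id, snps$ref, snps$alt, ".",
                "PASS", ".", "GT", apply(snps$gt, 1L, paste, collapse = "\t"),
                sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a BED file of genomic intervals
#'
#' Intervals use the BED half-open convention: `start` 0-based inclusive,
#' `end` exclusive.
#'
#' @param path Path to a BED3(+name) file.
#' @return `data.frame` with `chrom`, `start`, `end` and optional `name`.
#' @export
read_bed <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  names(df)[1:3] <- c("chrom", "start", "end")
  if (ncol(df) >= 4) names(df)[4] <- "name"
  df[, seq_len(min(4L, ncol(df))), drop = FALSE]
}

#' @rdname read_bed
#' @param intervals Interval `data.frame` (`chrom`, `start`, `end`, optional
#'   `name`).
#' @export
write_bed <- function(intervals, path) {
  cols <- intersect(c("chrom", "start", "end", "name"), names(intervals))
  write.table(intervals[, cols, drop = FALSE], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# 0-based half-open interval frame -> GRanges (1-based closed)
intervals_to_granges <- function(df) {
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = df$start + 1L, end = df$end))
}

granges_to_intervals <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr), stringsAsFactors = FALSE)
}

# SV query intervals as GRanges (for overlap tests)
sv_query_granges <- function(svs) {
  intervals_to_granges(sv_query_interval(svs))
}
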