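# Independent brute-force oracles used to check pipeline operations.

# transitive closure of the pairwise link predicate by label propagation
# over the full adjacency matrix (no sorting/window tricks)
oracle_single_linkage <- function(svs, params) {
  n <- nrow(svs)
  if (n == 0L) return(integer())
  same_chr <- outer(svs$chrom, svs$chrom, "==")
  near <- abs(outer(svs$pos, svs$pos, "-")) <= params$max_dist
  adj <- same_chr & near
  if (params$require_strand) {
    s_ok <- outer(seq_len(n), seq_len(n), function(i, j)
      svcellreg:::strands_compatible(svs$strand1[i], svs$strand2[i],
                                     svs$strand1[j], svs$strand2[j]))
    adj <- adj & s_ok
  }
  diag(adj) <- TRUE
  comp <- seq_len(n)
  repeat {
    new <- vapply(seq_len(n), function(i) min(comp[adj[i, ]]), 1L)
    if (identical(new, comp)) break
    comp <- new
  }
  match(comp, unique(comp))
}

# closed-form Pearson correlation squared, written out explicitly
oracle_pearson_r2 <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  (num / den)^2
}

# normal-equations OLS slope for y ~ 1 + x (+ covariates)
oracle_ols_slope <- function(y, x, covars = NULL) {
  X <- cbind(1, x, covars)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  beta[2]
}

# optimal one-to-one assignment size for a 0/1 match matrix
# (maximum bipartite matching by augmenting paths)
oracle_max_matching <- function(adj) {
  n <- nrow(adj); m <- ncol(adj)
  matched <- 0L
  match_b <- rep(0L, m)
  for (i in seq_len(n)) {
    seen <- rep(FALSE, m)
    aug <- function(u) {
      for (j in which(adj[u, ])) {
        if (!seen[j]) {
          seen[j] <<- TRUE
          if (match_b[j] == 0L || aug(match_b[j])) {
            match_b[j] <<- u
            return(TRUE)
          }
        }
      }
      FALSE
    }
    if (aug(i)) matched <- matched + 1L
  }
  matched
}

# quick SV table builder for tests
mk_svs <- function(pos, svtype = "DEL", svlen = -100L, chrom = "chr1",
                   caller = "c1", sample = NA, gt = NULL, ...) {
  sv_table(chrom = chrom, pos = pos, svtype = svtype, svlen = svlen,
           callers = caller, sample = sample, gt = gt, ...)
}

# genotype matrix builder: rows are genotype string vectors per SV
mk_gt <- function(..., samples = NULL) {
  rows <- list(...)
  m <- do.call(rbind, rows)
  colnames(m) <- if (is.null(samples)) paste0("S", seq_len(ncol(m))) else samples
  m
}
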