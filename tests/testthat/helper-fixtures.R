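# Shared fixtures, built in code at test time.

# small random catalog with full row rank
make_catalog <- function(p, n_channels = 96, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  simulate_signature_catalog(p)
}

# write a VCF with explicit raw lines (for filter/multi-allelic cases)
write_raw_vcf <- function(lines, path = tempfile(fileext = ".vcf")) {
  writeLines(c("##fileformat=VCFv4.2",
               "##contig=<ID=chr1,length=1000>",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               lines), path)
  path
}

# reference FASTA from named character sequences
write_ref <- function(seqs, path = tempfile(fileext = ".fa")) {
  dss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(dss, path)
  path
}

# brute-force two-sample K-S statistic over pooled points
ks_D_oracle <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  max(abs(vapply(pts, function(t) mean(a <= t) - mean(b <= t), numeric(1))))
}

# exact two-sample K-S p-value by enumeration of all assignments
ks_p_oracle <- function(a, b) {
  pooled <- c(a, b)
  n_a <- length(a)
  D_obs <- ks_D_oracle(a, b)
  combs <- utils::combn(length(pooled), n_a)
  hits <- 0
  for (j in seq_len(ncol(combs))) {
    aa <- pooled[combs[, j]]; bb <- pooled[-combs[, j]]
    if (ks_D_oracle(aa, bb) >= D_obs - 1e-12) hits <- hits + 1
  }
  hits / ncol(combs)
}

# two-sided Fisher exact p by enumeration over fixed margins
fisher_p_oracle <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  xs <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- stats::dhyper(xs, r1, n - r1, c1)
  p_obs <- stats::dhyper(tab[1, 1], r1, n - r1, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# O(n^2) pairwise-concordance AUC
auc_oracle <- function(scores, labels) {
  pos <- scores[labels == "yes" | labels == TRUE | labels == 1]
  neg <- scores[!(labels == "yes" | labels == TRUE | labels == 1)]
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

# classic B-H step-up rejection rule at level alpha
bh_reject_oracle <- function(p, alpha) {
  n <- length(p)
  o <- order(p)
  k <- max(c(0, which(p[o] <= alpha * seq_len(n) / n)))
  rej <- rep(FALSE, n)
  if (k > 0) rej[o[seq_len(k)]] <- TRUE
  rej
}
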