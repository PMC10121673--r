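#' Two-sample Kolmogorov-Smirnov test
#'
#' Two-sided K-S test of whether two samples come from the same
#' distribution. The statistic is the supremum distance between the
#' empirical CDFs; the p-value is exact for small tie-free samples and
#' asymptotic otherwise (the regimes agree where both apply).
#'
#' @param a,b numeric vectors (non-empty).
#' @return list with `D` and `p`.
#' @export
ks_two_sample <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) stop("empty sample in K-S test")
  res <- suppressWarnings(stats::ks.test(a, b, alternative = "two.sided"))
  list(D = unname(res$statistic), p = res$p.value)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate correction:
#' `q_(i) = min_{j>=i} p_(j) N / j`, capped at 1 and returned in the
#' input order. Rejecting at `q <= alpha` is equivalent to the classic
#' step-up rule at level alpha.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return vector of q-values.
#' @export
benjamini_hochberg <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Kendall tau-b rank correlation
#'
#' Tie-corrected tau-b with a two-sided p-value from the tie-adjusted
#' normal approximation. When either input has zero variance the
#' correlation is undefined; such pairs are flagged (`excluded = TRUE`,
#' tau and p `NA`) so callers can drop e.g. non-mutated genes before
#' multiple-testing correction.
#'
#' @param x,y equal-length numeric vectors (length >= 2).
#' @return list with `tau`, `p`, `excluded`.
#' @export
kendall_tau <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    return(list(tau = NA_real_, p = NA_real_, excluded = TRUE))
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "kendall",
                                         exact = FALSE))
  list(tau = unname(ct$estimate), p = ct$p.value, excluded = FALSE)
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Sums hypergeometric probabilities of all tables (with the observed
#' margins) no more probable than the observed one.
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return two-sided p-value.
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2, 2)))
  assert_counts(tab, "contingency table")
  stats::fisher.test(tab)$p.value
}

#' Screen signature attributions against durable benefit
#'
#' For each signature, compares the attribution distribution between
#' the durable-benefit and non-benefit strata with a two-sided K-S
#' test, then applies Benjamini-Hochberg across the signatures of the
#' channel system. Unknown-label samples are excluded; an empty
#' stratum is an error.
#'
#' @param W_norm attribution matrix (samples x signatures), typically
#'   per-Mb values.
#' @param db_labels labels in `c("yes","no","unknown")`, one per row.
#' @param alpha significance level on q (default 0.05).
#' @return data.frame per signature: `signature`, `D`, `p`, `q`,
#'   `significant`.
#' @export
screen_signatures <- function(W_norm, db_labels, alpha = 0.05) {
  stopifnot(nrow(W_norm) == length(db_labels))
  yes <- db_labels == "yes"; no <- db_labels == "no"
  if (!any(yes) || !any(no)) stop("empty durable-benefit stratum")
  res <- lapply(colnames(W_norm), function(s) {
    ks <- ks_two_sample(W_norm[yes, s], W_norm[no, s])
    data.frame(signature = s, D = ks$D, p = ks$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- benjamini_hochberg(out$p)
  out$significant <- out$q <= alpha
  out
}

#' Count nonsynonymous mutations per gene
#'
#' Overlaps variant positions with gene intervals (BED convention:
#' 0-based half-open start/end) and tallies amino-acid-changing
#' mutations per gene and sample.
#'
#' @param variants variant data.frame (needs `chrom`, `pos`,
#'   `sample_id`, `is_nonsynonymous`).
#' @param bed data.frame with `chrom`, `start` (0-based), `end`,
#'   `gene`, or a path to a BED file with those four columns.
#' @param samples optional sample set/order for the columns.
#' @return integer matrix, genes x samples.
#' @export
count_gene_mutations <- function(variants, bed, samples = NULL) {
  if (is.character(bed) && length(bed) == 1) {
    bed <- utils::read.delim(bed, header = FALSE, stringsAsFactors = FALSE,
                             col.names = c("chrom", "start", "end", "gene"))
  }
  if (is.null(samples)) samples <- unique(variants$sample_id)
  v <- variants[variants$is_nonsynonymous, , drop = FALSE]
  genes_gr <- GenomicRanges::GRanges(bed$chrom,
                                     IRanges::IRanges(bed$start + 1, bed$end))
  counts <- matrix(0L, nrow(bed), length(samples),
                   dimnames = list(bed$gene, samples))
  if (nrow(v) > 0) {
    var_gr <- GenomicRanges::GRanges(v$chrom, IRanges::IRanges(v$pos, v$pos))
    hits <- GenomicRanges::findOverlaps(var_gr, genes_gr)
    if (length(hits) > 0) {
      tab <- table(
        factor(bed$gene[S4Vectors::subjectHits(hits)], levels = bed$gene),
        factor(v$sample_id[S4Vectors::queryHits(hits)], levels = samples))
      counts[] <- as.integer(tab)
    }
  }
  counts
}

#' Correlate a signature's attribution with per-gene mutation counts
#'
#' Kendall tau-b between the signature attribution and each gene's
#' mutation count across samples, with Benjamini-Hochberg correction
#' across the tested gene panel. Non-mutated genes (all-zero counts,
#' where the correlation is trivially undefined) are excluded before
#' correction. Optionally normalises the attribution by TMB first, to
#' remove the correlation mediated by total mutation load.
#'
#' @param w named attribution vector (one value per sample).
#' @param gene_counts genes x samples count matrix (columns matching
#'   `names(w)`).
#' @param tmb optional per-sample TMB for normalisation.
#' @param alpha significance level on q.
#' @return data.frame per tested gene: `gene`, `tau`, `p`, `q`,
#'   `significant`.
#' @export
gene_correlation <- function(w, gene_counts, tmb = NULL, alpha = 0.05) {
  stopifnot(!is.null(names(w)), all(colnames(gene_counts) %in% names(w)))
  w <- w[colnames(gene_counts)]
  if (!is.null(tmb)) {
    tmb <- tmb[colnames(gene_counts)]
    if (any(tmb <= 0)) stop("TMB must be positive for normalisation")
    w <- w / tmb
  }
  mutated <- rowSums(gene_counts) > 0
  res <- lapply(rownames(gene_counts)[mutated], function(g) {
    kt <- kendall_tau(w, gene_counts[g, ])
    data.frame(gene = g, tau = kt$tau, p = kt$p,
               excluded = kt$excluded, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out <- out[!out$excluded, setdiff(names(out), "excluded"), drop = FALSE]
  if (is.null(out) || nrow(out) == 0) {
    return(data.frame(gene = character(), tau = numeric(), p = numeric(),
                      q = numeric(), significant = logical()))
  }
  out$q <- benjamini_hochberg(out$p)
  out$significant <- out$q <= alpha
  rownames(out) <- NULL
  out
}

#' Check whether a gene covariate confounds the TMB-outcome coefficient
#'
#' Fits two logistic regressions of durable benefit — on TMB alone and
#' on TMB plus a gene mutation indicator — by iteratively reweighted
#' least squares, and reports the relative change of the TMB
#' coefficient. A change above 10 % flags the gene as a potential
#' confounder. Perfect separation is flagged and the coefficients
#' reported as non-converged.
#'
#' @param db_labels labels in `c("yes","no")` (unknowns must be removed
#'   by the caller).
#' @param tmb per-sample TMB values.
#' @param gene_indicator numeric/logical per-sample gene covariate.
#' @return list: `coef_tmb_alone`, `coef_tmb_adjusted`, `coef_gene`,
#'   `change_ratio`, `confounding`, `converged`.
#' @export
logistic_confounding <- function(db_labels, tmb, gene_indicator) {
  stopifnot(all(db_labels %in% c("yes", "no")))
  y <- as.integer(db_labels == "yes")
  g <- as.numeric(gene_indicator)
  f1 <- suppressWarnings(stats::glm(y ~ tmb, family = stats::binomial()))
  f2 <- suppressWarnings(stats::glm(y ~ tmb + g, family = stats::binomial()))
  sep <- !f1$converged || !f2$converged ||
    max(abs(stats::coef(f2)), na.rm = TRUE) > 20
  b1 <- unname(stats::coef(f1)["tmb"])
  b2 <- unname(stats::coef(f2)["tmb"])
  change <- abs(b2 - b1) / abs(b1)
  list(coef_tmb_alone = b1, coef_tmb_adjusted = b2,
       coef_gene = unname(stats::coef(f2)["g"]),
       change_ratio = change,
       confounding = !sep && change > 0.10,
       converged = !sep)
}

#' Differential abundance of mutated-transcript counts
#'
#' Non-parametric per-gene comparison of mutated-transcript counts
#' between durable-benefit strata: two-sided K-S per gene with
#' Benjamini-Hochberg correction across the gene battery. Chosen over
#' count-model fits because genes with no mutated transcripts produce
#' zeros that defeat parametric count models.
#'
#' @param counts genes x samples matrix of mutated-transcript counts.
#' @param db_labels per-sample labels (`"yes"`/`"no"`).
#' @param alpha significance level on q.
#' @return data.frame per gene: `gene`, `D`, `p`, `q`, `significant`.
#' @export
de_bhks <- function(counts, db_labels, alpha = 0.05) {
  stopifnot(ncol(counts) == length(db_labels))
  yes <- db_labels == "yes"; no <- db_labels == "no"
  if (!any(yes) || !any(no)) stop("empty stratum")
  res <- lapply(rownames(counts), function(g) {
    ks <- ks_two_sample(counts[g, yes], counts[g, no])
    data.frame(gene = g, D = ks$D, p = ks$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- benjamini_hochberg(out$p)
  out$significant <- out$q <= alpha
  out
}
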