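#' Refit a mutation spectrum against a fixed signature catalog
#'
#' Solves, independently for each sample, the non-negative least
#' squares problem `min ||x - wH||^2, w >= 0` by cyclic coordinate
#' descent: `w_s <- max(0, w_s - g_s / (H H')_ss)` with `g` the
#' gradient, stopping when the relative objective decrease over a full
#' sweep falls below `tol` or after `max_iter` sweeps. Because the
#' catalog is fixed, per-sample solves are jointly optimal for the full
#' matrix problem `X ~ W H`. Starting point is the clipped
#' unconstrained projection `max(0, x H' (H H')^-1)`; the problem is
#' convex, so the start only affects speed.
#'
#' Channels are aligned by label between spectrum and catalog; a
#' spectrum channel missing from the catalog (or vice versa) is an
#' error, never silently dropped.
#'
#' @param X spectrum matrix, samples x channels, labelled columns.
#' @param catalog a `signature_catalog`.
#' @param tol relative objective tolerance (default 1e-6).
#' @param max_iter maximum coordinate-descent sweeps (default 1e4).
#' @return attribution matrix `W` (samples x signatures, mutation
#'   counts) with a `sweeps` attribute.
#' @export
refit <- function(X, catalog, tol = 1e-6, max_iter = 1e4) {
  stopifnot(inherits(catalog, "signature_catalog"), tol > 0, max_iter >= 1)
  H <- catalog$H
  if (is.null(colnames(X))) stop("spectrum must carry channel labels")
  if (!setequal(colnames(X), colnames(H))) {
    stop("spectrum and catalog channels do not match")
  }
  X <- X[, colnames(H), drop = FALSE]          # align by label
  G <- H %*% t(H)
  d <- diag(G)
  if (any(d == 0)) stop("all-zero signature row: ", rownames(H)[d == 0][1])
  p <- nrow(H)
  Ginv <- tryCatch(solve(G), error = function(e) NULL)
  W <- matrix(0, nrow(X), p, dimnames = list(rownames(X), rownames(H)))
  sweeps <- integer(nrow(X))
  HXt <- H %*% t(X)                            # p x m
  for (i in seq_len(nrow(X))) {
    x <- X[i, ]
    hx <- HXt[, i]
    xx <- sum(x * x)
    w <- if (is.null(Ginv)) rep(0, p) else pmax(0, drop(hx %*% Ginv))
    obj <- function(w) 0.5 * xx - sum(w * hx) + 0.5 * sum(w * (G %*% w))
    f_prev <- obj(w)
    it <- 0L
    repeat {
      it <- it + 1L
      for (s in seq_len(p)) {
        g_s <- sum(G[s, ] * w) - hx[s]
        w[s] <- max(0, w[s] - g_s / d[s])
      }
      f <- obj(w)
      if (f > f_prev + 1e-8 * max(1, abs(f_prev))) {
        stop("coordinate-descent objective increased (numerical failure)")
      }
      if (f_prev - f <= tol * max(f_prev, .Machine$double.eps) ||
          it >= max_iter) break
      f_prev <- f
    }
    W[i, ] <- w
    sweeps[i] <- it
  }
  attr(W, "sweeps") <- sweeps
  W
}

#' Normalise attributions per megabase
#'
#' Divides attributed mutation counts by the exome coverage size and
#' rounds half away from zero to two decimals, the convention used to
#' report per-Mb attribution values (retaining three significant
#' digits for typical magnitudes).
#'
#' @param W_counts attribution matrix (or vector) in mutation counts.
#' @param coverage_mb coverage in Mb: a scalar (default 47.9, the exome
#'   size used when per-sample coverage is unknown) or one value per
#'   sample.
#' @return per-Mb matrix, rounded to 2 decimals.
#' @export
normalise_attribution <- function(W_counts, coverage_mb = 47.9) {
  if (any(coverage_mb <= 0)) stop("coverage_mb must be positive")
  round_half_away(W_counts / coverage_mb, 2)
}

#' Tumor mutational burden per megabase
#'
#' Nonsynonymous mutation count divided by coverage, rounded to two
#' decimals (half away from zero).
#'
#' @param variant_counts nonsynonymous mutation count per sample.
#' @param coverage_mb coverage in Mb (scalar or per sample).
#' @return numeric TMB vector.
#' @export
tmb <- function(variant_counts, coverage_mb = 47.9) {
  if (any(coverage_mb <= 0)) stop("coverage_mb must be positive")
  round_half_away(variant_counts / coverage_mb, 2)
}

#' Exclude artefact and zero-variance signatures
#'
#' Drops signatures flagged as possible sequencing artefacts and
#' signatures whose attribution has exactly zero variance within the
#' durable-benefit stratum or within the non-benefit stratum of the
#' discovery set (unknown-label samples do not enter the variance
#' computation). Each stratum needs at least two samples for the
#' variance to be defined.
#'
#' @param W attribution matrix, samples x signatures.
#' @param catalog the matching `signature_catalog`.
#' @param db_labels per-sample labels in `c("yes","no","unknown")`.
#' @return list with filtered `W`, `catalog`, and `dropped` (named
#'   character vector of reasons).
#' @export
filter_signatures <- function(W, catalog, db_labels) {
  stopifnot(nrow(W) == length(db_labels))
  yes <- db_labels == "yes"; no <- db_labels == "no"
  if (sum(yes) < 2 || sum(no) < 2) {
    stop("each durable-benefit stratum needs >= 2 samples for variance")
  }
  dropped <- character(0)
  art <- catalog$artefact[colnames(W)]
  for (s in colnames(W)) {
    if (isTRUE(art[[s]])) {
      dropped[s] <- "artefact"
    } else if (stats::var(W[yes, s]) == 0 || stats::var(W[no, s]) == 0) {
      dropped[s] <- "zero variance in a stratum"
    }
  }
  keep <- setdiff(colnames(W), names(dropped))
  if (length(keep) == 0) stop("all signatures excluded")
  list(W = W[, keep, drop = FALSE],
       catalog = signature_catalog(catalog$H[keep, , drop = FALSE],
                                   artefacts = names(which(catalog$artefact))),
       dropped = dropped)
}

#' Per-variant signature responsibilities
#'
#' For a variant of sample `i` in channel `k`, signature `s` is
#' responsible for the share `W[i,s] H[s,k] / sum_t W[i,t] H[t,k]` of
#' the reconstructed channel intensity. Signatures reaching a share of
#' at least 0.5 are dominant for that variant; an exact 0.5/0.5 tie
#' reports both (the threshold is inclusive). Variants whose channel
#' has zero reconstructed intensity are flagged unattributed.
#'
#' @param W attribution matrix (counts or per-Mb; shares are scale-free
#'   within a sample row).
#' @param catalog a `signature_catalog`.
#' @param variants data.frame with `sample_id` and `channel` columns.
#' @return data.frame: `sample_id`, `channel`, one responsibility
#'   column per signature, `dominant` (comma-joined names, `""` if
#'   none) and `unattributed`.
#' @export
responsibilities <- function(W, catalog, variants) {
  H <- catalog$H
  stopifnot(all(colnames(W) == rownames(H)),
            all(c("sample_id", "channel") %in% names(variants)))
  bad_ch <- setdiff(unique(variants$channel), colnames(H))
  if (length(bad_ch) > 0) stop("unknown channel: ", bad_ch[1])
  n <- nrow(variants)
  R <- matrix(NA_real_, n, ncol(W), dimnames = list(NULL, colnames(W)))
  unattr <- logical(n)
  dominant <- character(n)
  for (v in seq_len(n)) {
    i <- variants$sample_id[v]
    contrib <- W[i, ] * H[, variants$channel[v]]
    tot <- sum(contrib)
    if (tot <= 0) {
      unattr[v] <- TRUE
      next
    }
    r <- contrib / tot
    R[v, ] <- r
    dom <- names(r)[r >= 0.5]
    if (length(dom) == 2) {
      sb_log("responsibility tie at 0.5 for variant ", v, level = "WARN")
    }
    dominant[v] <- paste(dom, collapse = ",")
  }
  out <- data.frame(sample_id = variants$sample_id,
                    channel = variants$channel, R,
                    dominant = dominant, unattributed = unattr,
                    stringsAsFactors = FALSE, check.names = FALSE)
  out
}
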