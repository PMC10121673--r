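#' Classification metrics from a confusion matrix
#'
#' Sensitivity TP/(TP+FN), specificity TN/(TN+FP), accuracy, and
#' F1 = 2TP/(2TP+FP+FN). Reported values are rounded half away from
#' zero to two decimals; unrounded values are kept in `$raw`. A metric
#' whose denominator is empty is reported as `NA`.
#'
#' @param TP,FP,TN,FN non-negative integer counts.
#' @return list with `sensitivity`, `specificity`, `accuracy`, `f1`
#'   (2-decimal values) and `raw` (unrounded named vector).
#' @export
confusion_metrics <- function(TP, FP, TN, FN) {
  assert_counts(c(TP, FP, TN, FN), "confusion counts")
  raw <- c(
    sensitivity = if (TP + FN > 0) TP / (TP + FN) else NA_real_,
    specificity = if (TN + FP > 0) TN / (TN + FP) else NA_real_,
    accuracy = if (TP + FP + TN + FN > 0) (TP + TN) / (TP + FP + TN + FN) else NA_real_,
    f1 = if (2 * TP + FP + FN > 0) 2 * TP / (2 * TP + FP + FN) else NA_real_
  )
  out <- as.list(round_half_away(raw, 2))
  out$raw <- raw
  out
}

#' Area under the ROC curve
#'
#' Pairwise concordance probability: the fraction of
#' (positive, negative) pairs where the positive scores higher, with
#' half credit for score ties (rank-based Mann-Whitney form).
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels logical or `"yes"`/`"no"` class labels.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  pos <- as_binary_labels(labels)
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both classes required for ROC AUC")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

as_binary_labels <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels)) return(labels != 0)
  labels == "yes"
}

#' Average precision
#'
#' Precision-weighted recall increments over descending score
#' thresholds (tied scores enter as one threshold).
#'
#' @inheritParams roc_auc
#' @return average precision in `[0, 1]`.
#' @export
average_precision <- function(scores, labels) {
  pos <- as_binary_labels(labels)
  if (!any(pos)) stop("no positive labels")
  thr <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(pos)
  recall_prev <- 0
  ap <- 0
  for (t in thr) {
    sel <- scores >= t
    tp <- sum(pos & sel)
    prec <- tp / sum(sel)
    recall <- tp / n_pos
    ap <- ap + (recall - recall_prev) * prec
    recall_prev <- recall
  }
  ap
}

#' Percentile bootstrap confidence interval for a metric
#'
#' Resamples (score, label) pairs with replacement `B` times and takes
#' the 2.5/97.5 percentile interval. Resamples containing a single
#' class (where AUC-type metrics are undefined) are redrawn. The
#' interval is stored alongside the point estimate in the
#' `a (-b, +c)` form used for reporting.
#'
#' @param metric function of `(scores, labels)`.
#' @param scores,labels the evaluation data.
#' @param B bootstrap iterations (default 1000).
#' @param conf confidence level (default 0.95).
#' @return list: `estimate`, `lower`, `upper`, `minus`, `plus`.
#' @export
bootstrap_ci <- function(metric, scores, labels, B = 1000, conf = 0.95) {
  stopifnot(B >= 1)
  n <- length(scores)
  pos <- as_binary_labels(labels)
  est <- metric(scores, labels)
  vals <- numeric(B)
  for (b in seq_len(B)) {
    for (try in 1:1000) {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(pos[idx])) == 2 || length(unique(pos)) < 2) break
    }
    vals[b] <- metric(scores[idx], labels[idx])
  }
  a <- (1 - conf) / 2
  q <- stats::quantile(vals, c(a, 1 - a), names = FALSE)
  list(estimate = est, lower = q[1], upper = q[2],
       minus = est - q[1], plus = q[2] - est)
}

#' Paired permutation test for comparing two models
#'
#' Both models score the same samples; under the null of equal
#' performance the per-sample score assignment to models is
#' exchangeable, so the null distribution swaps the two models' scores
#' per sample with probability 1/2. Two-sided p with the add-one
#' correction `(1 + #{|delta*| >= |delta|}) / (R + 1)`.
#'
#' @param scores_a,scores_b per-sample scores of the two models.
#' @param labels shared class labels.
#' @param metric performance function of `(scores, labels)` (default
#'   [roc_auc()]).
#' @param R permutation iterations (default 1e4).
#' @return two-sided p-value.
#' @export
paired_permutation_test <- function(scores_a, scores_b, labels,
                                    metric = roc_auc, R = 1e4) {
  if (length(scores_a) != length(scores_b)) stop("score length mismatch")
  if (R < 1) stop("R must be >= 1")
  n <- length(scores_a)
  obs <- metric(scores_a, labels) - metric(scores_b, labels)
  perm <- numeric(R)
  for (r in seq_len(R)) {
    swap <- stats::runif(n) < 0.5
    a <- ifelse(swap, scores_b, scores_a)
    b <- ifelse(swap, scores_a, scores_b)
    perm[r] <- metric(a, labels) - metric(b, labels)
  }
  (1 + sum(abs(perm) >= abs(obs) - 1e-12)) / (R + 1)
}

#' Unpaired permutation test for comparing performance across cohorts
#'
#' Compares a metric between two disjoint sample groups by permuting
#' group membership (group sizes fixed). Permutations that leave a
#' group with a single class are redrawn so the metric stays defined.
#'
#' @param scores,labels pooled per-sample scores and labels.
#' @param group factor/character with two levels assigning samples to
#'   groups.
#' @param metric performance function of `(scores, labels)`.
#' @param R permutation iterations.
#' @return two-sided p-value.
#' @export
unpaired_permutation_test <- function(scores, labels, group,
                                      metric = roc_auc, R = 1e4) {
  if (R < 1) stop("R must be >= 1")
  lev <- unique(group)
  if (length(lev) != 2) stop("exactly two groups required")
  g1 <- group == lev[1]
  if (!any(g1) || all(g1)) stop("a group is empty")
  pos <- as_binary_labels(labels)
  stat <- function(g) {
    metric(scores[g], labels[g]) - metric(scores[!g], labels[!g])
  }
  obs <- stat(g1)
  n <- length(scores); n1 <- sum(g1)
  perm <- numeric(R)
  for (r in seq_len(R)) {
    for (try in 1:1000) {
      idx <- sample.int(n, n1)
      g <- seq_len(n) %in% idx
      if (length(unique(pos[g])) == 2 && length(unique(pos[!g])) == 2) break
    }
    perm[r] <- stat(g)
  }
  (1 + sum(abs(perm) >= abs(obs) - 1e-12)) / (R + 1)
}

#' Net benefit of acting on a classifier at a threshold probability
#'
#' Treated-side net benefit `TP/n - FP/n * p_t / (1 - p_t)` (benefit of
#' treating predicted positives), untreated-side net benefit
#' `TN/n - FN/n * (1 - p_t) / p_t` (benefit of withholding treatment
#' from predicted negatives), and their sum.
#'
#' @param predictions logical (or `"yes"`/`"no"`) predicted-positive
#'   indicator.
#' @param labels true class labels.
#' @param p_t threshold probability in (0, 1).
#' @return list: `treated`, `untreated`, `combined`.
#' @export
net_benefit <- function(predictions, labels, p_t) {
  if (p_t <= 0 || p_t >= 1) stop("p_t must lie strictly in (0, 1)")
  pred <- as_binary_labels(predictions)
  pos <- as_binary_labels(labels)
  n <- length(pos)
  TP <- sum(pred & pos); FP <- sum(pred & !pos)
  TN <- sum(!pred & !pos); FN <- sum(!pred & pos)
  treated <- TP / n - FP / n * p_t / (1 - p_t)
  untreated <- TN / n - FN / n * (1 - p_t) / p_t
  list(treated = treated, untreated = untreated,
       combined = treated + untreated)
}

#' Net benefit of treating every patient
#'
#' `prevalence - (1 - prevalence) * p_t / (1 - p_t)`; exactly zero when
#' the threshold equals the prevalence.
#'
#' @param labels true class labels.
#' @param p_t threshold probability in (0, 1).
#' @return numeric net benefit.
#' @export
net_benefit_treat_all <- function(labels, p_t) {
  if (p_t <= 0 || p_t >= 1) stop("p_t must lie strictly in (0, 1)")
  prev <- mean(as_binary_labels(labels))
  prev - (1 - prev) * p_t / (1 - p_t)
}

#' Decision curve analysis
#'
#' Net benefit of treating model-predicted positives (and of
#' withholding treatment from predicted negatives) across a grid of
#' threshold probabilities, against the treat-all and treat-none
#' references. Integrated (trapezoid) net benefits are computed over
#' the full grid and over a focus range of clinically reasonable
#' thresholds; the integrated combined net benefit's median and IQR
#' are taken over bootstrap resamples of the cohort.
#'
#' @param posteriors predicted probabilities.
#' @param labels true class labels.
#' @param thresholds threshold grid (default 0.01 to 0.99 step 0.01).
#' @param focus_range range over which the focus integral is taken
#'   (default c(0.3, 0.6)).
#' @param B bootstrap iterations for the combined-integral
#'   distribution (default 1000).
#' @return list: `curve` (data.frame per threshold), `integrated`
#'   (full-grid trapezoids), `integrated_focus`,
#'   `combined_median`, `combined_iqr` (bootstrap over the focus
#'   range).
#' @export
decision_curve <- function(posteriors, labels, thresholds = seq(0.01, 0.99, 0.01),
                           focus_range = c(0.3, 0.6), B = 1000) {
  pos <- as_binary_labels(labels)
  one_curve <- function(post, pos) {
    t(vapply(thresholds, function(pt) {
      nb <- net_benefit(post >= pt, pos, pt)
      c(treated = nb$treated, untreated = nb$untreated,
        combined = nb$combined,
        treat_all = net_benefit_treat_all(pos, pt))
    }, numeric(4)))
  }
  cm <- one_curve(posteriors, pos)
  curve <- data.frame(threshold = thresholds, cm)
  trap <- function(y, x) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  in_focus <- thresholds >= focus_range[1] & thresholds <= focus_range[2]
  integrated <- vapply(c("treated", "untreated", "combined", "treat_all"),
                       function(k) trap(curve[[k]], thresholds), numeric(1))
  integrated_focus <- vapply(c("treated", "untreated", "combined", "treat_all"),
                             function(k) trap(curve[[k]][in_focus],
                                              thresholds[in_focus]), numeric(1))
  n <- length(pos)
  boot <- numeric(B)
  for (b in seq_len(B)) {
    for (try in 1:1000) {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(pos[idx])) == 2) break
    }
    cb <- one_curve(posteriors[idx], pos[idx])
    boot[b] <- trap(cb[in_focus, "combined"], thresholds[in_focus])
  }
  list(curve = curve, integrated = integrated,
       integrated_focus = integrated_focus,
       combined_median = stats::median(boot),
       combined_iqr = stats::quantile(boot, c(0.25, 0.75), names = FALSE))
}

#' Calibration curve
#'
#' Bins posteriors into equal-width bins on `[0, 1]` and reports, per
#' non-empty bin, the mean predicted probability and the observed
#' event rate.
#'
#' @param posteriors predicted probabilities.
#' @param labels true class labels.
#' @param bins number of bins (>= 2).
#' @return data.frame: `bin`, `mean_posterior`, `observed_rate`, `n`.
#' @export
calibration_curve <- function(posteriors, labels, bins = 10) {
  stopifnot(bins >= 2)
  pos <- as_binary_labels(labels)
  bin <- pmin(floor(posteriors * bins) + 1, bins)
  keep <- sort(unique(bin))
  data.frame(
    bin = keep,
    mean_posterior = vapply(keep, function(b) mean(posteriors[bin == b]), numeric(1)),
    observed_rate = vapply(keep, function(b) mean(pos[bin == b]), numeric(1)),
    n = vapply(keep, function(b) sum(bin == b), numeric(1))
  )
}
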