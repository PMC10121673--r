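#' Fit the zero-inflated-exponential naive Bayes classifier
#'
#' Signature attributions are semicontinuous: many patients have
#' exactly zero attribution for a signature, the rest a positive,
#' right-skewed value. Each feature is therefore modelled per class as
#' a point mass `pi` at zero plus an exponential density with rate
#' `lambda` on positive values, combined across features under the
#' naive (conditional independence) assumption.
#'
#' Estimation per class and feature: `pi = (n_zero + 1) / (n + 2)`
#' (add-one smoothing keeps both branches strictly positive so
#' log-space posteriors never degenerate), and `lambda` as the
#' exponential maximum likelihood estimate `n_pos / sum(positives)`.
#' When a class shows no positive values for a feature, `lambda` falls
#' back to `1 / max(feature)` over all training samples (1 if the
#' feature is identically zero), keeping the density proper. Class
#' priors are the empirical class frequencies.
#'
#' @param features m x d non-negative matrix (rows samples, columns
#'   features, e.g. the per-Mb SBS4 and SBS87 attributions).
#' @param labels character vector in `c("yes","no")`.
#' @param threshold posterior decision threshold (default 0.438, the
#'   estimated population prevalence of durable benefit).
#' @return object of class `zienb`: `priors`, `pi` (d x 2), `lambda`
#'   (d x 2), `threshold`, `features`.
#' @export
zienb_fit <- function(features, labels, threshold = 0.438) {
  features <- as.matrix(features)
  if (any(features < 0)) stop("features must be non-negative")
  stopifnot(nrow(features) == length(labels), threshold > 0, threshold < 1)
  classes <- c("yes", "no")
  if (!all(classes %in% labels)) stop("both classes must appear in training")
  if (!all(labels %in% classes)) stop("labels must be 'yes' or 'no'")
  d <- ncol(features)
  fn <- colnames(features) %||% paste0("f", seq_len(d))
  pi_m <- lam <- matrix(NA_real_, d, 2, dimnames = list(fn, classes))
  for (cl in classes) {
    Fc <- features[labels == cl, , drop = FALSE]
    n <- nrow(Fc)
    for (j in seq_len(d)) {
      v <- Fc[, j]
      pos <- v[v > 0]
      pi_m[j, cl] <- (sum(v == 0) + 1) / (n + 2)
      lam[j, cl] <- if (length(pos) > 0) {
        length(pos) / sum(pos)
      } else {
        mx <- max(features[, j])
        if (mx > 0) 1 / mx else 1
      }
    }
  }
  priors <- c(yes = mean(labels == "yes"), no = mean(labels == "no"))
  structure(list(priors = priors, pi = pi_m, lambda = lam,
                 threshold = threshold, features = fn),
            class = "zienb")
}

#' @export
print.zienb <- function(x, ...) {
  cat(sprintf("zero-inflated exponential naive Bayes (%d features, threshold %.3f)\n",
              length(x$features), x$threshold))
  cat(sprintf("priors: P(DB)=%.3f P(non-DB)=%.3f\n", x$priors["yes"],
              x$priors["no"]))
  invisible(x)
}

#' Posterior probability of durable benefit
#'
#' Per-feature likelihood is the mixed mass/density: `pi` at zero,
#' `(1 - pi) lambda exp(-lambda x)` at positive values. Features are
#' multiplied under conditional independence, combined with the class
#' priors and normalised, all in log space. A priors-only model (from a
#' degenerate cross-validation fold) returns the prior.
#'
#' @param model a `zienb` model.
#' @param x feature matrix (m x d) or vector (single sample).
#' @return numeric vector of posterior DB probabilities.
#' @export
zienb_posterior <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  x <- as.matrix(x)
  if (any(x < 0)) stop("features must be non-negative")
  if (isTRUE(attr(model, "priors_only"))) {
    return(rep(unname(model$priors["yes"]), nrow(x)))
  }
  stopifnot(ncol(x) == length(model$features))
  loglik <- sapply(c("yes", "no"), function(cl) {
    ll <- log(model$priors[[cl]])
    for (j in seq_along(model$features)) {
      pi_j <- model$pi[j, cl]; lam_j <- model$lambda[j, cl]
      ll <- ll + ifelse(x[, j] == 0, log(pi_j),
                        log1p(-pi_j) + log(lam_j) - lam_j * x[, j])
    }
    ll
  })
  loglik <- matrix(loglik, ncol = 2)
  mx <- apply(loglik, 1, max)
  post <- exp(loglik - mx)
  unname(post[, 1] / rowSums(post))
}

#' Predict durable benefit
#'
#' `"yes"` when the posterior reaches the decision threshold
#' (inclusive), `"no"` otherwise.
#'
#' @param model a `zienb` model.
#' @param x feature matrix or vector.
#' @return character vector of `"yes"`/`"no"`.
#' @export
zienb_predict <- function(model, x) {
  ifelse(zienb_posterior(model, x) >= model$threshold, "yes", "no")
}

#' Leave-one-out cross-validated posteriors
#'
#' Each labelled sample is scored by a model trained on the other
#' labelled samples; unknown-label samples (censored before the DB
#' cutoff) are scored by the full-data model and marked `fold = NA` —
#' they enter only the PFS analysis downstream. A training fold that
#' loses one class entirely falls back to a priors-only model (logged).
#'
#' @param features m x d feature matrix.
#' @param labels per-sample labels in `c("yes","no","unknown")`.
#' @param threshold decision threshold (default 0.438).
#' @return data.frame: `sample`, `posterior`, `predicted`, `fold`.
#' @export
zienb_loocv <- function(features, labels, threshold = 0.438) {
  features <- as.matrix(features)
  stopifnot(nrow(features) == length(labels))
  labelled <- which(labels %in% c("yes", "no"))
  if (length(labelled) < 3) stop("need >= 3 labelled samples for LOOCV")
  m <- nrow(features)
  posterior <- numeric(m)
  fold <- rep(NA_integer_, m)
  for (k in seq_along(labelled)) {
    i <- labelled[k]
    tr <- setdiff(labelled, i)
    tr_lab <- labels[tr]
    model <- if (length(unique(tr_lab)) < 2) {
      sb_log("fold ", k, ": single-class training set, priors-only model",
             level = "WARN")
      pm <- structure(list(priors = c(yes = mean(tr_lab == "yes"),
                                      no = mean(tr_lab == "no")),
                           threshold = threshold), class = "zienb")
      attr(pm, "priors_only") <- TRUE
      pm
    } else {
      zienb_fit(features[tr, , drop = FALSE], tr_lab, threshold)
    }
    posterior[i] <- zienb_posterior(model, features[i, , drop = FALSE])
    fold[i] <- k
  }
  if (length(labelled) < m) {
    full <- zienb_fit(features[labelled, , drop = FALSE], labels[labelled],
                      threshold)
    rest <- setdiff(seq_len(m), labelled)
    posterior[rest] <- zienb_posterior(full, features[rest, , drop = FALSE])
  }
  data.frame(sample = rownames(features) %||% as.character(seq_len(m)),
             posterior = posterior,
             predicted = ifelse(posterior >= threshold, "yes", "no"),
             fold = fold, stringsAsFactors = FALSE)
}

#' Serialise a fitted classifier to JSON
#' @param model a `zienb` model.
#' @param path output path.
#' @export
write_zienb <- function(model, path) {
  jsonlite::write_json(list(
    priors = as.list(model$priors),
    pi = as.data.frame(model$pi),
    lambda = as.data.frame(model$lambda),
    threshold = model$threshold,
    features = model$features), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a classifier serialised by [write_zienb()]
#' @param path JSON path.
#' @return a `zienb` model.
#' @export
read_zienb <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  pi_m <- as.matrix(j$pi); lam <- as.matrix(j$lambda)
  rownames(pi_m) <- rownames(lam) <- j$features
  structure(list(priors = unlist(j$priors), pi = pi_m, lambda = lam,
                 threshold = j$threshold, features = j$features),
            class = "zienb")
}
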