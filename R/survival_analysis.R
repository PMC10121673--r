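#' Kaplan-Meier estimate with median survival
#'
#' Product-limit estimator of the survival function, with the median
#' defined as the smallest time at which the estimate drops to 0.5 or
#' below (`NA` when never reached, e.g. under heavy censoring).
#'
#' @param times non-negative follow-up times (weeks).
#' @param events logical event indicator.
#' @return list: `time`, `surv` (step function support/values),
#'   `median`, and the underlying `survival::survfit` object as `fit`.
#' @export
kaplan_meier <- function(times, events) {
  if (any(times < 0)) stop("negative follow-up time")
  fit <- survival::survfit(survival::Surv(times, as.integer(events)) ~ 1)
  # median as inf{t : S(t) <= 0.5}; survfit's own summary interpolates
  # when the curve sits exactly at 0.5, which is not wanted here
  below <- which(fit$surv <= 0.5)
  med <- if (length(below) > 0) fit$time[min(below)] else NA_real_
  list(time = fit$time, surv = fit$surv, median = med, fit = fit)
}

#' Cox proportional hazards for a binary predictor
#'
#' Fits the partial likelihood with Breslow tie handling and reports
#' the hazard ratio of the second group level versus the first with a
#' Wald 95 % confidence interval `exp(beta +/- 1.96 se)` and p-value.
#' A group without any event makes the partial likelihood monotone;
#' the fit is then flagged inestimable.
#'
#' @param times follow-up times.
#' @param events logical event indicator.
#' @param group two-level factor/character/logical predictor.
#' @return object of class `hr_fit`: `beta`, `se`, `hr`, `lower`,
#'   `upper`, `minus`, `plus`, `p`, `estimable`.
#' @export
cox_binary <- function(times, events, group) {
  g <- factor(group)
  if (nlevels(g) != 2) stop("group must have exactly two levels")
  ev <- as.logical(events)
  ev_by_group <- tapply(ev, g, sum)
  if (any(ev_by_group == 0)) {
    sb_log("no events in group '", names(which(ev_by_group == 0))[1],
           "': monotone partial likelihood, no estimate", level = "WARN")
    return(structure(list(beta = NA_real_, se = NA_real_, hr = NA_real_,
                          lower = NA_real_, upper = NA_real_,
                          minus = NA_real_, plus = NA_real_, p = NA_real_,
                          estimable = FALSE), class = "hr_fit"))
  }
  fit <- survival::coxph(survival::Surv(times, as.integer(ev)) ~ g,
                         ties = "breslow")
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(stats::vcov(fit)[1, 1]))
  hr <- exp(beta)
  lower <- exp(beta - 1.96 * se); upper <- exp(beta + 1.96 * se)
  z <- beta / se
  structure(list(beta = beta, se = se, hr = hr, lower = lower, upper = upper,
                 minus = hr - lower, plus = upper - hr,
                 p = 2 * stats::pnorm(-abs(z)), estimable = TRUE,
                 cox = fit), class = "hr_fit")
}

#' @export
print.hr_fit <- function(x, ...) {
  if (!x$estimable) {
    cat("hazard ratio: not estimable (no events in a group)\n")
  } else {
    cat(sprintf("hazard ratio %.2f (95%% CI %.2f-%.2f), p = %.2g\n",
                x$hr, x$lower, x$upper, x$p))
  }
  invisible(x)
}

#' Build a hazard-ratio fit from a printed estimate and interval
#'
#' Reconstructs the log-hazard standard error from a published 95 %
#' confidence interval as `(log(upper) - log(lower)) / (2 * 1.96)`, so
#' printed results can enter [compare_hazard_ratios()].
#'
#' @param hr point estimate of the hazard ratio.
#' @param lower,upper 95 % confidence bounds.
#' @return an `hr_fit` object.
#' @export
hr_from_ci <- function(hr, lower, upper) {
  stopifnot(hr > 0, lower > 0, upper > lower)
  se <- (log(upper) - log(lower)) / (2 * 1.96)
  structure(list(beta = log(hr), se = se, hr = hr, lower = lower,
                 upper = upper, minus = hr - lower, plus = upper - hr,
                 p = NA_real_, estimable = TRUE), class = "hr_fit"
  )
}

#' Compare two independent hazard ratios
#'
#' Regression-coefficient test on the log scale:
#' `z = (beta1 - beta2) / sqrt(se1^2 + se2^2)` with a two-sided normal
#' p-value. Accepts fits from [cox_binary()] or reconstructed ones from
#' [hr_from_ci()].
#'
#' @param fit1,fit2 `hr_fit` objects with finite `beta` and `se`.
#' @return list: `z`, `p`.
#' @export
compare_hazard_ratios <- function(fit1, fit2) {
  for (f in list(fit1, fit2)) {
    if (!inherits(f, "hr_fit") || !isTRUE(f$estimable) ||
        !is.finite(f$beta) || !is.finite(f$se)) {
      stop("both fits need a finite log-hazard coefficient and SE")
    }
  }
  z <- (fit1$beta - fit2$beta) / sqrt(fit1$se^2 + fit2$se^2)
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Proportional-hazards diagnostic
#'
#' Scaled Schoenfeld-residual trend test against time for the binary
#' predictor. Undefined (flagged) with fewer than two events.
#'
#' @inheritParams cox_binary
#' @return list: `p`, `defined`.
#' @export
ph_check <- function(times, events, group) {
  if (sum(as.logical(events)) < 2) {
    return(list(p = NA_real_, defined = FALSE))
  }
  fit <- cox_binary(times, events, group)
  if (!fit$estimable) return(list(p = NA_real_, defined = FALSE))
  zph <- survival::cox.zph(fit$cox)
  list(p = unname(zph$table[1, "p"]), defined = TRUE)
}
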