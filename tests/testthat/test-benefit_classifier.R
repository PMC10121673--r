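test_that("zero-inflated exponential fit matches hand maximum likelihood", {
  feats <- matrix(c(0, 0, 1.0, 3.0, 2.0, 0, 0, 0), ncol = 1,
                  dimnames = list(NULL, "SBS4"))
  labels <- c(rep("yes", 4), rep("no", 4))
  model <- zienb_fit(feats, labels)
  expect_equal(unname(model$pi["SBS4", "yes"]), 0.5)      # (2+1)/(4+2)
  expect_equal(unname(model$lambda["SBS4", "yes"]), 0.5)  # 2 / 4.0
  expect_equal(unname(model$priors), c(0.5, 0.5))

  # class with only one positive value
  expect_equal(unname(model$pi["SBS4", "no"]), 4 / 6)
  expect_equal(unname(model$lambda["SBS4", "no"]), 1 / 2.0)

  # all-zero feature in a class: smoothed mass and fallback rate
  feats2 <- matrix(c(0, 0, 0, 4, 2, 0), ncol = 1)
  model2 <- zienb_fit(feats2, c("yes", "yes", "yes", "no", "no", "no"))
  expect_equal(unname(model2$pi[1, "yes"]), 4 / 5)        # (3+1)/(3+2)
  expect_equal(unname(model2$lambda[1, "yes"]), 1 / 4)    # 1 / max(feature)

  expect_error(zienb_fit(feats, rep("yes", 8)), "both classes")
  expect_error(zienb_fit(-feats, labels), "non-negative")
})

test_that("posterior follows the mixed mass/density Bayes computation", {
  model <- structure(list(
    priors = c(yes = 0.4, no = 0.6),
    pi = matrix(c(0.2, 0.6), 1, 2, dimnames = list("f", c("yes", "no"))),
    lambda = matrix(c(1, 1), 1, 2, dimnames = list("f", c("yes", "no"))),
    threshold = 0.438, features = "f"), class = "zienb")
  # at x = 0 the likelihood is the zero mass: 0.4*0.2 / (0.4*0.2 + 0.6*0.6)
  expect_equal(zienb_posterior(model, 0), 0.08 / 0.44, tolerance = 1e-12)

  # at x > 0: (1-pi) * lambda * exp(-lambda x) per class
  model$pi[] <- c(0.2, 0.6); model$lambda[] <- c(0.5, 2.0)
  x <- 1.0
  lik_yes <- 0.8 * 0.5 * exp(-0.5)      # = 0.2426
  lik_no <- 0.4 * 2.0 * exp(-2.0)
  expect_equal(lik_yes, 0.2426, tolerance = 1e-4)
  expect_equal(zienb_posterior(model, x),
               0.4 * lik_yes / (0.4 * lik_yes + 0.6 * lik_no),
               tolerance = 1e-12)

  # identical parameters in both classes: posterior equals the prior
  model$pi[] <- 0.3; model$lambda[] <- 1.2
  for (xv in c(0, 0.5, 7)) expect_equal(zienb_posterior(model, xv), 0.4)
})

test_that("posterior is normalised and class-symmetric", {
  set.seed(61)
  feats <- matrix(rexp(60) * rbinom(60, 1, 0.7), 30, 2,
                  dimnames = list(NULL, c("a", "b")))
  labels <- rep(c("yes", "no"), 15)
  model <- zienb_fit(feats, labels)
  p <- zienb_posterior(model, feats)
  expect_true(all(p > 0 & p < 1))
  # swapping the class roles gives the complementary posterior
  swapped <- model
  swapped$priors <- model$priors[c(2, 1)]; names(swapped$priors) <- c("yes", "no")
  swapped$pi <- model$pi[, c(2, 1)]; colnames(swapped$pi) <- c("yes", "no")
  swapped$lambda <- model$lambda[, c(2, 1)]; colnames(swapped$lambda) <- c("yes", "no")
  expect_equal(p + zienb_posterior(swapped, feats), rep(1, 30),
               tolerance = 1e-12)
})

test_that("posterior is invariant under feature rescaling with matched rates", {
  set.seed(62)
  feats <- matrix(rexp(40) * rbinom(40, 1, 0.6), 20, 2,
                  dimnames = list(NULL, c("a", "b")))
  labels <- rep(c("yes", "no"), 10)
  model <- zienb_fit(feats, labels)
  scaled <- model
  c_scale <- 7.3
  scaled$lambda[1, ] <- model$lambda[1, ] / c_scale
  feats_scaled <- feats
  feats_scaled[, 1] <- feats[, 1] * c_scale
  expect_equal(zienb_posterior(scaled, feats_scaled),
               zienb_posterior(model, feats), tolerance = 1e-12)
})

test_that("prediction threshold is inclusive at the decision boundary", {
  model <- structure(list(priors = c(yes = 0.438, no = 0.562),
                          threshold = 0.438), class = "zienb")
  attr(model, "priors_only") <- TRUE
  # priors-only posterior is exactly the prior 0.438: classified DB
  expect_equal(zienb_predict(model, matrix(1)), "yes")
  model$threshold <- 0.4381
  expect_equal(zienb_predict(model, matrix(1)), "no")
  model$threshold <- 1e-9
  expect_equal(zienb_predict(model, matrix(1)), "yes")
})

test_that("parameters are recovered from model-simulated data", {
  set.seed(63)
  n <- 500
  pi_true <- c(yes = 0.03, no = 0.03); lam_true <- c(yes = 0.02, no = 0.1)
  ok <- replicate(20, {
    gen <- function(pi0, lam, n) ifelse(runif(n) < pi0, 0, rexp(n, lam))
    feats <- matrix(c(gen(pi_true["yes"], lam_true["yes"], n),
                      gen(pi_true["no"], lam_true["no"], n)), ncol = 1)
    model <- zienb_fit(feats, rep(c("yes", "no"), each = n))
    vapply(c("yes", "no"), function(cl) {
      abs(model$pi[1, cl] - pi_true[[cl]]) <= 0.05 &&
        abs(model$lambda[1, cl] / lam_true[[cl]] - 1) <= 0.1
    }, logical(1))
  })
  expect_gte(mean(ok), 0.9)
})

test_that("LOOCV scores every labelled sample out of fold", {
  set.seed(64)
  cfg <- sim_config(m_patients = 60, p_signatures = 6, informative = c(1, 2))
  act <- simulate_activities(cfg)
  feats <- normalise_attribution(act$W[, cfg$informative], cfg$coverage_mb)
  labels <- ifelse(act$class == "db", "yes", "no")
  labels[1:4] <- "unknown"
  res <- zienb_loocv(feats, labels)
  expect_equal(nrow(res), 60)
  expect_true(all(!is.na(res$fold[labels != "unknown"])))
  expect_true(all(is.na(res$fold[labels == "unknown"])))

  # duplicated rows receive identical out-of-fold posteriors
  feats_dup <- rbind(feats, feats)
  labels_dup <- c(labels, labels)
  res_dup <- zienb_loocv(feats_dup, labels_dup)
  lab_idx <- which(labels != "unknown")
  expect_equal(res_dup$posterior[lab_idx], res_dup$posterior[60 + lab_idx],
               tolerance = 1e-10)
})

test_that("informative features stay K-S significant in every LOOCV fold", {
  set.seed(65)
  cfg <- sim_config(m_patients = 90, p_signatures = 6, informative = c(1, 2))
  act <- simulate_activities(cfg)
  W_norm <- normalise_attribution(act$W, cfg$coverage_mb)
  labels <- ifelse(act$class == "db", "yes", "no")
  labelled <- seq_along(labels)
  all_significant <- vapply(labelled, function(i) {
    tr <- setdiff(labelled, i)
    res <- screen_signatures(W_norm[tr, cfg$informative, drop = FALSE],
                             labels[tr])
    all(res$significant)
  }, logical(1))
  expect_true(all(all_significant))
})

test_that("classifier JSON serialisation round-trips", {
  set.seed(66)
  feats <- matrix(rexp(40) * rbinom(40, 1, 0.6), 20, 2,
                  dimnames = list(NULL, c("SBS4", "SBS87")))
  model <- zienb_fit(feats, rep(c("yes", "no"), 10))
  path <- tempfile(fileext = ".json")
  write_zienb(model, path)
  model2 <- read_zienb(path)
  expect_equal(model2$pi, model$pi)
  expect_equal(model2$lambda, model$lambda)
  expect_equal(model2$priors, model$priors)
  expect_equal(zienb_posterior(model2, feats), zienb_posterior(model, feats))
})
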