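test_that("K-S statistic and small-sample exact p match enumeration", {
  same <- ks_two_sample(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$D, 0)
  expect_equal(same$p, 1)

  sep <- ks_two_sample(c(1, 2, 3), c(4, 5, 6))
  expect_equal(sep$D, 1)
  expect_equal(sep$p, 0.1)                       # 2 / choose(6, 3)
  expect_equal(sep$p, ks_p_oracle(c(1, 2, 3), c(4, 5, 6)))

  set.seed(41)
  for (rep in 1:20) {
    a <- rnorm(sample(2:15, 1)); b <- rnorm(sample(2:15, 1), sample(0:2, 1))
    expect_equal(ks_two_sample(a, b)$D, ks_D_oracle(a, b), tolerance = 1e-12)
  }
  expect_error(ks_two_sample(numeric(0), 1:3), "empty")
})

test_that("K-S p-values are super-uniform under the null", {
  set.seed(42)
  p <- replicate(2000, ks_two_sample(rnorm(8), rnorm(8))$p)
  rate <- mean(p <= 0.05)
  expect_lt(rate, 0.05 + 3 * sqrt(0.05 * 0.95 / 2000))
})

test_that("Benjamini-Hochberg matches the hand example and step-up rule", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(benjamini_hochberg(rep(1, 5)), rep(1, 5))
  expect_equal(benjamini_hochberg(0.2), 0.2)
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(43)
  for (rep in 1:20) {
    p <- runif(sample(3:30, 1))^sample(1:3, 1)
    q <- benjamini_hochberg(p)
    expect_true(all(q[order(p)] == cummax(q[order(p)])))   # monotone in p
    for (alpha in c(0.01, 0.05, 0.2)) {
      expect_equal(q <= alpha, bh_reject_oracle(p, alpha))
    }
  }
})

test_that("Kendall tau-b handles ties and degenerate input", {
  expect_equal(kendall_tau(1:3, 1:3)$tau, 1)
  expect_equal(kendall_tau(1:3, 3:1)$tau, -1)
  expect_equal(kendall_tau(c(1, 1, 2), c(1, 2, 2))$tau, 0.5)
  deg <- kendall_tau(c(2, 2, 2), c(1, 2, 3))
  expect_true(deg$excluded)
  expect_true(is.na(deg$tau))
})

test_that("Fisher exact p matches hypergeometric enumeration", {
  expect_equal(fisher_exact_2x2(matrix(c(2, 0, 0, 2), 2)), 1 / 3,
               tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(matrix(1, 2, 2)), 1)
  expect_error(fisher_exact_2x2(matrix(c(-1, 1, 1, 1), 2)), "non-negative")

  set.seed(44)
  for (rep in 1:25) {
    tab <- matrix(rpois(4, 4), 2)
    expect_equal(fisher_exact_2x2(tab), fisher_p_oracle(tab),
                 tolerance = 1e-9)
    expect_equal(fisher_exact_2x2(tab), fisher_exact_2x2(t(tab)),
                 tolerance = 1e-12)
  }
})

test_that("signature screening flags informative signatures, not nulls", {
  set.seed(45)
  cfg <- sim_config(m_patients = 400, p_signatures = 20)
  act <- simulate_activities(cfg)
  W <- act$W
  labels <- ifelse(act$class == "db", "yes", "no")
  res <- screen_signatures(W, labels)
  expect_setequal(res$signature[res$significant],
                  cfg$signatures[cfg$informative])

  # identical strata: a signature equal in both groups is never flagged
  Wsame <- W
  Wsame[, 1] <- rep(1.5, nrow(W))
  res2 <- screen_signatures(Wsame, labels)
  expect_false(res2$significant[res2$signature == cfg$signatures[1]])
  expect_equal(res2$q[res2$signature == cfg$signatures[1]], 1)

  # shuffled labels (complete null): flagged fraction within FDR control
  set.seed(46)
  frac <- replicate(30, {
    r <- screen_signatures(W, sample(labels))
    mean(r$significant)
  })
  expect_lte(mean(frac), 0.05)
  expect_error(screen_signatures(W, rep("yes", nrow(W))), "empty")
})

test_that("gene counting respects BED half-open intervals", {
  bed <- data.frame(chrom = "chr1", start = c(0, 10), end = c(10, 20),
                    gene = c("GA", "GB"), stringsAsFactors = FALSE)
  v <- data.frame(sample_id = c("s1", "s1", "s2"),
                  chrom = "chr1", pos = c(10, 11, 15),
                  is_nonsynonymous = TRUE, stringsAsFactors = FALSE)
  counts <- count_gene_mutations(v, bed, samples = c("s1", "s2"))
  # BED [0,10) covers positions 1..10; [10,20) covers 11..20
  expect_equal(unname(counts["GA", ]), c(1L, 0L))
  expect_equal(unname(counts["GB", ]), c(1L, 1L))
})

test_that("gene correlation detects planted dependence and excludes dead genes", {
  set.seed(47)
  m <- 300
  w <- stats::setNames(rexp(m, 1 / 40), sprintf("s%03d", 1:m))
  counts <- rbind(
    planted = rbinom(m, size = round(w), prob = 0.15),  # thinned copy of w
    null1 = rpois(m, 2),
    null2 = rpois(m, 2),
    dead = rep(0L, m)
  )
  colnames(counts) <- names(w)
  res <- gene_correlation(w, counts)
  expect_false("dead" %in% res$gene)              # excluded before correction
  expect_true(res$significant[res$gene == "planted"])
  expect_gt(res$tau[res$gene == "planted"], 0)

  # counts independent of the attribution: the chance that anything
  # survives correction stays at the FDR level (within Monte-Carlo error)
  set.seed(48)
  hits <- replicate(100, {
    indep <- matrix(rpois(5 * m, 2), 5,
                    dimnames = list(paste0("g", 1:5), names(w)))
    any(gene_correlation(w, indep)$significant)
  })
  expect_lte(mean(hits), 0.05 + 3 * sqrt(0.05 * 0.95 / 100))
})

test_that("logistic confounding check matches a likelihood oracle and nulls out", {
  set.seed(49)
  # coefficients agree with a generic ML optimiser on small random data
  for (rep in 1:5) {
    n <- 40
    tmb_v <- rexp(n, 1 / 5)
    g <- rbinom(n, 1, 0.4)
    y <- rbinom(n, 1, plogis(-1 + 0.2 * tmb_v + 0.5 * g))
    res <- logistic_confounding(ifelse(y == 1, "yes", "no"), tmb_v, g)
    nll <- function(b) -sum(y * (b[1] + b[2] * tmb_v + b[3] * g) -
                              log1p(exp(b[1] + b[2] * tmb_v + b[3] * g)))
    opt <- stats::optim(c(0, 0, 0), nll, method = "BFGS",
                        control = list(reltol = 1e-14))
    expect_equal(res$coef_tmb_adjusted, opt$par[2], tolerance = 1e-4)
    expect_equal(res$coef_gene, opt$par[3], tolerance = 1e-4)
  }

  # gene independent of outcome and TMB: coefficient barely moves
  set.seed(50)
  n <- 10000
  tmb_v <- rexp(n, 1 / 5)
  y <- rbinom(n, 1, plogis(-1 + 0.15 * tmb_v))
  g <- rbinom(n, 1, 0.3)
  res <- logistic_confounding(ifelse(y == 1, "yes", "no"), tmb_v, g)
  expect_lt(res$change_ratio, 0.05)
  expect_false(res$confounding)
  expect_true(res$converged)

  # perfect separation is flagged as non-converged
  sep <- suppressWarnings(
    logistic_confounding(c("yes", "yes", "no", "no"),
                         c(10, 9, 1, 2), c(1, 1, 0, 0)))
  expect_false(sep$converged)
})

test_that("mutated-transcript differential abundance uses the K-S/B-H battery", {
  set.seed(51)
  labels <- rep(c("yes", "no"), each = 15)
  counts <- rbind(
    shifted = c(rnbinom(15, mu = 30, size = 2), rnbinom(15, mu = 2, size = 2)),
    flat = rnbinom(30, mu = 5, size = 2)
  )
  colnames(counts) <- paste0("s", 1:30)
  res <- de_bhks(counts, labels)
  expect_true(res$significant[res$gene == "shifted"])
  expect_false(res$significant[res$gene == "flat"])
  expect_true(all(res$q >= res$p))
})
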