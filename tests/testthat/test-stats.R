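test_that("Fisher exact matches exhaustive hypergeometric enumeration", {
  tables <- list(c(13, 40, 0, 20), c(13, 48, 0, 11), c(1, 1, 1, 1),
                 c(5, 0, 0, 5), c(2, 7, 8, 2), c(0, 10, 10, 0), c(3, 3, 3, 3))
  for (tb in tables) {
    got <- fisher_exact(tb[1], tb[2], tb[3], tb[4])$p_two_sided
    expect_equal(got, fisher_oracle(tb[1], tb[2], tb[3], tb[4]), tolerance = 1e-9)
  }
  set.seed(31)
  for (i in 1:50) {
    tb <- rmultinom(1, sample(4:60, 1), prob = runif(4, 0.05, 1))[, 1]
    got <- fisher_exact(tb[1], tb[2], tb[3], tb[4])$p_two_sided
    expect_equal(got, fisher_oracle(tb[1], tb[2], tb[3], tb[4]), tolerance = 1e-9)
  }
})

test_that("Fisher p is invariant to transposition and row swap; margins degenerate to 1", {
  set.seed(32)
  for (i in 1:25) {
    tb <- rmultinom(1, 40, prob = runif(4, 0.05, 1))[, 1]
    p0 <- fisher_exact(tb[1], tb[2], tb[3], tb[4])$p_two_sided
    expect_equal(fisher_exact(tb[1], tb[3], tb[2], tb[4])$p_two_sided, p0,
                 tolerance = 1e-12)  # transpose
    expect_equal(fisher_exact(tb[3], tb[4], tb[1], tb[2])$p_two_sided, p0,
                 tolerance = 1e-12)  # row swap
  }
  expect_equal(fisher_exact(0, 0, 5, 7)$p_two_sided, 1)
  expect_equal(fisher_exact(0, 4, 0, 7)$p_two_sided, 1)
  expect_equal(fisher_exact(1, 1, 1, 1)$p_two_sided, 1)
  expect_equal(fisher_exact(6, 2, 1, 9)$odds_ratio, 27)
  expect_equal(fisher_exact(5, 0, 0, 5)$odds_ratio, Inf)
})

test_that("pairwise co-occurrence detects coupled and constant gene columns", {
  m <- cbind(geneA = rep(c(TRUE, FALSE), each = 10),
             geneB = rep(c(TRUE, FALSE), each = 10))
  res <- pairwise_cooccurrence(m)
  expect_equal(res$odds_ratio, Inf)
  expect_lt(res$p, 0.01)
  expect_equal(res$direction, "co_occurrence")
  # exclusive pattern
  m2 <- cbind(geneA = rep(c(TRUE, FALSE), each = 10),
              geneB = rep(c(FALSE, TRUE), each = 10))
  expect_equal(pairwise_cooccurrence(m2)$direction, "exclusivity")
  # constant column: p = 1, direction undefined
  m3 <- cbind(geneA = rep(TRUE, 8), geneB = rep(c(TRUE, FALSE), 4))
  res3 <- pairwise_cooccurrence(m3)
  expect_equal(res3$p, 1)
  expect_true(is.na(res3$direction))
  # single case
  m4 <- cbind(geneA = TRUE, geneB = FALSE)
  expect_equal(pairwise_cooccurrence(m4)$p, 1)
  # BH adjustment adds a column, never smaller than raw p
  m5 <- matrix(runif(60) < 0.4, 20, 3,
               dimnames = list(NULL, c("g1", "g2", "g3")))
  res5 <- pairwise_cooccurrence(m5, adjust = TRUE)
  expect_true(all(res5$p_adj >= res5$p - 1e-12))
})

test_that("independent gene columns give approximately uniform p-values", {
  set.seed(33)
  ps <- replicate(400, {
    m <- cbind(a = runif(40) < 0.5, b = runif(40) < 0.5)
    pairwise_cooccurrence(m)$p
  })
  # Fisher p is discrete and conservative; check location and spread coarsely
  expect_gt(mean(ps), 0.45)
  expect_gt(mean(ps < 0.2), 0.05)
  expect_lt(mean(ps < 0.05), 0.08)
})

test_that("Mann-Whitney U reproduces exact enumeration and handles ties", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$p_two_sided, 0.1)   # 2/20 arrangements as extreme
  expect_equal(r$rank_biserial, -1)
  tied <- mann_whitney_u(c(1, 2, 2, 3), c(1, 2, 2, 3))
  expect_equal(tied$p_two_sided, 1)
  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
  # power exceeds the type-I rate for a location shift
  set.seed(34)
  rej_null <- mean(replicate(300, mann_whitney_u(rnorm(50), rnorm(50))$p_two_sided < 0.05))
  rej_alt <- mean(replicate(300, mann_whitney_u(rnorm(50), rnorm(50, 0.8))$p_two_sided < 0.05))
  expect_lt(rej_null, 0.1)
  expect_gt(rej_alt, 0.9)
})

test_that("correlation tests behave under transforms and reject degenerate input", {
  x <- c(1, 3, 4, 7, 9, 12)
  expect_equal(correlation_test(x, 2 * x, "pearson")$estimate, 1)
  y <- exp(x)   # monotone, nonlinear
  expect_equal(correlation_test(x, y, "spearman")$estimate, 1)
  expect_lt(correlation_test(x, y, "pearson")$estimate, 1)
  expect_error(correlation_test(x, rep(1, 6)), "zero-variance")
  expect_error(correlation_test(x, x[-1]), "paired")
  set.seed(35)
  r <- correlation_test(rnorm(100), rnorm(100))$estimate
  expect_lt(abs(r), 0.3)
})

test_that("ROC analysis: AUC, Youden cut-point and confusion metrics", {
  # perfect separation
  r <- roc_auc(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))
  expect_equal(r$auc, 1)
  expect_equal(r$youden_j, 1)
  # ordinal example: positives score 3-4, negatives 1-2
  r2 <- roc_auc(c(3, 4, 1, 2), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r2$cutpoint, 3)
  expect_equal(r2$sensitivity, 1)
  expect_equal(r2$specificity, 1)
  expect_equal(r2$accuracy, 1)
  # tie in J resolved toward the lowest threshold
  r3 <- roc_auc(c(0, 1, 2, 3), c(FALSE, TRUE, TRUE, TRUE))
  expect_equal(r3$cutpoint, 1)
  expect_error(roc_auc(1:4, c(TRUE, TRUE, TRUE, TRUE)), "both classes")
  # curve endpoints and monotonicity
  set.seed(36)
  sc <- rnorm(60); lb <- runif(60) < 0.4
  rr <- roc_auc(sc, lb)
  expect_equal(rr$roc_points$fpr[1], 0)
  expect_equal(rr$roc_points$tpr[nrow(rr$roc_points)], 1)
  expect_true(all(diff(rr$roc_points$fpr) >= 0))
  expect_true(all(diff(rr$roc_points$tpr) >= 0))
})

test_that("AUC equals the Mann-Whitney identity and is rank-invariant", {
  set.seed(37)
  sc <- sample(seq(0.01, 0.99, by = 0.01), 40)   # tie-free
  lb <- runif(40) < 0.5
  if (sum(lb) == 0 || sum(!lb) == 0) lb[1:2] <- c(TRUE, FALSE)
  r <- roc_auc(sc, lb)
  U <- sum(vapply(sc[lb], function(s) sum(s > sc[!lb]) + 0.5 * sum(s == sc[!lb]),
                  numeric(1)))
  expect_equal(r$auc, U / (sum(lb) * sum(!lb)), tolerance = 1e-12)
  # strictly monotone transform leaves the curve unchanged
  r2 <- roc_auc(exp(3 * sc), lb)
  expect_equal(r2$auc, r$auc, tolerance = 1e-12)
  expect_equal(r2$roc_points[, c("fpr", "tpr")], r$roc_points[, c("fpr", "tpr")])
  # random labels at large n give AUC near 1/2
  set.seed(38)
  big <- roc_auc(rnorm(4000), runif(4000) < 0.5)
  expect_lt(abs(big$auc - 0.5), 0.05)
})

test_that("AUC agrees with an established ROC implementation", {
  set.seed(39)
  sc <- rnorm(80); lb <- runif(80) < 0.45
  ours <- roc_auc(sc, lb)$auc
  ref <- suppressMessages(as.numeric(pROC::auc(pROC::roc(lb, sc, quiet = TRUE))))
  expect_equal(ours, ref, tolerance = 1e-10)
})
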