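test_that("ROC handles direction and separable data", {
  r <- rocCurve(c(1, 2, 3, 4), c(TRUE, TRUE, FALSE, FALSE),
                "lower_is_positive")
  expect_equal(r$auc, 1)
  rf <- rocCurve(c(1, 2, 3, 4), c(TRUE, TRUE, FALSE, FALSE),
                 "higher_is_positive")
  expect_equal(rf$auc, 0)
  expect_error(rocCurve(1:4, rep(TRUE, 4)), "each class")
  expect_true(r$auc >= r$auc_ci95[1] && r$auc <= r$auc_ci95[2])
})

test_that("AUC equals exhaustive pair enumeration on random data", {
  set.seed(17)
  for (i in 1:50) {
    n <- sample(6:40, 1)
    vals <- round(rnorm(n, 10, 3), sample(0:2, 1))   # induce ties sometimes
    labs <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(labs) || all(labs)) next
    dir <- sample(c("lower_is_positive", "higher_is_positive"), 1)
    r <- rocCurve(vals, labs, dir)
    expect_equal(r$auc, aucByPairs(vals, labs, dir), tolerance = 1e-12)
  }
})

test_that("AUC of the flipped direction is the complement on tie-free data", {
  set.seed(23)
  vals <- rnorm(30)
  labs <- rep(c(TRUE, FALSE), 15)
  a <- rocCurve(vals, labs, "lower_is_positive")$auc
  b <- rocCurve(vals, labs, "higher_is_positive")$auc
  expect_equal(a + b, 1)
})

test_that("Youden cutoff matches hand-worked and brute-force optima", {
  r <- rocCurve(c(0, 1, 2.5, 2, 3, 4), rep(c(TRUE, FALSE), each = 3),
                "lower_is_positive")
  y <- youdenCutoff(r)
  expect_equal(y$cutoff, 2.75)
  expect_equal(y$J, 2 / 3, tolerance = 1e-12)
  expect_equal(y$sens, 1)
  expect_equal(y$spec, 2 / 3, tolerance = 1e-12)

  sep <- rocCurve(c(1, 2, 3, 4), c(TRUE, TRUE, FALSE, FALSE),
                  "lower_is_positive")
  ys <- youdenCutoff(sep)
  expect_equal(ys$J, 1)
  expect_equal(ys$cutoff, 2.5)

  set.seed(31)
  for (i in 1:50) {
    n <- sample(8:40, 1)
    vals <- round(rnorm(n, 5, 2), sample(1:2, 1))
    labs <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(labs) || all(labs)) next
    dir <- sample(c("lower_is_positive", "higher_is_positive"), 1)
    y <- youdenCutoff(rocCurve(vals, labs, dir))
    expect_equal(y$J, youdenByGrid(vals, labs, dir), tolerance = 1e-12)
  }
})

test_that("Youden decision is invariant under strictly monotone transforms", {
  set.seed(37)
  vals <- rnorm(25, 3, 1)
  labs <- sample(c(TRUE, FALSE), 25, replace = TRUE, prob = c(0.6, 0.4))
  y1 <- youdenCutoff(rocCurve(vals, labs, "lower_is_positive"))
  y2 <- youdenCutoff(rocCurve(exp(vals), labs, "lower_is_positive"))
  expect_equal(y1$J, y2$J, tolerance = 1e-12)
  expect_equal(y1$sens, y2$sens)
  expect_equal(y1$spec, y2$spec)
  # the cutoff maps through the transform: same cases called positive
  expect_equal(vals < y1$cutoff, exp(vals) < y2$cutoff)
})

test_that("DeLong comparison is internally consistent and matches enumeration", {
  set.seed(41)
  vals <- rnorm(20); labs <- rep(c(TRUE, FALSE), 10)
  r <- rocCurve(vals, labs, "higher_is_positive")
  self <- delongCompare(r, r, paired = TRUE)
  expect_equal(self$z, 0)
  expect_equal(self$p, 1)

  # CI half-width implied variance equals the stored DeLong variance
  half <- (r$auc_ci95[2] - r$auc_ci95[1]) / 2
  expect_equal(half, qnorm(0.975) * sqrt(r$auc_var), tolerance = 1e-10)

  # 6-subject toy data: structural components enumerated by hand
  xa <- c(3, 5, 9);  ya <- c(1, 4, 8)     # marker A: pos 3,5,9 / neg 1,4,8
  psi <- function(x, y) (x > y) + 0.5 * (x == y)
  V10 <- sapply(xa, function(x) mean(sapply(ya, function(y) psi(x, y))))
  V01 <- sapply(ya, function(y) mean(sapply(xa, function(x) psi(x, y))))
  manual <- var(V10) / 3 + var(V01) / 3
  ra <- rocCurve(c(xa, ya), rep(c(TRUE, FALSE), each = 3),
                 "higher_is_positive")
  expect_equal(ra$auc, mean(outer(xa, ya, ">") + 0.5 * outer(xa, ya, "==")))
  expect_equal(ra$auc_var, manual, tolerance = 1e-12)

  # paired variance equals var_a + var_b - 2 cov of the components
  vb <- c(2, 7, 6, 1, 5, 8)
  rb <- rocCurve(vb, rep(c(TRUE, FALSE), each = 3), "higher_is_positive")
  cmp <- delongCompare(ra, rb, paired = TRUE)
  Vb10 <- sapply(vb[1:3], function(x) mean(sapply(vb[4:6], function(y) psi(x, y))))
  Vb01 <- sapply(vb[4:6], function(y) mean(sapply(vb[1:3], function(x) psi(x, y))))
  covTerm <- cov(V10, Vb10) / 3 + cov(V01, Vb01) / 3
  expect_equal(cmp$var, ra$auc_var + rb$auc_var - 2 * covTerm,
               tolerance = 1e-12)

  un <- delongCompare(ra, rb, paired = FALSE)
  expect_equal(un$var, ra$auc_var + rb$auc_var, tolerance = 1e-12)

  rshort <- rocCurve(c(1, 2, 3), c(TRUE, FALSE, FALSE), "higher_is_positive")
  expect_error(delongCompare(ra, rshort, paired = TRUE), "identical")
})

test_that("AUC and DeLong agree with the pROC reference implementation", {
  set.seed(47)
  vals <- rnorm(40); labs <- sample(c(TRUE, FALSE), 40, replace = TRUE)
  vals2 <- vals + rnorm(40, 0, 1.5)
  r1 <- rocCurve(vals, labs, "higher_is_positive")
  r2 <- rocCurve(vals2, labs, "higher_is_positive")
  p1 <- pROC::roc(labs, vals, direction = "<", quiet = TRUE)
  p2 <- pROC::roc(labs, vals2, direction = "<", quiet = TRUE)
  expect_equal(r1$auc, as.numeric(pROC::auc(p1)), tolerance = 1e-12)
  expect_equal(unname(delongCompare(r1, r2, paired = TRUE)$p),
               pROC::roc.test(p1, p2, method = "delong")$p.value,
               tolerance = 1e-8)
})

test_that("group comparison gates on normality and gets small-sample MWU right", {
  idn <- groupTest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(idn$test, "mann_whitney")
  expect_equal(idn$p, 1)

  sep <- groupTest(c(1, 2, 3), c(4, 5, 6))
  expect_equal(sep$test, "mann_whitney")
  expect_equal(sep$p, 0.1)          # exact: 2/20 two-sided

  set.seed(53)
  a <- rnorm(30, 0, 1); b <- rnorm(30, 3, 1)
  g <- groupTest(a, b)
  expect_equal(g$test, "welch_t")
  expect_lt(g$p, 1e-3)

  expect_error(groupTest(1, c(1, 2)), "at least 2")
})

test_that("confusion metrics reproduce the published reading results", {
  idf <- confusionMetrics(tp = 72, fn = 2, tn = 32, fp = 3)
  expect_equal(round(idf$sens, 3), 0.973)
  expect_equal(round(idf$spec, 3), 0.914)
  expect_equal(round(idf$acc, 3), 0.954)

  iadc <- confusionMetrics(tp = 70, fn = 4, tn = 29, fp = 6)
  expect_equal(round(c(iadc$sens, iadc$spec, iadc$acc), 3),
               c(0.946, 0.829, 0.908))

  perf <- confusionMetrics(tp = 10, fn = 0, tn = 5, fp = 0)
  expect_equal(c(perf$sens, perf$spec, perf$acc), c(1, 1, 1))

  deg <- confusionMetrics(tp = 0, fn = 0, tn = 3, fp = 1)
  expect_true(is.na(deg$sens))
  expect_equal(deg$undefined, "sens")
})

test_that("pooled accuracies from sens/spec and group sizes match the tables", {
  expect_equal(round(poolAccuracy(0.932, 0.943, 74, 35)$acc, 3), 0.936)
  expect_equal(round(poolAccuracy(0.892, 0.914, 74, 35)$acc, 3), 0.899)
  expect_equal(round(poolAccuracy(0.988, 0.913, 86, 23)$acc, 3), 0.972)
  expect_equal(round(poolAccuracy(0.907, 1.000, 97, 12)$acc, 3), 0.917)
})

test_that("ICC(2,1) matches an independent ANOVA mean-squares evaluation", {
  expect_equal(iccAgreement(cbind(1:5, 1:5))$icc, 1)

  shift <- cbind(1:6, 1:6 + 2)
  expect_lt(iccAgreement(shift)$icc, 1)
  expect_equal(iccAgreement(shift, form = "consistency")$icc, 1)

  # 5-subject toy matrix against aov-derived mean squares
  m <- cbind(c(9, 6, 8, 7, 10), c(2, 1, 4, 1, 5), c(5, 2, 6, 2, 6))
  d <- data.frame(y = as.vector(m),
                  subj = factor(rep(1:5, 3)),
                  rater = factor(rep(1:3, each = 5)))
  ms <- summary(aov(y ~ subj + rater, data = d))[[1]][["Mean Sq"]]
  MSR <- ms[1]; MSC <- ms[2]; MSE <- ms[3]
  want <- (MSR - MSE) / (MSR + 2 * MSE + 3 / 5 * (MSC - MSE))
  got <- iccAgreement(m)
  expect_equal(got$icc, want, tolerance = 1e-12)
  expect_equal(unname(got$ms["MSR"]), MSR, tolerance = 1e-12)

  expect_warning(z <- iccAgreement(cbind(rep(1, 3), rep(1, 3))), "undefined")
  expect_true(is.na(z$icc))
  expect_error(iccAgreement(cbind(c(1, NA), c(1, 2))), "complete")
})

test_that("cohort cutoff derivation points the right way", {
  rec <- simulateLesionCohort(200, seed = 61)
  cuts <- deriveCutoffs(rec)
  expect_gt(cuts@cD, 0)
  expect_gt(cuts@cF, 0)
  expect_gt(cuts@cADC, 0)
  # haemangioma means sit above the D' cutoff, FNH means above the f' cutoff
  expect_gt(mean(rec$mean_Dprime[rec$class == "haemangioma"]), cuts@cD)
  expect_gt(mean(rec$mean_fprime[rec$class == "FNH"]), cuts@cF)
  expect_lt(mean(rec$mean_Dprime[rec$class == "HCC"]), cuts@cD)
})
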