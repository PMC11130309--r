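test_that("myeloid classification applies the precedence rules", {
  genes <- c("C5AR1", "CD86", "CD163", "MRC1")
  m <- rbind(c(2, 5, 0, 0),   # C5AR1+ and CD86 high: precedence -> C5aR1hi
             c(0, 5, 0, 0),   # high CD86, no C5AR1/CD163/MRC1 -> CD86hi
             c(0, 0, 3, 0),   # CD163 only -> other
             c(0, 5, 1, 0),   # high CD86 but CD163 expressed -> other
             c(0, 1, 0, 0))   # low CD86 -> other
  colnames(m) <- genes
  cls <- classify_myeloid(m, patients = rep("p1", 5))
  expect_identical(cls$cell_class,
                   c("C5aR1hi", "CD86hi", "other", "other", "other"))
  expect_equal(cls$counts$c5ar1_hi, 1)
  expect_equal(cls$counts$cd86_hi, 1)
  expect_equal(cls$counts$other, 3)
  expect_error(classify_myeloid(m[, 1:3]), "missing")
})

test_that("the ratio statistic is pseudocount-guarded and monotone", {
  expect_equal(ratio_statistic(10, 5, pseudocount = 0), 2)
  expect_equal(ratio_statistic(3, 0, pseudocount = 1), 4)
  r <- ratio_statistic(0:10, 5)
  expect_true(all(diff(r) > 0))
  r2 <- ratio_statistic(5, 0:10)
  expect_true(all(diff(r2) < 0))
  expect_error(ratio_statistic(-1, 2), ">= 0")
})

test_that("upper-quartile stratification follows the quantile definition", {
  g8 <- stratify_quartile(1:8)
  expect_identical(which(g8 == "high"), c(7L, 8L))
  g4 <- stratify_quartile(c(10, 20, 30, 40))
  expect_equal(sum(g4 == "high"), 1)
  # rank-invariance under strictly monotone transforms
  r <- rlnorm(20)
  expect_identical(as.character(stratify_quartile(r)),
                   as.character(stratify_quartile(log(r))))
  expect_warning(gd <- stratify_quartile(rep(2, 6)), "equal")
  expect_true(all(gd == "high"))
  expect_error(stratify_quartile(1:3), "4 patients")
})

test_that("AUC equals brute-force pair counting and handles separation", {
  expect_equal(roc_auc(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE))$auc, 1)
  # NE = {3, 4} vs E = {1, 2}: all four cross-pairs concordant
  expect_equal(roc_auc(c(3, 4, 1, 2), c("NE", "NE", "E", "E") == "NE")$auc, 1)

  set.seed(12)
  for (i in 1:20) {
    n <- sample(8:50, 1)
    score <- sample(1:10, n, replace = TRUE)   # ties on purpose
    pos <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(pos) || all(pos)) next
    expect_equal(roc_auc(score, pos)$auc, oracle_auc(score, pos))
  }
  expect_error(roc_auc(1:4, rep(TRUE, 4)), "both outcome classes")
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(13)
  score <- rnorm(60)
  pos <- rbinom(60, 1, 0.4) == 1
  ours <- roc_auc(score, pos)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(pos, score, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("label permutation centers the AUC at one half", {
  set.seed(14)
  score <- rnorm(40)
  pos <- rep(c(TRUE, FALSE), each = 20)
  aucs <- replicate(200, roc_auc(score, sample(pos))$auc)
  expect_lt(abs(mean(aucs) - 0.5), 0.02)
})

test_that("log-rank matches the hand-computed oracle and its identities", {
  time <- c(6, 7, 10, 15, 4, 5, 8, 12)
  event <- c(1, 1, 0, 1, 1, 1, 1, 0)
  group <- rep(c("g1", "g2"), each = 4)
  res <- km_logrank(time, event, group)
  expect_equal(res$chisq, oracle_logrank_chisq(time, event, group),
               tolerance = 1e-10)
  # time-unit rescaling leaves the statistic unchanged
  res_days <- km_logrank(time * 365.25, event, group)
  expect_equal(res$chisq, res_days$chisq, tolerance = 1e-10)

  # identical groups: chi-square 0, p = 1
  res0 <- km_logrank(rep(time[1:4], 2), rep(event[1:4], 2), group)
  expect_equal(res0$chisq, 0, tolerance = 1e-12)
  expect_equal(res0$p, 1)

  # Kaplan-Meier identities: S(0) = 1, the curve is the product of the
  # stated at-risk factors, and it stays flat beyond the last event
  expect_true(all(summary(res$fit, times = 0)$surv == 1))
  g2 <- survival::survfit(survival::Surv(c(4, 5, 8, 12),
                                         c(1, 1, 1, 0)) ~ 1)
  expect_equal(g2$surv, c(3 / 4, 1 / 2, 1 / 4, 1 / 4))
  expect_equal(summary(g2, times = 100, extend = TRUE)$surv, 1 / 4)
  expect_error(km_logrank(time, rep(0, 8), group), "event")
  expect_error(km_logrank(time, event, rep("g1", 8)), "two groups")
})

test_that("Cox regression is reparameterization-consistent and recovers beta", {
  co <- generate_cohort(200, beta = 0.8, seed = 31)
  fit1 <- cox_univariate(co$time_days, co$event, co$z_ratio)
  fit2 <- cox_univariate(co$time_days, co$event, co$z_ratio * 10)
  expect_equal(fit1$beta, fit2$beta * 10, tolerance = 1e-6)
  expect_lt(abs(fit1$beta - 0.8), 0.3)
  expect_true(fit1$ci[1] < fit1$hr & fit1$hr < fit1$ci[2])
  expect_error(cox_univariate(co$time_days, rep(0, 200), co$z_ratio),
               "two events")
  expect_error(cox_univariate(co$time_days, co$event, rep(1, 200)),
               "constant")
})

test_that("high-ratio patients do worse end-to-end when the hazard says so", {
  directional <- 0
  for (s in 1:20) {
    co <- generate_cohort(80, beta = 1.0, seed = 400 + s)
    grp <- stratify_quartile(co$ratio)
    cx <- cox_univariate(co$time_days, co$event, as.numeric(grp == "high"))
    directional <- directional + (cx$hr > 1)
  }
  expect_gte(directional, 19)
})
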