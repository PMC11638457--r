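test_that("roc_auc equals exhaustive pair counting, including ties", {
  set.seed(11)
  for (k in 1:10) {
    n <- sample(10:60, 1)
    labels <- c(rep(1, 5), rbinom(n - 5, 1, 0.5))
    labels[1:3] <- 0                      # both classes guaranteed
    scores <- round(rnorm(n), sample(c(1, 2, 8), 1))  # coarse rounding -> ties
    r <- roc_auc(scores, labels)
    expect_equal(r$auc, oracle_auc(scores, labels), tolerance = 1e-12)
  }
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc, 1)
  expect_equal(roc_auc(rep(0.3, 10), rep(0:1, 5))$auc, 0.5)
  expect_error(roc_auc(1:4, rep(1, 4)), "both classes")
})

test_that("DeLong CI uses the structural-components variance", {
  set.seed(21)
  scores <- rnorm(50) + rep(c(0, 1), 25)
  labels <- rep(c(0, 1), 25)
  r <- roc_auc(scores, labels)
  expect_equal(r$se^2, oracle_delong_var(scores, labels), tolerance = 1e-12)
  expect_true(r$ci[1] <= r$auc && r$auc <= r$ci[2])
})

test_that("youden_cutoff matches a brute-force scan and its tie-break", {
  # worked example: any threshold in (0.2, 0.8] attains J = 1; the attained
  # observed score is 0.8 under the score >= t convention
  r <- roc_auc(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))
  expect_equal(youden_cutoff(r), 0.8)
  set.seed(31)
  for (k in 1:8) {
    scores <- round(runif(40), 2)
    labels <- rbinom(40, 1, 0.5); labels[1:2] <- c(0, 1)
    r <- roc_auc(scores, labels)
    o <- oracle_youden(scores, labels)
    cut <- youden_cutoff(r)
    expect_equal(cut, o$threshold)
    j_at <- mean(scores[labels == 1] >= cut) + mean(scores[labels == 0] < cut) - 1
    expect_equal(j_at, o$j, tolerance = 1e-12)
  }
  # max J invariant under order-preserving transforms
  scores <- runif(30); labels <- rbinom(30, 1, 0.6); labels[1:2] <- c(0, 1)
  j1 <- oracle_youden(scores, labels)$j
  j2 <- oracle_youden(qlogis(scores / 2 + 0.25), labels)$j
  expect_equal(j1, j2, tolerance = 1e-12)
})

test_that("confusion_at partitions and handles degenerate cutoffs", {
  scores <- runif(25); labels <- rbinom(25, 1, 0.5)
  cm <- confusion_at(scores, labels, 0.5)
  expect_equal(cm$tp + cm$fp + cm$fn + cm$tn, 25)
  hi <- confusion_at(scores, labels, max(scores) + 1)
  expect_equal(hi$tp + hi$fp, 0)
  lo <- confusion_at(scores, labels, min(scores))   # >= min: everyone positive
  expect_equal(lo$fn + lo$tn, 0)
})

test_that("metrics_with_ci reproduces published percent cells and edge cases", {
  # external testing dataset, combined model
  ms <- metrics_with_ci(confusion_counts(62, 11, 12, 30))
  got <- setNames(ms$percent, ms$metric)
  expect_equal(got[["sensitivity"]], 84)
  expect_equal(got[["specificity"]], 73)
  expect_equal(got[["ppv"]], 85)
  expect_equal(got[["npv"]], 71)
  expect_equal(got[["accuracy"]], 80)
  # internal testing dataset 1, combined model
  ms2 <- metrics_with_ci(confusion_counts(60, 5, 7, 22))
  got2 <- setNames(ms2$percent, ms2$metric)
  expect_equal(got2[["sensitivity"]], 90)
  expect_equal(got2[["accuracy"]], 87)
  # perfect classifier
  ms3 <- metrics_with_ci(confusion_counts(12, 0, 0, 0))
  expect_equal(ms3$percent[ms3$metric == "sensitivity"], 100)
  expect_true(is.na(ms3$estimate[ms3$metric == "specificity"]))
  expect_true("specificity" %in% attr(ms3, "undefined"))
  # Clopper-Pearson endpoints against binom.test
  bt <- binom.test(62, 74)$conf.int
  expect_equal(ms$lower[ms$metric == "sensitivity"], bt[1], tolerance = 1e-10)
  expect_equal(ms$upper[ms$metric == "sensitivity"], bt[2], tolerance = 1e-10)
})

test_that("paired DeLong test matches the component oracle and identity", {
  set.seed(41)
  labels <- rep(c(0, 1), 20)
  sa <- rnorm(40) + labels
  sb <- 0.6 * sa + rnorm(40, 0, 0.8)
  r <- delong_test(sa, sb, labels)
  expect_equal(r$statistic, oracle_delong_z(sa, sb, labels), tolerance = 1e-10)
  expect_true(r$p_value >= 0 && r$p_value <= 1)
  same <- delong_test(sa, sa, labels)
  expect_equal(same$p_value, 1)
  expect_equal(same$statistic, 0)
})

test_that("mcnemar_test: exact worked value, symmetry, subsets", {
  # construct paired calls on positives with b = 5, c = 1
  labels <- rep(1, 30)
  a <- rep(1, 30); b <- rep(1, 30)
  a[25:30] <- c(1, 1, 1, 1, 1, 0)   # A wrong on case 30
  b[25:30] <- c(0, 0, 0, 0, 0, 1)   # B wrong on 25..29
  r <- mcnemar_test(a, b, labels, "sensitivity")
  expect_equal(r$b, 5); expect_equal(r$c, 1)
  expect_equal(r$p_value, 0.21875)
  # symmetry
  r2 <- mcnemar_test(b, a, labels, "sensitivity")
  expect_equal(r2$p_value, r$p_value)
  # b == c -> p = 1 (exact)
  a3 <- c(1, 0, 1, 0); b3 <- c(0, 1, 0, 1)
  expect_equal(mcnemar_test(a3, b3, rep(1, 4), "sensitivity")$p_value, 1)
  # identical calls -> p = 1
  expect_equal(mcnemar_test(a, a, labels, "accuracy")$p_value, 1)
  # metric restriction: specificity ignores positives entirely
  lab <- c(rep(1, 10), rep(0, 10))
  ca <- c(rep(1, 10), rep(0, 5), rep(1, 5))
  cb <- c(rep(0, 10), rep(0, 5), rep(1, 5))
  expect_equal(mcnemar_test(ca, cb, lab, "specificity")$p_value, 1)
  # asymptotic branch kicks in at b + c >= 25
  lab2 <- rep(1, 60)
  a2 <- c(rep(0, 20), rep(1, 40)); b2 <- c(rep(1, 20), rep(0, 10), rep(1, 30))
  r3 <- mcnemar_test(a2, b2, lab2, "sensitivity")
  expect_false(r3$exact)
  expect_equal(r3$statistic, (abs(20 - 10) - 1)^2 / 30)
})

test_that("kosinski_test identity, exchangeability and undefined flag", {
  set.seed(51)
  labels <- rbinom(60, 1, 0.6)
  a <- as.integer(labels == 1 | runif(60) < 0.2)
  b <- as.integer(labels == 1 & runif(60) < 0.9)
  expect_equal(kosinski_test(a, a, labels, "ppv")$p_value, 1)
  r <- kosinski_test(a, b, labels, "ppv")
  ord <- sample(60)
  r2 <- kosinski_test(a[ord], b[ord], labels[ord], "ppv")
  expect_equal(r$statistic, r2$statistic, tolerance = 1e-12)
  # no positive calls -> undefined
  r3 <- kosinski_test(rep(0, 60), b, labels, "ppv")
  expect_true(r3$undefined)
  expect_true(is.na(r3$p_value))
  # npv variant runs and is symmetric-bounded
  r4 <- kosinski_test(a, b, labels, "npv")
  expect_true(r4$p_value >= 0 && r4$p_value <= 1)
})

test_that("calibration_bins: simulation recovery and degenerate inputs", {
  set.seed(61)
  p <- runif(5000)
  y <- rbinom(5000, 1, p)
  tab <- calibration_bins(p, y, 10)
  expect_equal(nrow(tab), 10)
  expect_true(max(abs(tab$mean_predicted - tab$observed_rate)) < 0.05)
  expect_true(max(tab$n) - min(tab$n) <= 1)
  # all identical scores -> one effective bin
  tab2 <- calibration_bins(rep(0.4, 50), rbinom(50, 1, 0.4), 10)
  expect_equal(nrow(tab2), 1)
  expect_warning(calibration_bins(runif(5), rbinom(5, 1, 0.5), 10), "fewer cases")
})

test_that("net_benefit worked value and bounds", {
  # external-test counts: 62 TP, 11 FP of n = 115 at pt = 0.2
  scores <- c(rep(0.9, 62), rep(0.9, 11), rep(0.1, 12), rep(0.1, 30))
  labels <- c(rep(1, 62), rep(0, 11), rep(1, 12), rep(0, 30))
  nb <- net_benefit(scores, labels, thresholds = 0.2)
  expect_equal(nb$nb_model, 62 / 115 - (11 / 115) * 0.25, tolerance = 1e-12)
  expect_equal(nb$nb_none, 0)
  curve <- net_benefit(runif(80), rbinom(80, 1, 0.4))
  expect_true(all(curve$nb_none == 0))
  # model never exceeds prevalence
  s <- runif(200); y <- rbinom(200, 1, 0.4)
  nb2 <- net_benefit(s, y)
  expect_true(all(nb2$nb_model <= mean(y) + 1e-12))
})

test_that("net benefit dominates treat-all when FPs are fewer at equal TPs", {
  # model catches every positive but rejects half the negatives: its FP
  # rate is lower at equal TP count, so NB_model >= NB_all at every pt
  labels <- c(rep(1, 40), rep(0, 60))
  scores <- c(rep(0.99, 40), rep(0.99, 30), rep(0.01, 30))
  nb <- net_benefit(scores, labels, thresholds = seq(0.05, 0.9, by = 0.05))
  expect_true(all(nb$nb_model >= nb$nb_all - 1e-12))
})

test_that("subgroup_auc: identity, exclusion, and power at a strong contrast", {
  set.seed(71)
  # identical strata -> p = 1
  s <- rnorm(80) + rep(c(0, 1.2), 40); l <- rep(c(0, 1), 40)
  sub <- subgroup_auc(c(s, s), c(l, l), rep(c("a", "b"), each = 80))
  expect_equal(sub$comparisons$p_value, 1)
  # single-class stratum flagged and excluded
  expect_warning(
    sub2 <- subgroup_auc(c(s, 1, 2, 3), c(l, 1, 1, 1),
                         c(rep("a", 80), rep("tiny", 3))),
    "single class")
  expect_equal(sub2$excluded, "tiny")
  # power: true AUCs 0.9 vs 0.7, n = 200 per stratum, 100 reps
  d1 <- sqrt(2) * qnorm(0.9); d2 <- sqrt(2) * qnorm(0.7)
  rej <- 0
  for (r in 1:100) {
    l1 <- rep(c(0, 1), 100); l2 <- rep(c(0, 1), 100)
    s1 <- rnorm(200) + d1 * l1
    s2 <- rnorm(200) + d2 * l2
    ct <- delong_test(s1, s2, list(l1, l2), paired = FALSE)
    rej <- rej + (ct$p_value < 0.05)
  }
  expect_gt(rej, 80)
})
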