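test_that("cohens_d matches the pooled-SD formula and published worked rows", {
  expect_equal(cohens_d(group_summary(10, 5, 2), group_summary(10, 5, 3)), 0)

  # published cognitive-battery rows: printed means/SDs with n = 3895 / 4249
  girls_boys <- list(
    list(f = c(101.68, 14.08), m = c(102.64, 14.68), d = 0.067),
    list(f = c(98.89, 15.07),  m = c(97.44, 15.54),  d = 0.095),
    list(f = c(96.29, 13.37),  m = c(97.09, 14.39),  d = 0.058),
    list(f = c(104.45, 19.53), m = c(103.65, 18.52), d = 0.042)
  )
  for (row in girls_boys) {
    d <- cohens_d(group_summary(3895, row$f[1], row$f[2]),
                  group_summary(4249, row$m[1], row$m[2]))
    expect_equal(round(d, 3), row$d, tolerance = 1e-9)
  }
})

test_that("summary-based d and t agree with raw-data computation", {
  set.seed(5)
  x <- rnorm(40, 10, 2)
  y <- rnorm(55, 11, 2.5)
  a <- summarize_group(x)
  b <- summarize_group(y)

  tt <- two_sample_t(a, b)
  ref <- t.test(x, y, var.equal = TRUE)
  expect_equal(tt$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(tt$p, ref$p.value, tolerance = 1e-12)

  # t^2 equals the one-way two-group F statistic
  fit <- anova(aov(c(x, y) ~ factor(rep(1:2, c(40, 55)))))
  expect_equal(tt$t^2, fit$`F value`[1], tolerance = 1e-10)

  # d from summaries equals d from the raw pooled formula
  sp <- sqrt(((39) * var(x) + (54) * var(y)) / 93)
  expect_equal(cohens_d(a, b), abs(mean(y) - mean(x)) / sp, tolerance = 1e-12)
})

test_that("two_sample_t reproduces the closed-form example and edge cases", {
  out <- two_sample_t(group_summary(10, 0, 1), group_summary(10, 2, 1))
  expect_equal(out$t, -2 / sqrt(2 / 10), tolerance = 1e-12)
  expect_equal(round(out$t, 3), -4.472)
  expect_equal(out$p, 2.6e-4, tolerance = 0.02)

  same <- two_sample_t(group_summary(10, 1, 2), group_summary(10, 1, 2))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
})

test_that("score_correlations: exact, invariant to affine rescaling, errors", {
  set.seed(9)
  s <- runif(50)
  tests <- data.frame(self = s, other = rnorm(50))
  out <- score_correlations(s, tests)
  expect_equal(out$r[out$test == "self"], 1, tolerance = 1e-12)

  shifted <- score_correlations(s, data.frame(other = 3 * tests$other - 7))
  expect_equal(shifted$r, out$r[out$test == "other"], tolerance = 1e-12)
  expect_equal(shifted$p, out$p[out$test == "other"], tolerance = 1e-12)

  expect_error(score_correlations(s, data.frame(flat = rep(1, 50))),
               "zero variance")
})

test_that("partial_mediation detects a constructed full mediation", {
  set.seed(31)
  n <- 1000
  latent <- rnorm(n)
  sex <- as.integer(latent > 0)
  mediator <- latent + rnorm(n, 0, 0.5)
  scores <- latent + rnorm(n, 0, 0.5)
  out <- partial_mediation(sex, scores, mediator, n_perm = 2000, seed = 4)
  expect_true(out$verdict)
  expect_lt(out$condition3_p, 0.01)
  expect_gt(out$observed_reduction, 0)

  # bit-exact reproducibility under a fixed seed
  again <- partial_mediation(sex, scores, mediator, n_perm = 2000, seed = 4)
  expect_identical(out$condition3_p, again$condition3_p)
})

test_that("partial_mediation is self-consistent under a pre-permuted mediator", {
  set.seed(77)
  n <- 400
  latent <- rnorm(n)
  sex <- as.integer(latent > 0)
  scores <- latent + rnorm(n, 0, 0.5)
  mediator <- sample(latent + rnorm(n, 0, 0.5))  # break the link
  out <- partial_mediation(sex, scores, mediator, n_perm = 1000, seed = 8)
  expect_gt(out$condition3_p, 0.025)  # observed stat inside its own null
  expect_error(partial_mediation(sex, scores, rep(1, n)), "constant")
})

test_that("misclassification chi-square matches the Pearson formula", {
  # 2x2 table [[30,10],[10,30]]: chi2 = 20, p ~ 7.7e-6
  correct <- data.frame(sex = 0, pds_level = rep(c(1, 2), c(30, 10)))
  wrong <- data.frame(sex = 0, pds_level = rep(c(1, 2), c(10, 30)))
  out <- misclassification_chi2(correct, wrong)
  row <- out[out$sex == 0, ]
  expect_equal(row$chi2, 20, tolerance = 1e-12)
  expect_equal(row$p, 7.7e-6, tolerance = 0.01)

  # doubling all cell counts doubles the statistic
  out2 <- misclassification_chi2(correct[rep(1:40, 2), ], wrong[rep(1:40, 2), ])
  expect_equal(out2[out2$sex == 0, "chi2"], 40, tolerance = 1e-12)

  # identical distributions: chi2 = 0, p = 1
  out0 <- misclassification_chi2(correct, correct)
  expect_equal(out0[out0$sex == 0, "chi2"], 0)
  expect_equal(out0[out0$sex == 0, "p"], 1)
})

test_that("chi-square agrees with stats::chisq.test on complete tables", {
  set.seed(3)
  for (rep in 1:5) {
    a <- sample(1:4, 120, replace = TRUE, prob = c(0.4, 0.3, 0.2, 0.1))
    w <- sample(1:4, 90, replace = TRUE)
    correct <- data.frame(sex = 1, pds_level = a)
    wrong <- data.frame(sex = 1, pds_level = w)
    out <- misclassification_chi2(correct, wrong)
    tab <- table(factor(c(a, w), levels = 1:4),
                 rep(c("c", "w"), c(120, 90)))
    ref <- suppressWarnings(chisq.test(tab, correct = FALSE))
    row <- out[out$sex == 1, ]
    if (!row$pooled) {
      expect_equal(row$chi2, unname(ref$statistic), tolerance = 1e-10)
      expect_equal(row$p, ref$p.value, tolerance = 1e-10)
    }
  }
})

test_that("sparse contingency levels are pooled with a warning", {
  correct <- data.frame(sex = 1, pds_level = c(rep(1, 50), rep(2, 40), 5))
  wrong <- data.frame(sex = 1, pds_level = c(rep(1, 10), rep(2, 20)))
  expect_warning(out <- misclassification_chi2(correct, wrong), "pooled")
  expect_true(out[out$sex == 1, "pooled"])
})

test_that("per-stratum accuracy counts correctly and applies the floor rule", {
  labels <- rep(c(1, 0), 20)                # 10 girls + 10 boys per stratum
  stratum <- rep(c(1, 2), each = 20)
  predicted <- labels
  predicted[c(1, 21, 23, 25)] <- 1 - predicted[c(1, 21, 23, 25)]
  out <- per_stratum_accuracy(predicted, labels, stratum, min_per_sex = 5)
  expect_equal(out$accuracy[out$stratum == 1], 19 / 20)
  expect_equal(out$accuracy[out$stratum == 2], 17 / 20)

  # stratum missing one sex entirely is excluded
  labels2 <- c(labels, rep(1, 12))
  stratum2 <- c(stratum, rep(3, 12))
  predicted2 <- c(predicted, rep(1, 12))
  out2 <- per_stratum_accuracy(predicted2, labels2, stratum2, min_per_sex = 5)
  expect_false(3 %in% out2$stratum)
})

test_that("compute_metrics reproduces hand-derived examples", {
  perfect <- compute_metrics(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_equal(perfect$balanced_accuracy, 1)
  expect_equal(perfect$auc, 1)

  m <- compute_metrics(c(0.9, 0.4, 0.2, 0.6), c(1, 1, 0, 0))
  expect_equal(m$tpr, 0.5)
  expect_equal(m$tnr, 0.5)
  expect_equal(m$balanced_accuracy, 0.5)
  expect_equal(m$auc, 0.75)

  # ties at the threshold go to class 0 (boy)
  tied <- compute_metrics(rep(0.5, 6), c(1, 1, 1, 0, 0, 0))
  expect_equal(tied$tpr, 0)
  expect_equal(tied$tnr, 1)
  expect_equal(tied$auc, 0.5)

  expect_error(compute_metrics(c(0.1, 0.9), c(1, 1)), "single-class")
})

test_that("AUC equals exhaustive pair concordance, including ties", {
  set.seed(12)
  for (rep in 1:5) {
    n <- sample(10:60, 1)
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    scores <- round(runif(n), 1)  # coarse grid forces ties
    m <- compute_metrics(scores, labels)
    expect_equal(m$auc, pairwise_auc(scores, labels), tolerance = 1e-12)
    expect_equal(m$balanced_accuracy, (m$tpr + m$tnr) / 2, tolerance = 1e-12)
  }
})

test_that("delong_test: degenerate equality, internal AUC, pROC agreement", {
  set.seed(21)
  labels <- rbinom(60, 1, 0.5)
  labels[1:2] <- c(0, 1)
  s <- runif(60)
  same <- delong_test(s, s, labels)
  expect_equal(same$z, 0)
  expect_equal(same$p, 1)

  s2 <- plogis(2 * labels + rnorm(60))
  s3 <- plogis(0.5 * labels + rnorm(60))  # weaker but same-direction scores
  out <- delong_test(s2, s3, labels)
  expect_equal(out$auc_a, compute_metrics(s2, labels)$auc, tolerance = 1e-12)
  expect_equal(out$auc_b, compute_metrics(s3, labels)$auc, tolerance = 1e-12)

  skip_if_not_installed("pROC")
  ref <- pROC::roc.test(
    pROC::roc(labels, s2, quiet = TRUE, direction = "<", levels = c(0, 1)),
    pROC::roc(labels, s3, quiet = TRUE, direction = "<", levels = c(0, 1)),
    method = "delong", paired = TRUE)
  expect_equal(abs(out$z), abs(unname(ref$statistic)), tolerance = 1e-8)
  expect_equal(out$p, ref$p.value, tolerance = 1e-8)
})

test_that("delong p agrees with a bootstrap difference test on a small instance", {
  set.seed(33)
  n <- 20
  labels <- rep(c(1, 0), each = n / 2)
  sa <- plogis(1.5 * labels + rnorm(n))
  sb <- plogis(0.3 * labels + rnorm(n))
  out <- delong_test(sa, sb, labels)

  # bootstrap the AUC difference; two-sided p from the normal approximation
  B <- 10000
  diffs <- numeric(B)
  for (b in seq_len(B)) {
    idx <- sample.int(n, replace = TRUE)
    if (length(unique(labels[idx])) < 2) { diffs[b] <- NA; next }
    diffs[b] <- pairwise_auc(sa[idx], labels[idx]) -
      pairwise_auc(sb[idx], labels[idx])
  }
  diffs <- diffs[!is.na(diffs)]
  zb <- (out$auc_a - out$auc_b) / sd(diffs)
  p_boot <- 2 * pnorm(-abs(zb))
  expect_lt(abs(out$p - p_boot), 0.02)
})

test_that("baseline classifiers separate trivial features and drop constants", {
  set.seed(2)
  labels <- rep(c(1, 0), each = 30)
  features <- cbind(signal = labels + rnorm(60, 0, 0.01),
                    flat = rep(1, 60),
                    junk = rnorm(60))
  expect_warning(out <- baseline_classifiers(features, labels, k = 5, seed = 3),
                 "constant")
  for (m in names(out))
    expect_gt(out[[m]]$metrics$balanced_accuracy, 0.99)
})
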