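#' Group summary statistics
#'
#' Container for the per-group summary (n, mean, SD) of a continuous measure,
#' the form in which cohort demographics and cognitive test scores are usually
#' published.
#'
#' @param n Number of observations (must be >= 2).
#' @param mean Sample mean.
#' @param sd Sample standard deviation (must be > 0).
#' @param label Optional group label.
#' @return An object of class `group_summary`.
#' @export
#' @examples
#' girls <- group_summary(3895, 101.68, 14.08)
#' boys  <- group_summary(4249, 102.64, 14.68)
#' cohens_d(girls, boys)
group_summary <- function(n, mean, sd, label = NULL) {
  stopifnot(is.numeric(n), length(n) == 1, is.numeric(mean), is.numeric(sd))
  if (n < 2) stop("group_summary: n must be >= 2")
  if (sd < 0) stop("group_summary: sd must be non-negative")
  structure(list(n = as.integer(n), mean = mean, sd = sd, label = label),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("%s: n = %d, %.3f +/- %.3f\n",
              if (is.null(x$label)) "group" else x$label, x$n, x$mean, x$sd))
  invisible(x)
}

#' Summarize a numeric vector as a group_summary
#'
#' @param x Numeric vector.
#' @param label Optional group label.
#' @return A [group_summary()].
#' @export
summarize_group <- function(x, label = NULL) {
  x <- x[is.finite(x)]
  group_summary(length(x), mean(x), stats::sd(x), label = label)
}

#' Cohen's d from group summaries
#'
#' Standardized mean difference with the pooled standard deviation using
#' (n - 1) weights: `d = |mean_b - mean_a| / s_pooled`,
#' `s_pooled^2 = ((n_a-1) s_a^2 + (n_b-1) s_b^2) / (n_a + n_b - 2)`.
#'
#' @param a,b [group_summary()] objects (or numeric vectors, which are
#'   summarized first).
#' @return The effect size d (non-negative scalar).
#' @export
cohens_d <- function(a, b) {
  a <- as_group_summary(a)
  b <- as_group_summary(b)
  if (a$sd <= 0 || b$sd <= 0) stop("cohens_d: both SDs must be > 0")
  sp <- pooled_sd(a, b)
  abs(b$mean - a$mean) / sp
}

as_group_summary <- function(x) {
  if (inherits(x, "group_summary")) return(x)
  if (is.numeric(x) && length(x) > 1) return(summarize_group(x))
  stop("expected a group_summary or a numeric vector")
}

pooled_sd <- function(a, b) {
  sqrt(((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / (a$n + b$n - 2))
}

#' Pooled-variance two-sample t-test from group summaries
#'
#' @param a,b [group_summary()] objects (or numeric vectors).
#' @return A list with elements `t`, `df`, `p` (two-sided).
#' @export
two_sample_t <- function(a, b) {
  a <- as_group_summary(a)
  b <- as_group_summary(b)
  if (a$sd <= 0 && b$sd <= 0) {
    if (a$mean == b$mean) return(list(t = 0, df = a$n + b$n - 2, p = 1))
    stop("two_sample_t: zero variance in both groups with unequal means")
  }
  sp <- pooled_sd(a, b)
  se <- sp * sqrt(1 / a$n + 1 / b$n)
  tt <- (a$mean - b$mean) / se
  df <- a$n + b$n - 2
  list(t = tt, df = df, p = 2 * stats::pt(-abs(tt), df))
}

#' Correlate a prediction score with cognitive test scores
#'
#' Pearson correlation of the per-subject prediction score S with each
#' cognitive test column, with two-sided p-values.
#'
#' @param scores Numeric vector of prediction scores, one per subject.
#' @param tests Data frame (or named list) of numeric test-score columns
#'   aligned with `scores`.
#' @return Data frame with columns `test`, `r`, `p`, `n`.
#' @export
score_correlations <- function(scores, tests) {
  tests <- as.data.frame(tests)
  stopifnot(nrow(tests) == length(scores))
  if (length(scores) <= 3) stop("score_correlations: need n > 3")
  out <- lapply(names(tests), function(nm) {
    x <- tests[[nm]]
    ok <- is.finite(x) & is.finite(scores)
    if (stats::sd(x[ok]) == 0)
      stop(sprintf("score_correlations: column '%s' has zero variance", nm))
    ct <- stats::cor.test(scores[ok], x[ok], method = "pearson")
    data.frame(test = nm, r = unname(ct$estimate), p = ct$p.value,
               n = sum(ok), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Three-condition partial mediation with a permutation null
#'
#' Tests whether a continuous mediator (e.g., a cognitive test score)
#' partially explains the association between observed sex and the prediction
#' score S. The three conditions are:
#' 1. sex is associated with the mediator (pooled two-sample t-test);
#' 2. the mediator is associated with S when accounting for sex
#'    (t-test of the mediator coefficient in `lm(S ~ sex + mediator)`);
#' 3. the sex--S correlation is significantly reduced when accounting for the
#'    mediator. The condition-3 statistic is
#'    `|r(sex, S)| - |partial r(sex, S | mediator)|`; its null distribution is
#'    obtained by permuting the mediator column, and
#'    `p = (1 + #\{permuted >= observed\}) / (1 + n_perm)`.
#'
#' The verdict is "partial mediation" iff all three p-values are < 0.05.
#'
#' @param sex Binary vector (girl = 1, boy = 0).
#' @param scores Prediction scores S, aligned with `sex`.
#' @param mediator Continuous mediator column.
#' @param n_perm Number of permutations for condition 3 (default 10000).
#' @param seed Integer seed for the permutations.
#' @param alpha Significance level for the verdict (default 0.05).
#' @return A list of class `mediation_result` with `condition1_p`,
#'   `condition2_p`, `condition3_p`, `observed_reduction`, `n_permutations`,
#'   `seed`, `verdict`.
#' @export
partial_mediation <- function(sex, scores, mediator, n_perm = 10000,
                              seed = 1, alpha = 0.05) {
  stopifnot(length(sex) == length(scores), length(sex) == length(mediator))
  ok <- is.finite(sex) & is.finite(scores) & is.finite(mediator)
  sex <- sex[ok]; scores <- scores[ok]; mediator <- mediator[ok]
  n <- length(sex)
  if (stats::sd(mediator) == 0) stop("partial_mediation: constant mediator")
  if (length(unique(sex)) < 2) stop("partial_mediation: need both sexes")

  # condition 1: sex ~ mediator
  c1 <- two_sample_t(summarize_group(mediator[sex == 1]),
                     summarize_group(mediator[sex == 0]))$p

  # condition 2: mediator coefficient in S ~ sex + mediator
  fit <- stats::lm(scores ~ sex + mediator)
  c2 <- summary(fit)$coefficients["mediator", "Pr(>|t|)"]

  # condition 3: reduction in |correlation| under partialling, permutation null
  zx <- as.numeric(scale(sex))
  zy <- as.numeric(scale(scores))
  zm <- as.numeric(scale(mediator))
  r_xy <- mean(zx * zy) * n / (n - 1)
  stat <- function(r_xm, r_ym) {
    pr <- (r_xy - r_xm * r_ym) / sqrt((1 - r_xm^2) * (1 - r_ym^2))
    abs(r_xy) - abs(pr)
  }
  obs <- stat(stats::cor(zx, zm), stats::cor(zy, zm))

  set.seed(seed)
  exceed <- 0L
  chunk <- 1000L
  done <- 0L
  while (done < n_perm) {
    b <- min(chunk, n_perm - done)
    Mp <- matrix(0, n, b)
    for (j in seq_len(b)) Mp[, j] <- zm[sample.int(n)]
    r_xm <- as.numeric(crossprod(Mp, zx)) / (n - 1)
    r_ym <- as.numeric(crossprod(Mp, zy)) / (n - 1)
    exceed <- exceed + sum(stat(r_xm, r_ym) >= obs)
    done <- done + b
  }
  c3 <- (1 + exceed) / (1 + n_perm)

  structure(list(condition1_p = c1, condition2_p = c2, condition3_p = c3,
                 observed_reduction = obs, n_permutations = n_perm,
                 seed = seed,
                 verdict = (c1 < alpha && c2 < alpha && c3 < alpha)),
            class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat("Partial mediation analysis\n")
  cat(sprintf("  condition 1 (sex ~ mediator):              p = %.4g\n", x$condition1_p))
  cat(sprintf("  condition 2 (mediator ~ S | sex):          p = %.4g\n", x$condition2_p))
  cat(sprintf("  condition 3 (correlation reduction, perm): p = %.4g  (%d permutations)\n",
              x$condition3_p, x$n_permutations))
  cat(sprintf("  verdict: %s\n", if (x$verdict) "partial mediation" else "no mediation"))
  invisible(x)
}

# Pearson chi-square on a complete k x 2 table, no continuity correction.
pearson_chi2 <- function(tab) {
  tab <- as.matrix(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  chi2 <- sum((tab - expected)^2 / expected)
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  list(chi2 = chi2, df = df, p = stats::pchisq(chi2, df, lower.tail = FALSE),
       expected = expected)
}

# Merge adjacent rows (PDS levels) until all expected cells are >= 1.
pool_sparse_levels <- function(tab) {
  pooled <- FALSE
  repeat {
    e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (all(e >= 1) || nrow(tab) <= 2) break
    pooled <- TRUE
    i <- which.min(rowSums(tab))
    j <- if (i == 1) 2 else if (i == nrow(tab)) i - 1 else
      if (rowSums(tab)[i - 1] <= rowSums(tab)[i + 1]) i - 1 else i + 1
    lo <- min(i, j); hi <- max(i, j)
    tab[lo, ] <- tab[lo, ] + tab[hi, ]
    rownames(tab)[lo] <- paste(rownames(tab)[lo], rownames(tab)[hi], sep = "+")
    tab <- tab[-hi, , drop = FALSE]
  }
  list(tab = tab, pooled = pooled)
}

#' Chi-square test of a covariate between always-correct and always-wrong groups
#'
#' Given subjects that were correctly classified in all repeated
#' cross-validation runs and subjects misclassified in all runs, tests (per
#' sex) whether the distribution of an ordinal covariate (by default the PDS
#' level) differs between the two groups, using the Pearson chi-square on the
#' level-by-group contingency table without continuity correction. Adjacent
#' levels are pooled (with a warning) if any expected cell count falls
#' below 1.
#'
#' @param always_correct,always_wrong Data frames of subject records with at
#'   least columns `sex` and the covariate named by `variable`.
#' @param variable Name of the ordinal covariate column (default `pds_level`).
#' @return Data frame with one row per sex: `sex`, `chi2`, `df`, `p`,
#'   `n_correct`, `n_wrong`, `pooled`.
#' @export
misclassification_chi2 <- function(always_correct, always_wrong,
                                   variable = "pds_level") {
  stopifnot(variable %in% names(always_correct),
            variable %in% names(always_wrong))
  out <- lapply(c(0, 1), function(sx) {
    a <- always_correct[always_correct$sex == sx, variable]
    w <- always_wrong[always_wrong$sex == sx, variable]
    if (length(a) == 0 || length(w) == 0)
      return(data.frame(sex = sx, chi2 = NA_real_, df = NA_integer_,
                        p = NA_real_, n_correct = length(a),
                        n_wrong = length(w), pooled = FALSE))
    levels_all <- sort(unique(c(a, w)))
    tab <- rbind(correct = table(factor(a, levels = levels_all)),
                 wrong = table(factor(w, levels = levels_all)))
    tab <- t(tab)  # levels x group
    pl <- pool_sparse_levels(tab)
    if (pl$pooled)
      warning(sprintf("sparse table for sex=%d: adjacent %s levels pooled",
                      sx, variable))
    ct <- pearson_chi2(pl$tab)
    data.frame(sex = sx, chi2 = ct$chi2, df = ct$df, p = ct$p,
               n_correct = length(a), n_wrong = length(w),
               pooled = pl$pooled)
  })
  do.call(rbind, out)
}

#' Prediction accuracy within covariate strata
#'
#' Accuracy of binarized predictions within each level of a stratifying
#' covariate (e.g., PDS level). Strata are reported only when both sexes have
#' at least `min_per_sex` subjects, mirroring the "sufficient number of
#' samples for each sex" reporting rule.
#'
#' @param predicted Binarized predicted labels (0/1).
#' @param labels True labels (girl = 1, boy = 0).
#' @param stratum Stratum label per subject (e.g., rounded PDS).
#' @param min_per_sex Minimum per-sex count for a stratum to be reported.
#' @return Data frame with columns `stratum`, `n`, `n_girls`, `n_boys`,
#'   `accuracy`.
#' @export
per_stratum_accuracy <- function(predicted, labels, stratum, min_per_sex = 10) {
  stopifnot(length(predicted) == length(labels),
            length(stratum) == length(labels))
  out <- lapply(sort(unique(stratum)), function(s) {
    idx <- which(stratum == s)
    ng <- sum(labels[idx] == 1); nb <- sum(labels[idx] == 0)
    if (ng < min_per_sex || nb < min_per_sex) return(NULL)
    data.frame(stratum = s, n = length(idx), n_girls = ng, n_boys = nb,
               accuracy = mean(predicted[idx] == labels[idx]))
  })
  out <- Filter(Negate(is.null), out)
  if (length(out) == 0)
    return(data.frame(stratum = numeric(0), n = integer(0),
                      n_girls = integer(0), n_boys = integer(0),
                      accuracy = numeric(0)))
  do.call(rbind, out)
}

# Tie-aware AUC (equals exhaustive pair concordance with ties counted 1/2).
auc_mann_whitney <- function(scores, labels) {
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("AUC undefined: single-class labels")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# DeLong placement values: for each positive, fraction of negatives it beats.
delong_placements <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  n1 <- length(pos); n0 <- length(neg)
  v10 <- vapply(pos, function(s) (sum(s > neg) + 0.5 * sum(s == neg)) / n0,
                numeric(1))
  v01 <- vapply(neg, function(s) (sum(pos > s) + 0.5 * sum(pos == s)) / n1,
                numeric(1))
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' DeLong test for two correlated ROC curves
#'
#' Nonparametric comparison of the AUCs of two score vectors computed on the
#' same subjects, using the DeLong structural-component (placement value)
#' estimate of the variance of the AUC difference.
#'
#' @param scores_a,scores_b Numeric score vectors on the same subjects.
#' @param labels Binary labels (positive = 1).
#' @return List with `auc_a`, `auc_b`, `z`, `p` (two-sided).
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  stopifnot(length(scores_a) == length(labels),
            length(scores_b) == length(labels))
  if (length(unique(labels)) < 2) stop("delong_test: single-class labels")
  pa <- delong_placements(scores_a, labels)
  pb <- delong_placements(scores_b, labels)
  n1 <- length(pa$v10); n0 <- length(pa$v01)
  d10 <- pa$v10 - pb$v10
  d01 <- pa$v01 - pb$v01
  var_diff <- stats::var(d10) / n1 + stats::var(d01) / n0
  diff <- pa$auc - pb$auc
  if (var_diff <= 0) {
    z <- 0; p <- 1
    if (abs(diff) > 0) { z <- Inf * sign(diff); p <- 0 }
  } else {
    z <- diff / sqrt(var_diff)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(auc_a = pa$auc, auc_b = pb$auc, z = z, p = p)
}

#' Baseline classifiers on tabular ROI features
#'
#' Applies the same subject-level k-fold cross-validation protocol as the deep
#' model to standard classifiers on tabular features (logistic regression,
#' support vector machine with an RBF kernel, random forest), the comparison
#' traditionally made against a priori ROI volume measurements.
#'
#' @param features Numeric matrix or data frame (subjects x features).
#' @param labels Binary labels (girl = 1, boy = 0).
#' @param k Number of folds (default 5).
#' @param seed Integer seed for the fold assignment and classifiers.
#' @param methods Subset of `c("logistic", "svm", "rf")`.
#' @return A list per method with elements `scores` (cross-validated
#'   probability of class 1 per subject), `metrics` (a [compute_metrics()]
#'   report), and `folds`.
#' @export
baseline_classifiers <- function(features, labels, k = 5, seed = 1,
                                 methods = c("logistic", "svm", "rf")) {
  features <- as.matrix(features)
  stopifnot(nrow(features) == length(labels))
  constant <- apply(features, 2, function(x) stats::sd(x) == 0)
  if (any(constant)) {
    warning(sprintf("dropping %d constant feature column(s)", sum(constant)))
    features <- features[, !constant, drop = FALSE]
  }
  folds <- stratified_folds(labels, k, seed)
  out <- list()
  for (m in methods) {
    scores <- rep(NA_real_, length(labels))
    for (f in seq_len(k)) {
      tr <- folds != f; te <- folds == f
      xtr <- features[tr, , drop = FALSE]; ytr <- labels[tr]
      xte <- features[te, , drop = FALSE]
      scores[te] <- switch(
        m,
        logistic = {
          df <- data.frame(y = ytr, xtr)
          fit <- suppressWarnings(
            stats::glm(y ~ ., data = df, family = stats::binomial()))
          as.numeric(stats::predict(fit, newdata = data.frame(xte),
                                    type = "response"))
        },
        svm = {
          set.seed(seed + f)
          fit <- e1071::svm(xtr, factor(ytr), kernel = "radial",
                            probability = TRUE)
          pr <- stats::predict(fit, xte, probability = TRUE)
          attr(pr, "probabilities")[, "1"]
        },
        rf = {
          set.seed(seed + f)
          fit <- randomForest::randomForest(xtr, factor(ytr), ntree = 200)
          stats::predict(fit, xte, type = "prob")[, "1"]
        },
        stop("unknown baseline method: ", m))
    }
    out[[m]] <- list(scores = scores,
                     metrics = compute_metrics(scores, labels),
                     folds = folds)
  }
  out
}

# Seeded k-fold assignment stratified by class; returns fold index per row.
stratified_folds <- function(labels, k, seed) {
  set.seed(seed)
  folds <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  folds
}
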