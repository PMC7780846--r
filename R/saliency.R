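#' Saliency map of a volume
#'
#' Voxel-wise absolute gradient of the pre-sigmoid classifier output with
#' respect to the input volume, obtained by back-propagation through the
#' trained model, then min-max scaled to \[0, 1\] (a constant map scales to
#' all zeros). The gradient flow can be restricted to a subset of the M
#' predictor variables: excluded predictors are treated as constants
#' (stop-gradient), which is how confounded predictors are omitted from the
#' confounder-free maps. Values are only comparable within one map, which is
#' why each map is scaled individually.
#'
#' @param model A trained `sexnet`.
#' @param v 3D array on the model's input grid.
#' @param predictors Integer indices of the predictors to keep, or `NULL` for
#'   all.
#' @param scale Min-max scale the map (default TRUE).
#' @return 3D array of saliency values.
#' @export
compute_saliency <- function(model, v, predictors = NULL, scale = TRUE) {
  M <- n_predictors(model)
  if (is.null(predictors)) predictors <- seq_len(M)
  predictors <- as.integer(predictors)
  if (length(predictors) == 0) stop("compute_saliency: empty predictor mask")
  stopifnot(all(predictors >= 1 & predictors <= M))
  X <- model_input(model, v)
  g <- cnn_input_grad_cpp(X, model$conv_W, model$conv_b, model$fc_W,
                          model$fc_b, model$cfg$grid, predictors)
  s <- array(abs(g[, 1]), dim = dim(v))
  if (scale) s <- minmax_scale(s)
  s
}

minmax_scale <- function(x) {
  rng <- range(x)
  if (rng[2] - rng[1] <= 0) return(array(0, dim = dim(x)))
  (x - rng[1]) / (rng[2] - rng[1])
}

# Bilateral per-subject map: saliency of the native volume averaged with the
# mirrored-back saliency of the flipped volume, then rescaled.
subject_saliency <- function(model, v, predictors = NULL) {
  s_native <- compute_saliency(model, v, predictors, scale = FALSE)
  s_flip <- compute_saliency(model, flip_volume(v), predictors, scale = FALSE)
  minmax_scale((s_native + flip_volume(s_flip)) / 2)
}

# Batched bilateral per-subject maps (single backprop call over all volumes
# and their mirrors); identical output to looping subject_saliency.
subject_saliency_batch <- function(model, volumes, predictors = NULL) {
  M <- n_predictors(model)
  if (is.null(predictors)) predictors <- seq_len(M)
  predictors <- as.integer(predictors)
  if (length(predictors) == 0) stop("empty predictor mask")
  grid <- model$cfg$grid
  d3 <- c(grid, grid, grid)
  pairs <- unlist(lapply(volumes,
                         function(v) list(v, flip_volume(v))),
                  recursive = FALSE)
  X <- model_input(model, pairs)
  g <- cnn_input_grad_cpp(X, model$conv_W, model$conv_b, model$fc_W,
                          model$fc_b, grid, predictors)
  lapply(seq_along(volumes), function(i) {
    nat <- array(abs(g[, 2 * i - 1]), dim = d3)
    flp <- array(abs(g[, 2 * i]), dim = d3)
    minmax_scale((nat + flip_volume(flp)) / 2)
  })
}

#' GLM confounder screen of the learned predictors
#'
#' For each predictor variable P_j, fits the general linear model
#' `P_j = b0 + b1 S + b2 z_pds + b3 z_age + b4 z_ses` by ordinary least
#' squares across all samples and tests the three confounder coefficients
#' (two-sided t-tests). A predictor is flagged as confounded if any
#' confounder p-value is <= `alpha`. The threshold is deliberately lenient
#' and uncorrected for multiple comparison, so the screen is sensitive and
#' the surviving pattern represents sex differences conservatively.
#'
#' @param P Matrix of predictor values (samples x M).
#' @param scores Prediction scores S aligned with the rows of `P`.
#' @param covariates Data frame with columns `age`, `pds`, `ses` aligned with
#'   the rows of `P` (z-scored internally).
#' @param alpha Screening level (default 0.05).
#' @return Data frame of class `screen_result`: one row per predictor with
#'   the five coefficients, the three confounder p-values, `min_p`,
#'   `worst_confounder`, and the `confounded` flag.
#' @export
screen_predictors <- function(P, scores, covariates, alpha = 0.05) {
  P <- as.matrix(P)
  scores <- as.numeric(scores)
  n <- nrow(P)
  stopifnot(length(scores) == n, nrow(covariates) == n)
  if (n <= 5) stop("screen_predictors: need n > 5 samples")
  cols <- list(S = scores, z_pds = covariates$pds, z_age = covariates$age,
               z_ses = covariates$ses)
  for (nm in names(cols)) {
    if (stats::sd(cols[[nm]]) == 0)
      stop(sprintf("degenerate design: column '%s' is constant", nm))
  }
  X <- cbind(`(Intercept)` = 1, S = scores,
             z_pds = as.numeric(scale(covariates$pds)),
             z_age = as.numeric(scale(covariates$age)),
             z_ses = as.numeric(scale(covariates$ses)))
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- setdiff(colnames(X), colnames(X)[qx$pivot[seq_len(qx$rank)]])
    stop(sprintf("degenerate design: column(s) %s linearly dependent",
                 paste(bad, collapse = ", ")))
  }
  xtx_inv <- solve(crossprod(X))            # X is 5 columns, full rank
  beta <- xtx_inv %*% crossprod(X, P)       # 5 x M
  rownames(beta) <- colnames(X)
  resid <- P - X %*% beta
  df <- n - ncol(X)
  sigma2 <- colSums(resid^2) / df
  se <- sqrt(outer(diag(xtx_inv), sigma2))  # 5 x M
  tval <- beta / se
  pval <- 2 * stats::pt(-abs(tval), df)
  # a constant (dead) predictor carries no association
  sd_p <- sqrt(pmax(apply(P, 2, stats::var), 0))
  pval[, sd_p <= 0] <- 1
  pval[!is.finite(pval)] <- 1
  # guard against float-noise coefficients when a predictor is explained
  # (almost) exactly by the design (e.g., P_j == S): a coefficient that is
  # negligible relative to the predictor's own scale is never significant
  negligible <- abs(beta) <= 1e-8 * rep(sd_p, each = nrow(beta))
  pval[negligible] <- 1
  conf_rows <- c("z_pds", "z_age", "z_ses")
  pmat <- t(pval[conf_rows, , drop = FALSE])  # M x 3
  min_p <- apply(pmat, 1, min)
  worst <- c("pds", "age", "ses")[apply(pmat, 1, which.min)]
  out <- data.frame(
    predictor = seq_len(ncol(P)),
    beta0 = beta["(Intercept)", ], beta_s = beta["S", ],
    beta_pds = beta["z_pds", ], beta_age = beta["z_age", ],
    beta_ses = beta["z_ses", ],
    p_pds = pmat[, 1], p_age = pmat[, 2], p_ses = pmat[, 3],
    min_p = min_p, worst_confounder = worst,
    confounded = min_p <= alpha,
    row.names = NULL, stringsAsFactors = FALSE
  )
  attr(out, "alpha") <- alpha
  class(out) <- c("screen_result", "data.frame")
  out
}

#' Cohort-average saliency pattern
#'
#' Averages the per-subject, per-map min-max-scaled bilateral saliency maps
#' across all subjects, with the gradient restricted to either the
#' confounder-free (unflagged) or the confounded (flagged) predictors. For a
#' confounder-specific pattern, flagged predictors are further restricted to
#' those whose smallest confounder p-value is achieved by that confounder.
#' The model should have been re-trained on the entire dataset.
#'
#' @param model A trained `sexnet`.
#' @param volumes List of subject volumes.
#' @param screen A [screen_predictors()] result for this model.
#' @param mode `"confounder_free"` or `"confounded"`.
#' @param confounder Optional: `"pds"`, `"age"` or `"ses"` to restrict a
#'   confounded pattern to one confounder's predictors.
#' @return 3D array: the cohort-average saliency pattern.
#' @export
cohort_pattern <- function(model, volumes, screen,
                           mode = c("confounder_free", "confounded"),
                           confounder = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(screen, "screen_result"))
  if (mode == "confounder_free") {
    keep <- screen$predictor[!screen$confounded]
    if (length(keep) == 0)
      stop(paste("all predictors are flagged as confounded;",
                 "no confounder-free pattern exists",
                 sprintf("(min confounder p ranges %.3g-%.3g)",
                         min(screen$min_p), max(screen$min_p))))
  } else {
    keep <- screen$predictor[screen$confounded]
    if (!is.null(confounder)) {
      stopifnot(confounder %in% c("pds", "age", "ses"))
      keep <- screen$predictor[screen$confounded &
                                 screen$worst_confounder == confounder]
    }
    if (length(keep) == 0)
      stop("no predictors flagged for the requested confounder")
  }
  maps <- subject_saliency_batch(model, volumes, keep)
  Reduce(`+`, maps) / length(volumes)
}

#' ROI statistics of per-subject saliency maps
#'
#' Computes the average saliency of each atlas ROI per subject, tests whether
#' that average differs between girls and boys (pooled two-sample t-test),
#' applies Bonferroni correction over ROIs, and ranks ROIs by cohort-mean
#' saliency (descending), the ordering used for "top-k" reporting.
#'
#' @param maps List of per-subject saliency maps (same grid as `atlas`).
#' @param atlas 3D integer label array (0 = unlabeled).
#' @param sex Binary vector aligned with `maps` (girl = 1, boy = 0).
#' @return Data frame: `label`, `n_voxels`, `mean_saliency`, `mean_girls`,
#'   `mean_boys`, `t`, `p`, `p_bonferroni`, `rank`. Empty ROIs are excluded
#'   with a warning.
#' @export
roi_statistics <- function(maps, atlas, sex) {
  stopifnot(length(maps) == length(sex), length(unique(sex)) == 2)
  labels <- sort(setdiff(unique(as.integer(atlas)), 0L))
  vox <- lapply(labels, function(l) which(atlas == l))
  empty <- lengths(vox) == 0
  if (any(empty)) {
    warning(sprintf("excluding %d empty ROI(s): %s", sum(empty),
                    paste(labels[empty], collapse = ", ")))
    labels <- labels[!empty]; vox <- vox[!empty]
  }
  roi_means <- vapply(maps, function(m) {
    vapply(vox, function(ix) mean(m[ix]), numeric(1))
  }, numeric(length(labels)))
  roi_means <- matrix(roi_means, nrow = length(labels))  # ROIs x subjects
  g <- sex == 1
  stats_rows <- lapply(seq_along(labels), function(i) {
    a <- roi_means[i, g]; b <- roi_means[i, !g]
    if (stats::sd(a) == 0 && stats::sd(b) == 0 && mean(a) == mean(b)) {
      tt <- list(t = 0, p = 1)
    } else {
      tt <- two_sample_t(summarize_group(a), summarize_group(b))
    }
    data.frame(label = labels[i], n_voxels = length(vox[[i]]),
               mean_saliency = mean(roi_means[i, ]),
               mean_girls = mean(a), mean_boys = mean(b),
               t = tt$t, p = tt$p)
  })
  out <- do.call(rbind, stats_rows)
  out$p_bonferroni <- pmin(1, out$p * nrow(out))
  out$rank <- rank(-out$mean_saliency, ties.method = "first")
  out[order(out$rank), ]
}

#' Threshold a scaled saliency pattern
#'
#' @param map Saliency map scaled to \[0, 1\].
#' @param tau Threshold in \[0, 1\] (default 0.1); voxels with value strictly
#'   above `tau` are kept.
#' @return Logical 3D mask.
#' @export
threshold_pattern <- function(map, tau = 0.1) {
  stopifnot(tau >= 0, tau <= 1)
  map > tau
}
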