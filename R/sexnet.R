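#' Model configuration for the sex-prediction network
#'
#' The network is a predictor/extractor plus classifier: a stack of 3D
#' convolutional blocks (3x3x3 kernels, zero padding, ReLU, 2x max pooling)
#' whose final feature map is flattened into the M predictor variables P
#' (one predictor per spatial position and channel, so each predictor has a
#' localized receptive field and can be attributed to brain regions), and a
#' fully connected classifier mapping P to a continuous prediction score
#' S = probability of the volume belonging to a girl. The architecture is
#' fully configurable through the channel widths and classifier widths, so
#' alternative layer configurations can be dropped in. The default (three
#' blocks, 16 final channels on a 16-voxel grid) yields M = 128 predictors.
#'
#' @param grid Input cube edge length in voxels.
#' @param channels Integer vector of conv-block output channels;
#'   `M = channels[last] * (grid / 2^length(channels))^3`. The grid must be
#'   divisible by `2^length(channels)`.
#' @param fc Integer vector of hidden fully connected widths (may be empty;
#'   the final 1-unit sigmoid layer is always appended).
#' @param lr Adam learning rate.
#' @param weight_decay Decoupled (AdamW-style) weight decay applied to the
#'   weight matrices (not biases); shrinks unused parameters and distributes
#'   weight across correlated informative features.
#' @param label_smoothing Training targets are softened to
#'   `y (1 - ls) + ls / 2`, bounding the optimal logits so the classifier
#'   cannot saturate on a single dominant feature and instead spreads weight
#'   over all informative predictors.
#' @param epochs Training epochs.
#' @param batch_size Minibatch size.
#' @param seed Seed for parameter initialization and batch shuffling.
#' @param target_per_class Per-class sample count after balancing-augmentation
#'   of the training folds (`NULL` balances to the largest class).
#' @param max_shift,max_rot Rigid augmentation bounds (voxels, degrees).
#' @param restarts Maximum number of re-initializations when training ends at
#'   chance-level loss (an occasional dead-ReLU start); each restart uses a
#'   new derived seed.
#' @param restart_loss Final-epoch loss above which a run counts as a failed
#'   start (chance level for balanced binary cross-entropy is log 2 = 0.693).
#' @return A `sexnet_config` list.
#' @export
sexnet_config <- function(grid = 16, channels = c(4, 8, 16), fc = c(8),
                          lr = 1e-2, weight_decay = 1e-3,
                          label_smoothing = 0, epochs = 10,
                          batch_size = 16, seed = 1,
                          target_per_class = NULL, max_shift = 1,
                          max_rot = 1, restarts = 2, restart_loss = 0.65) {
  stopifnot(length(channels) >= 1, all(channels >= 1))
  if (grid %% (2^length(channels)) != 0 || grid / 2^length(channels) < 1)
    stop(sprintf("grid %d incompatible with %d conv blocks", grid,
                 length(channels)))
  structure(list(grid = as.integer(grid), channels = as.integer(channels),
                 fc = as.integer(fc), lr = lr, weight_decay = weight_decay,
                 label_smoothing = label_smoothing,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 target_per_class = target_per_class, max_shift = max_shift,
                 max_rot = max_rot, restarts = as.integer(restarts),
                 restart_loss = restart_loss),
            class = "sexnet_config")
}

#' Build (initialize) a sex-prediction model
#'
#' He-initialized weights, seeded so identical seeds give identical initial
#' parameters.
#'
#' @param cfg A [sexnet_config()].
#' @return Object of class `sexnet`.
#' @export
build_model <- function(cfg) {
  stopifnot(inherits(cfg, "sexnet_config"))
  set.seed(cfg$seed)
  he <- function(nr, nc) matrix(stats::rnorm(nr * nc, 0, sqrt(2 / nr)), nr, nc)
  conv_W <- list(); conv_b <- list()
  cin <- 1L
  for (cout in cfg$channels) {
    conv_W[[length(conv_W) + 1]] <- he(27 * cin, cout)
    conv_b[[length(conv_b) + 1]] <- numeric(cout)
    cin <- cout
  }
  n_last <- cfg$grid / 2^length(cfg$channels)
  widths <- c(utils::tail(cfg$channels, 1) * n_last^3, cfg$fc, 1L)
  fc_W <- list(); fc_b <- list()
  for (l in seq_len(length(widths) - 1)) {
    fc_W[[l]] <- he(widths[l], widths[l + 1])
    fc_b[[l]] <- numeric(widths[l + 1])
  }
  structure(list(cfg = cfg, conv_W = conv_W, conv_b = conv_b,
                 fc_W = fc_W, fc_b = fc_b, trained = FALSE,
                 input_mean = NULL, loss_history = numeric(0)),
            class = "sexnet")
}

#' @export
print.sexnet <- function(x, ...) {
  cat(sprintf("sexnet: %d^3 input, conv channels [%s], M = %d predictors, fc [%s]%s\n",
              x$cfg$grid, paste(x$cfg$channels, collapse = ", "),
              n_predictors(x),
              paste(c(x$cfg$fc, 1), collapse = ", "),
              if (x$trained) " (trained)" else " (untrained)"))
  invisible(x)
}

#' Number of predictor variables of a model
#'
#' Predictors are the flattened final feature map: one per spatial position
#' and channel, ordered position-fastest (position `v` of channel `c` is
#' predictor `v + n_positions * c`, 1-based).
#'
#' @param model A `sexnet`.
#' @return M.
#' @export
n_predictors <- function(model) {
  n_last <- model$cfg$grid / 2^length(model$cfg$channels)
  utils::tail(model$cfg$channels, 1) * n_last^3
}

volumes_to_matrix <- function(volumes, grid) {
  if (is.matrix(volumes)) return(volumes)
  if (is.array(volumes) && length(dim(volumes)) == 3) volumes <- list(volumes)
  X <- vapply(volumes, function(v) {
    d <- dim(v)
    if (length(d) != 3 || any(d != grid))
      stop(sprintf("volume grid %s does not match model grid %d",
                   paste(d, collapse = "x"), grid))
    as.numeric(v)
  }, numeric(grid^3))
  matrix(X, nrow = grid^3)
}

# Centered input matrix: the model stores the mean training volume and
# subtracts it everywhere (mean-image subtraction; a constant offset, so
# input gradients are unaffected).
model_input <- function(model, volumes) {
  X <- volumes_to_matrix(volumes, model$cfg$grid)
  if (!is.null(model$input_mean)) X <- X - model$input_mean
  X
}

#' Forward pass: prediction scores and predictors
#'
#' @param model A `sexnet`.
#' @param volumes List of 3D arrays (or a single array).
#' @return List with `scores` (S in \[0, 1\]), `logits`, and `predictors`
#'   (matrix, one row per volume, M columns).
#' @export
sexnet_predict <- function(model, volumes) {
  X <- model_input(model, volumes)
  out <- cnn_predict_cpp(X, model$conv_W, model$conv_b, model$fc_W,
                         model$fc_b, model$cfg$grid)
  out$scores <- as.numeric(out$scores)
  out$logits <- as.numeric(out$logits)
  out
}

#' Train a model end-to-end
#'
#' Binary cross-entropy loss, Adam optimizer, seeded batch shuffling. The
#' dataset should already be balanced (see [balance_augment()]).
#'
#' @param model A `sexnet`.
#' @param volumes List of 3D arrays.
#' @param labels Binary labels (girl = 1, boy = 0), one per volume.
#' @param epochs Override of the configured epoch count.
#' @param verbose Print per-epoch loss.
#' @return The trained model, with `loss_history` (mean loss per epoch).
#' @export
sexnet_train <- function(model, volumes, labels, epochs = NULL,
                         verbose = FALSE) {
  cfg <- model$cfg
  if (is.null(epochs)) epochs <- cfg$epochs
  X <- volumes_to_matrix(volumes, cfg$grid)
  stopifnot(ncol(X) == length(labels))
  y <- as.numeric(labels)
  input_mean <- if (is.null(model$input_mean)) rowMeans(X) else
    model$input_mean
  Xc <- X - input_mean

  restarts <- cfg$restarts %||% 0L
  attempt <- 0L
  repeat {
    model$input_mean <- input_mean
    trained <- train_epochs(model, Xc, y, epochs, verbose,
                            seed = cfg$seed + 1L + 7777L * attempt)
    final <- utils::tail(trained$history, 1)
    if (final <= (cfg$restart_loss %||% Inf) || attempt >= restarts) break
    attempt <- attempt + 1L
    if (verbose)
      message(sprintf("restart %d: final loss %.3f at chance level", attempt,
                      final))
    restart_cfg <- cfg
    restart_cfg$seed <- cfg$seed + 7777L * attempt
    model <- build_model(restart_cfg)
    model$cfg <- cfg
  }
  model <- trained$model
  model$trained <- TRUE
  model$loss_history <- c(model$loss_history, trained$history)
  model
}

train_epochs <- function(model, X, y, epochs, verbose, seed) {
  cfg <- model$cfg
  ls <- cfg$label_smoothing %||% 0
  y <- y * (1 - ls) + ls / 2
  adam <- new_adam(model, cfg$lr, wd = cfg$weight_decay %||% 0)
  set.seed(seed)
  history <- numeric(epochs)
  nb <- ncol(X)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(nb)
    ep_loss <- 0; nbatches <- 0
    for (start in seq(1, nb, by = cfg$batch_size)) {
      sel <- ord[start:min(start + cfg$batch_size - 1, nb)]
      g <- cnn_batch_grad_cpp(X[, sel, drop = FALSE], y[sel],
                              model$conv_W, model$conv_b,
                              model$fc_W, model$fc_b, cfg$grid)
      if (!is.finite(g$loss))
        stop(sprintf("training failure: non-finite loss at epoch %d", ep))
      upd <- adam_step(adam, model, g)
      model <- upd$model; adam <- upd$adam
      ep_loss <- ep_loss + g$loss; nbatches <- nbatches + 1
    }
    history[ep] <- ep_loss / nbatches
    if (verbose) message(sprintf("epoch %d: loss %.4f", ep, history[ep]))
  }
  list(model = model, history = history)
}

# Adam state is kept as flat numeric vectors; parameter shapes are preserved
# on the model side.
new_adam <- function(model, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                     wd = 0) {
  zero_of <- function(p) lapply(p, function(w) numeric(length(w)))
  list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps, wd = wd, t = 0,
       m = list(conv_W = zero_of(model$conv_W), conv_b = zero_of(model$conv_b),
                fc_W = zero_of(model$fc_W), fc_b = zero_of(model$fc_b)),
       v = list(conv_W = zero_of(model$conv_W), conv_b = zero_of(model$conv_b),
                fc_W = zero_of(model$fc_W), fc_b = zero_of(model$fc_b)))
}

adam_step <- function(adam, model, grads) {
  adam$t <- adam$t + 1
  bc1 <- 1 - adam$beta1^adam$t
  bc2 <- 1 - adam$beta2^adam$t
  for (grp in c("conv_W", "conv_b", "fc_W", "fc_b")) {
    gl <- grads[[grp]]
    for (l in seq_along(gl)) {
      g <- as.numeric(gl[[l]])
      w <- model[[grp]][[l]]
      m <- adam$beta1 * adam$m[[grp]][[l]] + (1 - adam$beta1) * g
      v <- adam$beta2 * adam$v[[grp]][[l]] + (1 - adam$beta2) * g^2
      step <- adam$lr * (m / bc1) / (sqrt(v / bc2) + adam$eps)
      if (grp %in% c("conv_W", "fc_W") && adam$wd > 0)
        step <- step + adam$lr * adam$wd * as.numeric(w)
      model[[grp]][[l]] <- w - array(step, dim = dim(w) %||% length(w))
      adam$m[[grp]][[l]] <- m
      adam$v[[grp]][[l]] <- v
    }
  }
  list(model = model, adam = adam)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Extract the predictor rows for a hemisphere pair
#'
#' @param model A trained `sexnet`.
#' @param pair A [flip_to_pair()] result.
#' @return 2 x M matrix, rows named `native_right` and `flipped_left`.
#' @export
extract_predictors <- function(model, pair) {
  stopifnot(inherits(pair, "hemisphere_pair"))
  out <- sexnet_predict(model, list(pair$native_right, pair$flipped_left))
  P <- out$predictors
  rownames(P) <- c("native_right", "flipped_left")
  P
}

#' Per-subject prediction score from both hemisphere copies
#'
#' @param model A trained `sexnet`.
#' @param pair A [flip_to_pair()] result.
#' @return List with `score` (mean of the two hemisphere scores),
#'   `score_right`, `score_left`.
#' @export
predict_pair <- function(model, pair) {
  stopifnot(inherits(pair, "hemisphere_pair"))
  out <- sexnet_predict(model, list(pair$native_right, pair$flipped_left))
  list(score = mean(out$scores), score_right = out$scores[1],
       score_left = out$scores[2])
}

# Training samples for a set of subjects: each hemisphere copy is one sample.
cohort_samples <- function(cohort, idx) {
  out <- list()
  for (i in idx) {
    pair <- flip_to_pair(cohort$volumes[[i]])
    lab <- cohort$records$sex[i]
    out[[length(out) + 1]] <- list(volume = pair$native_right, label = lab,
                                   subject = i)
    out[[length(out) + 1]] <- list(volume = pair$flipped_left, label = lab,
                                   subject = i)
  }
  out
}

#' Train a model on the full cohort
#'
#' Used before computing cohort-level saliency patterns: the model is
#' re-trained on the entire dataset (balanced-augmented).
#'
#' @param cohort A `synthetic_cohort` (or any list with `volumes` and
#'   `records$sex`).
#' @param cfg A [sexnet_config()].
#' @return A trained `sexnet`.
#' @export
train_full <- function(cohort, cfg) {
  samples <- cohort_samples(cohort, seq_len(nrow(cohort$records)))
  samples <- balance_augment(samples, cfg$target_per_class, seed = cfg$seed,
                             max_shift = cfg$max_shift, max_rot = cfg$max_rot)
  model <- build_model(cfg)
  sexnet_train(model,
               lapply(samples, `[[`, "volume"),
               vapply(samples, `[[`, numeric(1), "label"))
}

#' Subject-level k-fold cross-validation
#'
#' Splits subjects into k folds (stratified by sex, seeded), trains the model
#' from scratch on the balanced-augmented training folds, and records the
#' prediction score of every held-out subject (never augmented) as the
#' average score over its two hemisphere copies. Each subject appears in
#' exactly one test fold, so every subject receives one score from a model
#' that never saw it.
#'
#' @param cohort A `synthetic_cohort`.
#' @param cfg A [sexnet_config()].
#' @param k Number of folds (default 5).
#' @param seed Seed for the fold split (model seeds derive from `cfg$seed`).
#' @return List of class `cv_result`: `predictions` (data frame with
#'   subject_id, fold, score, score_right, score_left, label), `metrics`
#'   (a [compute_metrics()] report), `folds`, `seed`.
#' @export
crossvalidate <- function(cohort, cfg, k = 5, seed = 1) {
  stopifnot(k >= 2)
  records <- cohort$records
  n <- nrow(records)
  folds <- stratified_folds(records$sex, k, seed)

  scores <- score_r <- score_l <- rep(NA_real_, n)
  for (f in seq_len(k)) {
    tr_idx <- which(folds != f)
    te_idx <- which(folds == f)
    stopifnot(length(intersect(tr_idx, te_idx)) == 0)
    samples <- cohort_samples(cohort, tr_idx)
    samples <- balance_augment(samples, cfg$target_per_class,
                               seed = cfg$seed + f,
                               max_shift = cfg$max_shift,
                               max_rot = cfg$max_rot)
    fold_cfg <- cfg
    fold_cfg$seed <- cfg$seed + 100L * f
    model <- build_model(fold_cfg)
    model <- sexnet_train(model,
                          lapply(samples, `[[`, "volume"),
                          vapply(samples, `[[`, numeric(1), "label"))
    for (i in te_idx) {
      pr <- predict_pair(model, flip_to_pair(cohort$volumes[[i]]))
      scores[i] <- pr$score
      score_r[i] <- pr$score_right
      score_l[i] <- pr$score_left
    }
  }
  if (any(is.na(scores))) stop("internal error: subject without a test score")
  predictions <- data.frame(subject_id = records$subject_id, fold = folds,
                            score = scores, score_right = score_r,
                            score_left = score_l, label = records$sex,
                            stringsAsFactors = FALSE)
  structure(list(predictions = predictions,
                 metrics = compute_metrics(scores, records$sex),
                 folds = folds, seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation over %d subjects\n",
              length(unique(x$folds)), nrow(x$predictions)))
  print(x$metrics)
  invisible(x)
}

#' Repeated cross-validation runs and classification-agreement groups
#'
#' Runs `runs` independent k-fold cross-validations with different fold
#' splits, reports the per-run balanced accuracy and its SD (the stability
#' protocol), and partitions subjects into the always-correct and
#' always-wrong groups used by the misclassification-by-puberty analysis.
#'
#' @param cohort A `synthetic_cohort`.
#' @param cfg A [sexnet_config()].
#' @param runs Number of repeated runs (default 5).
#' @param k Folds per run.
#' @param seed Base seed; run r uses `seed + r` for its fold split.
#' @return List with `runs` (list of `cv_result`), `balanced_accuracies`,
#'   `accuracy_sd`, `always_correct`, `always_wrong` (subject indices).
#' @export
repeat_crossvalidate <- function(cohort, cfg, runs = 5, k = 5, seed = 1) {
  results <- vector("list", runs)
  correct <- matrix(NA, nrow(cohort$records), runs)
  for (r in seq_len(runs)) {
    run_cfg <- cfg
    run_cfg$seed <- cfg$seed + 1000L * r
    cv <- crossvalidate(cohort, run_cfg, k = k, seed = seed + r)
    results[[r]] <- cv
    correct[, r] <- as.integer(cv$predictions$score > 0.5) ==
      cv$predictions$label
  }
  accs <- vapply(results, function(cv) cv$metrics$balanced_accuracy,
                 numeric(1))
  list(runs = results,
       balanced_accuracies = accs,
       accuracy_sd = stats::sd(accs),
       always_correct = which(rowSums(correct) == runs),
       always_wrong = which(rowSums(correct) == 0))
}
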