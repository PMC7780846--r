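# Shared fixtures, built once per test run and cached in an environment.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# Small strongly-separable cohort (sex intensity effect, magnitude 5).
separable_cohort <- function() {
  fixture("separable_cohort", function() {
    generate_cohort(80, grid = 16,
                    effects = list(effect_spec(1, "intensity_shift", "sex", 5)),
                    seed = 101)
  })
}

# Model trained on the full separable cohort (used by several test files).
separable_model <- function() {
  fixture("separable_model", function() {
    cfg <- sexnet_config(grid = 16, epochs = 8, seed = 7)
    train_full(separable_cohort(), cfg)
  })
}

# Tiny handcrafted two-channel model for analytic saliency checks:
# conv kernels are pure center taps (+1 for channel 1, -1 for channel 2),
# so channel activations are rectified copies of the input sign. With one
# block on a grid-8 input the M = 2 * 4^3 = 128 predictors split into
# channel 1 (indices 1:64) and channel 2 (indices 65:128).
toy_two_branch_model <- function(grid = 8) {
  cfg <- sexnet_config(grid = grid, channels = c(2), fc = integer(0), seed = 1)
  model <- build_model(cfg)
  W <- matrix(0, 27, 2)
  center <- 14  # offset (0,0,0) in the 3x3x3 neighborhood ordering
  W[center, 1] <- 1
  W[center, 2] <- -1
  model$conv_W[[1]] <- W
  model$conv_b[[1]] <- c(0, 0)
  model$fc_W[[1]] <- matrix(1, n_predictors(model), 1)
  model$fc_b[[1]] <- 0
  model$input_mean <- rep(0, grid^3)
  model$trained <- TRUE
  model
}

toy_channel <- function(model, ch) {
  npos <- n_predictors(model) / 2
  seq_len(npos) + (ch - 1) * npos
}

# Brute-force AUC by exhaustive pair concordance (ties count 1/2).
pairwise_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}
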