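# The two-branch toy model (helper-fixtures.R) has center-tap kernels of
# opposite sign, so with a positive blob (region A) and a negative blob
# (region B) each channel responds to exactly one region; the other path is
# closed up to the small leak of the rectifier (slope 0.01), which bounds any
# residual gradient at 1% of the open-path gradient.

toy_input <- function(grid = 8) {
  v <- array(0, dim = c(grid, grid, grid))
  A <- array(FALSE, dim = dim(v)); A[2:3, 2:3, 2:3] <- TRUE
  B <- array(FALSE, dim = dim(v)); B[6:7, 6:7, 6:7] <- TRUE
  v[A] <- seq_len(sum(A))          # distinct values avoid pooling ties
  v[B] <- -seq_len(sum(B))
  list(v = v, A = A, B = B)
}

# number of 2x2x2 pooling cells whose maximum lies inside region A
pool_argmax_in <- function(v, A) {
  n <- dim(v)[1]
  cells <- 0
  for (i in seq(1, n, 2)) for (j in seq(1, n, 2)) for (k in seq(1, n, 2)) {
    block <- v[i:(i + 1), j:(j + 1), k:(k + 1)]
    inA <- A[i:(i + 1), j:(j + 1), k:(k + 1)]
    if (max(block) > 0 && inA[which.max(block)]) cells <- cells + 1
  }
  cells
}

test_that("predictor masking confines gradient flow to the kept branch", {
  model <- toy_two_branch_model()
  ti <- toy_input()
  s1 <- compute_saliency(model, ti$v, predictors = toy_channel(model, 1),
                         scale = FALSE)
  expect_equal(max(s1[ti$A]), 1)             # open path: full gradient
  expect_lte(max(s1[ti$B]), 0.01 + 1e-12)    # closed path: leak only

  s2 <- compute_saliency(model, ti$v, predictors = toy_channel(model, 2),
                         scale = FALSE)
  expect_lte(max(s2[ti$A]), 0.01 + 1e-12)
  expect_equal(max(s2[ti$B]), 1)

  expect_error(compute_saliency(model, ti$v, predictors = integer(0)),
               "empty")
})

test_that("mask union never carries less total saliency than a sub-mask", {
  model <- toy_two_branch_model()
  ti <- toy_input()
  both <- compute_saliency(model, ti$v, scale = FALSE)
  s1 <- compute_saliency(model, ti$v, predictors = toy_channel(model, 1),
                         scale = FALSE)
  s2 <- compute_saliency(model, ti$v, predictors = toy_channel(model, 2),
                         scale = FALSE)
  expect_gte(sum(both), sum(s1))
  expect_gte(sum(both), sum(s2))
  # branch supports are disjoint up to the leak, so the union is additive
  # within the leak's contribution
  expect_equal(sum(both), sum(s1) + sum(s2), tolerance = 0.1)
})

test_that("saliency of the toy model matches the analytic gradient", {
  model <- toy_two_branch_model()
  ti <- toy_input()
  s <- compute_saliency(model, ti$v, predictors = toy_channel(model, 1),
                        scale = FALSE)
  # open path: voxel -> center tap (w = 1) -> rectifier gate 1 -> max-pool
  # (argmax only) -> fc weight 1, so gradient 1 at each pooled argmax of
  # region A; every other voxel sees at most the leak-scaled gradient 0.01.
  in_A <- sort(unique(round(as.numeric(s[ti$A]), 12)))
  expect_true(all(in_A %in% c(0, 1)))
  expect_equal(sum(s == 1), pool_argmax_in(ti$v, ti$A))
  expect_lte(max(s[!ti$A]), 0.01 + 1e-12)
})

test_that("symmetric model and input produce a mirror-symmetric map", {
  model <- toy_two_branch_model(8)
  v <- array(0, dim = c(8, 8, 8))
  v[3, 4, 4] <- 2; v[6, 4, 4] <- 2  # mirrored bright voxels (3 <-> 6 on 8)
  s <- compute_saliency(model, v)
  # above the leak floor the map is exactly mirror-symmetric (the leak part
  # depends on first-index argmax tie-breaks of all-zero pooling cells)
  strong <- s * (s > 0.5)
  expect_equal(strong, flip_volume(strong), tolerance = 1e-12)
  expect_gt(sum(strong > 0), 0)
})

test_that("per-map scaling lands in [0,1]; constant maps scale to zero", {
  model <- separable_model()
  v <- separable_cohort()$volumes[[1]]
  s <- compute_saliency(model, v)
  expect_equal(min(s), 0)
  expect_equal(max(s), 1)
  flat <- threshold_pattern(array(0.5, dim = c(4, 4, 4)), 0.1)
  expect_equal(sum(flat), 64)
  expect_equal(sum(threshold_pattern(array(0.5, dim = c(4, 4, 4)), 1)), 0)
  expect_equal(sum(threshold_pattern(s, 0)), sum(s > 0))
})

test_that("the GLM screen flags constructed confounded predictors", {
  set.seed(61)
  n <- 500
  cov <- data.frame(age = rnorm(n), pds = rnorm(n), ses = rnorm(n))
  S <- rnorm(n)
  P <- cbind(conf_age = 2 * scale(cov$age)[, 1] + rnorm(n, 0, 0.1),
             pure_s = S,
             noise = rnorm(n))
  out <- screen_predictors(P, S, cov)
  expect_true(out$confounded[1])
  expect_lt(out$p_age[1], 1e-10)
  expect_equal(out$worst_confounder[1], "age")
  expect_false(out$confounded[2])
  expect_equal(out$beta_s[2], 1, tolerance = 1e-9)
})

test_that("degenerate screen designs raise named errors", {
  set.seed(62)
  n <- 50
  P <- matrix(rnorm(n * 2), n, 2)
  cov <- data.frame(age = rnorm(n), pds = rep(2, n), ses = rnorm(n))
  expect_error(screen_predictors(P, rnorm(n), cov), "z_pds")
  expect_error(screen_predictors(P[1:4, ], rnorm(4), cov[1:4, ]), "n > 5")
})

test_that("roi_statistics: degenerate equality, Bonferroni, injected recovery", {
  atlas <- brain_template(16)$atlas
  sex <- rep(c(1, 0), each = 100)

  same <- array(runif(16^3), dim = c(16, 16, 16))
  maps_same <- lapply(1:20, function(i) same)
  tab <- roi_statistics(maps_same, atlas, rep(c(1, 0), each = 10))
  expect_true(all(tab$t == 0))
  expect_true(all(tab$p_bonferroni == 1))

  set.seed(63)
  target <- which(atlas == 4)
  maps <- lapply(seq_along(sex), function(i) {
    m <- array(abs(rnorm(16^3, 0.3, 0.05)), dim = c(16, 16, 16))
    if (sex[i] == 1) m[target] <- m[target] + 0.2
    m
  })
  tab2 <- roi_statistics(maps, atlas, sex)
  expect_lt(tab2$p_bonferroni[tab2$label == 4], 0.05)
  expect_true(all(tab2$p_bonferroni[tab2$label != 4] > 0.05))
  expect_equal(tab2$p_bonferroni, pmin(1, tab2$p * nrow(tab2)),
               tolerance = 1e-12)
  expect_equal(tab2$rank[tab2$label == 4], 1)
})

test_that("cohort_pattern with every predictor flagged is an explicit error", {
  set.seed(64)
  n <- 40
  cov <- data.frame(age = rnorm(n), pds = rnorm(n), ses = rnorm(n))
  P <- cbind(2 * cov$age + rnorm(n, 0, 0.01), 2 * cov$pds + rnorm(n, 0, 0.01))
  sc <- screen_predictors(P, rnorm(n), cov)
  expect_true(all(sc$confounded))
  model <- toy_two_branch_model()
  expect_error(cohort_pattern(model, list(toy_input()$v), sc,
                              "confounder_free"),
               "no confounder-free pattern")
  expect_error(cohort_pattern(model, list(toy_input()$v), sc,
                              "confounded", confounder = "ses"),
               "no predictors flagged")
})
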