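test_that("cohort regeneration from the same seed is bit-identical", {
  eff <- list(effect_spec(3, "intensity_shift", "sex", 3))
  a <- generate_cohort(20, grid = 16, effects = eff, seed = 42)
  b <- generate_cohort(20, grid = 16, effects = eff, seed = 42)
  expect_identical(a$records, b$records)
  expect_identical(a$volumes, b$volumes)
  c <- generate_cohort(20, grid = 16, effects = eff, seed = 43)
  expect_false(identical(a$volumes[[1]], c$volumes[[1]]))
})

test_that("sexes are balanced within one subject", {
  for (n in c(11, 24)) {
    co <- generate_cohort(n, grid = 8, seed = n)
    expect_lte(abs(sum(co$records$sex == 1) - sum(co$records$sex == 0)), 1)
  }
})

test_that("an injected sex effect is recovered by a direct regional t-test", {
  co <- generate_cohort(200, grid = 16,
                        effects = list(effect_spec(3, "intensity_shift",
                                                   "sex", 3)),
                        seed = 7)
  idx <- which(co$atlas == 3)
  m <- vapply(co$volumes, function(v) mean(v[idx]), numeric(1))
  p <- t.test(m[co$records$sex == 1], m[co$records$sex == 0])$p.value
  expect_lt(p, 1e-6)

  # an untouched region shows nothing comparable
  idx0 <- which(co$atlas == 5)
  m0 <- vapply(co$volumes, function(v) mean(v[idx0]), numeric(1))
  p0 <- t.test(m0[co$records$sex == 1], m0[co$records$sex == 0])$p.value
  expect_gt(p0, 1e-4)
})

test_that("intensity effects are linear in magnitude", {
  gen_diff <- function(mag) {
    eff <- if (mag == 0) list() else
      list(effect_spec(1, "intensity_shift", "sex", mag))
    co <- generate_cohort(60, grid = 16, effects = eff, seed = 9)
    idx <- which(co$atlas == 1)
    m <- vapply(co$volumes, function(v) mean(v[idx]), numeric(1))
    mean(m[co$records$sex == 1]) - mean(m[co$records$sex == 0])
  }
  d0 <- gen_diff(0); d2 <- gen_diff(2); d4 <- gen_diff(4)
  # same seed, so noise cancels exactly in the difference of differences
  expect_equal(d4 - d2, d2 - d0, tolerance = 1e-10)
  expect_gt(d2 - d0, 0)
})

test_that("template, atlas and injected effects are bilaterally symmetric", {
  tpl <- brain_template(16)
  expect_identical(tpl$atlas, flip_volume(tpl$atlas))
  expect_equal(tpl$template, flip_volume(tpl$template), tolerance = 1e-12)

  co <- generate_cohort(100, grid = 16,
                        effects = list(effect_spec(2, "intensity_shift",
                                                   "sex", 10)),
                        seed = 3)
  n <- co$grid
  right <- co$atlas == 2
  right[1:(n / 2), , ] <- FALSE
  left <- flip_volume(right)
  gd <- function(half) {
    m <- vapply(co$volumes, function(v) mean(v[half]), numeric(1))
    mean(m[co$records$sex == 1]) - mean(m[co$records$sex == 0])
  }
  expect_equal(gd(right), gd(left), tolerance = 0.1)
})

test_that("volume_scale effects are invisible to the ROI mean but not to voxels", {
  co <- generate_cohort(80, grid = 16,
                        effects = list(effect_spec(1, "volume_scale",
                                                   "sex", 4)),
                        seed = 11)
  idx <- which(co$atlas == 1)
  roi_mean <- vapply(co$volumes, function(v) mean(v[idx]), numeric(1))
  p_mean <- t.test(roi_mean[co$records$sex == 1],
                   roi_mean[co$records$sex == 0])$p.value
  expect_gt(p_mean, 0.01)  # zero-mean redistribution within the ROI

  # but the inner-core voxels separate the sexes strongly
  inner <- idx[brain_template(16)$region_rr[idx] <= 0.62]
  core <- vapply(co$volumes, function(v) mean(v[inner]), numeric(1))
  p_core <- t.test(core[co$records$sex == 1],
                   core[co$records$sex == 0])$p.value
  expect_lt(p_core, 1e-6)
})

test_that("invalid cohort arguments are rejected", {
  expect_error(generate_cohort(1, grid = 8), "n must be")
  expect_error(generate_cohort(10, grid = 8, noise_sd = 0), "noise_sd")
  expect_error(
    generate_cohort(10, grid = 16,
                    effects = list(effect_spec(99, "intensity_shift", "sex"))),
    "absent from the atlas")
  expect_error(effect_spec(1, magnitude = Inf), "finite")
})

test_that("cognitive scores converge to their per-sex specification", {
  co <- generate_cohort(8144, grid = 8, seed = 13)
  co <- generate_cognitive_scores(co, seed = 14)
  r <- co$records
  x <- r$list_sorting
  # direct effect-size computation as the oracle
  f <- x[r$sex == 1]; m <- x[r$sex == 0]
  sp <- sqrt(((length(f) - 1) * var(f) + (length(m) - 1) * var(m)) /
               (length(f) + length(m) - 2))
  d <- abs(mean(m) - mean(f)) / sp
  expect_lt(abs(d - 0.067), 0.02)
  expect_equal(mean(f), 101.68, tolerance = 1)
  expect_equal(sd(m), 14.68, tolerance = 1)
})

test_that("the mediation link adds class-signal variance beyond the label", {
  co <- generate_cohort(600, grid = 8, seed = 21)
  co0 <- generate_cognitive_scores(co, mediation_link = 0, seed = 5)
  co1 <- generate_cognitive_scores(co, mediation_link = 8, seed = 5)
  r0 <- co0$records; r1 <- co1$records
  within_sex <- r1$class_signal - 2 * (r1$sex - 0.5)
  expect_lt(abs(cor(r0$list_sorting, within_sex)), 0.1)
  expect_gt(cor(r1$list_sorting, within_sex), 0.2)
  # per-sex means undisturbed in expectation (the added component is the
  # zero-mean within-sex part of the class signal)
  expect_lt(abs(mean(r1$list_sorting[r1$sex == 1]) -
                  mean(r0$list_sorting[r0$sex == 1])), 1)
})

test_that("unknown test names and degenerate specs are rejected", {
  co <- generate_cohort(10, grid = 8, seed = 2)
  expect_error(generate_cognitive_scores(co, test_specs = list(bogus = c(1, 1, 1, 1))),
               "unknown cognitive test")
  expect_error(generate_cognitive_scores(co,
                 test_specs = list(flanker = c(100, 0, 100, 15))),
               "SDs must be > 0")
})

test_that("write_cohort produces readable NIfTI volumes and cohort CSV", {
  co <- generate_cohort(4, grid = 8, seed = 6)
  co <- generate_cognitive_scores(co, seed = 7)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  v <- read_volume(file.path(dir, "volumes", "S0001.nii.gz"))
  expect_equal(dim(v), c(8, 8, 8))
  expect_equal(v, co$volumes[[1]], tolerance = 1e-6, ignore_attr = TRUE)
  records <- read_cohort(file.path(dir, "cohort.csv"))
  expect_equal(nrow(records), 4)
  expect_true(all(c("flanker", "list_sorting") %in% names(records)))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(truth$seed, 6)
})
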