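#' Spherical pseudo-brain template and atlas
#'
#' Builds the fixed phantom used by the synthetic cohort generator: a smooth
#' radial "brain" (bright cortical shell, mid-intensity interior) on a cubic
#' grid, plus an integer atlas of bilateral sub-regions. Regions are spheres
#' placed symmetrically about the left-right axis (axis 1); the mirrored pair
#' shares one label, so injected effects are bilateral by construction. Each
#' region has its own baseline intensity so regions are visually
#' distinguishable, like tissue classes in a real template.
#'
#' @param grid Edge length in voxels (cubic grid, >= 8).
#' @return List with `template` (3D array), `atlas` (3D integer array, 0 =
#'   unlabeled), `region_rr` (3D array of normalized within-region radius, 1
#'   outside any region), and `regions` (data frame: label, name, cx, cy, cz,
#'   radius, base_intensity).
#' @export
brain_template <- function(grid = 64) {
  stopifnot(grid >= 8)
  n <- as.integer(grid)
  cc <- ((seq_len(n) - 1) - (n - 1) / 2) / (n / 2)  # voxel centers in [-1, 1]
  X <- array(cc, dim = c(n, n, n))
  Y <- aperm(X, c(2, 1, 3))
  Z <- aperm(X, c(3, 2, 1))
  r <- sqrt(X^2 + Y^2 + Z^2)

  template <- array(0, dim = c(n, n, n))
  template[r < 0.88] <- 0.4              # interior "white matter"
  template[r >= 0.68 & r < 0.88] <- 1.0  # bright "cortical" shell

  regions <- data.frame(
    label = 1:6,
    name = c("deep_nucleus_a", "deep_nucleus_b", "inferior_lobule",
             "superior_lobule", "lateral_nucleus", "central_core"),
    cx = c(0.35, 0.30, 0.40, 0.25, 0.45, 0.18),
    cy = c(0.30, -0.35, 0.05, -0.05, 0.35, 0.10),
    cz = c(0.20, -0.15, -0.35, 0.40, -0.10, -0.05),
    radius = c(0.20, 0.18, 0.16, 0.17, 0.19, 0.15),
    base_intensity = 0.55 + 0.05 * (1:6)
  )

  atlas <- array(0L, dim = c(n, n, n))
  region_rr <- array(1, dim = c(n, n, n))
  for (i in seq_len(nrow(regions))) {
    for (sgn in c(1, -1)) {  # right and mirrored left copy
      d <- sqrt((X - sgn * regions$cx[i])^2 + (Y - regions$cy[i])^2 +
                (Z - regions$cz[i])^2)
      inside <- d <= regions$radius[i]
      atlas[inside] <- regions$label[i]
      region_rr[inside] <- (d / regions$radius[i])[inside]
      template[inside] <- regions$base_intensity[i]
    }
  }
  list(template = template, atlas = atlas, region_rr = region_rr,
       regions = regions)
}

#' Declare a ground-truth effect for the synthetic cohort
#'
#' @param region Atlas label (integer) the effect is placed in.
#' @param kind `"intensity_shift"` (adds a uniform intensity offset to the
#'   region, in units of the voxel-noise SD per unit driver) or
#'   `"volume_scale"` (a volume-preserving shape cue: the region's bright core
#'   grows or shrinks with the driver via a zero-mean radial redistribution,
#'   so the region-average intensity carries no signal).
#' @param driver `"sex"`, `"age"`, `"pds"`, `"ses"`, or `"mediator"` (the
#'   latent class signal).
#' @param magnitude Dimensionless effect size in units of voxel-noise SD per
#'   unit driver.
#' @return An `effect_spec` object.
#' @export
effect_spec <- function(region, kind = c("intensity_shift", "volume_scale"),
                        driver = c("sex", "age", "pds", "ses", "mediator"),
                        magnitude = 1) {
  kind <- match.arg(kind)
  driver <- match.arg(driver)
  if (!is.finite(magnitude)) stop("effect_spec: magnitude must be finite")
  structure(list(region = as.integer(region), kind = kind, driver = driver,
                 magnitude = magnitude), class = "effect_spec")
}

#' Default covariate model for the synthetic cohort
#'
#' Per-sex normal distributions emulating a published pre-adolescent cohort:
#' age about 9.9 +/- 0.6 years in both sexes, pubertal development scale (PDS)
#' higher and more variable in girls (2.0 +/- 1.0) than boys (1.3 +/- 0.6) --
#' the built-in sex-PDS confounding -- and an arbitrary continuous
#' socioeconomic index. `latent_sd` is the SD of the noise on the latent class
#' signal (`2*(sex-0.5) + noise`), which drives `"mediator"` effects.
#' Optional `latent_loadings` add a shared standard-normal factor to the
#' covariates for extra correlation structure.
#'
#' @param ... Named overrides of the default entries.
#' @return A list of distribution parameters.
#' @export
default_covariate_model <- function(...) {
  m <- list(
    age_f = c(9.92, 0.62), age_m = c(9.95, 0.62),
    pds_f = c(2.0, 1.0),   pds_m = c(1.3, 0.6),
    ses_f = c(18.0, 66.8), ses_m = c(18.5, 67.8),
    latent_sd = 0.5,
    latent_loadings = c(age = 0, pds = 0, ses = 0)
  )
  utils::modifyList(m, list(...))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' PDS category from the continuous average scale
#'
#' @param pds Continuous PDS values.
#' @return Integer levels 1 (pre-pubertal) to 5 (post-pubertal).
#' @export
pds_level <- function(pds) as.integer(clamp(round(pds), 1, 5))

# Per-subject driver values for an effect, on a comparable scale:
# sex gives a between-group gap of 1, continuous covariates are z-scored,
# mediator is the latent class signal halved (between-sex gap ~1).
effect_driver_values <- function(records, driver) {
  switch(driver,
         sex = records$sex - 0.5,
         age = as.numeric(scale(records$age)),
         pds = as.numeric(scale(records$pds)),
         ses = as.numeric(scale(records$ses)),
         mediator = records$class_signal / 2,
         stop("unknown effect driver: ", driver))
}

#' Generate a synthetic cohort of pseudo-brain volumes
#'
#' Draws a balanced cohort of subject records (sex, age, PDS, SES, latent
#' class signal) and one volume per subject: the fixed phantom template plus
#' the contribution of each declared effect, scaled by that subject's driver
#' value, plus i.i.d. Gaussian voxel noise. Effects are bilateral because
#' atlas labels cover both mirror copies of a region. Regeneration with the
#' same arguments and seed is bit-identical.
#'
#' @param n Number of subjects (>= 2); sexes are balanced within 1.
#' @param grid Cube edge length in voxels (>= 8; 16 is the desk-scale
#'   default, 64 the full-resolution grid).
#' @param effects List of [effect_spec()] objects (ground truth).
#' @param covariate_model See [default_covariate_model()].
#' @param noise_sd SD of the additive voxel noise (> 0).
#' @param seed Integer seed.
#' @return Object of class `synthetic_cohort`: list with `records` (data
#'   frame), `volumes` (list of 3D arrays), `atlas`, `template`, `regions`,
#'   `truth`, `noise_sd`, `grid`, `seed`.
#' @export
generate_cohort <- function(n, grid = 16, effects = list(),
                            covariate_model = default_covariate_model(),
                            noise_sd = 0.2, seed = 1) {
  if (n < 2) stop("generate_cohort: n must be >= 2")
  if (noise_sd <= 0) stop("generate_cohort: noise_sd must be > 0")
  if (inherits(effects, "effect_spec")) effects <- list(effects)
  tpl <- brain_template(grid)
  present <- sort(unique(as.integer(tpl$atlas)))
  for (e in effects) {
    if (!inherits(e, "effect_spec")) stop("effects must be effect_spec objects")
    if (!(e$region %in% present))
      stop(sprintf("effect references atlas label %d, absent from the atlas",
                   e$region))
  }

  set.seed(seed)
  cm <- covariate_model
  n_girls <- floor(n / 2) + sample(0:1, 1) * (n %% 2)
  sex <- sample(rep(c(1L, 0L), c(n_girls, n - n_girls)))
  u <- stats::rnorm(n)  # shared latent factor for extra covariate correlation
  draw <- function(pf, pm, load = 0) {
    ifelse(sex == 1, stats::rnorm(n, pf[1], pf[2]),
           stats::rnorm(n, pm[1], pm[2])) + load * u
  }
  records <- data.frame(
    subject_id = sprintf("S%04d", seq_len(n)),
    sex = sex,
    age = draw(cm$age_f, cm$age_m, cm$latent_loadings["age"]),
    pds = clamp(draw(cm$pds_f, cm$pds_m, cm$latent_loadings["pds"]), 1, 5),
    ses = draw(cm$ses_f, cm$ses_m, cm$latent_loadings["ses"]),
    stringsAsFactors = FALSE
  )
  records$pds_level <- pds_level(records$pds)
  records$class_signal <- 2 * (sex - 0.5) + stats::rnorm(n, 0, cm$latent_sd)

  # precompute each effect's spatial pattern (sparse: indices + weights)
  patterns <- lapply(effects, function(e) {
    idx <- which(tpl$atlas == e$region)
    w <- rep(1, length(idx))
    if (e$kind == "volume_scale") {
      rr <- tpl$region_rr[idx]
      inner <- rr <= 0.62
      if (!any(inner) || all(inner))
        stop(sprintf("volume_scale effect in region %d degenerate at grid %d",
                     e$region, grid))
      w[inner] <- 1
      w[!inner] <- -sum(inner) / sum(!inner)  # zero mean within the region
    }
    drv <- effect_driver_values(records, e$driver)
    list(idx = idx, w = w * e$magnitude * noise_sd, driver = drv)
  })

  nv <- grid^3
  volumes <- vector("list", n)
  base <- as.numeric(tpl$template)
  for (i in seq_len(n)) {
    v <- base + stats::rnorm(nv, 0, noise_sd)
    for (p in patterns) v[p$idx] <- v[p$idx] + p$driver[i] * p$w
    volumes[[i]] <- array(v, dim = c(grid, grid, grid))
  }

  structure(list(records = records, volumes = volumes, atlas = tpl$atlas,
                 template = tpl$template, regions = tpl$regions,
                 truth = effects, noise_sd = noise_sd, grid = grid,
                 seed = seed),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic cohort: %d subjects (%d girls, %d boys), %d^3 grid\n",
              nrow(x$records), sum(x$records$sex == 1),
              sum(x$records$sex == 0), x$grid))
  cat(sprintf("  %d injected effect(s), noise SD %.3g, seed %d\n",
              length(x$truth), x$noise_sd, x$seed))
  invisible(x)
}

#' Registry of cognitive test specifications
#'
#' Per-sex (girl, boy) means and SDs of age-corrected standard scores for the
#' seven-test battery the cohort table mirrors (attention/cognitive control,
#' working memory, set shifting, reading, processing speed, episodic memory,
#' vocabulary).
#'
#' @return Named list; each element is `c(mean_f, sd_f, mean_m, sd_m)`.
#' @export
nih_test_specs <- function() {
  list(
    flanker            = c(96.29, 13.37, 97.09, 14.39),
    list_sorting       = c(101.68, 14.08, 102.64, 14.68),
    card_sort          = c(98.89, 15.07, 97.44, 15.54),
    oral_reading       = c(104.45, 19.53, 103.65, 18.52),
    pattern_comparison = c(96.70, 20.92, 93.72, 22.18),
    picture_sequence   = c(103.47, 16.47, 100.62, 15.81),
    picture_vocab      = c(108.53, 16.98, 109.35, 17.05)
  )
}

#' Add cognitive test scores to a synthetic cohort
#'
#' Draws each test score from the per-sex normal distribution in `test_specs`.
#' When `mediation_link` is nonzero, the named mediation test additionally
#' receives `mediation_link` times the within-sex component of the latent
#' class signal, so that score carries variance of the class signal beyond the
#' binary sex label (the structure a partial mediation analysis detects)
#' without disturbing the per-sex means.
#'
#' @param cohort A `synthetic_cohort` (or a records data frame with `sex` and
#'   `class_signal` columns).
#' @param test_specs Named list as in [nih_test_specs()]; names must belong to
#'   the fixed registry.
#' @param mediation_link Coefficient linking `mediation_test` to the latent
#'   class signal (score units per unit signal).
#' @param mediation_test Name of the linked test.
#' @param seed Integer seed.
#' @return The cohort with score columns appended to `records` (or the
#'   augmented data frame, if a data frame was supplied).
#' @export
generate_cognitive_scores <- function(cohort, test_specs = nih_test_specs(),
                                      mediation_link = 0,
                                      mediation_test = "list_sorting",
                                      seed = 1) {
  registry <- names(nih_test_specs())
  unknown <- setdiff(names(test_specs), registry)
  if (length(unknown))
    stop("unknown cognitive test name(s): ", paste(unknown, collapse = ", "))
  for (sp in test_specs)
    if (any(sp[c(2, 4)] <= 0)) stop("test spec SDs must be > 0")
  if (mediation_link != 0 && !(mediation_test %in% names(test_specs)))
    stop("mediation_test must name an entry of test_specs")

  records <- if (inherits(cohort, "synthetic_cohort")) cohort$records else cohort
  stopifnot(all(c("sex", "class_signal") %in% names(records)))
  n <- nrow(records)
  set.seed(seed)
  for (nm in names(test_specs)) {
    sp <- test_specs[[nm]]
    sc <- ifelse(records$sex == 1, stats::rnorm(n, sp[1], sp[2]),
                 stats::rnorm(n, sp[3], sp[4]))
    if (mediation_link != 0 && nm == mediation_test) {
      within_sex <- records$class_signal - 2 * (records$sex - 0.5)
      sc <- sc + mediation_link * within_sex
    }
    records[[nm]] <- sc
  }
  if (inherits(cohort, "synthetic_cohort")) {
    cohort$records <- records
    cohort
  } else records
}

#' Write a synthetic cohort to disk
#'
#' Volumes and atlas as NIfTI with 2 mm isotropic spacing metadata, the cohort
#' table as CSV, and the ground-truth effect list as a JSON sidecar.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @param spacing Voxel spacing in mm (default 2).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, spacing = 2) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vol_dir <- file.path(dir, "volumes")
  dir.create(vol_dir, showWarnings = FALSE)
  for (i in seq_len(nrow(cohort$records))) {
    write_volume(cohort$volumes[[i]],
                 file.path(vol_dir,
                           paste0(cohort$records$subject_id[i], ".nii.gz")),
                 spacing = spacing)
  }
  write_volume(cohort$atlas, file.path(dir, "atlas.nii.gz"), spacing = spacing)
  utils::write.csv(cohort$records, file.path(dir, "cohort.csv"),
                   row.names = FALSE)
  truth <- lapply(cohort$truth, unclass)
  jsonlite::write_json(list(seed = cohort$seed, noise_sd = cohort$noise_sd,
                            grid = cohort$grid, effects = truth),
                       file.path(dir, "truth.json"), auto_unbox = TRUE)
  invisible(dir)
}
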