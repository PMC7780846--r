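#' Mirror a volume along the left-right axis
#'
#' @param v 3D array (cubic grid).
#' @param lr_axis Axis index of the left-right direction (1, 2, or 3).
#' @return The mirrored array. Applying the mirror twice returns `v` exactly.
#' @export
flip_volume <- function(v, lr_axis = 1) {
  check_cubic(v)
  if (!(lr_axis %in% 1:3)) stop("lr_axis must be 1, 2 or 3")
  n <- dim(v)[1]
  idx <- rep(list(quote(expr = )), 3)
  idx[[lr_axis]] <- n:1
  do.call(`[`, c(list(v), idx, list(drop = FALSE)))
}

#' Hemisphere pair: native volume plus its mirror
#'
#' Sex differences in brain structure are treated as bilateral: the left
#' hemisphere is flipped to create a second "right" hemisphere, and each
#' subject contributes both copies to training and scoring. Here the pair is
#' the native volume and its left-right mirror on the same grid.
#'
#' @param v 3D array (cubic grid).
#' @param lr_axis Left-right axis index (default 1).
#' @return List of class `hemisphere_pair` with `native_right` and
#'   `flipped_left`.
#' @export
flip_to_pair <- function(v, lr_axis = 1) {
  structure(list(native_right = v, flipped_left = flip_volume(v, lr_axis),
                 lr_axis = lr_axis),
            class = "hemisphere_pair")
}

check_cubic <- function(v) {
  d <- dim(v)
  if (is.null(d) || length(d) != 3 || length(unique(d)) != 1)
    stop("expected a cubic 3D array")
  if (any(!is.finite(v))) stop("volume contains non-finite values")
  invisible(d[1])
}

#' Resample a volume under a rigid transform
#'
#' Rotates about the grid center (x, then y, then z axis, in degrees) and
#' translates (in voxels), resampling with trilinear or nearest-neighbor
#' interpolation and constant boundary fill 0. The transform maps output
#' voxel coordinates back into the input volume.
#'
#' @param v 3D array (cubic grid).
#' @param shift Numeric length-3 translation in voxels.
#' @param angles Numeric length-3 rotation in degrees about the three axes.
#' @param interpolation `"trilinear"` (default) or `"nearest"`.
#' @return The resampled array.
#' @export
rigid_transform <- function(v, shift = c(0, 0, 0), angles = c(0, 0, 0),
                            interpolation = c("trilinear", "nearest")) {
  n <- check_cubic(v)
  interpolation <- match.arg(interpolation)
  if (all(shift == 0) && all(angles == 0)) return(v)

  th <- angles * pi / 180
  rot1 <- function(a, axis) {
    R <- diag(3)
    i <- setdiff(1:3, axis)
    R[i[1], i[1]] <- cos(a); R[i[2], i[2]] <- cos(a)
    R[i[1], i[2]] <- -sin(a); R[i[2], i[1]] <- sin(a)
    R
  }
  R <- rot1(th[3], 3) %*% rot1(th[2], 2) %*% rot1(th[1], 1)

  ctr <- (n + 1) / 2
  g <- seq_len(n)
  out_coords <- cbind(rep(g, times = n * n) - ctr,
                      rep(rep(g, each = n), times = n) - ctr,
                      rep(g, each = n * n) - ctr)
  # inverse map: source = R^-1 ((out - shift))  (R orthogonal)
  src <- sweep(out_coords, 2, shift) %*% R  # (out - shift) %*% R == t(R^T (out-shift))
  src <- sweep(src, 2, -c(ctr, ctr, ctr))

  if (interpolation == "nearest") {
    ij <- round(src)
    ok <- ij[, 1] >= 1 & ij[, 1] <= n & ij[, 2] >= 1 & ij[, 2] <= n &
      ij[, 3] >= 1 & ij[, 3] <= n
    vals <- numeric(nrow(src))
    vals[ok] <- v[ij[ok, , drop = FALSE]]
  } else {
    f0 <- floor(src)
    w <- src - f0
    vals <- numeric(nrow(src))
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      ij <- f0 + matrix(rep(c(dx, dy, dz), each = nrow(f0)), ncol = 3)
      wt <- (if (dx == 1) w[, 1] else 1 - w[, 1]) *
            (if (dy == 1) w[, 2] else 1 - w[, 2]) *
            (if (dz == 1) w[, 3] else 1 - w[, 3])
      ok <- ij[, 1] >= 1 & ij[, 1] <= n & ij[, 2] >= 1 & ij[, 2] <= n &
        ij[, 3] >= 1 & ij[, 3] <= n & wt > 0
      if (any(ok)) vals[ok] <- vals[ok] + wt[ok] * v[ij[ok, , drop = FALSE]]
    }
  }
  array(vals, dim = c(n, n, n))
}

#' Random rigid augmentation of a volume
#'
#' Applies a random rigid transform with each translation component drawn
#' uniformly from `[-max_shift, max_shift]` voxels (continuous, reading the
#' "within one voxel" bound as a bound) and each rotation from
#' `[-max_rot, max_rot]` degrees about the three axes. Deterministic given
#' `seed`.
#'
#' @param v 3D array.
#' @param max_shift Maximum translation in voxels (default 1).
#' @param max_rot Maximum rotation in degrees (default 1).
#' @param seed Optional integer seed.
#' @param interpolation Passed to [rigid_transform()].
#' @return The augmented array.
#' @export
augment_rigid <- function(v, max_shift = 1, max_rot = 1, seed = NULL,
                          interpolation = "trilinear") {
  stopifnot(max_shift >= 0, max_rot >= 0)
  if (!is.null(seed)) set.seed(seed)
  shift <- stats::runif(3, -max_shift, max_shift)
  angles <- stats::runif(3, -max_rot, max_rot)
  rigid_transform(v, shift, angles, interpolation)
}

#' Balance a labeled dataset by rigid augmentation
#'
#' Ensures training is based on a balanced and sufficient number of samples
#' per class: all originals are retained, and extras are rigidly augmented
#' copies sampled uniformly with replacement within each class until both
#' classes reach `target_per_class`. For hemisphere pairs, both members are
#' augmented with the same random transform parameters.
#'
#' @param dataset List of samples; each sample is a list with elements
#'   `volume` (3D array or `hemisphere_pair`) and `label` (0/1).
#' @param target_per_class Desired per-class count; must be at least the
#'   current size of the largest class. `NULL` (default) balances to the
#'   largest class.
#' @param seed Integer seed.
#' @param max_shift,max_rot Augmentation bounds (see [augment_rigid()]).
#' @return The augmented list; added samples carry `augmented = TRUE`.
#' @export
balance_augment <- function(dataset, target_per_class = NULL, seed = 1,
                            max_shift = 1, max_rot = 1) {
  labels <- vapply(dataset, function(s) as.integer(s$label), integer(1))
  counts <- table(factor(labels, levels = c(0, 1)))
  if (any(counts == 0)) stop("balance_augment: a class is absent")
  if (is.null(target_per_class)) target_per_class <- max(counts)
  if (target_per_class < max(counts))
    stop("target_per_class is below the current size of the largest class")

  set.seed(seed)
  out <- dataset
  for (cl in c(0, 1)) {
    idx <- which(labels == cl)
    need <- target_per_class - length(idx)
    if (need <= 0) next
    pick <- sample(idx, need, replace = TRUE)
    for (p in pick) {
      s <- dataset[[p]]
      shift <- stats::runif(3, -max_shift, max_shift)
      angles <- stats::runif(3, -max_rot, max_rot)
      s$volume <- if (inherits(s$volume, "hemisphere_pair")) {
        structure(list(
          native_right = rigid_transform(s$volume$native_right, shift, angles),
          flipped_left = rigid_transform(s$volume$flipped_left, shift, angles),
          lr_axis = s$volume$lr_axis), class = "hemisphere_pair")
      } else rigid_transform(s$volume, shift, angles)
      s$augmented <- TRUE
      out[[length(out) + 1]] <- s
    }
  }
  out
}
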