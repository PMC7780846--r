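#' Read a 3D volume from NIfTI
#'
#' @param path Path to a `.nii` / `.nii.gz` file.
#' @return A plain 3D array.
#' @export
read_volume <- function(path) {
  v <- RNifti::readNifti(path)
  arr <- as.array(v)
  if (length(dim(arr)) != 3) stop("expected a 3D volume: ", path)
  arr
}

#' Write a 3D volume to NIfTI
#'
#' @param v 3D array.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param spacing Isotropic voxel spacing in mm (default 2).
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path, spacing = 2) {
  img <- RNifti::asNifti(array(as.numeric(v), dim = dim(v)))
  RNifti::pixdim(img) <- rep(spacing, 3)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a cohort table
#'
#' Reads the subject CSV with required columns `subject_id`, `sex`, `age`,
#' `pds`, `ses` and any additional cognitive-score columns. Rows with missing
#' required fields are dropped and counted. The sex column accepts 0/1 or
#' F/M (girls coded 1, boys 0); any other value is a schema error.
#'
#' @param path Path to the CSV file.
#' @return Data frame of subject records with attribute `n_dropped`.
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("subject_id", "sex", "age", "pds", "ses")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("cohort table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  sex_raw <- trimws(as.character(df$sex))
  map <- c(`0` = 0L, `1` = 1L, F = 1L, M = 0L)
  known <- sex_raw %in% names(map) | sex_raw == "" | is.na(df$sex)
  if (!all(known))
    stop("sex column contains value(s) outside {0, 1, F, M}: ",
         paste(unique(sex_raw[!known]), collapse = ", "))
  df$sex <- unname(map[sex_raw])
  for (col in c("age", "pds", "ses")) df[[col]] <- as.numeric(df[[col]])
  complete <- !Reduce(`|`, lapply(df[required], function(x) is.na(x) | x == ""))
  n_dropped <- sum(!complete)
  if (n_dropped > 0)
    message(sprintf("read_cohort: dropped %d row(s) with missing required fields",
                    n_dropped))
  df <- df[complete, , drop = FALSE]
  if (any(df$pds < 1 | df$pds > 5))
    stop("pds values must lie in [1, 5]")
  df$pds_level <- pds_level(df$pds)
  rownames(df) <- NULL
  attr(df, "n_dropped") <- n_dropped
  df
}

#' Tabular ROI features from volumes and an atlas
#'
#' The a-priori feature set the baseline classifiers consume: per atlas ROI,
#' the mean intensity within the ROI and its voxel-count volume taken from
#' the atlas parcellation. With a fixed atlas the volumes are constant
#' across subjects (the synthetic registration is exact), so they are
#' dropped by the baseline classifiers' constant-column rule; the ROI means
#' are the informative a-priori summaries.
#'
#' @param volumes List of 3D arrays.
#' @param atlas 3D integer label array on the same grid.
#' @return Data frame with columns `roi<label>_mean` and `roi<label>_vol`.
#' @export
roi_features <- function(volumes, atlas) {
  labels <- sort(setdiff(unique(as.integer(atlas)), 0L))
  vox <- lapply(labels, function(l) which(atlas == l))
  counts <- lengths(vox)
  rows <- lapply(volumes, function(v) {
    means <- vapply(vox, function(ix) mean(v[ix]), numeric(1))
    c(means, counts)
  })
  out <- do.call(rbind, rows)
  colnames(out) <- c(paste0("roi", labels, "_mean"),
                     paste0("roi", labels, "_vol"))
  as.data.frame(out)
}
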