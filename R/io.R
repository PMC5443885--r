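# NIfTI-1 and CSV round-trip helpers.

#' Write a 3D volume as NIfTI-1
#'
#' Writes with a diagonal RAS+ affine carrying the voxel sizes.
#'
#' @param image 3D numeric or logical array.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param voxel_size Voxel edge lengths in mm.
#' @return The path, invisibly.
#' @export
write_volume_nifti <- function(image, path, voxel_size = c(1, 1, 1)) {
  img <- RNifti::asNifti(array(as.numeric(image), dim = dim(image)))
  RNifti::pixdim(img) <- voxel_size
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a 3D volume from NIfTI-1
#'
#' @param path NIfTI file path.
#' @return A list: `image` (plain 3D array), `voxel_size` (mm),
#'   `voxel_volume_ml` (product of the three pixel dimensions, in ml).
#' @export
read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  vox <- RNifti::pixdim(img)
  if (length(vox) < 3 || any(!is.finite(vox[1:3])) || any(vox[1:3] <= 0)) {
    stop("malformed NIfTI header: non-positive pixel dimensions in ", path)
  }
  arr <- array(as.numeric(img), dim = dim(img))
  list(image = arr, voxel_size = as.numeric(vox[1:3]),
       voxel_volume_ml = prod(vox[1:3]) / 1000)
}

#' Read an image/mask pair, enforcing a common grid
#'
#' @param image_path,mask_path NIfTI paths.
#' @return A list with the image volume and a logical mask.
#' @export
read_image_with_mask <- function(image_path, mask_path) {
  img <- read_volume_nifti(image_path)
  msk <- read_volume_nifti(mask_path)
  if (!identical(dim(img$image), dim(msk$image))) {
    stop(sprintf("grid mismatch: image %s vs mask %s",
                 paste(dim(img$image), collapse = "x"),
                 paste(dim(msk$image), collapse = "x")))
  }
  list(image = img$image, mask = msk$image > 0,
       voxel_size = img$voxel_size, voxel_volume_ml = img$voxel_volume_ml)
}

COHORT_COLUMNS <- c("subject_id", "diagnosis", "visit_j", "visit_k",
                    "t_years", "scan_type", "y_ml")

#' Write a cohort change table as CSV
#'
#' @param records Data frame with the cohort schema (`subject_id`,
#'   `diagnosis`, `visit_j`, `visit_k`, `t_years`, `scan_type`, `y_ml`).
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_cohort_csv <- function(records, path) {
  miss <- setdiff(COHORT_COLUMNS, names(records))
  if (length(miss)) stop("records missing columns: ", paste(miss, collapse = ", "))
  utils::write.csv(records[, COHORT_COLUMNS], path, row.names = FALSE)
  invisible(path)
}

#' Read and validate a cohort change table
#'
#' Rejects missing or non-numeric cells with the offending row number.
#'
#' @param path CSV path with a header row matching the cohort schema.
#' @return A validated data frame.
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(COHORT_COLUMNS, names(df))
  if (length(miss)) {
    stop("cohort CSV missing columns: ", paste(miss, collapse = ", "))
  }
  for (col in c("visit_j", "visit_k", "t_years", "y_ml")) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(df[[col]]))))
    if (length(bad)) {
      stop(sprintf("cohort CSV: missing or non-numeric '%s' at row %d",
                   col, bad[1]))
    }
    df[[col]] <- as.numeric(df[[col]])
  }
  validate_change_records(df)
  df
}
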