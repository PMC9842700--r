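#' Construct a mask volume
#'
#' A mask volume couples a 3-D grid of values with a 4x4 voxel-to-world
#' affine in millimetres. World coordinates (MNI space) relate to 0-based
#' voxel indices by `world = affine %*% c(i, j, k, 1)`.
#'
#' @param grid 3-D numeric array.
#' @param affine 4x4 invertible voxel-to-world matrix.
#' @param name Mask name used in provenance reporting.
#' @return An object of class `mask_volume`.
#' @export
mask_volume <- function(grid, affine, name = "mask") {
  if (length(dim(grid)) != 3) {
    stop_imagetx("mask grid must be a 3-D array")
  }
  if (anyNA(grid) || any(!is.finite(grid))) {
    stop_imagetx("mask grid contains non-finite values")
  }
  affine <- unname(as.matrix(affine))
  if (!all(dim(affine) == c(4, 4)) || abs(det(affine)) < 1e-12) {
    stop_imagetx("mask affine must be an invertible 4x4 matrix")
  }
  structure(list(grid = grid, affine = affine, name = name),
            class = "mask_volume")
}

#' Read a 3-D NIfTI mask
#'
#' The affine is taken from the NIfTI header (sform/qform) and values are
#' left untransformed. 4-D input is rejected: thresholded statistical masks
#' are single volumes.
#'
#' @param path NIfTI-1 file (`.nii` or `.nii.gz`).
#' @param name Optional mask name; defaults to the file name.
#' @return A `mask_volume`.
#' @export
read_mask <- function(path, name = NULL) {
  if (!file.exists(path)) {
    stop_imagetx(sprintf("mask file not found: %s", path))
  }
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4 && d[4] == 1) {
    img <- array(as.numeric(img), dim = d[1:3])
    d <- d[1:3]
  } else if (length(d) != 3) {
    stop_imagetx(sprintf("mask must be a single 3-D volume, got %d dims: %s",
                         length(d), path))
  }
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = c(4, 4))
  mask_volume(array(as.numeric(img), dim = d), aff,
              name = name %||% basename(path))
}

#' Write a mask volume as NIfTI-1
#'
#' @param mask A `mask_volume` with an axis-aligned affine (diagonal spacing
#'   plus translation), which is what the pipeline's fixtures use.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  img <- RNifti::asNifti(mask$grid)
  # pixdim must be set before the qform, otherwise spacing is lost on write
  RNifti::pixdim(img) <- abs(diag(mask$affine)[1:3])
  RNifti::qform(img) <- structure(mask$affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a results table as TSV
#'
#' One record per row, tab-separated, with a header; the documented output
#' format for DE, stability and enrichment tables.
#'
#' @param tbl A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results_tsv <- function(tbl, path) {
  flat <- as_tibble(tbl)
  is_list_col <- vapply(flat, is.list, logical(1))
  flat[is_list_col] <- lapply(flat[is_list_col],
                              vapply, paste, character(1), collapse = ",")
  readr::write_tsv(flat, path, progress = FALSE)
  invisible(path)
}
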