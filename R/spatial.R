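#' Mirror world coordinates across the midsagittal plane
#'
#' Flips MNI world coordinates from one hemisphere to the other:
#' `(x, y, z) -> (-x, y, z)`. An involution; midline points are fixed.
#'
#' @param coords Numeric length-3 vector or n x 3 matrix of millimetre world
#'   coordinates.
#' @return Same shape as the input with the x sign flipped.
#' @export
mirror_x <- function(coords) {
  if (is.matrix(coords)) {
    coords[, 1] <- -coords[, 1]
    coords
  } else {
    c(-coords[1], coords[2:3])
  }
}

#' Sample a mask volume at world coordinates by trilinear interpolation
#'
#' Maps each world point through the inverse affine into continuous voxel
#' index space and blends the 8 surrounding voxel values with trilinear
#' weights. Points outside the grid bounding box return 0.
#'
#' @param vol A [mask_volume()].
#' @param points Length-3 vector or n x 3 matrix of world coordinates (mm).
#' @return Numeric vector of interpolated values, one per point.
#' @export
trilinear_sample <- function(vol, points) {
  stopifnot(inherits(vol, "mask_volume"))
  if (!is.matrix(points)) points <- matrix(points, ncol = 3)
  inv <- solve(vol$affine)
  idx <- t(inv %*% rbind(t(points), 1))[, 1:3, drop = FALSE]
  dims <- dim(vol$grid)
  out <- numeric(nrow(points))
  # clamp to the box: outside points keep value 0
  inside <- idx[, 1] >= 0 & idx[, 1] <= dims[1] - 1 &
    idx[, 2] >= 0 & idx[, 2] <= dims[2] - 1 &
    idx[, 3] >= 0 & idx[, 3] <= dims[3] - 1
  if (!any(inside)) return(out)
  p <- idx[inside, , drop = FALSE]
  i0 <- pmin(floor(p[, 1]), dims[1] - 2); i0 <- pmax(i0, 0)
  j0 <- pmin(floor(p[, 2]), dims[2] - 2); j0 <- pmax(j0, 0)
  k0 <- pmin(floor(p[, 3]), dims[3] - 2); k0 <- pmax(k0, 0)
  fx <- p[, 1] - i0; fy <- p[, 2] - j0; fz <- p[, 3] - k0
  g <- vol$grid
  at <- function(di, dj, dk) {
    g[cbind(i0 + di + 1, j0 + dj + 1, k0 + dk + 1)]
  }
  val <-
    at(0, 0, 0) * (1 - fx) * (1 - fy) * (1 - fz) +
    at(1, 0, 0) * fx       * (1 - fy) * (1 - fz) +
    at(0, 1, 0) * (1 - fx) * fy       * (1 - fz) +
    at(0, 0, 1) * (1 - fx) * (1 - fy) * fz       +
    at(1, 1, 0) * fx       * fy       * (1 - fz) +
    at(1, 0, 1) * fx       * (1 - fy) * fz       +
    at(0, 1, 1) * (1 - fx) * fy       * fz       +
    at(1, 1, 1) * fx       * fy       * fz
  out[inside] <- val
  out
}

#' Assign samples to affected and control regions
#'
#' Restricts to left-hemisphere samples whose structure label belongs to the
#' cortical selection, then scores each sample coordinate against every mask
#' by trilinear interpolation. A sample is `affected` when the maximum
#' interpolated value across masks (union rule) reaches `threshold`
#' (inclusive), `control` otherwise; non-cortical or right-hemisphere samples
#' are `excluded`. With `mirror = TRUE` the sample x-coordinate is negated
#' before lookup, which mirrors right-hemisphere masks onto the left cortex
#' in world space without resampling any volume.
#'
#' @param samples Sample tibble (`sample_id`, `donor_id`, `structure_label`,
#'   `mni_x`, `mni_y`, `mni_z`, `hemisphere`).
#' @param masks A `mask_volume` or list of them.
#' @param cortical_labels Character vector of structure labels forming the
#'   cortical selection.
#' @param threshold Inside-mask rule on the interpolated value, default 0.5.
#' @param mirror Negate sample x before mask lookup.
#' @return Tibble of class `region_assignment`: `sample_id`, `donor_id`,
#'   `label` (`affected`/`control`/`excluded`), `mask_value`, `mask_name`.
#' @export
assign_samples <- function(samples, masks, cortical_labels,
                           threshold = 0.5, mirror = FALSE) {
  if (inherits(masks, "mask_volume")) masks <- list(masks)
  cortical <- samples$structure_label %in% cortical_labels &
    samples$hemisphere == "left"
  if (!any(cortical)) stop_imagetx("empty cortical selection")
  coords <- as.matrix(samples[, c("mni_x", "mni_y", "mni_z")])
  if (mirror) coords <- mirror_x(coords)
  vals <- vapply(masks, trilinear_sample, numeric(nrow(coords)),
                 points = coords)
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = 1)
  best <- max.col(vals, ties.method = "first")
  mask_value <- vals[cbind(seq_len(nrow(vals)), best)]
  mask_name <- vapply(masks, function(m) m$name, character(1))[best]
  label <- ifelse(!cortical, "excluded",
                  ifelse(mask_value >= threshold, "affected", "control"))
  out <- tibble(sample_id = samples$sample_id,
                donor_id = samples$donor_id,
                label = label,
                mask_value = mask_value,
                mask_name = ifelse(label == "affected", mask_name,
                                   NA_character_))
  class(out) <- c("region_assignment", class(out))
  out
}

#' Per-donor assignment counts
#'
#' The bookkeeping table behind a cohort description: affected / control /
#' excluded sample counts for each donor.
#'
#' @param assignment A `region_assignment`.
#' @return Tibble `donor_id`, `affected`, `control`, `excluded`.
#' @export
assignment_counts <- function(assignment) {
  assignment |>
    count(.data$donor_id, .data$label) |>
    tidyr::pivot_wider(names_from = "label", values_from = "n",
                       values_fill = 0L)
}
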