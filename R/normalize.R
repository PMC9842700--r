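#' Remove donor batch structure from an expression matrix
#'
#' Per gene, ordinary least squares of expression on an intercept plus
#' sum-to-zero donor contrasts; the returned values are the input minus the
#' fitted batch terms, with the grand intercept retained. For a one-factor
#' design this has the closed form
#' `x - (batch mean - unweighted mean of batch means)`, and matches linear
#' batch removal as practised for donor-driven atlas variance.
#'
#' @param X Gene x sample matrix.
#' @param batch Donor label per sample (length `ncol(X)`).
#' @return Matrix of the same shape, stage-tagged `"batch_removed"`. A single
#'   batch returns the input unchanged (only the intercept is estimable).
#' @export
remove_batch_effects <- function(X, batch) {
  check_expression_matrix(X)
  batch <- as.character(batch)
  if (length(batch) != ncol(X)) {
    stop_imagetx("batch labels must match the sample columns")
  }
  tab <- table(batch)
  if (any(tab == 0)) stop_imagetx("a batch has no samples")
  if (length(tab) == 1) {
    attr(X, "stage") <- "batch_removed"
    return(X)
  }
  if (any(tab < 2)) {
    stop_imagetx("each batch needs at least 2 samples")
  }
  grp <- factor(batch)
  counts <- as.numeric(table(grp))
  sums <- t(rowsum(t(X), grp))            # gene x batch totals
  bmeans <- sweep(sums, 2, counts, "/")   # gene x batch means
  centre <- rowMeans(bmeans)              # unweighted: sum-to-zero contrasts
  out <- X - (bmeans[, as.integer(grp), drop = FALSE] - centre)
  dimnames(out) <- dimnames(X)
  attr(out, "stage") <- "batch_removed"
  out
}

#' Scaled robust sigmoid normalization of a vector
#'
#' Two printed formulas applied in sequence: a sigmoid centred at the median
#' with scale `IQR/1.35` (the normal-consistency constant),
#' `x_y = 1 / (1 + exp(-(x - median(x)) / (IQR/1.35)))`,
#' followed by min-max rescaling of the sigmoid values to the unit interval.
#' Quartiles use linear interpolation (type 7). Strictly rank-preserving for
#' non-degenerate input.
#'
#' Degenerate scales fall back in order: zero IQR uses `1.349 x MAD`; if that
#' is also zero but values differ, the standard deviation; all-equal input
#' maps to 0.5 everywhere (as does a zero range after the sigmoid).
#'
#' @param x Numeric vector, length >= 2.
#' @return Numeric vector in `[0, 1]`.
#' @export
srs_vector <- function(x) {
  if (length(x) < 2) stop_imagetx("srs_vector needs length >= 2")
  if (all(x == x[1])) return(rep(0.5, length(x)))
  ctr <- median(x)
  scale <- stats::IQR(x, type = 7) / 1.35
  if (scale == 0) scale <- 1.349 * mad(x, constant = 1)
  if (scale == 0) scale <- sd(x)
  y <- plogis((x - ctr) / scale)
  rng <- range(y)
  if (rng[1] == rng[2]) return(rep(0.5, length(x)))
  (y - rng[1]) / (rng[2] - rng[1])
}

#' Across-sample SRS normalization (per gene)
#'
#' Applies [srs_vector()] to every gene row, scaling each gene's profile
#' across samples to `[0, 1]`.
#'
#' @param X Gene x sample matrix (batch-removed).
#' @return Matrix of the same shape, stage-tagged `"srs_across_samples"`.
#' @export
srs_across_samples <- function(X) {
  check_expression_matrix(X)
  out <- t(apply(X, 1, srs_vector))
  dimnames(out) <- dimnames(X)
  attr(out, "stage") <- "srs_across_samples"
  out
}

#' Within-sample SRS normalization (per sample, across genes)
#'
#' The second pass of the two-pass strategy: the same SRS and unit-interval
#' scaling applied within each sample column, across all genes, to absorb
#' sample-specific gene outliers. Run after [srs_across_samples()].
#'
#' @param X Gene x sample matrix from the across-sample pass.
#' @return Matrix of the same shape, stage-tagged `"srs_within_sample"`.
#' @export
srs_within_sample <- function(X) {
  check_expression_matrix(X)
  out <- apply(X, 2, srs_vector)
  dimnames(out) <- dimnames(X)
  attr(out, "stage") <- "srs_within_sample"
  out
}

#' Full normalization stage
#'
#' Donor batch removal, then gene-wise SRS across samples, then (optionally)
#' SRS within each sample across genes, in that order.
#'
#' @param X Gene x sample matrix.
#' @param batch Donor label per sample.
#' @param within_sample Run the within-sample pass (default `TRUE`).
#' @return Normalized matrix with a `stage` attribute naming the last pass.
#' @export
normalize_expression <- function(X, batch, within_sample = TRUE) {
  out <- srs_across_samples(remove_batch_effects(X, batch))
  if (within_sample) out <- srs_within_sample(out)
  out
}
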