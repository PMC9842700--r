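#' Differential stability of gene expression across donors
#'
#' Differential stability (DS) measures how consistently a gene's regional
#' expression pattern reproduces across donor brains. Per gene, expression is
#' averaged within each (donor, structure) cell; DS is the mean over all
#' donor pairs of the Pearson correlation between the two donors'
#' structure-mean vectors, restricted to structures both donors sampled. A
#' donor pair contributes only when it shares at least 3 structures and both
#' profiles are non-constant; genes with no contributing pair are excluded
#' (and reported).
#'
#' @param X Gene x sample matrix (normalized).
#' @param samples Sample tibble with `sample_id`, `donor_id`,
#'   `structure_label` covering the columns of `X`.
#' @return Tibble of class `ds_table`: `gene`, `ds`, `n_pairs`; excluded
#'   genes are absent, with their ids in attribute `excluded`.
#' @export
differential_stability <- function(X, samples) {
  check_expression_matrix(X)
  samples <- samples |> filter(.data$sample_id %in% colnames(X))
  if (nrow(samples) < ncol(X)) {
    stop_imagetx("sample table does not cover all expression columns")
  }
  X <- X[, samples$sample_id, drop = FALSE]
  cell <- interaction(samples$donor_id, samples$structure_label, drop = TRUE,
                      sep = "\r")
  means <- t(rowsum(t(X), cell)) /
    rep(as.numeric(table(cell)), each = nrow(X))      # gene x (donor,structure)
  key <- do.call(rbind, strsplit(colnames(means), "\r", fixed = TRUE))
  donors <- sort(unique(samples$donor_id))
  if (length(donors) < 2) stop_imagetx("need at least 2 donors for DS")

  pair_cors <- list()
  for (a in seq_along(donors)[-length(donors)]) {
    for (b in seq((a + 1), length(donors))) {
      sa <- key[, 1] == donors[a]
      sb <- key[, 1] == donors[b]
      common <- intersect(key[sa, 2], key[sb, 2])
      if (length(common) < 3) next
      Ma <- means[, sa, drop = FALSE][, match(common, key[sa, 2]),
                                      drop = FALSE]
      Mb <- means[, sb, drop = FALSE][, match(common, key[sb, 2]),
                                      drop = FALSE]
      pair_cors[[length(pair_cors) + 1]] <- row_cor(Ma, Mb)
    }
  }
  if (length(pair_cors) == 0) {
    stop_imagetx("no donor pair shares 3 or more structures")
  }
  cm <- do.call(cbind, pair_cors)                     # gene x pair
  n_pairs <- rowSums(!is.na(cm))
  ds <- rowMeans(cm, na.rm = TRUE)
  keep <- n_pairs > 0
  excluded <- rownames(X)[!keep]
  if (length(excluded) > 0) {
    inform(sprintf("DS undefined for %d gene(s) (constant profiles); excluded",
                   length(excluded)))
  }
  out <- tibble(gene = rownames(X)[keep], ds = unname(ds[keep]),
                n_pairs = unname(n_pairs[keep]))
  attr(out, "excluded") <- excluded
  class(out) <- c("ds_table", class(out))
  out
}

# rowwise Pearson correlation of two matrices with matched columns
row_cor <- function(A, B) {
  A <- A - rowMeans(A)
  B <- B - rowMeans(B)
  den <- sqrt(rowSums(A^2) * rowSums(B^2))
  r <- rowSums(A * B) / den
  r[den == 0] <- NA_real_
  r
}

#' Compare differential stability between gene groups
#'
#' Two-sided Mann-Whitney U test of DS values for the differentially
#' expressed genes against the remainder. The reported `u` is the statistic
#' for the first group (rank-sum form). Exact enumeration is used for small
#' tie-free samples (both groups of size <= 20); otherwise the tie-corrected
#' normal approximation with continuity correction.
#'
#' @param ds_de DS values of the DE genes.
#' @param ds_other DS values of the remaining genes.
#' @return Tibble: `u`, `p_value`, `median_de`, `median_other`, `n_de`,
#'   `n_other`, `method`.
#' @export
compare_ds <- function(ds_de, ds_other) {
  if (length(ds_de) == 0 || length(ds_other) == 0) {
    stop_imagetx("both DS groups must be non-empty")
  }
  small <- max(length(ds_de), length(ds_other)) <= 20
  ties <- anyDuplicated(c(ds_de, ds_other)) > 0
  exact <- small && !ties
  wt <- suppressWarnings(
    wilcox.test(ds_de, ds_other, alternative = "two.sided",
                exact = exact, correct = TRUE))
  tibble(u = unname(wt$statistic),
         p_value = wt$p.value,
         median_de = median(ds_de),
         median_other = median(ds_other),
         n_de = length(ds_de),
         n_other = length(ds_other),
         method = if (exact) "exact" else "normal_approx")
}

#' Group DS values by differential-expression call
#'
#' @param ds A `ds_table`.
#' @param calls The `higher`/`lower` list from [call_de()] or a `de_fit`.
#' @return The table with a `group` column in
#'   `{de_higher, de_lower, other}`.
#' @export
label_ds_groups <- function(ds, calls) {
  if (inherits(calls, "de_fit")) calls <- calls$calls
  ds |>
    mutate(group = dplyr::case_when(
      .data$gene %in% calls$higher ~ "de_higher",
      .data$gene %in% calls$lower ~ "de_lower",
      TRUE ~ "other"))
}
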