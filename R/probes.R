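#' Filter probes by detection rate
#'
#' Keeps probes whose signal rises above background noise in at least
#' `min_fraction` of samples, pooled across all donors ("at least" is
#' inclusive, so a probe detected in exactly half the samples is kept).
#'
#' @param det Binary probe x sample detection matrix, all donors pooled.
#' @param min_fraction Minimum detection fraction, default 0.5.
#' @return Character vector of retained probe ids.
#' @export
filter_by_detection <- function(det, min_fraction = 0.5) {
  if (!is.matrix(det) || nrow(det) == 0 || ncol(det) == 0) {
    stop_imagetx("detection matrix is empty")
  }
  if (!all(det %in% c(0, 1))) {
    stop_imagetx("detection matrix must be binary")
  }
  keep <- rowMeans(det) >= min_fraction
  rownames(det)[keep]
}

#' Collapse probes to one best probe per gene by RNA-seq concordance
#'
#' For every annotated gene with at least one surviving probe, computes the
#' Spearman correlation of each probe against the gene's RNA-seq profile on
#' the shared samples and keeps the probe with the highest correlation. Genes
#' absent from the RNA-seq rows (or all-zero there, i.e. not detected by
#' RNA-seq) are dropped; so are genes whose winning probe correlates below
#' `rho_min` (strict). Losing probes are marked `outcompeted`. Ties in the
#' winning correlation resolve to the lexicographically smallest probe id.
#'
#' Spearman correlations use average ranks (Pearson on mid-ranks), so ties in
#' either profile are handled deterministically.
#'
#' @param expr Probe-level expression matrix (probes already
#'   detection-filtered).
#' @param probes Probe annotation tibble (`probe_id`, `gene_symbol`,
#'   `is_annotated`).
#' @param rnaseq Gene-level RNA-seq matrix; its columns must be a subset of
#'   `expr` columns. Needs at least 3 shared samples.
#' @param rho_min Exclusion threshold on the winning Spearman rho
#'   (default 0.2, strict `<`).
#' @return A list of class `probe_selection` with `kept` (tibble
#'   `gene_symbol`, `probe_id`, `rho`), `dropped` (tibble `probe_id`,
#'   `gene_symbol`, `reason`), and `expression` (gene-level matrix of the
#'   winning probes' rows, rownames = gene symbols).
#' @export
collapse_probes <- function(expr, probes, rnaseq, rho_min = 0.2) {
  check_expression_matrix(expr, "expr")
  shared <- intersect(colnames(rnaseq), colnames(expr))
  if (length(shared) < 3) {
    stop_imagetx("correlation undefined: fewer than 3 samples shared with RNA-seq")
  }
  probes <- probes |> filter(.data$probe_id %in% rownames(expr))
  annotated <- probes |> filter(.data$is_annotated)
  if (nrow(annotated) == 0) stop_imagetx("no annotated probes to collapse")

  em <- expr[annotated$probe_id, shared, drop = FALSE]
  # mid-rank transform once per probe row and per gene row
  rank_rows <- function(m) t(apply(m, 1, rank, ties.method = "average"))
  probe_ranks <- rank_rows(em)

  genes <- unique(annotated$gene_symbol)
  in_rna <- genes %in% rownames(rnaseq)
  rna_sub <- rnaseq[genes[in_rna], shared, drop = FALSE]
  rna_zero <- rowSums(abs(rna_sub)) == 0
  gene_ranks <- rank_rows(rna_sub)

  kept <- vector("list", length(genes))
  dropped <- vector("list", length(genes))
  for (gi in seq_along(genes)) {
    g <- genes[gi]
    pid <- sort(annotated$probe_id[annotated$gene_symbol == g])
    if (!in_rna[gi] || rna_zero[match(g, rownames(rna_sub))]) {
      dropped[[gi]] <- tibble(probe_id = pid, gene_symbol = g,
                              reason = "not_in_rnaseq")
      next
    }
    gr <- gene_ranks[match(g, rownames(rna_sub)), ]
    rho <- as.numeric(cor(t(probe_ranks[pid, , drop = FALSE]), gr))
    rho[is.na(rho)] <- -Inf  # constant probe profile: correlation undefined
    win <- which(rho == max(rho))[1]  # pid sorted, so ties pick smallest id
    # strict "< rho_min" rule, guarded against floating-point representation
    # of rank correlations that sit exactly on the threshold
    if (!is.finite(rho[win]) || rho[win] < rho_min - 1e-9) {
      dropped[[gi]] <- tibble(probe_id = pid, gene_symbol = g,
                              reason = "low_rnaseq_correlation")
      next
    }
    kept[[gi]] <- tibble(gene_symbol = g, probe_id = pid[win],
                         rho = rho[win])
    if (length(pid) > 1) {
      dropped[[gi]] <- tibble(probe_id = pid[-win], gene_symbol = g,
                              reason = "outcompeted")
    }
  }
  empty_kept <- tibble(gene_symbol = character(), probe_id = character(),
                       rho = numeric())
  kept <- bind_rows(c(list(empty_kept), kept)) |> arrange(.data$gene_symbol)
  dropped <- bind_rows(c(list(tibble(probe_id = character(),
                                     gene_symbol = character(),
                                     reason = character())), dropped))

  gene_expr <- expr[kept$probe_id, , drop = FALSE]
  rownames(gene_expr) <- kept$gene_symbol
  structure(list(kept = kept, dropped = dropped, expression = gene_expr,
                 rho_min = rho_min, n_shared_samples = length(shared)),
            class = "probe_selection")
}

#' @export
print.probe_selection <- function(x, ...) {
  cat(sprintf("probe selection: %d genes kept, %d probes dropped (%d shared RNA-seq samples)\n",
              nrow(x$kept), nrow(x$dropped), x$n_shared_samples))
  if (nrow(x$dropped) > 0) {
    tab <- table(x$dropped$reason)
    for (r in names(tab)) cat(sprintf("  dropped %s: %d\n", r, tab[[r]]))
  }
  invisible(x)
}

#' Run the full probe-selection stage
#'
#' Detection filtering followed by RNA-seq concordance collapse, with a
#' per-probe report of every exclusion.
#'
#' @inheritParams collapse_probes
#' @param det Detection matrix matching `expr`.
#' @param min_fraction Detection threshold passed to [filter_by_detection()].
#' @return A `probe_selection`; probes failing detection appear in `dropped`
#'   with reason `low_detection`.
#' @export
select_probes <- function(expr, det, probes, rnaseq,
                          min_fraction = 0.5, rho_min = 0.2) {
  keep <- filter_by_detection(det, min_fraction)
  lost <- setdiff(rownames(expr), keep)
  res <- collapse_probes(expr[keep, , drop = FALSE], probes, rnaseq,
                         rho_min = rho_min)
  if (length(lost) > 0) {
    res$dropped <- bind_rows(
      tibble(probe_id = lost,
             gene_symbol = probes$gene_symbol[match(lost, probes$probe_id)],
             reason = "low_detection"),
      res$dropped)
  }
  res
}
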