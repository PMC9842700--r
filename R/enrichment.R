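#' Hypergeometric gene-set enrichment
#'
#' Upper-tail hypergeometric test of the overlap between a query gene set
#' (e.g. the differentially expressed genes) and each collection set,
#' against a background universe: `p = P(X >= k)` with `N = |background|`,
#' `K = |set ∩ background|`, `n = |query|`. Fold enrichment is the
#' percentage of query genes in the set divided by the corresponding
#' background percentage, `(k/n) / (K/N)`. Sets empty after intersection
#' with the background are skipped (0/0 fold enrichment is undefined) and
#' reported via a message.
#'
#' An EASE-style conservative variant (one overlap gene discounted from the
#' tail) is available behind `ease = TRUE`.
#'
#' @param query Character vector of query genes; must be a subset of
#'   `background`.
#' @param sets A `gene_sets` collection.
#' @param background Character vector, the gene universe (e.g. all genes
#'   covered by the selected probes).
#' @param ease Use the EASE-discounted tail. Default `FALSE`.
#' @return Tibble: `set_name`, `overlap_k`, `set_size_K`, `query_size_n`,
#'   `background_N`, `fold_enrichment`, `p_value`.
#' @export
hypergeom_enrich <- function(query, sets, background, ease = FALSE) {
  query <- unique(query)
  background <- unique(background)
  if (length(query) == 0) stop_imagetx("query gene set is empty")
  stray <- setdiff(query, background)
  if (length(stray) > 0) {
    stop_imagetx(sprintf("query gene not in background: %s", stray[1]))
  }
  N <- length(background)
  n <- length(query)
  rows <- purrr::pmap(list(sets$set_name, sets$genes), function(nm, g) {
    members <- intersect(g, background)
    K <- length(members)
    if (K == 0) {
      inform(sprintf("set %s has no background genes; skipped", nm))
      return(NULL)
    }
    k <- length(intersect(members, query))
    k_tail <- if (ease) max(k - 1, 0) else k
    tibble(set_name = nm, overlap_k = k, set_size_K = K,
           query_size_n = n, background_N = N,
           fold_enrichment = (k / n) / (K / N),
           p_value = phyper(k_tail - 1, K, N - K, n, lower.tail = FALSE))
  })
  bind_rows(rows)
}

#' Adjust enrichment p-values and call significance
#'
#' `bonferroni`: `min(1, m p)` over the `m` tested sets, with significance
#' called at adjusted `p < alpha` (the cell-type marker rule).
#' `BH`: step-up false-discovery-rate adjustment, with significance calling
#' additionally requiring fold enrichment > 1 (the functional-term rule).
#'
#' @param records Output of [hypergeom_enrich()].
#' @param method `"bonferroni"` or `"BH"`.
#' @param alpha Significance threshold on the adjusted p-value.
#' @return `records` with `adjusted_p`, `correction` and `significant`
#'   columns.
#' @export
adjust_enrichment <- function(records, method = c("bonferroni", "BH"),
                              alpha = 0.05) {
  method <- match.arg(method)
  adjusted <- if (method == "bonferroni") {
    pmin(1, length(records$p_value) * records$p_value)
  } else {
    bh_adjust(records$p_value)
  }
  records |>
    mutate(adjusted_p = adjusted,
           correction = method,
           significant = if (method == "bonferroni") {
             adjusted < alpha
           } else {
             adjusted < alpha & .data$fold_enrichment > 1
           })
}

#' Drop marker sets with too few genes
#'
#' Cell types need at least `min_genes` distinct marker genes to be testable
#' ("at least five" keeps size-5 sets).
#'
#' @param sets A `gene_sets` collection.
#' @param min_genes Inclusion threshold, default 5.
#' @return The filtered collection; removals are reported via a message.
#' @export
filter_marker_sets <- function(sets, min_genes = 5) {
  sizes <- vapply(sets$genes, length, integer(1))
  drop <- sizes < min_genes
  if (all(drop)) stop_imagetx("all marker sets fall below min_genes")
  if (any(drop)) {
    inform(sprintf("excluded %d marker set(s) with fewer than %d genes: %s",
                   sum(drop), min_genes,
                   paste(sets$set_name[drop], collapse = ", ")))
  }
  sets[!drop, ]
}

#' Cross-reference DE genes against cell-type-exclusive expression
#'
#' Some genes are measurably expressed in only one cell type; their presence
#' among the differentially expressed genes can indicate that cell type even
#' when the marker-set test lacks power. Reports DE genes whose trimmed-mean
#' expression is positive in exactly one cell type, or whose top cell type
#' carries at least `specificity_threshold` of the gene's total trimmed-mean
#' mass. These are indications, not significance calls.
#'
#' @param de_genes Character vector of DE genes.
#' @param expression A `cell_type_expression` object (see
#'   [trimmed_mean_expression()]) or a gene x cell-type matrix of
#'   trimmed-mean values.
#' @param specificity_threshold Fraction of total mass carried by the top
#'   cell type, default 0.9.
#' @return Tibble: `gene`, `cell_type`, `specificity`.
#' @export
single_marker_crossref <- function(de_genes, expression,
                                   specificity_threshold = 0.9) {
  m <- if (inherits(expression, "cell_type_expression")) {
    expression$values
  } else expression
  m <- m[intersect(de_genes, rownames(m)), , drop = FALSE]
  if (nrow(m) == 0) return(tibble(gene = character(),
                                  cell_type = character(),
                                  specificity = numeric()))
  total <- rowSums(m)
  top <- apply(m, 1, which.max)
  n_pos <- rowSums(m > 0)
  spec <- ifelse(total > 0, m[cbind(seq_len(nrow(m)), top)] / total, 0)
  hit <- total > 0 & (n_pos == 1 | spec >= specificity_threshold)
  tibble(gene = rownames(m)[hit],
         cell_type = colnames(m)[top[hit]],
         specificity = spec[hit])
}

#' Build disease signature gene sets from a transcriptomic table
#'
#' A gene joins a disease group when its FDR-corrected p-value is at most
#' `q_max` (inclusive), split into `higher` / `lower` sets by a strict
#' log-fold-change gate (`> lfc_abs_min` or `< -lfc_abs_min`). Empty sets are
#' retained with a warning (more stringent criteria are known to empty these
#' groups).
#'
#' @param signature_table Tibble with columns `gene`, `disease`, `logFC`,
#'   `q`.
#' @param q_max FDR gate, inclusive; default 0.05.
#' @param lfc_abs_min Log-fold-change gate, strict; default 0.1.
#' @return A tibble in `gene_sets` shape (possibly with empty sets), set
#'   names `<disease>_higher` / `<disease>_lower`.
#' @export
build_disease_sets <- function(signature_table, q_max = 0.05,
                               lfc_abs_min = 0.1) {
  need <- c("gene", "disease", "logFC", "q")
  if (!all(need %in% names(signature_table))) {
    stop_imagetx(sprintf("signature table lacks columns: %s",
                         paste(setdiff(need, names(signature_table)),
                               collapse = ", ")))
  }
  diseases <- unique(signature_table$disease)
  rows <- purrr::map_dfr(diseases, function(d) {
    sub <- signature_table |> filter(.data$disease == d, .data$q <= q_max)
    tibble(set_name = paste0(d, c("_higher", "_lower")),
           description = sprintf("%s transcriptomic signature (%s)", d,
                                 c("higher", "lower")),
           genes = list(unique(sub$gene[sub$logFC > lfc_abs_min]),
                        unique(sub$gene[sub$logFC < -lfc_abs_min])))
  })
  empty <- vapply(rows$genes, length, integer(1)) == 0
  if (any(empty)) {
    warn(sprintf("empty disease set(s): %s",
                 paste(rows$set_name[empty], collapse = ", ")))
  }
  class(rows) <- c("gene_sets", class(rows))
  rows
}

#' Trimmed-mean expression per gene and cell type
#'
#' For each (gene, cell type): log2-transform expression with a +1
#' pseudocount, drop the lowest and highest quartiles of cells
#' (`floor(n/4)` each side), and average the middle 50%. Cell types with
#' fewer than 4 cells cannot be trimmed and are excluded with a message.
#'
#' @param counts Gene x cell matrix of non-negative expression values.
#' @param cell_labels Cell-type label per cell (length `ncol(counts)`).
#' @return Object of class `cell_type_expression`: `values` (gene x
#'   cell-type trimmed-mean matrix), `cell_counts` (named vector),
#'   `omitted_genes` (zero in every cell type, flagged for plot omission).
#' @export
trimmed_mean_expression <- function(counts, cell_labels) {
  stopifnot(is.matrix(counts), length(cell_labels) == ncol(counts))
  if (any(counts < 0)) stop_imagetx("expression values must be non-negative")
  lab <- factor(as.character(cell_labels))
  sizes <- table(lab)
  usable <- names(sizes)[sizes >= 4]
  if (length(usable) == 0) stop_imagetx("no cell type has 4 or more cells")
  if (length(usable) < length(sizes)) {
    inform(sprintf("excluded cell type(s) with fewer than 4 cells: %s",
                   paste(setdiff(names(sizes), usable), collapse = ", ")))
  }
  lg <- log2(counts + 1)
  vals <- vapply(usable, function(ct) {
    sub <- lg[, lab == ct, drop = FALSE]
    nc <- ncol(sub)
    cut <- floor(nc / 4)
    apply(sub, 1, function(v) {
      s <- sort(v)
      mean(s[(cut + 1):(nc - cut)])
    })
  }, numeric(nrow(counts)))
  vals <- matrix(vals, nrow = nrow(counts),
                 dimnames = list(rownames(counts), usable))
  omitted <- rownames(counts)[rowSums(vals) == 0]
  structure(list(values = vals,
                 cell_counts = stats::setNames(as.integer(sizes[usable]),
                                               usable),
                 omitted_genes = omitted),
            class = "cell_type_expression")
}
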