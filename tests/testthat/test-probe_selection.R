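make_det <- function(rates, n = 10) {
  m <- t(vapply(rates, function(r) rep(c(1, 0), c(round(r * n), n - round(r * n))),
                numeric(n)))
  dimnames(m) <- list(sprintf("p%02d", seq_along(rates)),
                      sprintf("s%02d", seq_len(n)))
  m
}

test_that("detection filter keeps probes at or above the threshold", {
  det <- make_det(0.5, n = 6)           # 3 of 6 samples
  expect_equal(filter_by_detection(det), "p01")
  expect_equal(filter_by_detection(make_det(0, n = 6)), character(0))

  det10 <- make_det(seq(0, 0.9, by = 0.1))
  expect_equal(length(filter_by_detection(det10)), 5)
  expect_error(filter_by_detection(matrix(numeric(0), 0, 0)), "empty")
})

# fixed 6-sample fixture: RNA-seq profile 1..6 and probes with known
# rank agreements
collapse_fixture <- function() {
  samples <- sprintf("s%d", 1:6)
  rnaseq <- matrix(1:6, 1, 6, dimnames = list("GENE1", samples))
  expr <- rbind(
    GENE1_a = c(1, 2, 3, 6, 5, 4),   # Spearman rho = 1 - 6*8/210
    GENE1_b = exp(1:6))              # strictly increasing: rho = 1
  colnames(expr) <- samples
  probes <- tibble::tibble(probe_id = rownames(expr),
                           gene_symbol = "GENE1", is_annotated = TRUE)
  list(expr = expr, probes = probes, rnaseq = rnaseq)
}

test_that("collapse keeps the probe most concordant with RNA-seq", {
  fx <- collapse_fixture()
  res <- collapse_probes(fx$expr, fx$probes, fx$rnaseq)
  expect_equal(res$kept$probe_id, "GENE1_b")
  expect_equal(res$kept$rho, 1)
  expect_equal(res$dropped$reason, "outcompeted")
  # losing probe's rho against the independent rank-correlation oracle
  expect_equal(cor(fx$expr["GENE1_a", ], fx$rnaseq[1, ],
                   method = "spearman"), 1 - 6 * 8 / (6 * 35))
  # winner row is exposed under the gene symbol
  expect_equal(rownames(res$expression), "GENE1")
})

test_that("low-concordance and RNA-seq-absent genes are excluded", {
  samples <- sprintf("s%d", 1:6)
  rnaseq <- rbind(GENE1 = 1:6, GENE3 = rep(0, 6))
  colnames(rnaseq) <- samples
  expr <- rbind(GENE1_a = c(3, 4, 6, 1, 2, 5),  # rho = 0 vs 1..6
               GENE1_b = c(2, 4, 6, 1, 3, 5),   # rho = 0.2 exactly
               GENE2_a = 1:6,                   # gene not in RNA-seq
               GENE3_a = 1:6)                   # RNA-seq all zero
  colnames(expr) <- samples
  probes <- tibble::tibble(probe_id = rownames(expr),
                           gene_symbol = c("GENE1", "GENE1", "GENE2", "GENE3"),
                           is_annotated = TRUE)
  res <- collapse_probes(expr, probes, rnaseq)
  # winning rho 0.2 is kept: the exclusion rule is strictly below 0.2
  expect_equal(res$kept$gene_symbol, "GENE1")
  expect_equal(res$kept$rho, 0.2)
  reasons <- setNames(res$dropped$reason, res$dropped$probe_id)
  expect_equal(unname(reasons[c("GENE2_a", "GENE3_a")]),
               c("not_in_rnaseq", "not_in_rnaseq"))

  # push the winner below 0.2: whole gene is dropped
  res2 <- collapse_probes(expr[c("GENE1_a"), , drop = FALSE],
                          probes[1, ], rnaseq)
  expect_equal(nrow(res2$kept), 0)
  expect_equal(res2$dropped$reason, "low_rnaseq_correlation")

  expect_error(collapse_probes(expr[, 1:2], probes, rnaseq[, 1:2]),
               "correlation undefined")
})

test_that("collapse is idempotent and bounded by the RNA-seq universe", {
  fx <- collapse_fixture()
  res <- collapse_probes(fx$expr, fx$probes, fx$rnaseq)
  expect_lte(nrow(res$kept), nrow(fx$rnaseq))
  again <- collapse_probes(res$expression,
                           tibble::tibble(probe_id = rownames(res$expression),
                                          gene_symbol = rownames(res$expression),
                                          is_annotated = TRUE),
                           fx$rnaseq)
  expect_equal(again$kept$gene_symbol, res$kept$gene_symbol)
  expect_equal(rownames(again$expression), rownames(res$expression))
})

test_that("the designated best probe wins for nearly all genes", {
  sim <- default_sim()
  b <- sim$bundle
  sel <- suppressMessages(
    select_probes(b$expression, b$detection, b$probes, b$rnaseq))
  won <- grepl("_p1$", sel$kept$probe_id)
  expect_gte(mean(won), 0.95)
  # detection-filtered probes carry their reason in the report
  expect_true("low_detection" %in% sel$dropped$reason)
  # kept and dropped partition the loaded annotated probes
  expect_equal(sort(c(sel$kept$probe_id, sel$dropped$probe_id)),
               sort(b$probes$probe_id))
})
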