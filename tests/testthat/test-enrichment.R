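# exhaustive-draw oracle: P(overlap >= k) when drawing n genes from N
enum_hyper_p <- function(N, K, n, k_obs) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)        # set = first K labels
  mean(hits >= k_obs)
}

test_that("hypergeometric enrichment matches closed forms and conventions", {
  bg <- sprintf("g%02d", 1:10)
  sets <- gene_sets("S", "d", list(bg[1:5]))
  rec <- hypergeom_enrich(bg[1:5], sets, bg)
  expect_equal(rec$p_value, 1 / choose(10, 5))   # 1/252
  expect_equal(rec$fold_enrichment, 2)

  # zero overlap: fold enrichment 0, p = 1 when the draw can miss the set
  rec0 <- hypergeom_enrich(bg[6:10], sets, bg)
  expect_equal(rec0$overlap_k, 0)
  expect_equal(rec0$fold_enrichment, 0)
  expect_equal(rec0$p_value, 1)

  # the printed fold-enrichment example: (10/100) / (200/10000) = 5
  bg2 <- sprintf("h%05d", 1:10000)
  sets2 <- gene_sets("T", "d", list(c(bg2[1:10], bg2[201:390])))
  query <- c(bg2[1:10], bg2[9001:9090])
  rec2 <- hypergeom_enrich(query, sets2, bg2)
  expect_equal(rec2$overlap_k, 10)
  expect_equal(rec2$set_size_K, 200)
  expect_equal(rec2$fold_enrichment, 5.0)

  expect_error(hypergeom_enrich(character(0), sets, bg), "empty")
  expect_error(hypergeom_enrich("absent", sets, bg), "absent")
})

test_that("hypergeometric p equals exhaustive enumeration for small universes", {
  set.seed(40)
  for (rep in 1:20) {
    N <- sample(5:12, 1)
    K <- sample(1:(N - 1), 1)
    n <- sample(1:(N - 1), 1)
    bg <- sprintf("g%02d", 1:N)
    sets <- gene_sets("S", "d", list(bg[1:K]))
    query <- sample(bg, n)
    rec <- hypergeom_enrich(query, sets, bg)
    expect_equal(rec$p_value, enum_hyper_p(N, K, n, rec$overlap_k),
                 tolerance = 1e-12)
  }
})

test_that("p-value adjustment follows the bonferroni and BH definitions", {
  rec <- tibble::tibble(set_name = paste0("s", 1:20),
                        p_value = c(0.01, runif(19, 0.2, 1)),
                        fold_enrichment = 2)
  adj <- adjust_enrichment(rec, "bonferroni")
  expect_equal(adj$adjusted_p[1], 0.2)          # 20 * 0.01
  expect_true(all(adj$adjusted_p <= 1))

  one <- adjust_enrichment(rec[1, ], "bonferroni")
  expect_equal(one$adjusted_p, one$p_value)

  bh <- adjust_enrichment(rec, "BH")
  expect_equal(bh$adjusted_p, bh_adjust(rec$p_value))
  # BH significance additionally requires fold enrichment > 1
  low_fold <- dplyr::mutate(rec, fold_enrichment = 0.5)
  expect_false(any(adjust_enrichment(low_fold, "BH")$significant))
})

test_that("marker sets below five genes are excluded, five kept", {
  sets <- gene_sets(paste0("ct", 3:6), "d",
                    lapply(3:6, function(k) sprintf("g%d_%d", k, 1:k)))
  kept <- suppressMessages(filter_marker_sets(sets))
  expect_equal(kept$set_name, c("ct5", "ct6"))
  expect_error(suppressMessages(filter_marker_sets(sets, min_genes = 10)),
               "below")
})

test_that("cell-type-exclusive DE genes are cross-referenced", {
  m <- rbind(exclusive = c(0, 0, 2.5, 0),
             uniform = c(1, 1, 1, 1),
             dominant = c(0.05, 9, 0.2, 0.05),
             silent = c(0, 0, 0, 0))
  colnames(m) <- paste0("ct", 1:4)
  hits <- single_marker_crossref(rownames(m), m)
  expect_equal(hits$gene, c("exclusive", "dominant"))
  expect_equal(hits$cell_type, c("ct3", "ct2"))
  # not reported: uniform expression or silence everywhere
  expect_false(any(c("uniform", "silent") %in% hits$gene))
  # restricting the query restricts the report
  expect_equal(nrow(single_marker_crossref("uniform", m)), 0)
})

test_that("disease sets gate on inclusive q and strict logFC", {
  tab <- tibble::tibble(
    gene = c("a", "b", "c", "d"),
    disease = "MDD",
    logFC = c(0.2, 0.1, -0.5, 0.3),
    q = c(0.05, 0.04, 0.02, 0.2))
  sets <- build_disease_sets(tab)
  higher <- sets$genes[[match("MDD_higher", sets$set_name)]]
  lower <- sets$genes[[match("MDD_lower", sets$set_name)]]
  expect_true("a" %in% higher)        # q = 0.05 inclusive
  expect_false("b" %in% higher)       # logFC = 0.1 strict
  expect_false("d" %in% higher)       # q gate
  expect_equal(lower, "c")
  expect_error(build_disease_sets(tab[, 1:2]), "lacks columns")
})

test_that("trimmed means drop the outer quartiles of log2 expression", {
  counts <- rbind(g1 = c(0, 1, 3, 7),
                  g2 = rep(5, 4),
                  g3 = rep(0, 4))
  colnames(counts) <- paste0("c", 1:4)
  ct <- trimmed_mean_expression(counts, rep("typeA", 4))
  expect_equal(ct$values["g1", "typeA"], 1.5)  # middle 50% of (0,1,2,3)
  expect_equal(ct$values["g2", "typeA"], log2(6))
  expect_equal(ct$values["g3", "typeA"], 0)
  expect_equal(ct$omitted_genes, "g3")

  # a 3-cell type cannot be trimmed and is excluded with a message
  counts2 <- cbind(counts, c5 = c(1, 1, 1), c6 = c(2, 2, 2), c7 = c(3, 3, 3))
  expect_message(
    ct2 <- trimmed_mean_expression(counts2,
                                   c(rep("typeA", 4), rep("tiny", 3))),
    "tiny")
  expect_equal(colnames(ct2$values), "typeA")
  expect_error(trimmed_mean_expression(counts[, 1:3], rep("t", 3)),
               "4 or more")
})

test_that("planted marker sets reach bonferroni significance, disjoint sets do not", {
  run <- default_pipeline()
  sim <- default_sim()
  enr <- run$results$enrichment
  expect_setequal(enr$set_name[enr$significant],
                  sim$truth$enriched_marker_sets)
  disjoint <- paste0("CellType_", c("D", "E", "F", "G"))
  expect_false(any(enr$significant[enr$set_name %in% disjoint]))
})
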