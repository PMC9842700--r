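named_mat <- function(m) {
  dimnames(m) <- list(paste0("g", seq_len(nrow(m))),
                      paste0("s", seq_len(ncol(m))))
  m
}

test_that("batch removal has the sum-to-zero closed form", {
  X <- named_mat(matrix(c(1, 1, 3, 3), 1, 4))
  out <- remove_batch_effects(X, c("A", "A", "B", "B"))
  expect_equal(unname(out[1, ]), rep(2, 4))

  # single batch: nothing estimable beyond the retained intercept
  expect_equal(remove_batch_effects(X, rep("A", 4)), X,
               ignore_attr = "stage")

  # a constant added to one batch is fully absorbed by the batch terms and
  # the retained intercept: outputs change only by the uniform offset c/2
  set.seed(1)
  Y <- named_mat(matrix(rnorm(40), 5, 8))
  batch <- rep(c("A", "B"), each = 4)
  shifted <- Y; shifted[, batch == "B"] <- shifted[, batch == "B"] + 7.3
  delta <- remove_batch_effects(shifted, batch) -
    remove_batch_effects(Y, batch)
  expect_equal(unname(delta), matrix(7.3 / 2, 5, 8), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("batch removal agrees with a per-gene OLS oracle", {
  set.seed(2)
  X <- named_mat(matrix(rnorm(20 * 12), 20, 12))
  batch <- factor(rep(c("A", "B", "C"), times = c(3, 4, 5)))
  out <- remove_batch_effects(X, as.character(batch))
  # dense oracle: intercept + sum-to-zero contrasts, batch part subtracted
  design <- model.matrix(~ batch, contrasts.arg = list(batch = contr.sum))
  for (g in seq_len(nrow(X))) {
    beta <- solve(crossprod(design), crossprod(design, X[g, ]))
    oracle <- X[g, ] - design[, -1, drop = FALSE] %*% beta[-1]
    expect_equal(unname(out[g, ]), as.numeric(oracle), tolerance = 1e-10)
  }
  # and with the reference batch-removal implementation
  skip_if_not_installed("limma")
  expect_equal(unname(out),
               unname(limma::removeBatchEffect(X, batch = batch)),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("srs_vector follows the sigmoid and unit-rescale formulas", {
  x <- c(0, 1, 2, 3, 4)
  # independent evaluation of the two printed formulas, type-7 quartiles
  iqr <- unname(diff(quantile(x, c(0.25, 0.75), type = 7)))
  y <- 1 / (1 + exp(-(x - median(x)) / (iqr / 1.35)))
  oracle <- (y - min(y)) / (max(y) - min(y))
  expect_equal(srs_vector(x), oracle, tolerance = 1e-12)

  # the median element sits at 0.5 before rescaling
  expect_equal(y[3], 0.5)

  expect_equal(srs_vector(rep(3.7, 6)), rep(0.5, 6))
  # zero IQR with unequal values still rank-preserves via the MAD fallback
  z <- c(1, 2, 2, 2, 2, 2, 2, 9)
  expect_equal(order(srs_vector(z)), order(z))
  expect_true(all(srs_vector(z) >= 0 & srs_vector(z) <= 1))
})

test_that("matrix SRS passes scale rows then columns, preserving ranks", {
  set.seed(3)
  X <- named_mat(matrix(rnorm(5 * 4, sd = 2), 5, 4))
  across <- srs_across_samples(X)
  expect_equal(unname(apply(across, 1, min)), rep(0, 5))
  expect_equal(unname(apply(across, 1, max)), rep(1, 5))
  for (g in 1:5) expect_equal(order(across[g, ]), order(X[g, ]))

  within <- srs_within_sample(across)
  expect_equal(unname(apply(within, 2, min)), rep(0, 4))
  for (s in 1:4) expect_equal(order(within[, s]), order(across[, s]))

  # fixed fixture equals sequential application of the vector formula
  oracle <- t(apply(X, 1, srs_vector))
  oracle <- apply(oracle, 2, srs_vector)
  expect_equal(unname(within), unname(oracle), tolerance = 1e-12,
               ignore_attr = TRUE)

  # degenerate all-equal column maps to 0.5
  Xc <- named_mat(matrix(c(1, 1, 1, 5, 6, 7), 3, 2))
  expect_equal(unname(srs_within_sample(Xc)[, 1]), rep(0.5, 3))
})

test_that("normalization is invariant to donor relabeling", {
  set.seed(4)
  X <- named_mat(matrix(rnorm(8 * 12), 8, 12))
  batch <- rep(c("A", "B", "C"), each = 4)
  norm1 <- normalize_expression(X, batch)
  perm <- sample(ncol(X))
  norm2 <- normalize_expression(X[, perm], batch[perm])
  expect_equal(norm2[, colnames(norm1)], norm1, ignore_attr = "stage")
})

test_that("batch removal equalizes per-donor gene means on offset-only data", {
  cfg <- simulation_config(n_donors = 4, samples_per_donor = 30,
                           n_genes = 100, n_planted_de = 0,
                           marker_set_specs = zero_overlap_specs(),
                           seed = 8)
  sim <- simulate_atlas(cfg)
  out <- remove_batch_effects(sim$gene_expression,
                              sim$bundle$samples$donor_id)
  donor <- factor(sim$bundle$samples$donor_id)
  means <- t(rowsum(t(out), donor)) / as.numeric(table(donor))[1]
  spread <- apply(means, 1, function(v) diff(range(v)))
  expect_lt(max(spread), 1e-8)
})

test_that("normalization shrinks donor-driven sample clustering", {
  cfg <- tiny_config()
  sim <- simulate_atlas(cfg)
  donor <- sim$bundle$samples$donor_id
  sil <- function(M) {
    sc <- prcomp(t(M), rank. = 2)$x          # 2-D embedding
    d <- as.matrix(dist(sc))
    s <- vapply(seq_len(nrow(sc)), function(i) {
      a <- mean(d[i, setdiff(which(donor == donor[i]), i)])
      b <- min(vapply(setdiff(unique(donor), donor[i]),
                      function(k) mean(d[i, donor == k]), numeric(1)))
      (b - a) / max(a, b)
    }, numeric(1))
    mean(s)
  }
  raw_sil <- sil(sim$gene_expression)
  norm_sil <- sil(normalize_expression(sim$gene_expression, donor))
  expect_lt(norm_sil, raw_sil)
})
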