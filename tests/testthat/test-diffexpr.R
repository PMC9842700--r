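named_mat <- function(m) {
  dimnames(m) <- list(paste0("g", seq_len(nrow(m))),
                      paste0("s", seq_len(ncol(m))))
  m
}

two_group_design <- function(affected) {
  cbind(intercept = 1, affected = as.numeric(affected))
}

test_that("consensus correlation returns 0 for all-singleton blocks", {
  set.seed(10)
  X <- named_mat(matrix(rnorm(50 * 6), 50, 6))
  d <- two_group_design(c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_warning(
    rho <- estimate_consensus_correlation(X, d, paste0("b", 1:6)),
    "singleton")
  expect_equal(rho, 0)
})

test_that("GLS reduces to OLS at rho = 0 and to mean differences on balanced toys", {
  set.seed(11)
  X <- named_mat(matrix(rnorm(30 * 8), 30, 8))
  aff <- rep(c(FALSE, TRUE), each = 4)
  d <- two_group_design(aff)
  block <- rep(c("b1", "b2"), each = 4)
  fit0 <- fit_gene_models(X, d, block, consensus_rho = 0)
  ols <- t(qr.coef(qr(d), t(X)))
  expect_equal(fit0$coefficients, ols, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(unname(fit0$coefficients[, "affected"]),
               unname(rowMeans(X[, aff]) - rowMeans(X[, !aff])),
               tolerance = 1e-10)
})

test_that("GLS matches a dense whole-covariance oracle", {
  set.seed(12)
  X <- named_mat(matrix(rnorm(20 * 6), 20, 6))
  aff <- c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE)
  d <- two_group_design(aff)
  block <- c("b1", "b1", "b2", "b2", "b3", "b3")
  rho <- 0.5
  fit <- fit_gene_models(X, d, block, consensus_rho = rho)
  # dense oracle: explicit correlation matrix inverse per gene
  R <- diag(6)
  for (i in 1:6) for (j in 1:6) {
    if (i != j && block[i] == block[j]) R[i, j] <- rho
  }
  Ri <- solve(R)
  A <- solve(t(d) %*% Ri %*% d)
  for (g in 1:20) {
    beta <- A %*% t(d) %*% Ri %*% X[g, ]
    expect_equal(unname(fit$coefficients[g, ]), as.numeric(beta),
                 tolerance = 1e-8)
    r <- X[g, ] - d %*% beta
    s2 <- as.numeric(t(r) %*% Ri %*% r) / (6 - 2)
    expect_equal(unname(fit$sigma2[g]), s2, tolerance = 1e-8)
  }
  expect_equal(unname(fit$stdev_unscaled), unname(sqrt(diag(A))),
               tolerance = 1e-8)
})

test_that("moderation limits recover the ordinary and pooled t-statistics", {
  set.seed(13)
  n <- 10
  X <- named_mat(matrix(rnorm(60 * n), 60, n))
  aff <- rep(c(FALSE, TRUE), each = n / 2)
  d <- two_group_design(aff)
  fit <- fit_gene_models(X, d, rep("b1", n), consensus_rho = 0)

  # d0 forced to 0: ordinary per-gene t
  tab0 <- ebayes_moderate(fit, coef = "affected", force_d0 = 0)
  tt <- apply(X, 1, function(y) t.test(y[aff], y[!aff],
                                       var.equal = TRUE)$statistic)
  expect_equal(unname(tab0$moderated_t), unname(tt), tolerance = 1e-8)
  expect_equal(unname(tab0$df_total), rep(n - 2, 60))

  # identical sample variances: the prior df go to infinity and every gene
  # is pooled to the single prior variance (the log-scale consistent
  # estimate of the common value, with the Bartlett-type correction the
  # reference empirical-Bayes fit applies)
  fit2 <- fit
  fit2$sigma2 <- rep(0.3, 60)
  tab2 <- suppressMessages(ebayes_moderate(fit2, coef = "affected"))
  s_pool <- 0.3 * exp(log((n - 2) / 2) - digamma((n - 2) / 2))
  expect_equal(unname(tab2$posterior_sigma2), rep(s_pool, 60))
  expect_equal(unname(tab2$moderated_t),
               unname(fit$coefficients[, "affected"] /
                        (sqrt(s_pool) * fit$stdev_unscaled["affected"])))
  expect_equal(attr(tab2, "prior")$d0, Inf)
})

test_that("moderated statistics agree with the limma reference", {
  skip_if_not_installed("limma")
  set.seed(14)
  X <- named_mat(matrix(rnorm(100 * 20, sd = rep(runif(100, 0.5, 2), 20)),
                        100, 20))
  aff <- rep(c(FALSE, TRUE), 10)
  d <- two_group_design(aff)
  block <- rep(paste0("b", 1:4), each = 5)
  rho <- 0.4
  fit <- fit_gene_models(X, d, block, consensus_rho = rho)
  tab <- ebayes_moderate(fit, coef = "affected")
  lfit <- limma::lmFit(X, design = d, block = block, correlation = rho)
  lfit <- limma::eBayes(lfit)
  expect_equal(unname(tab$log_fold_change),
               unname(lfit$coefficients[, "affected"]), tolerance = 1e-8)
  expect_equal(unname(tab$moderated_t), unname(lfit$t[, "affected"]),
               tolerance = 1e-6)
  expect_equal(unname(tab$p_value), unname(lfit$p.value[, "affected"]),
               tolerance = 1e-6)
  expect_equal(attr(tab, "prior")$d0, lfit$df.prior, tolerance = 1e-6)
  expect_equal(attr(tab, "prior")$s0_sq, lfit$s2.prior, tolerance = 1e-6)
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  set.seed(15)
  p <- runif(200)
  # direct definition: q_(i) = min over j >= i of m p_(j) / j
  o <- order(p)
  m <- length(p)
  q_sorted <- rev(cummin(rev(m * p[o] / seq_len(m))))
  oracle <- numeric(m); oracle[o] <- pmin(q_sorted, 1)
  expect_equal(bh_adjust(p), oracle, tolerance = 1e-12)
})

test_that("DE calls use a strict threshold and carry direction", {
  tab <- tibble::tibble(gene = c("a", "b", "c"),
                        log_fold_change = c(1, -1, 2),
                        q_value = c(0.05, 0.01, 0.049))
  calls <- call_de(tab, alpha = 0.05)
  expect_false("a" %in% c(calls$higher, calls$lower))  # q = 0.05 exactly
  expect_equal(calls$lower, "b")
  expect_equal(calls$higher, "c")
})

test_that("moderated t is antisymmetric under group-label swap", {
  set.seed(16)
  X <- named_mat(matrix(rnorm(80 * 12), 80, 12))
  aff <- rep(c(TRUE, FALSE), 6)
  block <- rep(c("b1", "b2", "b3"), each = 4)
  f1 <- fit_differential_expression(X, aff, block)
  f2 <- fit_differential_expression(X, !aff, block)
  expect_equal(f1$table$moderated_t, -f2$table$moderated_t,
               tolerance = 1e-8)
  expect_equal(f1$table$p_value, f2$table$p_value, tolerance = 1e-8)
})

test_that("tidy and glance expose the fit in broom shape", {
  sim <- default_sim()
  run <- default_pipeline()
  de <- run$results$de
  td <- tidy(de)
  expect_true(all(c("gene", "log_fold_change", "moderated_t", "p_value",
                    "q_value", "direction") %in% names(td)))
  expect_false(is.unsorted(td$p_value))
  # q monotone non-decreasing in p
  expect_false(is.unsorted(td$q_value[order(td$p_value)]))
  gl <- glance(de)
  expect_equal(gl$n_higher, length(de$calls$higher))
  expect_equal(gl$n_affected + gl$n_control, ncol(run$results$normalized))
})
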