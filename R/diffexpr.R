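#' Estimate the consensus intra-donor correlation
#'
#' Samples from the same donor brain are not independent. Per gene, an
#' intra-block (donor) correlation is estimated from the residuals of the
#' ordinary least-squares fit by a moment estimator: the between-sample
#' excess covariance within blocks relative to the residual variance. Both
#' moments are corrected exactly for the OLS projection (which absorbs part
#' of any shared block effect into the fitted coefficients and would
#' otherwise attenuate the estimate when blocks are few) using the trace
#' identities `E[r'Ar] = sigma^2 (tr(AM) + rho tr(AMAM))` and
#' `E[r'r] = sigma^2 (n - p + rho tr(AM))`, with `A` the within-block
#' pairing matrix and `M` the residual projector. The per-gene estimates are
#' pooled on Fisher's z scale by a 15%-trimmed mean and transformed back,
#' yielding a single consensus value shared by all genes in the generalized
#' least-squares fit.
#'
#' @param X Gene x sample matrix (normalized).
#' @param design Sample x coefficient model matrix.
#' @param block Donor label per sample.
#' @param trim Trim fraction for the pooled mean of atanh values.
#' @return Consensus correlation (scalar). All-singleton blocks return 0 with
#'   a warning (no within-donor information).
#' @export
estimate_consensus_correlation <- function(X, design, block, trim = 0.15) {
  check_expression_matrix(X)
  block <- factor(as.character(block))
  n <- ncol(X)
  stopifnot(nrow(design) == n, length(block) == n)
  sizes <- table(block)
  if (all(sizes < 2)) {
    warn("all donor blocks are singletons; consensus correlation set to 0")
    return(0)
  }
  design <- as.matrix(design)
  qrd <- qr(design)
  res <- t(qr.resid(qrd, t(X)))                     # gene x sample
  D_g <- rowSums(res^2)                             # r'r per gene
  bsum <- t(rowsum(t(res), block))                  # gene x block sums
  bssq <- t(rowsum(t(res^2), block))
  N_g <- rowSums(bsum^2 - bssq)                     # r'Ar per gene

  # projection-corrected moments: A = blockdiag(J - I), M = I - H
  nu <- n - qrd$rank
  xtx_inv <- chol2inv(qr.R(qrd))
  B1 <- rowsum(design, block)                       # block x p, X_b' 1_b
  hb <- design %*% (xtx_inv %*% t(B1))              # n x blocks, H 1_b
  hb_sum <- vapply(seq_along(levels(block)),
                   function(b) sum(hb[block == levels(block)[b], b]),
                   numeric(1))                      # 1_b' H 1_b
  hdiag <- rowSums((design %*% xtx_inv) * design)   # diag(H)
  hdiag_b <- as.numeric(rowsum(hdiag, block))
  tr_AH <- sum(hb_sum - hdiag_b)
  t1 <- -tr_AH                                      # tr(AM); tr(A) = 0
  nb <- as.numeric(sizes)
  tr_A2 <- sum(nb * (nb - 1))
  tr_A2H <- sum((nb - 2) * hb_sum + hdiag_b)        # A^2 = (nb-2)J + I
  XtAX <- t(B1) %*% B1 - crossprod(design)
  C <- xtx_inv %*% XtAX
  tr_AHAH <- sum(C * t(C))
  t2 <- tr_A2 - 2 * tr_A2H + tr_AHAH                # tr(AMAM)

  rho_g <- (N_g * nu - D_g * t1) / (D_g * t2 - N_g * t1)
  rho_g <- pmin(pmax(rho_g, -0.99), 0.99)
  tanh(mean(atanh(rho_g), trim = trim))
}

#' Fit per-gene linear models under block-exchangeable correlation
#'
#' Generalized least squares for every gene with correlation `consensus_rho`
#' between samples of the same donor block and 0 between blocks. The
#' block-exchangeable correlation has a closed-form inverse square root, so
#' each block's rows are whitened analytically:
#' `W y = (y - ybar) / sqrt(1 - rho) + ybar / sqrt(1 + (nb - 1) rho)`
#' applied per block, after which one ordinary fit serves all genes. With
#' `consensus_rho = 0` this reduces exactly to OLS.
#'
#' @param X Gene x sample matrix.
#' @param design Sample x coefficient model matrix (full rank).
#' @param block Donor label per sample.
#' @param consensus_rho Intra-block correlation in (-1, 1).
#' @return A list of class `gene_fits`: `coefficients` (gene x coefficient),
#'   `sigma2` (residual variance per gene), `df_residual`,
#'   `stdev_unscaled` (per coefficient), `design`, `consensus_rho`.
#' @export
fit_gene_models <- function(X, design, block, consensus_rho = 0) {
  check_expression_matrix(X)
  design <- as.matrix(design)
  n <- ncol(X)
  p <- ncol(design)
  stopifnot(nrow(design) == n, abs(consensus_rho) < 1)
  block <- factor(as.character(block))
  Y <- t(X)                                        # sample x gene
  if (consensus_rho != 0) {
    a <- 1 / sqrt(1 - consensus_rho)
    for (b in levels(block)) {
      idx <- which(block == b)
      nb <- length(idx)
      bb <- 1 / sqrt(1 + (nb - 1) * consensus_rho)
      ym <- colMeans(Y[idx, , drop = FALSE])
      Y[idx, ] <- a * sweep(Y[idx, , drop = FALSE], 2, ym) +
        rep(bb * ym, each = nb)
      dm <- colMeans(design[idx, , drop = FALSE])
      design[idx, ] <- a * sweep(design[idx, , drop = FALSE], 2, dm) +
        rep(bb * dm, each = nb)
    }
  }
  qrd <- qr(design)
  if (qrd$rank < p) stop_imagetx("whitened design is rank deficient")
  coefs <- t(qr.coef(qrd, Y))                      # gene x coefficient
  res <- qr.resid(qrd, Y)
  df <- n - p
  sigma2 <- colSums(res^2) / df
  xtx_inv <- chol2inv(qr.R(qrd))
  structure(list(coefficients = coefs,
                 sigma2 = unname(sigma2),
                 df_residual = df,
                 stdev_unscaled = setNames(sqrt(diag(xtx_inv)),
                                           colnames(design)),
                 design = design,
                 consensus_rho = consensus_rho,
                 genes = rownames(X)),
            class = "gene_fits")
}

#' Fit a scaled-F prior to per-gene sample variances
#'
#' Empirical-Bayes hyper-parameters `(d0, s0^2)` obtained by matching the
#' first two moments of `log(sigma2)` to those implied by a scaled F
#' distribution, via the digamma/trigamma equations. When the observed
#' spread of log variances does not exceed what sampling alone implies, the
#' prior degrees of freedom are infinite (complete pooling) and a message is
#' logged.
#'
#' @param sigma2 Positive per-gene sample variances (zeros are excluded from
#'   the fit).
#' @param df_residual Residual degrees of freedom (scalar).
#' @return List with `d0` (possibly `Inf`) and `s0_sq`.
#' @export
fit_variance_prior <- function(sigma2, df_residual) {
  if (any(sigma2 < 0)) stop_imagetx("negative sample variances")
  ok <- sigma2 > 0
  if (sum(ok) < 30) {
    stop_imagetx("need at least 30 positive variances to fit the prior")
  }
  z <- log(sigma2[ok])
  e <- z - digamma(df_residual / 2) + log(df_residual / 2)
  emean <- mean(e)
  evar <- var(e) - trigamma(df_residual / 2)
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    inform("log-variance spread within sampling noise; prior df set to Inf")
    d0 <- Inf
    s0_sq <- exp(emean)
  }
  list(d0 = d0, s0_sq = s0_sq)
}

#' Empirical-Bayes moderation of a per-gene fit
#'
#' Shrinks each gene's sample variance towards the fitted prior,
#' `s~^2 = (d0 s0^2 + df s^2) / (d0 + df)`, and computes moderated
#' t-statistics for one coefficient with `df + d0` degrees of freedom
#' (two-sided p-values). Genes with zero residual variance are assigned the
#' prior variance and flagged.
#'
#' @param fit A `gene_fits` object.
#' @param coef Column of the design to test (index or name); default the
#'   last, the group indicator in an intercept + indicator design.
#' @param force_d0 Optional override of the prior degrees of freedom; `0`
#'   recovers the ordinary per-gene t-test, `Inf` the fully pooled one.
#' @return Tibble: `gene`, `log_fold_change`, `sigma2`, `posterior_sigma2`,
#'   `df_residual`, `df_total`, `moderated_t`, `p_value`, `flagged`; the
#'   prior is attached as attribute `prior`.
#' @export
ebayes_moderate <- function(fit, coef = ncol(fit$coefficients),
                            force_d0 = NULL) {
  stopifnot(inherits(fit, "gene_fits"))
  s2 <- fit$sigma2
  df <- fit$df_residual
  beta <- fit$coefficients[, coef]
  su <- fit$stdev_unscaled[coef]
  if (!is.null(force_d0)) {
    prior <- list(d0 = force_d0,
                  s0_sq = if (force_d0 > 0)
                    fit_variance_prior(s2, df)$s0_sq else NA_real_)
  } else {
    prior <- fit_variance_prior(s2, df)
  }
  d0 <- prior$d0
  zero <- s2 == 0
  if (d0 == 0) {
    post <- s2
  } else if (is.infinite(d0)) {
    post <- rep(prior$s0_sq, length(s2))
  } else {
    post <- (d0 * prior$s0_sq + df * s2) / (d0 + df)
    post[zero] <- prior$s0_sq
  }
  df_total <- df + d0
  tstat <- beta / (sqrt(post) * su)
  p <- 2 * pt(-abs(tstat), df = df_total)
  out <- tibble(gene = fit$genes,
                log_fold_change = unname(beta),
                sigma2 = s2,
                posterior_sigma2 = post,
                df_residual = df,
                df_total = df_total,
                moderated_t = unname(tstat),
                p_value = p,
                flagged = zero)
  attr(out, "prior") <- prior
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return BH-adjusted q-values (clipped at 1, monotone).
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop_imagetx("p-values outside [0, 1]")
  p.adjust(p, method = "BH")
}

#' Call differentially expressed gene sets
#'
#' Splits significant genes (strict `q < alpha`, matching a "corrected
#' p < 0.05" rule) by the sign of the log-fold-change.
#'
#' @param table Tidy DE table with `gene`, `log_fold_change`, `q_value`.
#' @param alpha Significance threshold, default 0.05 (strict).
#' @return List with character vectors `higher` and `lower`.
#' @export
call_de <- function(table, alpha = 0.05) {
  sig <- table$q_value < alpha
  list(higher = table$gene[sig & table$log_fold_change > 0],
       lower = table$gene[sig & table$log_fold_change < 0])
}

#' Moderated differential expression between affected and control samples
#'
#' The full Step-5 style analysis: estimate a consensus intra-donor
#' correlation, fit per-gene generalized least squares with an intercept plus
#' affected indicator, moderate the variances by empirical Bayes, and adjust
#' p-values by Benjamini-Hochberg.
#'
#' @param X Gene x sample normalized matrix.
#' @param affected Logical vector (or vector of `"affected"`/`"control"`)
#'   per sample.
#' @param block Donor label per sample.
#' @param alpha Significance threshold for [call_de()].
#' @param force_rho,force_d0 Optional overrides of the consensus correlation
#'   and prior degrees of freedom.
#' @return Object of class `de_fit`; see [tidy.de_fit()] and
#'   [glance.de_fit()].
#' @export
fit_differential_expression <- function(X, affected, block, alpha = 0.05,
                                        force_rho = NULL, force_d0 = NULL) {
  check_expression_matrix(X)
  if (is.character(affected)) affected <- affected == "affected"
  stopifnot(length(affected) == ncol(X), is.logical(affected))
  if (!any(affected) || all(affected)) {
    stop_imagetx("need both affected and control samples")
  }
  design <- cbind(intercept = 1, affected = as.numeric(affected))
  rho <- force_rho %||%
    estimate_consensus_correlation(X, design, block)
  fit <- fit_gene_models(X, design, block, consensus_rho = rho)
  tab <- ebayes_moderate(fit, coef = "affected", force_d0 = force_d0)
  prior <- attr(tab, "prior")
  tab$q_value <- bh_adjust(tab$p_value)
  tab$direction <- dplyr::case_when(tab$log_fold_change > 0 ~ "higher",
                                    tab$log_fold_change < 0 ~ "lower",
                                    TRUE ~ "none")
  calls <- call_de(tab, alpha)
  structure(list(table = tab,
                 consensus_rho = rho,
                 prior = prior,
                 calls = calls,
                 alpha = alpha,
                 n_affected = sum(affected),
                 n_control = sum(!affected)),
            class = "de_fit")
}

#' @export
print.de_fit <- function(x, ...) {
  cat(sprintf("differential expression: %d genes, %d affected vs %d control samples\n",
              nrow(x$table), x$n_affected, x$n_control))
  cat(sprintf("  consensus intra-donor correlation: %.4f\n", x$consensus_rho))
  cat(sprintf("  eBayes prior: d0 = %.3g, s0^2 = %.3g\n",
              x$prior$d0, x$prior$s0_sq))
  cat(sprintf("  q < %g: %d higher, %d lower\n", x$alpha,
              length(x$calls$higher), length(x$calls$lower)))
  invisible(x)
}

#' Tidy a differential-expression fit
#'
#' @param x A `de_fit`.
#' @param ... Unused.
#' @return One row per gene: `gene`, `log_fold_change`, `moderated_t`,
#'   `p_value`, `q_value`, `direction`, `sigma2`, `df_residual`, `flagged`.
#' @export
tidy.de_fit <- function(x, ...) {
  x$table |>
    select("gene", "log_fold_change", "moderated_t", "p_value", "q_value",
           "direction", "sigma2", "posterior_sigma2", "df_residual",
           "flagged") |>
    arrange(.data$p_value)
}

#' One-row summary of a differential-expression fit
#'
#' @param x A `de_fit`.
#' @param ... Unused.
#' @return Tibble with gene/sample counts, the consensus correlation, the
#'   prior hyper-parameters and the higher/lower call counts.
#' @export
glance.de_fit <- function(x, ...) {
  tibble(n_genes = nrow(x$table),
         n_affected = x$n_affected,
         n_control = x$n_control,
         consensus_rho = x$consensus_rho,
         prior_d0 = x$prior$d0,
         prior_s0_sq = x$prior$s0_sq,
         n_higher = length(x$calls$higher),
         n_lower = length(x$calls$lower),
         alpha = x$alpha)
}
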