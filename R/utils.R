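# Internal helpers shared across modules.

# Stop with a classed condition so the pipeline driver can attribute the
# failure to a stage.
stop_imagetx <- function(msg, class = "imagetx_error", ...) {
  rlang::abort(msg, class = c(class, "imagetx_error"), ...)
}

# Invert the trigamma function by Newton iteration (monotone decreasing on
# (0, Inf)); used when matching moments of log sample variances to a scaled-F
# prior. Returns Inf for non-positive input (flat prior limit).
trigamma_inverse <- function(y) {
  vapply(y, function(yi) {
    if (!is.finite(yi) || yi <= 0) return(Inf)
    if (yi > 1e7) return(1 / sqrt(yi))
    if (yi < 1e-6) return(1 / yi)
    x <- 0.5 + 1 / yi
    for (i in 1:50) {
      tri <- trigamma(x)
      # Newton on 1/trigamma, which is nearly linear in x
      dif <- tri * (1 - tri / yi) / psigamma(x, deriv = 2L)
      x <- x + dif
      if (abs(dif) / x < 1e-10) break
    }
    x
  }, numeric(1))
}

# Validate a gene x sample numeric matrix with complete dimnames.
check_expression_matrix <- function(x, arg = "x") {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop_imagetx(sprintf("`%s` must be a numeric matrix", arg))
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop_imagetx(sprintf("`%s` must carry row and column names", arg))
  }
  if (anyNA(x) || any(!is.finite(x))) {
    stop_imagetx(sprintf("`%s` contains missing or non-finite values", arg))
  }
  invisible(x)
}

# rounds to nearest integer, half away from zero (deterministic bookkeeping)
round_half_up <- function(x) floor(x + 0.5)
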