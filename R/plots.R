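#' Volcano plot of a differential-expression fit
#'
#' @param object A `de_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.de_fit <- function(object, ...) {
  tab <- tidy(object) |>
    mutate(called = .data$q_value < object$alpha)
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$log_fold_change,
                                    y = -log10(.data$p_value),
                                    colour = .data$called)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick"),
                                 name = sprintf("q < %g", object$alpha)) +
    ggplot2::labs(x = "log fold change (affected - control)",
                  y = expression(-log[10] ~ p)) +
    ggplot2::theme_minimal()
}

#' Density plot of differential stability by DE group
#'
#' The numeric content of a DS density figure: one density per group
#' (`de_higher`, `de_lower`, `other`).
#'
#' @param ds A `ds_table` with a `group` column (see [label_ds_groups()]).
#' @return A ggplot.
#' @export
plot_ds_density <- function(ds) {
  if (!"group" %in% names(ds)) stop_imagetx("ds table lacks a group column")
  ggplot2::ggplot(ds, ggplot2::aes(x = .data$ds, fill = .data$group)) +
    ggplot2::geom_density(alpha = 0.4) +
    ggplot2::labs(x = "differential stability", y = "density") +
    ggplot2::theme_minimal()
}

#' Dot plot of gene-set enrichment results
#'
#' @param records Output of [adjust_enrichment()].
#' @return A ggplot.
#' @export
plot_enrichment <- function(records) {
  ggplot2::ggplot(records,
                  ggplot2::aes(x = .data$fold_enrichment,
                               y = stats::reorder(.data$set_name,
                                                  .data$fold_enrichment),
                               size = .data$overlap_k,
                               colour = -log10(.data$adjusted_p))) +
    ggplot2::geom_point() +
    ggplot2::scale_colour_viridis_c(name = expression(-log[10] ~ p[adj])) +
    ggplot2::labs(x = "fold enrichment", y = NULL, size = "overlap") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
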