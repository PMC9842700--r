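#' Configure an end-to-end pipeline run
#'
#' Collects every path and stage parameter for [run_pipeline()]. Parameters
#' are range-checked here; input files are checked by the stage that consumes
#' them, so a missing file aborts with the stage name attached.
#'
#' @param bundle_dirs Character vector of per-donor bundle directories.
#' @param mask_paths One or more NIfTI mask paths ("affected" regions);
#'   multiple masks combine by union (max).
#' @param marker_gmt Path to a GMT of cell-type marker sets.
#' @param cortical_labels Structure labels forming the cortical selection;
#'   `NULL` (default) accepts every structure label present.
#' @param min_fraction Detection-rate threshold (Step-2 filter).
#' @param rho_min RNA-seq concordance threshold (strict).
#' @param mask_threshold Inside-mask rule on interpolated values.
#' @param mirror Mirror sample x-coordinates before mask lookup (use when
#'   masks sit on the right hemisphere).
#' @param alpha DE significance threshold (strict, BH-adjusted).
#' @param min_marker_genes Marker-set inclusion threshold.
#' @param within_sample Run the within-sample SRS pass.
#' @param headered Bundles use headered matrix CSVs.
#' @param ds_table_path Optional external gene/DS TSV replacing the
#'   recomputed differential stability (cross-referencing mode).
#' @param seed Integer seed recorded in the report.
#' @param outdir Optional directory for persisted stage outputs.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(bundle_dirs, mask_paths, marker_gmt,
                            cortical_labels = NULL,
                            min_fraction = 0.5, rho_min = 0.2,
                            mask_threshold = 0.5, mirror = FALSE,
                            alpha = 0.05, min_marker_genes = 5,
                            within_sample = TRUE, headered = FALSE,
                            ds_table_path = NULL,
                            seed = 1L, outdir = NULL) {
  stopifnot(length(bundle_dirs) >= 1, length(mask_paths) >= 1)
  for (x in c(min_fraction, mask_threshold, alpha)) {
    if (x < 0 || x > 1) stop_imagetx("thresholds must lie in [0, 1]")
  }
  structure(list(bundle_dirs = bundle_dirs, mask_paths = mask_paths,
                 marker_gmt = marker_gmt,
                 cortical_labels = cortical_labels,
                 min_fraction = min_fraction, rho_min = rho_min,
                 mask_threshold = mask_threshold, mirror = mirror,
                 alpha = alpha, min_marker_genes = min_marker_genes,
                 within_sample = within_sample, headered = headered,
                 ds_table_path = ds_table_path,
                 seed = as.integer(seed), outdir = outdir),
            class = "pipeline_config")
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    rlang::abort(sprintf("stage %s failed: %s", stage, conditionMessage(e)),
                 class = "imagetx_stage_error")
  })
}

#' Run the full imaging-transcriptomics pipeline
#'
#' Executes, in order: bundle loading, probe selection, spatial mask
#' assignment, normalization, moderated differential expression,
#' differential stability, and marker-set enrichment. Every stage output can
#' be persisted to `config$outdir`; the returned report collects all counts
#' and summary statistics, and is deterministic given the same inputs and
#' configuration.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `pipeline_report`; persisted outputs (when
#'   `outdir` is set) include stage TSVs and a `report.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  t0 <- proc.time()[["elapsed"]]
  timings <- c()
  tick <- function(stage) {
    t1 <- proc.time()[["elapsed"]]
    timings[[stage]] <<- round(t1 - t0, 3)
    t0 <<- t1
  }

  bundle <- run_stage("io_formats", {
    bind_bundles(lapply(config$bundle_dirs, read_expression_bundle,
                        headered = config$headered))
  })
  if (is.null(bundle$rnaseq)) {
    stop_imagetx("stage probe_selection failed: no RNA-seq companion in any bundle")
  }
  tick("io_formats")

  sel <- run_stage("probe_selection", {
    select_probes(bundle$expression, bundle$detection, bundle$probes,
                  bundle$rnaseq, min_fraction = config$min_fraction,
                  rho_min = config$rho_min)
  })
  tick("probe_selection")

  assign <- run_stage("spatial_mapping", {
    missing <- config$mask_paths[!file.exists(config$mask_paths)]
    if (length(missing) > 0) {
      stop_imagetx(sprintf("mask file not found: %s", missing[1]))
    }
    masks <- lapply(config$mask_paths, read_mask)
    labels <- config$cortical_labels %||%
      unique(bundle$samples$structure_label)
    assign_samples(bundle$samples, masks, cortical_labels = labels,
                   threshold = config$mask_threshold,
                   mirror = config$mirror)
  })
  tick("spatial_mapping")

  analysed <- assign |> filter(.data$label != "excluded")
  X <- run_stage("normalization", {
    normalize_expression(
      sel$expression[, analysed$sample_id, drop = FALSE],
      batch = analysed$donor_id,
      within_sample = config$within_sample)
  })
  tick("normalization")

  de <- run_stage("diffexpr", {
    fit_differential_expression(X, analysed$label == "affected",
                                block = analysed$donor_id,
                                alpha = config$alpha)
  })
  tick("diffexpr")

  stab <- run_stage("stability", {
    ds <- if (!is.null(config$ds_table_path)) {
      ext <- readr::read_tsv(config$ds_table_path, show_col_types = FALSE,
                             progress = FALSE)
      if (!all(c("gene", "ds") %in% names(ext))) {
        stop_imagetx("external DS table needs columns gene, ds")
      }
      structure(as_tibble(ext[, c("gene", "ds")]),
                class = c("ds_table", class(as_tibble(ext))))
    } else {
      differential_stability(X, bundle$samples)
    }
    ds <- label_ds_groups(ds, de)
    de_ds <- ds$ds[ds$group != "other"]
    other_ds <- ds$ds[ds$group == "other"]
    cmp <- if (length(de_ds) > 0 && length(other_ds) > 0) {
      compare_ds(de_ds, other_ds)
    } else NULL
    list(table = ds, comparison = cmp)
  })
  tick("stability")

  enr <- run_stage("enrichment", {
    markers <- filter_marker_sets(read_gmt(config$marker_gmt),
                                  min_genes = config$min_marker_genes)
    query <- unique(c(de$calls$higher, de$calls$lower))
    background <- de$table$gene
    if (length(query) == 0) {
      inform("no DE genes called; marker enrichment skipped")
      NULL
    } else {
      hypergeom_enrich(query, markers, background) |>
        adjust_enrichment(method = "bonferroni", alpha = 0.05)
    }
  })
  tick("enrichment")

  report <- structure(list(
    n_samples_loaded = nrow(bundle$samples),
    n_probes_loaded = nrow(bundle$probes),
    n_genes_kept = nrow(sel$kept),
    probes_dropped = as.list(table(sel$dropped$reason)),
    sample_counts = assignment_counts(assign),
    n_affected = sum(assign$label == "affected"),
    n_control = sum(assign$label == "control"),
    n_excluded = sum(assign$label == "excluded"),
    de = glance(de),
    ds_comparison = stab$comparison,
    n_marker_sets_tested = if (is.null(enr)) 0L else nrow(enr),
    significant_marker_sets = if (is.null(enr)) character(0) else
      enr$set_name[enr$significant],
    config = config[setdiff(names(config), "outdir")],
    version = as.character(utils::packageVersion("imagetx"))),
    class = "pipeline_report")
  attr(report, "timings") <- timings

  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    out <- function(f) file.path(config$outdir, f)
    write_results_tsv(
      bind_rows(sel$kept |> mutate(reason = "kept") |>
                  rename(status = "reason"),
                sel$dropped |> rename(status = "reason") |>
                  mutate(rho = NA_real_) |>
                  select("gene_symbol", "probe_id", "rho", "status")),
      out("probe_selection.tsv"))
    write_results_tsv(assign, out("sample_assignment.tsv"))
    write_results_tsv(tidy(de), out("differential_expression.tsv"))
    write_results_tsv(stab$table, out("differential_stability.tsv"))
    if (!is.null(enr)) write_results_tsv(enr, out("marker_enrichment.tsv"))
    jsonlite::write_json(report_to_json(report), out("report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  report$results <- list(selection = sel, assignment = assign,
                         normalized = X, de = de, ds = stab$table,
                         enrichment = enr)
  report
}

# flatten the report for JSON, dropping the heavyweight results element
report_to_json <- function(report) {
  keep <- setdiff(names(report), "results")
  out <- unclass(report)[keep]
  out$config <- out$config[setdiff(names(out$config), "cortical_labels")]
  out$timings <- as.list(attr(report, "timings"))
  out
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("imaging-transcriptomics pipeline report\n")
  cat(sprintf("  samples: %d loaded; %d affected / %d control / %d excluded\n",
              x$n_samples_loaded, x$n_affected, x$n_control, x$n_excluded))
  cat(sprintf("  probes: %d loaded -> %d genes kept\n",
              x$n_probes_loaded, x$n_genes_kept))
  cat(sprintf("  DE: %d higher, %d lower (q < %g); consensus rho = %.4f; prior d0 = %.3g\n",
              x$de$n_higher, x$de$n_lower, x$de$alpha,
              x$de$consensus_rho, x$de$prior_d0))
  if (!is.null(x$ds_comparison)) {
    cat(sprintf("  DS medians: DE %.3f vs other %.3f (MWU p = %.3g)\n",
                x$ds_comparison$median_de, x$ds_comparison$median_other,
                x$ds_comparison$p_value))
  }
  cat(sprintf("  marker sets: %d tested, %d significant (bonferroni)\n",
              x$n_marker_sets_tested, length(x$significant_marker_sets)))
  if (length(x$significant_marker_sets) > 0) {
    cat("   ", paste(x$significant_marker_sets, collapse = ", "), "\n")
  }
  invisible(x)
}
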