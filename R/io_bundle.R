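#' Read a per-donor AHBA-dialect expression bundle
#'
#' Loads the four CSV files that make up one donor's microarray release in the
#' Allen Human Brain Atlas dialect: `Probes.csv` (probe annotation),
#' `SampleAnnot.csv` (per-sample donor, structure label, MNI world coordinate,
#' hemisphere), `MicroarrayExpression.csv` (log-intensity matrix) and
#' `PACall.csv` (binary detection calls). Expression and detection files
#' carry no header by default; their first column is the probe id and their
#' remaining columns follow the row order of `SampleAnnot.csv`. A companion
#' gene-level `RNAseq.csv` is loaded when present.
#'
#' All cross-table identifier constraints are validated at load time:
#' probe ids must agree between annotation, expression and detection, and the
#' number of expression columns must equal the number of annotated samples.
#' Expression values are treated as already log-scaled, matching the released
#' atlas files.
#'
#' @param dir_path Directory holding the four CSV files for one donor.
#' @param headered Logical; if `TRUE` the expression/detection CSVs carry a
#'   header row of sample ids (useful for hand-written fixtures). Default
#'   `FALSE`, the atlas dialect.
#'
#' @return A list of class `"expression_bundle"` with elements
#'   `probes` (tibble: `probe_id`, `gene_symbol`, `is_annotated`),
#'   `samples` (tibble: `sample_id`, `donor_id`, `structure_label`,
#'   `mni_x`, `mni_y`, `mni_z`, `hemisphere`),
#'   `expression` (probe x sample matrix), `detection` (binary matrix of the
#'   same shape) and `rnaseq` (gene x sample matrix or `NULL`).
#' @export
#' @examples
#' cfg <- simulation_config(n_donors = 2, samples_per_donor = 12,
#'                          n_genes = 30, seed = 1)
#' dir <- tempfile(); sim <- simulate_atlas(cfg, dir = dir)
#' b <- read_expression_bundle(file.path(dir, "donor_D1"))
#' dim(b$expression)
read_expression_bundle <- function(dir_path, headered = FALSE) {
  if (!dir.exists(dir_path)) {
    stop_imagetx(sprintf("bundle directory not found: %s", dir_path))
  }
  need <- c("Probes.csv", "SampleAnnot.csv",
            "MicroarrayExpression.csv", "PACall.csv")
  paths <- file.path(dir_path, need)
  missing <- need[!file.exists(paths)]
  if (length(missing) > 0) {
    stop_imagetx(sprintf("bundle file missing from %s: %s",
                         dir_path, paste(missing, collapse = ", ")))
  }

  probes <- readr::read_csv(paths[1], show_col_types = FALSE,
                            progress = FALSE)
  if (!all(c("probe_id", "gene_symbol") %in% names(probes))) {
    stop_imagetx("Probes.csv must have columns probe_id, gene_symbol")
  }
  probes <- probes |>
    mutate(probe_id = as.character(.data$probe_id),
           gene_symbol = as.character(.data$gene_symbol),
           gene_symbol = ifelse(is.na(.data$gene_symbol), "",
                                .data$gene_symbol),
           is_annotated = .data$gene_symbol != "") |>
    select("probe_id", "gene_symbol", "is_annotated")
  if (anyDuplicated(probes$probe_id)) {
    stop_imagetx(sprintf("duplicated probe_id in Probes.csv: %s",
                         probes$probe_id[duplicated(probes$probe_id)][1]))
  }

  samples <- readr::read_csv(paths[2], show_col_types = FALSE,
                             progress = FALSE)
  need_cols <- c("sample_id", "donor_id", "structure_label",
                 "mni_x", "mni_y", "mni_z", "hemisphere")
  if (!all(need_cols %in% names(samples))) {
    stop_imagetx(sprintf("SampleAnnot.csv lacks columns: %s",
                         paste(setdiff(need_cols, names(samples)),
                               collapse = ", ")))
  }
  samples <- samples |>
    mutate(across(c("sample_id", "donor_id", "structure_label",
                    "hemisphere"), as.character)) |>
    select(dplyr::all_of(need_cols))
  if (anyDuplicated(samples$sample_id)) {
    stop_imagetx(sprintf("duplicated sample_id in SampleAnnot.csv: %s",
                         samples$sample_id[duplicated(samples$sample_id)][1]))
  }
  if (anyNA(samples$mni_x) || anyNA(samples$mni_y) || anyNA(samples$mni_z) ||
      any(!is.finite(c(samples$mni_x, samples$mni_y, samples$mni_z)))) {
    stop_imagetx("SampleAnnot.csv has non-finite MNI coordinates")
  }

  expr <- read_id_matrix(paths[3], headered)
  det <- read_id_matrix(paths[4], headered)

  check_bundle_ids(expr, det, probes, samples, headered)
  colnames(expr) <- samples$sample_id
  colnames(det) <- samples$sample_id

  if (anyNA(expr) || any(!is.finite(expr))) {
    stop_imagetx("MicroarrayExpression.csv contains missing values")
  }
  if (!all(det %in% c(0, 1))) {
    stop_imagetx("PACall.csv must contain only 0/1 detection calls")
  }

  rnaseq_path <- file.path(dir_path, "RNAseq.csv")
  rnaseq <- NULL
  if (file.exists(rnaseq_path)) {
    rnaseq <- read_rnaseq(rnaseq_path)
    bad <- setdiff(colnames(rnaseq), samples$sample_id)
    if (length(bad) > 0) {
      stop_imagetx(sprintf("RNAseq.csv sample not in annotation: %s", bad[1]))
    }
  }

  structure(list(probes = probes, samples = samples, expression = expr,
                 detection = det, rnaseq = rnaseq),
            class = "expression_bundle")
}

# shared loader for the headerless id-first-column matrix dialect
read_id_matrix <- function(path, headered) {
  if (headered) {
    tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  } else {
    tab <- readr::read_csv(path, col_names = FALSE, show_col_types = FALSE,
                           progress = FALSE)
  }
  if (ncol(tab) < 2) {
    stop_imagetx(sprintf("%s has no sample columns", basename(path)))
  }
  ids <- as.character(tab[[1]])
  m <- as.matrix(tab[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- ids
  if (!headered) colnames(m) <- NULL
  m
}

check_bundle_ids <- function(expr, det, probes, samples, headered) {
  if (!identical(rownames(expr), probes$probe_id)) {
    off <- setdiff(rownames(expr), probes$probe_id)
    if (length(off) == 0) off <- setdiff(probes$probe_id, rownames(expr))
    if (length(off) == 0) off <- "(ordering differs)"
    stop_imagetx(sprintf(
      "probe ids disagree between MicroarrayExpression.csv and Probes.csv; first offender: %s",
      off[1]))
  }
  if (!identical(rownames(det), rownames(expr))) {
    stop_imagetx("probe ids disagree between PACall.csv and MicroarrayExpression.csv")
  }
  if (headered) {
    off <- setdiff(colnames(expr), samples$sample_id)
    if (length(off) > 0) {
      stop_imagetx(sprintf(
        "expression sample absent from SampleAnnot.csv: %s", off[1]))
    }
    off <- setdiff(samples$sample_id, colnames(expr))
    if (length(off) > 0) {
      stop_imagetx(sprintf(
        "annotated sample absent from expression: %s", off[1]))
    }
  } else if (ncol(expr) != nrow(samples)) {
    stop_imagetx(sprintf(
      "MicroarrayExpression.csv has %d sample columns but SampleAnnot.csv annotates %d samples",
      ncol(expr), nrow(samples)))
  }
  if (ncol(det) != ncol(expr)) {
    stop_imagetx("PACall.csv and MicroarrayExpression.csv column counts differ")
  }
  invisible(TRUE)
}

#' Read a gene-level RNA-seq companion table
#'
#' Headered CSV, first column `gene_symbol`, remaining columns named by
#' sample id.
#'
#' @param path CSV file path.
#' @return gene x sample numeric matrix.
#' @export
read_rnaseq <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (names(tab)[1] != "gene_symbol") {
    stop_imagetx("RNAseq.csv first column must be gene_symbol")
  }
  m <- as.matrix(tab[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- as.character(tab[[1]])
  if (anyDuplicated(rownames(m))) {
    stop_imagetx("duplicated gene_symbol in RNAseq.csv")
  }
  m
}

#' Concatenate several donor bundles into one cohort
#'
#' Checks that all bundles share the same probe annotation, then binds the
#' sample tables and expression/detection columns. RNA-seq matrices (present
#' for a subset of donors) are likewise concatenated.
#'
#' @param bundles List of `expression_bundle` objects.
#' @return A single `expression_bundle` covering all donors.
#' @export
bind_bundles <- function(bundles) {
  if (length(bundles) == 0) stop_imagetx("no bundles supplied")
  ref <- bundles[[1]]$probes
  for (b in bundles[-1]) {
    if (!identical(b$probes$probe_id, ref$probe_id)) {
      stop_imagetx("bundles disagree on probe annotation; cannot concatenate")
    }
  }
  samples <- bind_rows(lapply(bundles, `[[`, "samples"))
  if (anyDuplicated(samples$sample_id)) {
    stop_imagetx(sprintf("duplicated sample_id across bundles: %s",
                         samples$sample_id[duplicated(samples$sample_id)][1]))
  }
  expr <- do.call(cbind, lapply(bundles, `[[`, "expression"))
  det <- do.call(cbind, lapply(bundles, `[[`, "detection"))
  rna <- Filter(Negate(is.null), lapply(bundles, `[[`, "rnaseq"))
  rnaseq <- if (length(rna) > 0) do.call(cbind, rna) else NULL
  structure(list(probes = ref, samples = samples, expression = expr,
                 detection = det, rnaseq = rnaseq),
            class = "expression_bundle")
}

#' Write a per-donor bundle in the AHBA CSV dialect
#'
#' Inverse of [read_expression_bundle()]; used by the synthetic atlas
#' generator and useful for building small fixtures.
#'
#' @param bundle An `expression_bundle` (single donor).
#' @param dir_path Output directory (created if needed).
#' @param headered Write sample-id headers on the matrix CSVs.
#' @return `dir_path`, invisibly.
#' @export
write_expression_bundle <- function(bundle, dir_path, headered = FALSE) {
  dir.create(dir_path, recursive = TRUE, showWarnings = FALSE)
  probes_out <- bundle$probes |> select("probe_id", "gene_symbol")
  readr::write_csv(probes_out, file.path(dir_path, "Probes.csv"),
                   progress = FALSE)
  readr::write_csv(bundle$samples, file.path(dir_path, "SampleAnnot.csv"),
                   progress = FALSE)
  write_id_matrix(bundle$expression,
                  file.path(dir_path, "MicroarrayExpression.csv"), headered)
  write_id_matrix(bundle$detection, file.path(dir_path, "PACall.csv"),
                  headered)
  if (!is.null(bundle$rnaseq)) {
    out <- tibble(gene_symbol = rownames(bundle$rnaseq)) |>
      dplyr::bind_cols(as_tibble(bundle$rnaseq))
    readr::write_csv(out, file.path(dir_path, "RNAseq.csv"), progress = FALSE)
  }
  invisible(dir_path)
}

write_id_matrix <- function(m, path, headered = FALSE) {
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (headered) {
    names(df) <- c("probe_id", colnames(m))
    readr::write_csv(df, path, progress = FALSE)
  } else {
    readr::write_csv(df, path, col_names = FALSE, progress = FALSE)
  }
  invisible(path)
}
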