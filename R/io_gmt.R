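#' Read a GMT gene-set collection
#'
#' Standard tab-separated GMT: one set per line, fields
#' `name<TAB>description<TAB>member1<TAB>member2...`. Member symbols are
#' case-sensitive strings; duplicates within a set are collapsed.
#'
#' @param path GMT file path.
#' @return A tibble of class `gene_sets` with columns `set_name`,
#'   `description` and a list-column `genes`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop_imagetx(sprintf("GMT file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(gene_sets(character(), character(), list()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, integer(1)) < 3)
  if (length(bad) > 0) {
    stop_imagetx(sprintf("GMT line %d has fewer than 3 tab-separated fields",
                         bad[1]))
  }
  nm <- vapply(fields, `[[`, character(1), 1)
  desc <- vapply(fields, `[[`, character(1), 2)
  genes <- lapply(fields, function(f) unique(f[-(1:2)][nzchar(f[-(1:2)])]))
  empty <- which(vapply(genes, length, integer(1)) == 0)
  if (length(empty) > 0) {
    stop_imagetx(sprintf("GMT line %d defines an empty gene set (%s)",
                         empty[1], nm[empty[1]]))
  }
  gene_sets(nm, desc, genes)
}

#' Construct a gene-set collection
#'
#' @param set_name Character vector of unique set names.
#' @param description Character vector of descriptions (recycled if length 1).
#' @param genes List of character vectors of member gene symbols.
#' @return A `gene_sets` tibble.
#' @export
gene_sets <- function(set_name, description = "", genes = list()) {
  if (length(description) == 1) description <- rep(description,
                                                   length(set_name))
  stopifnot(length(set_name) == length(genes),
            length(set_name) == length(description))
  if (anyDuplicated(set_name)) {
    stop_imagetx("duplicated set_name in gene set collection")
  }
  out <- tibble(set_name = as.character(set_name),
                description = as.character(description),
                genes = lapply(genes, function(g) unique(as.character(g))))
  class(out) <- c("gene_sets", class(out))
  out
}

#' Write a gene-set collection to GMT
#'
#' @param sets A `gene_sets` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- purrr::pmap_chr(
    list(sets$set_name, sets$description, sets$genes),
    function(nm, d, g) paste(c(nm, d, g), collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}
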