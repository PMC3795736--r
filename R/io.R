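#' Read / write the pipeline's plain-text formats
#'
#' Expression TSV: genes in rows, samples in columns, header row of sample
#' ids, first column `gene_id`. Labels TSV: `sample_id<TAB>phenotype`. GMT:
#' one gene set per line, `name<TAB>description<TAB>gene...`. Probe map TSV:
#' `probe_id<TAB>gene_id`, one row per mapping.
#'
#' @param m Expression matrix; `path` a file path.
#' @param layer Layer tag to attach on read.
#' @name dirac_io
NULL

#' @rdname dirac_io
#' @export
write_expression_tsv <- function(m, path) {
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname dirac_io
#' @export
read_expression_tsv <- function(path, layer = c("intensity", "rank")) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  expression_matrix(m, layer = match.arg(layer))
}

#' @rdname dirac_io
#' @param labels Named factor from [phenotype_labels()].
#' @export
write_labels_tsv <- function(labels, path) {
  utils::write.table(
    data.frame(sample_id = names(labels), phenotype = as.character(labels)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname dirac_io
#' @param phenotype_levels Ordered phenotype universe for the read labels.
#' @export
read_labels_tsv <- function(path,
                            phenotype_levels = c("Normal", "G2", "G3", "pGBM", "sGBM")) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  phenotype_labels(df$phenotype, phenotype_levels = phenotype_levels,
                   sample_ids = df$sample_id)
}

#' @rdname dirac_io
#' @param sets Named list of gene-id vectors.
#' @param descriptions Optional per-set description column.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname dirac_io
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3
  if (any(bad)) stop("malformed GMT line(s): ", paste(which(bad), collapse = ", "))
  sets <- lapply(parts, function(x) x[-(1:2)])
  names(sets) <- vapply(parts, `[`, character(1), 1)
  if (anyDuplicated(names(sets))) stop("duplicate gene-set names in GMT")
  structure(sets, class = "gene_set_collection")
}

#' @rdname dirac_io
#' @param probes A [probe_layer()]; `dir` an output directory.
#' @export
write_probe_layer <- function(probes, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(probes$map, file.path(dir, "probe_map.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  int <- data.frame(probe_id = rownames(probes$intensity), probes$intensity,
                    check.names = FALSE)
  utils::write.table(int, file.path(dir, "probe_intensity.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  calls <- data.frame(probe_id = rownames(probes$calls), probes$calls * 1L,
                      check.names = FALSE)
  utils::write.table(calls, file.path(dir, "probe_calls.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname dirac_io
#' @export
read_probe_layer <- function(dir) {
  map <- utils::read.delim(file.path(dir, "probe_map.tsv"),
                           stringsAsFactors = FALSE)
  names(map) <- c("probe", "gene")
  rd <- function(f) {
    df <- utils::read.delim(file.path(dir, f), check.names = FALSE,
                            stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
    m
  }
  probe_layer(map, rd("probe_intensity.tsv"), rd("probe_calls.tsv") > 0)
}

#' @rdname dirac_io
#' @param truth Ground-truth record from [generate_cohort()].
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname dirac_io
#' @export
read_truth_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
}

#' Write a full synthetic cohort to a directory
#'
#' Emits `expression.tsv`, `labels.tsv`, `networks.gmt`, `truth.json`, and
#' the probe-layer TSVs under `probes/`.
#'
#' @param cohort Result of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression_tsv(cohort$expr, file.path(dir, "expression.tsv"))
  write_labels_tsv(cohort$labels, file.path(dir, "labels.tsv"))
  write_gmt(cohort$networks, file.path(dir, "networks.gmt"))
  write_truth_json(cohort$truth, file.path(dir, "truth.json"))
  write_probe_layer(cohort$probes, file.path(dir, "probes"))
  invisible(dir)
}
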