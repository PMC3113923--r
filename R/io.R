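# Readers and writers for the flat-file formats the pipeline touches:
# GenomeStudio-style sample probe profiles, GEO series matrices, result
# tables (one row per differentially expressed probe), qPCR Ct tables and
# sample-design tables. Array files are tab-delimited, qPCR and design files
# comma-delimited; encoding UTF-8 throughout.

RESULT_COLUMNS <- c("probe_id",
                    "p_ND_D", "p_ND_DI", "p_D_DI",
                    "fc_ND_D", "fc_ND_DI", "fc_D_DI",
                    "gene_symbol", "entrez_id", "gene_name")

ANNOTATION_ALIASES <- c(probe_id = "ProbeID", gene_symbol = "SYMBOL",
                        entrez_id = "ENTREZ_GENE_ID", gene_name = "DEFINITION")

#' Read a probe-profile expression file
#'
#' Two dialects are supported. `genomestudio_flat` is the tab-delimited
#' sample probe profile exported by Illumina GenomeStudio: a `ProbeID`
#' column, optional annotation columns (`SYMBOL`, `ENTREZ_GENE_ID`,
#' `DEFINITION`), and per sample a paired `AVG_Signal.<sample>` and
#' `Detection Pval.<sample>` column. `geo_series_matrix` is the GEO series
#' matrix format (`!`-prefixed header lines, the expression block between
#' `!series_matrix_table_begin` and `!series_matrix_table_end`); series
#' matrices carry no detection p-values and are typically deposited after
#' normalization, so the returned object has `detection = NULL` and
#' `normalized = TRUE`.
#'
#' @param path Path to the file.
#' @param dialect `"genomestudio_flat"` or `"geo_series_matrix"`.
#' @return An [expression_matrix()].
#' @export
read_probe_profile <- function(path,
                               dialect = c("genomestudio_flat",
                                           "geo_series_matrix")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(dialect,
         genomestudio_flat = read_genomestudio_flat(path),
         geo_series_matrix = read_geo_series_matrix(path))
}

read_genomestudio_flat <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  cols <- names(tab)
  if (!"ProbeID" %in% cols)
    stop("format error: missing required column 'ProbeID'")
  sig_cols <- grep("^AVG_Signal\\.", cols, value = TRUE)
  det_cols <- grep("^Detection Pval\\.", cols, value = TRUE)
  if (!length(sig_cols))
    stop("format error: no 'AVG_Signal.<sample>' columns found")
  sig_samples <- sub("^AVG_Signal\\.", "", sig_cols)
  det_samples <- sub("^Detection Pval\\.", "", det_cols)
  miss_det <- setdiff(sig_samples, det_samples)
  if (length(miss_det))
    stop("format error: missing column 'Detection Pval.", miss_det[1L], "'")
  miss_sig <- setdiff(det_samples, sig_samples)
  if (length(miss_sig))
    stop("format error: missing column 'AVG_Signal.", miss_sig[1L], "'")
  probe_id <- as.character(tab$ProbeID)
  if (anyDuplicated(probe_id))
    stop("integrity error: duplicate ProbeID in ", path)
  signal <- as.matrix(tab[, paste0("AVG_Signal.", sig_samples), drop = FALSE])
  detection <- as.matrix(tab[, paste0("Detection Pval.", sig_samples),
                             drop = FALSE])
  dimnames(signal) <- dimnames(detection) <- list(probe_id, sig_samples)
  ann <- data.frame(probe_id = probe_id, stringsAsFactors = FALSE)
  for (field in names(ANNOTATION_ALIASES)[-1L]) {
    alias <- ANNOTATION_ALIASES[[field]]
    if (alias %in% cols) ann[[field]] <- as.character(tab[[alias]])
  }
  expression_matrix(signal, detection, ann, normalized = FALSE)
}

read_geo_series_matrix <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  begin <- grep("^!series_matrix_table_begin", lines)
  end <- grep("^!series_matrix_table_end", lines)
  if (length(begin) != 1L || length(end) != 1L || end <= begin + 1L)
    stop("format error: series_matrix_table_begin/end block not found")
  block <- lines[(begin + 1L):(end - 1L)]
  tab <- utils::read.delim(text = block, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (names(tab)[1L] != "ID_REF")
    stop("format error: series matrix table must start with 'ID_REF'")
  probe_id <- as.character(tab$ID_REF)
  if (anyDuplicated(probe_id))
    stop("integrity error: duplicate ID_REF in ", path)
  signal <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(signal) <- probe_id
  # detection p-values are absent from this dialect: recorded as absent,
  # never imputed as 0; values assumed already normalized (provenance flag).
  expression_matrix(signal, detection = NULL,
                    annotation = data.frame(probe_id = probe_id,
                                            stringsAsFactors = FALSE),
                    normalized = TRUE)
}

#' Write an ExpressionMatrix as a GenomeStudio-style probe profile
#'
#' @param em An [expression_matrix()] with a detection layer.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_probe_profile <- function(em, path) {
  if (is.null(em$detection))
    stop("integrity error: cannot write genomestudio_flat without detection p-values")
  out <- data.frame(ProbeID = rownames(em$signal), stringsAsFactors = FALSE)
  for (field in names(ANNOTATION_ALIASES)[-1L]) {
    if (field %in% names(em$annotation))
      out[[ANNOTATION_ALIASES[[field]]]] <- em$annotation[[field]]
  }
  for (s in colnames(em$signal)) {
    out[[paste0("AVG_Signal.", s)]] <- em$signal[, s]
    out[[paste0("Detection Pval.", s)]] <- em$detection[, s]
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Write differential-expression result rows
#'
#' Writes the per-probe result table: probe id, the p-value for each of the
#' three pairwise comparisons, the signed fold change (direction of
#' regulation) for each comparison, then gene symbol, Entrez id and gene
#' name. Downregulation is written as a negative reciprocal (`-2` means
#' halved). By default one file is written per response category (mirroring
#' the four per-category supplementary tables of this kind of study);
#' `split = FALSE` writes a single file with an extra `category` column.
#'
#' @param rows `data.frame` containing the columns in `RESULT_COLUMNS` plus
#'   `category`.
#' @param path Output directory (when `split = TRUE`) or file path.
#' @param split Write one file per category?
#' @return Character vector of the paths written, invisibly.
#' @export
write_result_rows <- function(rows, path, split = TRUE) {
  if (!nrow(rows)) stop("`rows` must be non-empty")
  for (f in c("gene_symbol", "entrez_id", "gene_name"))
    if (!f %in% names(rows)) rows[[f]] <- NA_character_
  missing_cols <- setdiff(c(RESULT_COLUMNS, "category"), names(rows))
  if (length(missing_cols))
    stop("`rows` is missing columns: ", paste(missing_cols, collapse = ", "))
  if (split) {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    paths <- character(0)
    for (cat in unique(as.character(rows$category))) {
      sub <- rows[rows$category == cat, RESULT_COLUMNS, drop = FALSE]
      p <- file.path(path, paste0(cat, "_probes.tsv"))
      utils::write.table(sub, p, sep = "\t", quote = FALSE,
                         row.names = FALSE, fileEncoding = "UTF-8")
      paths <- c(paths, p)
    }
    invisible(paths)
  } else {
    utils::write.table(rows[, c(RESULT_COLUMNS, "category"), drop = FALSE],
                       path, sep = "\t", quote = FALSE, row.names = FALSE,
                       fileEncoding = "UTF-8")
    invisible(path)
  }
}

#' Read a result-row table written by [write_result_rows()]
#'
#' @param path Path to one result TSV.
#' @param category Category label to attach when the file has no `category`
#'   column (the per-category split layout).
#' @return `data.frame` of result rows.
#' @export
read_result_rows <- function(path, category = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(probe_id = "character",
                                          gene_symbol = "character",
                                          entrez_id = "character",
                                          gene_name = "character"))
  missing_cols <- setdiff(RESULT_COLUMNS, names(tab))
  if (length(missing_cols))
    stop("format error: result table missing columns: ",
         paste(missing_cols, collapse = ", "))
  if (!"category" %in% names(tab)) {
    if (is.null(category))
      stop("file has no category column; supply `category`")
    tab$category <- category
  }
  tab
}

#' Read a qPCR Ct table
#'
#' Expects a CSV with columns `sample_id`, `gene`, `ct`,
#' `is_endogenous_control`. Every sample must carry a Ct for the single
#' endogenous-control gene (the reference the ddCt method divides out).
#'
#' @param path CSV path.
#' @return `data.frame` of Ct records.
#' @export
read_qpcr_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "gene", "ct", "is_endogenous_control")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols))
    stop("format error: qPCR table missing columns: ",
         paste(missing_cols, collapse = ", "))
  tab$sample_id <- as.character(tab$sample_id)
  tab$gene <- as.character(tab$gene)
  tab$ct <- as.numeric(tab$ct)
  tab$is_endogenous_control <- as.logical(tab$is_endogenous_control)
  if (any(!is.finite(tab$ct)))
    stop("integrity error: non-finite Ct values")
  validate_qpcr_records(tab)
  tab
}

validate_qpcr_records <- function(records) {
  ctrl <- unique(records$gene[records$is_endogenous_control])
  if (length(ctrl) == 0L)
    stop("integrity error: no endogenous-control rows in qPCR table")
  if (length(ctrl) > 1L)
    stop("integrity error: multiple endogenous-control genes: ",
         paste(ctrl, collapse = ", "))
  has_ctrl <- unique(records$sample_id[records$is_endogenous_control])
  miss <- setdiff(unique(records$sample_id), has_ctrl)
  if (length(miss))
    stop("integrity error: samples lacking a control-gene Ct: ",
         paste(miss, collapse = ", "))
  invisible(ctrl)
}

#' @rdname read_qpcr_table
#' @param records qPCR record `data.frame` to write.
#' @export
write_qpcr_table <- function(records, path) {
  utils::write.csv(
    records[, c("sample_id", "gene", "ct", "is_endogenous_control")],
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a sample-design table
#'
#' CSV with columns `sample_id`, `group` (ND/D/DI), `timepoint` (M1/M3).
#'
#' @param path CSV path.
#' @return `data.frame` as returned by [sample_design()].
#' @export
read_sample_design <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "group", "timepoint")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols))
    stop("format error: design table missing columns: ",
         paste(missing_cols, collapse = ", "))
  sample_design(tab$sample_id, tab$group, tab$timepoint)
}

#' @rdname read_sample_design
#' @param design Design `data.frame` to write.
#' @export
write_sample_design <- function(design, path) {
  utils::write.csv(design, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
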