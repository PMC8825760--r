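# File I/O: expression matrices (dense CSV/TSV, Matrix Market triplet with
# barcode/feature sidecars), pseudotime CSVs and JSON run reports.

new_expression <- function(values, cell_ids, gene_ids) {
  if (anyDuplicated(cell_ids)) ps_stop("duplicate cell ids", "ps_invalid_input")
  if (anyDuplicated(gene_ids)) ps_stop("duplicate gene ids", "ps_invalid_input")
  values <- check_matrix(values, what = "expression")
  if (nrow(values) != length(cell_ids) || ncol(values) != length(gene_ids)) {
    ps_stop("expression dimensions do not match id lists", "ps_invalid_input")
  }
  if (any(values < 0)) {
    ps_stop("expression values must be non-negative (normalized counts expected)",
            "ps_invalid_input")
  }
  dimnames(values) <- list(cell_ids, gene_ids)
  structure(list(values = values, cell_ids = as.character(cell_ids),
                 gene_ids = as.character(gene_ids)),
            class = "ps_expression")
}

#' @export
print.ps_expression <- function(x, ...) {
  cat("Expression matrix:", length(x$cell_ids), "cells x",
      length(x$gene_ids), "genes\n")
  invisible(x)
}

#' Read a normalized expression matrix
#'
#' Dense `csv`/`tsv`: first column holds cell ids, the header row holds
#' gene ids. Sparse `mtx`: a Matrix Market triplet file in the usual
#' genes x cells orientation (transposed on load) with `barcodes.tsv` and
#' `features.tsv` sidecars next to it (override with `barcodes`/`features`).
#' Input is validated: unique ids, finite non-negative values, dimensions
#' consistent with the id lists.
#'
#' @param path path to the matrix file.
#' @param format `"csv"`, `"tsv"` or `"mtx"`.
#' @param barcodes,features optional sidecar paths for `mtx` input.
#' @return a `ps_expression`: `values` (cells x genes), `cell_ids`,
#'   `gene_ids`.
#' @export
read_expression <- function(path, format = c("csv", "tsv", "mtx"),
                            barcodes = NULL, features = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) ps_stop(sprintf("file not found: %s", path), "ps_invalid_input")

  if (format %in% c("csv", "tsv")) {
    dt <- data.table::fread(path, sep = if (format == "csv") "," else "\t",
                            header = TRUE, data.table = FALSE)
    if (ncol(dt) < 2L) ps_stop("expected a cell-id column plus gene columns", "ps_invalid_input")
    cell_ids <- as.character(dt[[1L]])
    vals <- as.matrix(dt[, -1L, drop = FALSE])
    if (!is.numeric(vals)) ps_stop("non-numeric expression entries", "ps_invalid_input")
    return(new_expression(vals, cell_ids, colnames(dt)[-1L]))
  }

  m <- tryCatch(Matrix::readMM(path),
                error = function(e) ps_stop(sprintf("malformed MTX file: %s",
                                                    conditionMessage(e)),
                                            "ps_invalid_input"))
  dir <- dirname(path)
  if (is.null(barcodes)) barcodes <- file.path(dir, "barcodes.tsv")
  if (is.null(features)) features <- file.path(dir, "features.tsv")
  for (f in c(barcodes, features)) {
    if (!file.exists(f)) ps_stop(sprintf("missing sidecar file: %s", f), "ps_invalid_input")
  }
  bc <- data.table::fread(barcodes, header = FALSE, data.table = FALSE)[[1L]]
  ft <- data.table::fread(features, header = FALSE, data.table = FALSE)[[1L]]
  if (nrow(m) != length(ft) || ncol(m) != length(bc)) {
    ps_stop(sprintf("MTX dimensions %d x %d do not match %d features / %d barcodes",
                    nrow(m), ncol(m), length(ft), length(bc)), "ps_invalid_input")
  }
  new_expression(as.matrix(Matrix::t(m)), bc, ft)
}

#' Write a pseudotime to CSV
#'
#' Two columns, `cell_id,pseudotime`, in input cell order, full double
#' precision; ids containing commas or quotes are quoted per CSV
#' convention.
#'
#' @param p numeric pseudotime vector, or a `ps_run`.
#' @param cell_ids character vector, same length as `p`.
#' @param path output file path.
#' @export
write_pseudotime <- function(p, cell_ids, path) {
  if (inherits(p, "ps_run")) p <- p$pseudotime
  if (length(p) != length(cell_ids)) {
    ps_stop("pseudotime and cell_ids lengths differ", "ps_invalid_input")
  }
  df <- data.frame(cell_id = as.character(cell_ids),
                   pseudotime = format(p, digits = 17, trim = TRUE,
                                       scientific = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = 1L)
  invisible(path)
}

#' Read a pseudotime CSV written by [write_pseudotime()]
#'
#' @param path input file path.
#' @return data.frame with `cell_id` and numeric `pseudotime`.
#' @export
read_pseudotime <- function(path) {
  if (!file.exists(path)) ps_stop(sprintf("file not found: %s", path), "ps_invalid_input")
  df <- utils::read.csv(path, colClasses = c("character", "numeric"))
  if (!identical(names(df), c("cell_id", "pseudotime"))) {
    ps_stop("expected columns cell_id,pseudotime", "ps_invalid_input")
  }
  df
}

#' Write a pipeline run report as JSON
#'
#' Serialises the provenance record of a [shape_pseudotime()] run (k values
#' computed and skipped, columns selected, fallback flag, parameters).
#'
#' @param run a `ps_run`.
#' @param path output file path.
#' @export
write_run_report <- function(run, path) {
  if (!inherits(run, "ps_run")) ps_stop("expected a ps_run object", "ps_invalid_input")
  jsonlite::write_json(run$report, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
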