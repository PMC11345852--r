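#' Write a screen to MTX + TSV sidecars
#'
#' Counts go to `matrix.mtx` (Matrix Market), gene annotation to
#' `genes.tsv` (id, symbol, mito, ribo), cell annotation to `cells.tsv`
#' (cell id, variant call, n_barcodes, replicate, condition); an optional
#' truth record is serialised to `truth.json`.
#'
#' @param screen `SingleCellExperiment` with assay `counts`.
#' @param dir output directory (created if missing).
#' @param truth optional truth list from [simulate_screen()].
#' @return `dir`, invisibly.
#' @export
write_screen <- function(screen, dir, truth = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(SummarizedExperiment::assay(screen, "counts"),
                  file.path(dir, "matrix.mtx"))
  rd <- as.data.frame(SummarizedExperiment::rowData(screen))
  utils::write.table(rd, file.path(dir, "genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cd <- as.data.frame(SummarizedExperiment::colData(screen))
  utils::write.table(cd, file.path(dir, "cells.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(truth)) {
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Read a screen from MTX + TSV sidecars
#'
#' @param dir directory written by [write_screen()].
#' @return `SingleCellExperiment` (plus a `truth` entry in its metadata if
#'   `truth.json` is present).
#' @export
read_screen <- function(dir) {
  counts <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")),
                        "CsparseMatrix")
  rd <- utils::read.table(file.path(dir, "genes.tsv"), sep = "\t",
                          header = TRUE, stringsAsFactors = FALSE)
  cd <- utils::read.table(file.path(dir, "cells.tsv"), sep = "\t",
                          header = TRUE, stringsAsFactors = FALSE)
  dimnames(counts) <- list(rd$gene_id, cd$cell_id)
  screen <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = counts),
    rowData = S4Vectors::DataFrame(rd, row.names = rd$gene_id),
    colData = S4Vectors::DataFrame(cd, row.names = cd$cell_id))
  tj <- file.path(dir, "truth.json")
  if (file.exists(tj)) {
    S4Vectors::metadata(screen)$truth <- jsonlite::read_json(
      tj, simplifyVector = TRUE)
  }
  screen
}

#' Write / read a barcode timecourse table
#'
#' Long TSV with columns `variant`, `replicate`, `day`, `count`.
#'
#' @param bc data.frame from [simulate_barcode_timecourse()].
#' @param path TSV path.
#' @return `path` invisibly (write) or the data.frame (read).
#' @export
write_timecourse <- function(bc, path) {
  utils::write.table(bc, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_timecourse
#' @export
read_timecourse <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}
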