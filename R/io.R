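# Reading and writing the CellRanger-style count-matrix triple and the
# small TSV/CSV side tables used across the pipeline.

#' Write a count matrix as Matrix Market plus features/barcodes TSVs
#'
#' @param sim Output of [simulate_lobule()], or any list with `counts`,
#'   `genes` and `nuclei` in the same shape.
#' @param dir Output directory (created if needed). Writes `matrix.mtx`,
#'   `features.tsv` (gene, class, mito) and `barcodes.tsv`
#'   (nucleus, genotype).
#' @return `dir`, invisibly.
#' @export
write_counts_mtx <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(methods::as(sim$counts, "CsparseMatrix"),
                  file.path(dir, "matrix.mtx"))
  utils::write.table(sim$genes, file.path(dir, "features.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$nuclei, file.path(dir, "barcodes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a count matrix written by [write_counts_mtx()]
#'
#' @param dir Directory holding `matrix.mtx`, `features.tsv`,
#'   `barcodes.tsv`.
#' @return List with `counts` (genes x nuclei sparse matrix with
#'   dimnames), `genes`, `nuclei`.
#' @export
read_counts_mtx <- function(dir) {
  counts <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  genes <- utils::read.delim(file.path(dir, "features.tsv"),
                             stringsAsFactors = FALSE)
  nuclei <- utils::read.delim(file.path(dir, "barcodes.tsv"),
                              stringsAsFactors = FALSE)
  if (anyDuplicated(genes$gene)) stop("duplicate gene IDs in features.tsv")
  if (anyDuplicated(nuclei$nucleus))
    stop("duplicate nucleus IDs in barcodes.tsv")
  dimnames(counts) <- list(genes$gene, nuclei$nucleus)
  list(counts = methods::as(counts, "CsparseMatrix"),
       genes = genes, nuclei = nuclei)
}

#' Read pericentral/periportal marker sets from a two-column TSV
#'
#' @param path TSV with columns `gene` and `set`; `set` values must be
#'   `pericentral` or `periportal`.
#' @return List with character vectors `pericentral` and `periportal`.
#' @export
read_marker_sets <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("gene", "set") %in% names(tab)))
  bad <- setdiff(unique(tab$set), c("pericentral", "periportal"))
  if (length(bad)) stop("unknown marker set label(s): ",
                        paste(bad, collapse = ", "))
  list(pericentral = tab$gene[tab$set == "pericentral"],
       periportal = tab$gene[tab$set == "periportal"])
}
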