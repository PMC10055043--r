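#' Read / write a count matrix directory (MTX triplet convention)
#'
#' A directory holding \code{matrix.mtx} (genes x cells, MatrixMarket
#' triplet), \code{features.tsv} (gene_id, is_OR, zone, is_mito),
#' \code{barcodes.tsv} (cell ids) and \code{cells.tsv} (cell metadata).
#'
#' @param m a [zonal_count_matrix()]
#' @param dir directory path (created if needed)
#' @return \code{read_counts_dir} returns a \code{zonal_count_matrix}
#' @export
write_counts_dir <- function(m, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(m$counts, file.path(dir, "matrix.mtx"))
  utils::write.table(m$gene_meta, file.path(dir, "features.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(m$cell_meta$cell_id, file.path(dir, "barcodes.tsv"))
  utils::write.table(m$cell_meta, file.path(dir, "cells.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname write_counts_dir
#' @export
read_counts_dir <- function(dir) {
  counts <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")),
                        "CsparseMatrix")
  gene_meta <- utils::read.table(file.path(dir, "features.tsv"),
                                 header = TRUE, sep = "\t",
                                 stringsAsFactors = FALSE)
  cell_meta <- utils::read.table(file.path(dir, "cells.tsv"),
                                 header = TRUE, sep = "\t",
                                 stringsAsFactors = FALSE)
  dimnames(counts) <- list(gene_meta$gene_id, cell_meta$cell_id)
  zonal_count_matrix(counts, cell_meta, gene_meta)
}
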