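#' Read a labeled count matrix from disk
#'
#' Two on-disk layouts are supported:
#' \describe{
#'   \item{`mtx`}{a directory with `matrix.mtx` (MatrixMarket, cells in rows),
#'     `genes.tsv` (one gene id per line) and `cells.tsv` (tab-delimited with
#'     header `cell_id`, `cell_type`, `modality`, `donor`).}
#'   \item{`dense`}{a single tab-delimited table whose first four columns are
#'     `cell_id`, `cell_type`, `modality`, `donor`, followed by one column per
#'     gene.}
#' }
#' Source modality vocabularies are mapped to the fixed `{cell, nucleus}`
#' tokens through `modality_map` at read time.
#'
#' @param path Directory (`mtx`) or file (`dense`).
#' @param format `"mtx"` or `"dense"`.
#' @param modality_map Named character vector mapping source labels to
#'   `"cell"` / `"nucleus"`; unmapped labels are kept as is.
#' @param dataset_tag Dataset label stored on the result.
#' @return A `labeled_counts`.
#' @export
read_counts <- function(path, format = c("mtx", "dense"),
                        modality_map = NULL, dataset_tag = "") {
  format <- match.arg(format)
  if (format == "mtx") {
    m <- Matrix::readMM(file.path(path, "matrix.mtx"))
    genes <- readLines(file.path(path, "genes.tsv"))
    cells <- utils::read.delim(file.path(path, "cells.tsv"),
                               stringsAsFactors = FALSE)
  } else {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
    meta_cols <- c("cell_id", "cell_type", "modality", "donor")
    if (!all(meta_cols %in% names(tab)[1:4])) {
      stop("dense layout requires leading columns cell_id, cell_type, modality, donor")
    }
    cells <- tab[meta_cols]
    m <- as.matrix(tab[setdiff(names(tab), meta_cols)])
    genes <- colnames(m)
  }
  if (nrow(cells) != nrow(m)) {
    stop(sprintf("cell annotation rows (%d) do not match matrix rows (%d)",
                 nrow(cells), nrow(m)))
  }
  if (length(genes) != ncol(m)) {
    stop(sprintf("gene list length (%d) does not match matrix columns (%d)",
                 length(genes), ncol(m)))
  }
  if (anyDuplicated(genes)) stop("duplicate gene ids in input")
  mod <- cells$modality
  if (!is.null(modality_map)) {
    hit <- mod %in% names(modality_map)
    mod[hit] <- modality_map[mod[hit]]
  }
  if (!all(mod %in% c("cell", "nucleus"))) {
    bad <- unique(mod[!mod %in% c("cell", "nucleus")])
    stop("unknown modality label(s): ", paste(bad, collapse = ", "))
  }
  labeled_counts(m, cell_type = cells$cell_type, modality = mod,
                 donor = cells$donor, gene_ids = genes,
                 cell_ids = cells$cell_id, dataset_tag = dataset_tag)
}

#' Write a labeled count matrix to disk
#'
#' Inverse of [read_counts()]; `read_counts(write_counts(x))` reproduces
#' integer counts exactly and real values to full printed precision.
#'
#' @param lc A `labeled_counts`.
#' @param path Output directory (`mtx`) or file (`dense`).
#' @param format `"mtx"` or `"dense"`.
#' @return `path`, invisibly.
#' @export
write_counts <- function(lc, path, format = c("mtx", "dense")) {
  format <- match.arg(format)
  ann <- data.frame(cell_id = lc$cell_ids, cell_type = lc$cell_type,
                    modality = lc$modality, donor = lc$donor)
  if (format == "mtx") {
    dir.create(path, recursive = TRUE, showWarnings = FALSE)
    sm <- methods::as(methods::as(Matrix::Matrix(as_dense(lc$values), sparse = TRUE),
                                  "generalMatrix"), "CsparseMatrix")
    Matrix::writeMM(sm, file.path(path, "matrix.mtx"))
    writeLines(lc$gene_ids, file.path(path, "genes.tsv"))
    utils::write.table(ann, file.path(path, "cells.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  } else {
    tab <- cbind(ann, as.data.frame(as_dense(lc$values), check.names = FALSE))
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read / write bulk expression tables
#'
#' Bulk matrices are stored as delimited tables with samples in rows; the
#' first column holds the sample id and the remaining columns are genes.
#'
#' @param path File path.
#' @param sep Field separator (default tab).
#' @return `read_bulk`: a `bulk_matrix`; `write_bulk`: `path` invisibly.
#' @export
read_bulk <- function(path, sep = "\t") {
  tab <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE,
                           check.names = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  bulk_matrix(m, sample_ids = tab[[1]], gene_ids = colnames(m))
}

#' @rdname read_bulk
#' @param b A `bulk_matrix`.
#' @export
write_bulk <- function(b, path, sep = "\t") {
  tab <- cbind(data.frame(sample_id = b$sample_ids),
               as.data.frame(as_dense(b$values), check.names = FALSE))
  utils::write.table(tab, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
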