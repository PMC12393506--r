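#' Labeled single-cell count matrix
#'
#' The universal container for single-cell or single-nucleus expression: a
#' cells x genes non-negative matrix plus per-cell labels. Raw data are
#' integer counts; transformed cells may hold non-integer values.
#'
#' @param values Numeric cells x genes matrix (base or `Matrix`), non-negative.
#' @param cell_type Character vector, one label per cell.
#' @param modality Character vector per cell, each `"cell"` or `"nucleus"`.
#' @param donor Character vector per cell.
#' @param gene_ids Unique gene identifiers (default: `colnames(values)`).
#' @param cell_ids Unique cell identifiers (default: rownames or generated).
#' @param dataset_tag Free-text label for the source dataset.
#' @return An object of class `labeled_counts`.
#' @export
labeled_counts <- function(values, cell_type, modality, donor,
                           gene_ids = colnames(values),
                           cell_ids = rownames(values),
                           dataset_tag = "") {
  if (is.null(gene_ids)) stop("gene_ids required (no colnames on values)")
  if (is.null(cell_ids)) cell_ids <- sprintf("cell%06d", seq_len(nrow(values)))
  n <- nrow(values)
  if (n < 1L || ncol(values) < 1L) stop("need at least 1 cell and 1 gene")
  if (anyDuplicated(gene_ids)) stop("gene_ids must be unique")
  if (length(gene_ids) != ncol(values)) stop("gene_ids length != n_genes")
  for (lab in list(cell_type = cell_type, modality = modality, donor = donor)) {
    if (length(lab) != n) stop("label vectors must have one entry per cell")
  }
  if (!all(modality %in% c("cell", "nucleus"))) {
    stop("modality labels must be 'cell' or 'nucleus'")
  }
  if (min_value(values) < 0) stop("negative entries not allowed")
  dimnames(values) <- list(cell_ids, gene_ids)
  structure(list(values = values,
                 gene_ids = as.character(gene_ids),
                 cell_ids = as.character(cell_ids),
                 cell_type = as.character(cell_type),
                 modality = as.character(modality),
                 donor = as.character(donor),
                 dataset_tag = dataset_tag),
            class = "labeled_counts")
}

#' Bulk expression matrix
#'
#' @param values Numeric samples x genes matrix, non-negative.
#' @param sample_ids Unique sample identifiers.
#' @param gene_ids Unique gene identifiers.
#' @return An object of class `bulk_matrix`.
#' @export
bulk_matrix <- function(values, sample_ids = rownames(values),
                        gene_ids = colnames(values)) {
  if (is.null(sample_ids)) sample_ids <- sprintf("sample%04d", seq_len(nrow(values)))
  if (is.null(gene_ids)) stop("gene_ids required")
  if (anyDuplicated(sample_ids)) stop("sample_ids must be unique")
  if (anyDuplicated(gene_ids)) stop("gene_ids must be unique")
  if (min_value(values) < 0) stop("negative entries not allowed")
  dimnames(values) <- list(sample_ids, gene_ids)
  structure(list(values = values,
                 sample_ids = as.character(sample_ids),
                 gene_ids = as.character(gene_ids)),
            class = "bulk_matrix")
}

min_value <- function(m) {
  if (inherits(m, "sparseMatrix")) {
    x <- m@x
    if (length(x) < length(m)) min(c(x, 0)) else min(x)
  } else min(m)
}

#' @export
print.labeled_counts <- function(x, ...) {
  cat(sprintf("<labeled_counts> %d cells x %d genes%s\n",
              nrow(x$values), ncol(x$values),
              if (nzchar(x$dataset_tag)) paste0(" [", x$dataset_tag, "]") else ""))
  tab <- table(x$cell_type, x$modality)
  print(tab)
  invisible(x)
}

#' @export
print.bulk_matrix <- function(x, ...) {
  cat(sprintf("<bulk_matrix> %d samples x %d genes\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.labeled_counts <- function(x) dim(x$values)
#' @export
dim.bulk_matrix <- function(x) dim(x$values)

## ---- gene-level accessors shared by both containers -------------------------

gene_ids_of <- function(x) x$gene_ids

restrict_genes <- function(x, genes) {
  idx <- match(genes, x$gene_ids)
  if (anyNA(idx)) stop("requested genes missing from object")
  x$values <- x$values[, idx, drop = FALSE]
  x$gene_ids <- genes
  x
}

#' Subset a labeled count matrix by cell index or predicate
#'
#' @param lc A `labeled_counts`.
#' @param i Integer or logical index over cells.
#' @return The subsetted `labeled_counts`.
#' @export
subset_cells <- function(lc, i) {
  lc$values <- lc$values[i, , drop = FALSE]
  lc$cell_ids <- lc$cell_ids[i]
  lc$cell_type <- lc$cell_type[i]
  lc$modality <- lc$modality[i]
  lc$donor <- lc$donor[i]
  lc
}

#' Restrict objects to their shared genes
#'
#' Intersects the gene identifiers of two or more expression containers
#' (`labeled_counts` or `bulk_matrix`) and returns each object restricted to
#' the common genes in a deterministic (lexicographic) order. Inputs are not
#' modified.
#'
#' @param ... Two or more `labeled_counts` / `bulk_matrix` objects.
#' @return A list of the same objects, all carrying the identical ordered
#'   shared gene list.
#' @export
align_genes <- function(...) {
  objs <- list(...)
  if (length(objs) == 1L && is.list(objs[[1]]) &&
      !inherits(objs[[1]], c("labeled_counts", "bulk_matrix"))) {
    objs <- objs[[1]]
  }
  if (length(objs) < 2L) stop("align_genes needs at least two objects")
  gene_sets <- lapply(objs, gene_ids_of)
  shared <- sort(Reduce(intersect, gene_sets))
  if (length(shared) == 0L) {
    nm <- names(objs) %||% paste0("input", seq_along(objs))
    stop(sprintf("no shared genes between inputs (%s)",
                 paste(nm, collapse = ", ")))
  }
  lapply(objs, restrict_genes, genes = shared)
}

#' Drop cell types with too few cells in either of two datasets
#'
#' Cell types with fewer than `min_cells` cells in either input are removed
#' from both, ensuring every retained type is usable for pseudobulks and
#' references in both modalities.
#'
#' @param lc,partner `labeled_counts` objects sharing a cell-type vocabulary.
#' @param min_cells Minimum cells per type per dataset (default 50).
#' @return A list with the two filtered objects and `dropped`, the removed
#'   type names.
#' @export
filter_min_cells <- function(lc, partner, min_cells = 50) {
  types <- union(unique(lc$cell_type), unique(partner$cell_type))
  n_a <- table(factor(lc$cell_type, levels = types))
  n_b <- table(factor(partner$cell_type, levels = types))
  keep <- types[n_a >= min_cells & n_b >= min_cells]
  dropped <- setdiff(types, keep)
  if (length(keep) == 0L) stop("all cell types fall below min_cells in at least one dataset")
  if (length(dropped)) {
    message("filter_min_cells: dropping ", paste(dropped, collapse = ", "))
  }
  list(a = subset_cells(lc, lc$cell_type %in% keep),
       b = subset_cells(partner, partner$cell_type %in% keep),
       dropped = dropped)
}

#' Remove a gene set from an expression container
#'
#' @param x A `labeled_counts` or `bulk_matrix`.
#' @param remove Character vector of gene ids to drop (ids absent from `x`
#'   are ignored).
#' @return The same type of object with the genes removed; gene order of the
#'   survivors is preserved and values are untouched.
#' @export
prune_genes <- function(x, remove) {
  keep <- setdiff(x$gene_ids, remove)
  if (length(keep) == 0L) stop("pruning would remove every gene")
  restrict_genes(x, x$gene_ids[x$gene_ids %in% keep])
}
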