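#' Build a per-type signature matrix from a reference panel
#'
#' Each cell is normalized to counts per million and the arithmetic mean is
#' taken per cell type.
#'
#' @param panel A `reference_panel` (or a bare `labeled_counts`).
#' @return Numeric types x genes matrix on the CPM scale.
#' @export
build_signature <- function(panel) {
  cells <- if (inherits(panel, "reference_panel")) panel$cells else panel
  vals <- as_dense(cells$values)
  if (any(rowSums(vals) == 0)) stop("a reference cell has zero total counts")
  cpm <- cpm_rows(vals)
  types <- sort(unique(cells$cell_type))
  sig <- t(vapply(types,
                  function(ty) colMeans(cpm[cells$cell_type == ty, , drop = FALSE]),
                  numeric(ncol(cpm))))
  rownames(sig) <- types
  sig
}

#' Estimate cell-type proportions of bulk samples
#'
#' The built-in backend CPM-normalizes each bulk sample and solves a
#' non-negative least-squares problem against the transposed signature
#' matrix; the weights are renormalized to proportions. It is a
#' deterministic, dependency-light solver adequate for ranking reference
#' variants; the harmonization transforms themselves are solver-agnostic and
#' an external Bayesian tool can be substituted through the adapter contract
#' (see [write_adapter_inputs()]).
#'
#' @param bulk A `bulk_matrix`.
#' @param panel A `reference_panel` (genes are aligned automatically).
#' @param backend `"nnls"` (built-in) only; external tools run out of
#'   process via the adapter files.
#' @return A `deconvolution_result`: `proportions` (samples x types, rows
#'   summing to 1), `residuals` (per-sample residual norms), `solver`.
#' @export
deconvolve <- function(bulk, panel, backend = c("nnls")) {
  backend <- match.arg(backend)
  al <- align_genes(bulk = bulk, panel = panel$cells)
  sig <- build_signature(structure(list(cells = al$panel),
                                   class = "reference_panel"))
  if (nrow(sig) < 2) stop("reference needs at least 2 cell types")
  A <- t(sig)                              # genes x types
  B <- cpm_rows(as_dense(al$bulk$values))  # samples x genes
  P <- matrix(0, nrow(B), nrow(sig), dimnames = list(al$bulk$sample_ids,
                                                     rownames(sig)))
  resid <- numeric(nrow(B))
  degenerate <- 0L
  for (i in seq_len(nrow(B))) {
    fit <- pracma::lsqnonneg(A, B[i, ])
    w <- fit$x
    if (sum(w) == 0) {
      degenerate <- degenerate + 1L
      P[i, ] <- 1 / nrow(sig)
    } else {
      P[i, ] <- w / sum(w)
    }
    resid[i] <- sqrt(sum((A %*% w - B[i, ])^2))
  }
  if (degenerate > 0) {
    warning(sprintf("%d bulk sample(s) had an all-zero solution; uniform proportions returned",
                    degenerate))
  }
  structure(list(proportions = P, residuals = resid, solver = backend,
                 reference = panel$spec$label %||% "custom"),
            class = "deconvolution_result")
}

#' @export
print.deconvolution_result <- function(x, ...) {
  cat(sprintf("<deconvolution_result> %d samples x %d types (%s, reference %s)\n",
              nrow(x$proportions), ncol(x$proportions), x$solver, x$reference))
  invisible(x)
}

#' Write proportions to CSV (samples in rows, 6 decimal places)
#'
#' @param res A `deconvolution_result`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_proportions <- function(res, path) {
  tab <- cbind(data.frame(sample_id = rownames(res$proportions)),
               as.data.frame(round(res$proportions, 6)))
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' External deconvolution tool adapter: exchange files
#'
#' Writes the inputs an external reference-based deconvolution tool needs:
#' `reference.csv` (genes x cells raw counts), `cell_types.csv` (cell id to
#' type map), `bulks.csv` (genes x samples), and `config.json` with the
#' iteration count (default 5000). Raw counts are passed; normalization is
#' left to the tool. The tool's output is read back with
#' [read_adapter_output()] as a samples x types proportion CSV.
#'
#' @param panel A `reference_panel`.
#' @param bulk A `bulk_matrix`.
#' @param dir Exchange directory.
#' @param n_iter Iteration count recorded in the config (default 5000).
#' @return `dir`, invisibly.
#' @export
write_adapter_inputs <- function(panel, bulk, dir, n_iter = 5000) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  al <- align_genes(bulk = bulk, panel = panel$cells)
  ref <- t(as_dense(al$panel$values))
  utils::write.csv(cbind(data.frame(gene = rownames(ref)),
                         as.data.frame(ref, check.names = FALSE)),
                   file.path(dir, "reference.csv"), row.names = FALSE)
  utils::write.csv(data.frame(cell_id = al$panel$cell_ids,
                              cell_type = al$panel$cell_type),
                   file.path(dir, "cell_types.csv"), row.names = FALSE)
  bl <- t(as_dense(al$bulk$values))
  utils::write.csv(cbind(data.frame(gene = rownames(bl)),
                         as.data.frame(bl, check.names = FALSE)),
                   file.path(dir, "bulks.csv"), row.names = FALSE)
  jsonlite::write_json(list(n_iter = n_iter, reference = panel$spec$label),
                       file.path(dir, "config.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_adapter_inputs
#' @param path Proportion CSV produced by the external tool (first column
#'   sample id, remaining columns one per type).
#' @export
read_adapter_output <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE)
  P <- as.matrix(tab[, -1, drop = FALSE])
  rownames(P) <- tab[[1]]
  if (any(P < 0) || any(abs(rowSums(P) - 1) > 1e-6)) {
    stop("malformed adapter output: proportions must be non-negative rows summing to 1")
  }
  structure(list(proportions = P / rowSums(P), residuals = rep(NA_real_, nrow(P)),
                 solver = "external_adapter", reference = "external"),
            class = "deconvolution_result")
}
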