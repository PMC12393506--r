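#' Fit the PCA neighbour-based shift model
#'
#' Expression of the scRNA-seq training cells and the snRNA-seq cells of
#' overlapping types is log1p-transformed and standardized to zero mean and
#' unit variance (statistics fitted on the concatenated pool; zero-variance
#' genes get sd floored at 1). A PCA is fitted on the pooled scaled data,
#' retaining the minimum number of components capturing at least
#' `var_threshold` of total variance. The centroid of the scRNA-seq
#' projections is computed, and every overlapping snRNA-seq cell stores a
#' shift vector pointing from its projection to that centroid. The target
#' library size `L` is the median (or mean) of per-cell totals of the
#' scRNA-seq training cells.
#'
#' @param sc_train scRNA-seq training cells (`labeled_counts`), gene-aligned
#'   with `sn_overlap`; the held-out type must already be absent (caller's
#'   duty).
#' @param sn_overlap snRNA-seq cells of types shared with the scRNA-seq data.
#' @param var_threshold Minimum fraction of variance retained (default 0.75).
#' @param k Neighbour count used at application time (default 10).
#' @param target_library `"median"` (default) or `"mean"` of scRNA-seq
#'   per-cell totals.
#' @return A `pca_shift_model`.
#' @export
fit_pca_shift <- function(sc_train, sn_overlap, var_threshold = 0.75, k = 10,
                          target_library = c("median", "mean")) {
  target_library <- match.arg(target_library)
  if (!identical(sc_train$gene_ids, sn_overlap$gene_ids)) {
    stop("inputs must be gene-aligned; run align_genes() first")
  }
  xc <- log1p(as_dense(sc_train$values))
  xn <- log1p(as_dense(sn_overlap$values))
  pool <- rbind(xc, xn)
  mu <- colMeans(pool)
  sd <- apply(pool, 2, stats::sd)
  if (all(sd == 0)) stop("every gene has zero variance in the training pool")
  sd[sd == 0] <- 1                      # floor: avoid division blow-ups
  scaled <- sweep(sweep(pool, 2, mu), 2, sd, "/")
  pc <- stats::prcomp(scaled, center = FALSE, scale. = FALSE)
  var_ratio <- pc$sdev^2 / sum(pc$sdev^2)
  d <- which(cumsum(var_ratio) >= var_threshold - 1e-12)[1]
  if (is.na(d)) d <- length(var_ratio)
  if (nrow(pool) <= d) stop("fewer training cells than retained components")
  rot <- pc$rotation[, seq_len(d), drop = FALSE]
  z <- scaled %*% rot
  z_sc <- z[seq_len(nrow(xc)), , drop = FALSE]
  z_sn <- z[nrow(xc) + seq_len(nrow(xn)), , drop = FALSE]
  centroid <- colMeans(z_sc)
  shifts <- sweep(-z_sn, 2, centroid, "+")   # centroid - z_i per overlap cell
  totals <- rowSums(as_dense(sc_train$values))
  L <- if (target_library == "median") stats::median(totals) else mean(totals)
  structure(list(mu = mu, sd = sd, rotation = rot, d = d,
                 explained = sum(var_ratio[seq_len(d)]),
                 centroid = centroid, train_latent = z_sn, shifts = shifts,
                 k = k, L = L, gene_ids = sc_train$gene_ids,
                 shift_mode = "neighbour_shift_vectors"),
            class = "pca_shift_model")
}

#' @export
print.pca_shift_model <- function(x, ...) {
  cat(sprintf("<pca_shift_model> %d components (%.1f%% variance), k = %d, L = %.0f, %d anchor cells\n",
              x$d, 100 * x$explained, x$k, x$L, nrow(x$train_latent)))
  invisible(x)
}

## stable k-nearest-neighbour indices (Euclidean), ties broken by index order
knn_indices <- function(query, anchors, k) {
  k <- min(k, nrow(anchors))
  a2 <- rowSums(anchors^2)
  d2 <- outer(rowSums(query^2), a2, "+") - 2 * query %*% t(anchors)
  out <- vapply(seq_len(nrow(d2)),
                function(i) order(d2[i, ])[seq_len(k)], integer(k))
  matrix(out, ncol = k, byrow = TRUE)
}

#' Shift missing-type snRNA-seq cells through the PCA model
#'
#' Each missing-type cell is log1p-standardized with the fitted scaler and
#' projected into the component space. Its `k` nearest overlapping snRNA-seq
#' training cells (Euclidean distance, ties broken by stable index order) are
#' found, and the mean of those neighbours' stored shift vectors is added to
#' its coordinates. The shifted coordinates are inverse-projected,
#' un-standardized, `expm1`-transformed, clipped at zero, and each cell is
#' rescaled to total `L`.
#'
#' @param model A `pca_shift_model`.
#' @param sn_missing `labeled_counts` of the missing-type nucleus cells,
#'   gene-aligned to the model.
#' @param shift_mode `"neighbour_shift_vectors"` (default: mean of the
#'   neighbours' centroid-pointing shift vectors) or `"displacement"` (mean
#'   displacement from the cell to its neighbours) for sensitivity checks.
#' @return A `labeled_counts` of transformed cells with modality `"cell"`.
#' @export
apply_pca_shift <- function(model, sn_missing,
                            shift_mode = c("neighbour_shift_vectors",
                                           "displacement")) {
  shift_mode <- match.arg(shift_mode)
  if (!identical(model$gene_ids, sn_missing$gene_ids)) {
    stop("sn_missing must be gene-aligned to the model")
  }
  x <- log1p(as_dense(sn_missing$values))
  scaled <- sweep(sweep(x, 2, model$mu), 2, model$sd, "/")
  z <- scaled %*% model$rotation
  k <- model$k
  if (nrow(model$train_latent) < k) {
    k <- nrow(model$train_latent)
    warning(sprintf("only %d anchor cells available; k lowered to %d", k, k))
  }
  nn <- knn_indices(z, model$train_latent, k)
  shift <- do.call(rbind, lapply(seq_len(nrow(nn)), function(i) {
    idx <- nn[i, ]
    if (shift_mode == "neighbour_shift_vectors") {
      colMeans(model$shifts[idx, , drop = FALSE])
    } else {
      colMeans(model$train_latent[idx, , drop = FALSE])
    }
  }))
  z_shifted <- if (shift_mode == "neighbour_shift_vectors") z + shift else
    z + (shift - z)
  back <- z_shifted %*% t(model$rotation)
  back <- sweep(sweep(back, 2, model$sd, "*"), 2, model$mu, "+")
  expr <- expm1(back)
  expr[expr < 0] <- 0
  expr <- cpm_rows(expr, model$L)
  labeled_counts(expr, cell_type = sn_missing$cell_type,
                 modality = rep("cell", nrow(expr)),
                 donor = sn_missing$donor, gene_ids = model$gene_ids,
                 cell_ids = paste0(sn_missing$cell_ids, "_pcashift"),
                 dataset_tag = sn_missing$dataset_tag)
}
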