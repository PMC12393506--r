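#' Sum cells into pseudo-replicate aggregates per (type, modality) stratum
#'
#' Within each cell-type x modality stratum, cells are shuffled, partitioned
#' into non-overlapping groups of `group_size`, and summed; remainder cells
#' are discarded. Aggregation reduces single-cell sparsity so the aggregates
#' can be treated as replicate count libraries for differential expression.
#' Strata with fewer than 3 aggregates are flagged in `low_replicate`.
#'
#' @param lc A `labeled_counts` with integer counts.
#' @param group_size Cells per aggregate (default 10).
#' @param seed Integer seed for the shuffle.
#' @return An `aggregate_matrix`: integer `values` (aggregates x genes),
#'   `cell_type` / `modality` / `replicate` labels, `membership` (list of the
#'   member cell indices of each aggregate), and `low_replicate`.
#' @export
make_aggregates <- function(lc, group_size = 10, seed = 1L) {
  vals <- as_dense(lc$values)
  if (any(vals != round(vals))) stop("make_aggregates requires integer counts")
  with_seed(seed, {
    key <- paste(lc$cell_type, lc$modality, sep = "\r")
    strata <- split(seq_along(lc$cell_type), key)
    rows <- list(); type <- character(); mod <- character(); rep_i <- integer()
    membership <- list()
    for (nm in names(strata)) {
      idx <- sample(strata[[nm]])
      n_grp <- length(idx) %/% group_size
      if (n_grp == 0) next
      parts <- strsplit(nm, "\r", fixed = TRUE)[[1]]
      for (g in seq_len(n_grp)) {
        mem <- idx[((g - 1) * group_size + 1):(g * group_size)]
        rows[[length(rows) + 1L]] <- colSums(vals[mem, , drop = FALSE])
        membership[[length(membership) + 1L]] <- mem
        type <- c(type, parts[1]); mod <- c(mod, parts[2])
        rep_i <- c(rep_i, g)
      }
    }
    if (!length(rows)) stop("no stratum has enough cells for a single aggregate")
    values <- do.call(rbind, rows)
    colnames(values) <- lc$gene_ids
    tab <- table(paste(type, mod))
    structure(list(values = values, cell_type = type, modality = mod,
                   replicate = rep_i, membership = membership,
                   gene_ids = lc$gene_ids, group_size = group_size,
                   low_replicate = names(tab)[tab < 3]),
              class = "aggregate_matrix")
  })
}

## ---- negative-binomial Wald engine ------------------------------------------

## DESeq-style median-of-ratios size factors
size_factors_mor <- function(counts) {
  if (any(rowSums(counts) == 0)) stop("an aggregate has zero total counts")
  logg <- colMeans(log(counts + 0L), na.rm = FALSE)  # log geometric means
  usable <- is.finite(logg)
  if (!any(usable)) stop("no gene is expressed in every aggregate; cannot form size factors")
  sf <- apply(counts[, usable, drop = FALSE], 1, function(y) {
    exp(stats::median(log(y[y > 0]) - logg[usable][y > 0]))
  })
  sf / exp(mean(log(sf)))
}

## gene-wise moment dispersion alpha (var = mu + alpha mu^2) from
## size-factor-normalized counts, pooled within groups, with a small floor
moment_dispersion <- function(norm, group, floor = 1e-8) {
  levs <- unique(group)
  ssq <- 0; df <- 0
  for (g in levs) {
    sub <- norm[group == g, , drop = FALSE]
    if (nrow(sub) > 1) {
      ssq <- ssq + colSums(sweep(sub, 2, colMeans(sub))^2)
      df <- df + nrow(sub) - 1
    }
  }
  v <- ssq / df
  m <- colMeans(norm)
  a <- (v - m) / m^2
  a[!is.finite(a)] <- floor
  pmax(a, floor)
}

## Vectorized two-group NB GLM (log link, offsets log sf, fixed gene-wise
## dispersion): IRLS shared across genes, Wald statistic on the group
## coefficient.  y: samples x genes.
nb_wald_two_group <- function(y, group, sf, alpha, max_iter = 25, tol = 1e-8) {
  x <- as.numeric(group == levels(factor(group))[2])
  n <- nrow(y); G <- ncol(y)
  off <- log(sf)
  A <- matrix(alpha, n, G, byrow = TRUE)
  ## initialize from normalized group means (pseudocount for empty groups)
  norm <- y / sf
  m1 <- colMeans(norm[x == 0, , drop = FALSE]); m2 <- colMeans(norm[x == 1, , drop = FALSE])
  eps <- 1e-8
  b0 <- log(m1 + eps); b1 <- log(m2 + eps) - b0
  for (it in seq_len(max_iter)) {
    eta <- outer(off, rep(1, G)) + matrix(b0, n, G, byrow = TRUE) +
      outer(x, b1)
    mu <- pmin(exp(eta), 1e12)
    mu <- pmax(mu, 1e-10)
    w <- mu / (1 + A * mu)
    z <- (eta - off) + (y - mu) / mu
    S0 <- colSums(w); S1 <- colSums(w * x)
    T0 <- colSums(w * z); T1 <- colSums(w * x * z)
    det <- S0 * S1 - S1^2           # S2 == S1 since x is 0/1
    det[det <= 0] <- NA
    new_b1 <- (S0 * T1 - S1 * T0) / det
    new_b0 <- (T0 - S1 * new_b1) / S0
    delta <- max(abs(c(new_b0 - b0, new_b1 - b1)), na.rm = TRUE)
    b0 <- new_b0; b1 <- new_b1
    if (is.finite(delta) && delta < tol) break
  }
  se <- sqrt(S0 / det)
  stat <- b1 / se
  list(log2fc = b1 / log(2), stat = stat,
       pvalue = 2 * stats::pnorm(-abs(stat)))
}

#' Test genes for differential expression between modalities
#'
#' Runs a per-gene two-group negative-binomial Wald test (nucleus vs cell) on
#' the aggregates of one cell type: median-of-ratios size factors, gene-wise
#' moment dispersion with a small floor, a shared-design IRLS fit of the
#' log-link NB GLM, a Wald statistic on the modality coefficient, and
#' Benjamini-Hochberg adjustment over all tested genes. Genes with zero
#' counts in every aggregate are excluded from testing and reported with
#' missing p-values. The engine is pluggable: pass `engine` as a function
#' `(counts, group) -> data.frame(log2fc, pvalue)` to substitute an external
#' DESeq2-compatible implementation.
#'
#' @param agg An `aggregate_matrix` from [make_aggregates()].
#' @param cell_type The cell type to test.
#' @param engine Optional replacement test engine.
#' @param dispersion_floor Lower bound on the moment dispersion.
#' @return A `de_result` data frame with columns `gene`, `base_mean`,
#'   `log2fc` (nucleus vs cell), `pvalue`, `padj`.
#' @export
de_test <- function(agg, cell_type, engine = NULL, dispersion_floor = 1e-8) {
  sel <- agg$cell_type == cell_type
  if (!any(sel)) stop("cell type not present in aggregates: ", cell_type)
  mods <- unique(agg$modality[sel])
  if (!all(c("cell", "nucleus") %in% mods)) {
    stop("both modalities needed to test cell type ", cell_type)
  }
  y <- agg$values[sel, , drop = FALSE]
  group <- factor(agg$modality[sel], levels = c("cell", "nucleus"))
  if (min(table(group)) < 2) stop("need >= 2 aggregates per modality")
  tested <- colSums(y) > 0
  res <- data.frame(gene = agg$gene_ids, base_mean = NA_real_,
                    log2fc = NA_real_, pvalue = NA_real_, padj = NA_real_)
  yt <- y[, tested, drop = FALSE]
  if (is.null(engine)) {
    sf <- size_factors_mor(yt)
    norm <- yt / sf
    alpha <- moment_dispersion(norm, group, floor = dispersion_floor)
    fit <- nb_wald_two_group(yt, group, sf, alpha)
    res$base_mean[tested] <- colMeans(norm)
    res$log2fc[tested] <- fit$log2fc
    res$pvalue[tested] <- fit$pvalue
  } else {
    ext <- engine(yt, group)
    res$base_mean[tested] <- colMeans(yt)
    res$log2fc[tested] <- ext$log2fc
    res$pvalue[tested] <- ext$pvalue
  }
  res$padj[tested] <- stats::p.adjust(res$pvalue[tested], method = "BH")
  class(res) <- c("de_result", "data.frame")
  res
}

#' Build the catalog of cross-modality gene-removal sets
#'
#' From per-(dataset, cell type) differential-expression results, assembles
#' every gene set used to prune references: per-dataset unions of significant
#' genes (optionally excluding a held-out type), the intersection of those
#' unions across datasets, for each dataset the union over the *other*
#' datasets, and a size-matched random gene set drawn from the tested
#' universe.
#'
#' @param de_results Nested list: `de_results[[dataset]][[cell_type]]` is a
#'   `de_result`.
#' @param alpha Adjusted-p threshold for calling a gene differential
#'   (default 0.01).
#' @param held_out Cell type excluded from the per-dataset unions, or `NULL`.
#' @param random_seed Seed for the random matched set.
#' @return A `gene_set_catalog`.
#' @export
build_catalog <- function(de_results, alpha = 0.01, held_out = NULL,
                          random_seed = 1L) {
  datasets <- names(de_results)
  if (is.null(datasets)) stop("de_results must be a named list keyed by dataset")
  sig <- lapply(de_results, function(ds) {
    lapply(ds, function(r) r$gene[!is.na(r$padj) & r$padj < alpha])
  })
  universe <- sort(unique(unlist(lapply(de_results, function(ds) {
    unlist(lapply(ds, function(r) r$gene[!is.na(r$padj)]))
  }))))
  union_of <- function(dataset, exclude = NULL) {
    sets <- sig[[dataset]]
    keep <- setdiff(names(sets), exclude)
    sort(unique(as.character(unlist(sets[keep]))))
  }
  per_dataset_union <- lapply(datasets, union_of, exclude = held_out)
  names(per_dataset_union) <- datasets
  all_type_union <- lapply(datasets, union_of)
  names(all_type_union) <- datasets
  intersection <- sort(Reduce(intersect, all_type_union))
  other_union <- lapply(datasets, function(d) {
    sort(unique(unlist(all_type_union[setdiff(datasets, d)])))
  })
  names(other_union) <- datasets
  ref_size <- length(per_dataset_union[[1]])
  random_matched <- with_seed(random_seed,
                              sort(sample(universe, min(ref_size, length(universe)))))
  structure(list(per_type = sig, per_dataset_union = per_dataset_union,
                 all_type_union = all_type_union,
                 intersection = intersection, other_union = other_union,
                 random_matched = random_matched, universe = universe,
                 alpha = alpha, held_out = held_out, seed = random_seed),
            class = "gene_set_catalog")
}

#' @export
print.gene_set_catalog <- function(x, ...) {
  cat(sprintf("<gene_set_catalog> %d dataset(s); intersection %d genes; universe %d genes\n",
              length(x$per_dataset_union), length(x$intersection),
              length(x$universe)))
  for (d in names(x$per_dataset_union)) {
    cat(sprintf("  %s: union %d genes (held out: %s)\n", d,
                length(x$per_dataset_union[[d]]), x$held_out %||% "none"))
  }
  invisible(x)
}

#' Export a gene-set catalog as plain text
#'
#' One-column gene files per set plus a JSON manifest.
#'
#' @param catalog A `gene_set_catalog`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_catalog <- function(catalog, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (d in names(catalog$per_dataset_union)) {
    writeLines(catalog$per_dataset_union[[d]],
               file.path(dir, paste0("deg_union_", d, ".txt")))
  }
  writeLines(catalog$intersection, file.path(dir, "deg_intersection.txt"))
  writeLines(catalog$random_matched, file.path(dir, "random_matched.txt"))
  jsonlite::write_json(list(alpha = catalog$alpha,
                            held_out = catalog$held_out %||% NA,
                            seed = catalog$seed,
                            sizes = lapply(catalog$per_dataset_union, length)),
                       file.path(dir, "catalog.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
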