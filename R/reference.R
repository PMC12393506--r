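## The reference-variant vocabulary: machine codes, display labels, and which
## ingredients each variant needs.
.variant_table <- data.frame(
  code = c("pos_ctrl", "neg_ctrl", "sn_all_minus_deg_int", "sn_raw",
           "sn_minus_deg", "pca", "pca_minus_deg", "vae_ls",
           "vae_ls_minus_deg", "vae_cond", "vae_cond_minus_deg",
           "minus_deg_int", "minus_deg_other", "minus_random"),
  label = c("scRNA All (PosCtrl)", "snRNA All (NegCtrl)",
            "snRNA All (-DEG Int.)", "snRNA", "snRNA -DEG", "PCA",
            "PCA -DEG", "scVILS", "scVILS -DEG", "scVIcond",
            "scVIcond -DEG", "-DEG Int.", "-DEG Other Datasets",
            "-Random Genes"),
  needs_held_out = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE,
                     TRUE, TRUE, TRUE, TRUE, TRUE),
  needs_catalog = c(FALSE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE,
                    FALSE, TRUE, TRUE, TRUE, TRUE),
  stringsAsFactors = FALSE)

#' Available reference-variant codes
#' @return Data frame of variant codes, display labels and requirements.
#' @export
transform_variants <- function() .variant_table

#' Describe one reference-construction variant
#'
#' A transform spec names one of the benchmarked reference variants: the two
#' single-modality controls, raw or transformed snRNA-seq substitution of a
#' held-out type, and the gene-pruning variants (dataset DEG union,
#' cross-dataset intersection, other-dataset unions, size-matched random
#' set).
#'
#' @param variant One of `transform_variants()$code`.
#' @param held_out Held-out cell type (required for substitution variants).
#' @return A `transform_spec`.
#' @export
transform_spec <- function(variant, held_out = NULL) {
  row <- .variant_table[.variant_table$code == variant, ]
  if (nrow(row) != 1) {
    stop("unknown variant '", variant, "'; see transform_variants()")
  }
  if (row$needs_held_out && is.null(held_out)) {
    stop("variant '", variant, "' requires a held-out cell type")
  }
  structure(list(variant = variant, label = row$label, held_out = held_out,
                 needs_catalog = row$needs_catalog),
            class = "transform_spec")
}

#' @export
print.transform_spec <- function(x, ...) {
  cat(sprintf("<transform_spec> %s%s\n", x$label,
              if (!is.null(x$held_out)) paste0(" [held out: ", x$held_out, "]") else ""))
  invisible(x)
}

## per-type target counts shared by every variant: min of the two modalities'
## availabilities, so all references carry identical cell numbers per type
equalized_counts <- function(sc, sn) {
  types <- sort(intersect(unique(sc$cell_type), unique(sn$cell_type)))
  n_sc <- table(factor(sc$cell_type, levels = types))
  n_sn <- table(factor(sn$cell_type, levels = types))
  stats::setNames(pmin(as.integer(n_sc), as.integer(n_sn)), types)
}

sample_types <- function(lc, counts, seed) {
  with_seed(seed, {
    idx <- unlist(lapply(names(counts), function(ty) {
      pool <- which(lc$cell_type == ty)
      sample(pool, counts[[ty]])
    }))
    subset_cells(lc, idx)
  })
}

#' Concatenate two gene-aligned labeled count matrices row-wise
#'
#' @param a,b Gene-aligned `labeled_counts`.
#' @return A `labeled_counts` holding the cells of both inputs.
#' @export
bind_cells <- function(a, b) {
  stopifnot(identical(a$gene_ids, b$gene_ids))
  labeled_counts(rbind(as_dense(a$values), as_dense(b$values)),
                 cell_type = c(a$cell_type, b$cell_type),
                 modality = c(a$modality, b$modality),
                 donor = c(a$donor, b$donor),
                 gene_ids = a$gene_ids,
                 cell_ids = make.unique(c(a$cell_ids, b$cell_ids)),
                 dataset_tag = a$dataset_tag)
}

## the gene-removal set each variant prescribes
removal_set <- function(spec, catalog, dataset, seed) {
  if (!spec$needs_catalog) return(character())
  if (is.null(catalog)) stop("variant '", spec$variant, "' needs a gene-set catalog")
  h <- spec$held_out
  switch(spec$variant,
    sn_all_minus_deg_int = catalog$intersection,
    sn_minus_deg = ,
    pca_minus_deg = ,
    vae_ls_minus_deg = ,
    vae_cond_minus_deg = deg_union_excluding(catalog, dataset, h),
    minus_deg_int = setdiff(catalog$intersection,
                            catalog$per_type[[dataset]][[h]] %||% character()),
    minus_deg_other = catalog$other_union[[dataset]],
    minus_random = with_seed(seed, {
      size <- length(deg_union_excluding(catalog, dataset, h))
      sort(sample(catalog$universe, min(size, length(catalog$universe))))
    }),
    stop("no removal rule for variant ", spec$variant))
}

deg_union_excluding <- function(catalog, dataset, held_out) {
  sets <- catalog$per_type[[dataset]]
  if (is.null(sets)) stop("unknown dataset '", dataset, "' in catalog")
  sort(unique(unlist(sets[setdiff(names(sets), held_out)])))
}

#' Assemble one deconvolution reference panel
#'
#' Builds the reference a given [transform_spec()] prescribes from a
#' gene-aligned scRNA-seq / snRNA-seq pair: control panels take every cell
#' type from a single modality; substitution panels take all non-held-out
#' types from scRNA-seq and the held-out type from snRNA-seq, raw or passed
#' through the requested transform; pruning variants then remove their gene
#' set. Cell numbers per type are equalized across variants (the per-type
#' minimum of the two modalities' availabilities), so panels differ only in
#' the held-out type's source and the gene space. Transform models are
#' fitted here under the held-out protocol — the held-out type is excluded
#' from the scRNA-seq pool, the snRNA-seq anchor pool, and any VAE training
#' set — unless prefit `models` are supplied.
#'
#' @param spec A `transform_spec`.
#' @param sc,sn Gene-aligned `labeled_counts` for the two modalities.
#' @param catalog A `gene_set_catalog` (required for pruning variants).
#' @param dataset Dataset key into the catalog (default: first entry).
#' @param models Optional prefit list with elements `pca`, `vae`,
#'   `vae_cond` for the matching gene space.
#' @param vae_args List of extra arguments for [fit_vae()] (epochs, width...).
#' @param seed Integer seed (cell sampling, model fits).
#' @return A `reference_panel`: `cells`, `genes`, `spec`, `held_out`, and a
#'   `manifest` recording the training-pool composition.
#' @export
assemble_reference <- function(spec, sc, sn, catalog = NULL, dataset = NULL,
                               models = NULL, vae_args = list(), seed = 1L) {
  stopifnot(inherits(spec, "transform_spec"))
  if (!identical(sc$gene_ids, sn$gene_ids)) {
    stop("sc and sn must be gene-aligned; run align_genes() first")
  }
  if (!is.null(spec$held_out) && !spec$held_out %in% sn$cell_type) {
    stop("held-out type '", spec$held_out, "' absent from the snRNA-seq data")
  }
  dataset <- dataset %||% if (!is.null(catalog)) names(catalog$per_type)[1] else "dataset"
  counts <- equalized_counts(sc, sn)
  h <- spec$held_out
  remove <- removal_set(spec, catalog, dataset,
                        derive_seed(seed, "random_genes", spec$variant))
  ## gene space the panel (and any transform model) lives in
  genes_kept <- setdiff(sc$gene_ids, remove)
  sc_p <- if (length(remove)) prune_genes(sc, remove) else sc
  sn_p <- if (length(remove)) prune_genes(sn, remove) else sn

  pick_seed <- derive_seed(seed, "cells", spec$variant)
  manifest <- list(variant = spec$variant, held_out = h, seed = seed,
                   n_genes = length(genes_kept), removed = length(remove))

  if (spec$variant %in% c("pos_ctrl")) {
    cells <- sample_types(sc_p, counts, pick_seed)
  } else if (spec$variant %in% c("neg_ctrl", "sn_all_minus_deg_int")) {
    cells <- sample_types(sn_p, counts, pick_seed)
  } else {
    keep_counts <- counts[setdiff(names(counts), h)]
    sc_part <- sample_types(sc_p, keep_counts, pick_seed)
    sn_held <- sample_types(sn_p, counts[h], derive_seed(seed, "held", spec$variant))
    manifest$training_types <- setdiff(names(counts), h)
    held_cells <- switch(spec$variant,
      sn_raw = , sn_minus_deg = , minus_deg_int = , minus_deg_other = ,
      minus_random = sn_held,
      pca = , pca_minus_deg = {
        model <- models$pca %||% {
          sn_overlap <- subset_cells(sn_p, sn_p$cell_type != h)
          fit_pca_shift(sc_part, sn_overlap)
        }
        apply_pca_shift(model, sn_held)
      },
      vae_ls = , vae_ls_minus_deg = {
        model <- models$vae %||% do.call(fit_vae, c(
          list(train = bind_cells(sc_part, subset_cells(sn_p, sn_p$cell_type != h)),
               conditional = FALSE, held_out = h,
               seed = derive_seed(seed, "vae", spec$variant)),
          vae_args))
        apply_latent_shift(model, subset_cells(sn_p, sn_p$cell_type != h),
                           sn_held, sc_part)
      },
      vae_cond = , vae_cond_minus_deg = {
        model <- models$vae_cond %||% do.call(fit_vae, c(
          list(train = bind_cells(sc_part, subset_cells(sn_p, sn_p$cell_type != h)),
               conditional = TRUE, held_out = h,
               seed = derive_seed(seed, "vae_cond", spec$variant)),
          vae_args))
        L <- stats::median(rowSums(as_dense(sc_part$values)))
        apply_conditional(model, sn_held, L = L)
      },
      stop("unhandled variant ", spec$variant))
    cells <- bind_cells(sc_part, held_cells)
  }
  structure(list(cells = cells, genes = cells$gene_ids, spec = spec,
                 held_out = h, manifest = manifest),
            class = "reference_panel")
}

#' @export
print.reference_panel <- function(x, ...) {
  cat(sprintf("<reference_panel> %s: %d cells, %d genes%s\n", x$spec$label,
              nrow(x$cells$values), length(x$genes),
              if (!is.null(x$held_out)) paste0(", held out ", x$held_out) else ""))
  invisible(x)
}
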