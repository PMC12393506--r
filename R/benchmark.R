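#' Run the synthetic held-out benchmark end to end, in memory
#'
#' Generates a paired scRNA-seq / snRNA-seq world, builds pseudobulks from
#' the single-cell data of half the donors, assembles one reference panel
#' per requested variant from the remaining donors (computing the
#' cross-modality DEG catalog and fitting transform models as needed),
#' deconvolves the pseudobulks with each panel, and returns the per-sample
#' evaluation records. VAE-based transforms are trained on a size-capped
#' subsample of the reference pool so the benchmark stays desk-scale.
#'
#' @param seed Master seed; all stage streams derive from it.
#' @param synthetic List of [synthetic_config()] overrides.
#' @param variants Reference-variant codes to benchmark.
#' @param held_out Held-out cell type (default: the second most abundant
#'   shared type).
#' @param n_random,n_realistic,total_cells Pseudobulk parameters.
#' @param vae_train_cells Cap on cells per modality in the VAE training pool.
#' @param vae_args Extra [fit_vae()] arguments (e.g. `max_epochs`).
#' @param alpha,group_size DEG-calling parameters.
#' @return A list: `records` (tidy evaluation table over all variants and
#'   scenarios), `mean_pearson` (named, all-cells scenario), `per_sample`
#'   (named list of per-sample all-cells Pearson vectors), `held_out`,
#'   `catalog` (or `NULL`), and `world`.
#' @export
run_synthetic_benchmark <- function(seed,
                                    synthetic = list(),
                                    variants = c("pos_ctrl", "neg_ctrl",
                                                 "sn_raw", "sn_minus_deg",
                                                 "pca", "pca_minus_deg",
                                                 "minus_random"),
                                    held_out = NULL,
                                    n_random = 50, n_realistic = 50,
                                    total_cells = 1000,
                                    vae_train_cells = 500,
                                    vae_args = list(max_epochs = 30),
                                    alpha = 0.01, group_size = 10) {
  cfg <- do.call(synthetic_config,
                 c(synthetic,
                   if (!"seed" %in% names(synthetic))
                     list(seed = derive_seed(seed, "world"))))
  world <- generate_paired(cfg)
  donors <- sort(unique(world$sc$donor))
  pb_donors <- donors[seq_len(max(1, length(donors) %/% 2))]
  pbsrc <- subset_cells(world$sc, world$sc$donor %in% pb_donors)
  scref <- subset_cells(world$sc, !world$sc$donor %in% pb_donors)
  snref <- world$sn
  pb <- build_pseudobulks(pbsrc, n_random = n_random,
                          n_realistic = n_realistic,
                          total_cells = total_cells,
                          seed = derive_seed(seed, "pseudobulk"))
  al <- align_genes(sc = scref, sn = snref)
  shared <- sort(intersect(unique(al$sc$cell_type), unique(al$sn$cell_type)))
  if (is.null(held_out)) held_out <- shared[min(2, length(shared))]

  vt <- transform_variants()
  need_cat <- any(vt$needs_catalog[vt$code %in% variants])
  catalog <- NULL
  if (need_cat) {
    agg <- make_aggregates(bind_cells(al$sc, al$sn), group_size = group_size,
                           seed = derive_seed(seed, "aggregates"))
    de <- lapply(shared, function(ty) de_test(agg, ty))
    names(de) <- shared
    catalog <- build_catalog(list(synthetic = de), alpha = alpha,
                             random_seed = derive_seed(seed, "catalog"))
  }

  models <- list()
  if (any(c("vae_ls", "vae_cond") %in% variants)) {
    sc_nh <- subset_cells(al$sc, al$sc$cell_type != held_out)
    sn_nh <- subset_cells(al$sn, al$sn$cell_type != held_out)
    cap <- function(lc, tag) {
      n <- min(vae_train_cells, nrow(lc$values))
      with_seed(derive_seed(seed, "vae_pool", tag),
                subset_cells(lc, sample(nrow(lc$values), n)))
    }
    vtrain <- bind_cells(cap(sc_nh, "sc"), cap(sn_nh, "sn"))
    if ("vae_ls" %in% variants) {
      models$vae <- do.call(fit_vae, c(
        list(train = vtrain, conditional = FALSE, held_out = held_out,
             seed = derive_seed(seed, "vae")), vae_args))
    }
    if ("vae_cond" %in% variants) {
      models$vae_cond <- do.call(fit_vae, c(
        list(train = vtrain, conditional = TRUE, held_out = held_out,
             seed = derive_seed(seed, "vae_cond")), vae_args))
    }
  }

  records <- list()
  per_sample <- list()
  for (v in variants) {
    spec <- transform_spec(v, held_out = if (vt$needs_held_out[vt$code == v])
      held_out else NULL)
    panel <- assemble_reference(spec, al$sc, al$sn, catalog = catalog,
                                dataset = "synthetic", models = models,
                                vae_args = vae_args,
                                seed = derive_seed(seed, "reference", v))
    res <- deconvolve(pb$bulk, panel)
    rec <- evaluate_deconvolution(pb$proportions, res, transform = v,
                                  dataset = "synthetic",
                                  held_out = panel$held_out)
    records[[v]] <- rec
    per_sample[[v]] <- rec$pearson[rec$scenario == "all"]
  }
  records <- do.call(rbind, records)
  means <- vapply(per_sample, function(x) mean(x, na.rm = TRUE), numeric(1))
  list(records = records, mean_pearson = means, per_sample = per_sample,
       held_out = held_out, catalog = catalog, world = world)
}
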