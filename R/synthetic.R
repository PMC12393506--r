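#' Configuration for the paired-modality synthetic generator
#'
#' Describes a ground-truth world with shared cell-type expression programs
#' observed through two assays: whole cells (`cell`) and nuclei (`nucleus`).
#' A configurable fraction of genes carries a systematic nucleus-vs-cell
#' abundance shift, emulating the loss of cytoplasmic transcripts in
#' single-nucleus data. Donor structure and variable library sizes are
#' modelled as per-cell multiplicative factors.
#'
#' @param n_genes Number of genes.
#' @param cell_types Data frame with columns `name`, `n_cell`, `n_nucleus`
#'   (cells per type per modality; a zero means the type is absent from that
#'   modality), or a named integer vector used for both modalities.
#' @param n_markers_per_type Marker genes per type, assigned disjointly.
#' @param marker_log2fc log2 fold elevation of a marker in its own type.
#' @param modality_effect_fraction Fraction of genes with a nucleus-specific
#'   abundance shift, in `[0, 1]`.
#' @param modality_log2fc_range Length-2 numeric `(lo, hi)`: the magnitude of
#'   each effect gene's log2 shift is drawn uniformly from this range.
#' @param modality_effect_sign `"both"` (default): each effect gene is
#'   either nuclear enriched or nuclear depleted with equal probability,
#'   mirroring real nucleus data where unspliced and nuclear-retained
#'   transcripts gain relative abundance while abundant cytoplasm-dominant
#'   programs lose it; `"depletion"` / `"enrichment"` force one direction.
#' @param modality_effect_weighted Sample effect genes with probability
#'   proportional to their baseline expression (default `TRUE`): the
#'   strongest nucleus-vs-cell differences in real data involve abundant
#'   transcripts (ribosomal and mitochondrial programs are cytoplasmic),
#'   which is what makes the distortion matter after normalization.
#' @param modality_type_sd Per-cell-type spread (sd, log2 scale) around each
#'   effect gene's central shift. Nuclear bias interacts with cell type in
#'   real tissue -- each type's cytoplasmic program differs, which is why
#'   cross-modality differential genes are called per cell type -- and a
#'   purely gene-global multiplier would be absorbed by per-gene scaling
#'   common to all reference types, leaving deconvolution untouched.
#' @param nb_dispersion Negative-binomial size parameter `theta`
#'   (variance `mu + mu^2 / theta`), shared by all genes.
#' @param library_size_lognorm Length-2 `(meanlog, sdlog)` of the per-cell
#'   library-size factor.
#' @param n_donors Number of donors; every donor contributes to both
#'   modalities.
#' @param donor_effect_sd sdlog of per-donor, per-gene lognormal multipliers.
#' @param base_mean_lognorm Length-2 `(meanlog, sdlog)` of baseline per-gene
#'   mean expression.
#' @param type_var_lognorm_sd Scale (sdlog) of graded cross-type expression
#'   heterogeneity on top of the shared baseline. Real cell types differ in
#'   thousands of genes by modest graded amounts, not only in discrete
#'   marker sets; this term gives every type a genome-wide expression
#'   fingerprint.
#' @param type_factor_dim Number of latent expression programs generating
#'   the cross-type heterogeneity: each type's log fingerprint is a linear
#'   combination of `type_factor_dim` gene modules, mirroring the low-rank
#'   co-expression structure of real transcriptomes (types lie on a
#'   low-dimensional manifold rather than spanning independent directions).
#' @param seed Integer seed; the whole generation is a pure function of the
#'   config including this seed.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_genes = 2000,
                             cell_types = c(typeA = 450, typeB = 300,
                                            typeC = 200, typeD = 120),
                             n_markers_per_type = 50,
                             marker_log2fc = 2,
                             modality_effect_fraction = 0.1,
                             modality_log2fc_range = c(1, 2),
                             modality_effect_sign = c("both", "depletion",
                                                      "enrichment"),
                             modality_effect_weighted = TRUE,
                             modality_type_sd = 1.25,
                             nb_dispersion = 10,
                             library_size_lognorm = c(0, 0.3),
                             n_donors = 4,
                             donor_effect_sd = 0.1,
                             base_mean_lognorm = c(0, 1),
                             type_var_lognorm_sd = 0.3,
                             type_factor_dim = 3,
                             seed = 1L) {
  modality_effect_sign <- match.arg(modality_effect_sign)
  if (!is.data.frame(cell_types)) {
    cell_types <- data.frame(name = names(cell_types),
                             n_cell = as.integer(cell_types),
                             n_nucleus = as.integer(cell_types))
  }
  cfg <- list(n_genes = as.integer(n_genes), cell_types = cell_types,
              n_markers_per_type = as.integer(n_markers_per_type),
              marker_log2fc = marker_log2fc,
              modality_effect_fraction = modality_effect_fraction,
              modality_log2fc_range = modality_log2fc_range,
              modality_effect_sign = modality_effect_sign,
              modality_effect_weighted = modality_effect_weighted,
              modality_type_sd = modality_type_sd,
              nb_dispersion = nb_dispersion,
              library_size_lognorm = library_size_lognorm,
              n_donors = as.integer(n_donors),
              donor_effect_sd = donor_effect_sd,
              base_mean_lognorm = base_mean_lognorm,
              type_var_lognorm_sd = type_var_lognorm_sd,
              type_factor_dim = as.integer(type_factor_dim),
              seed = as.integer(seed))
  stopifnot(cfg$n_genes >= 1,
            all(cfg$cell_types$n_cell >= 0), all(cfg$cell_types$n_nucleus >= 0),
            cfg$modality_effect_fraction >= 0, cfg$modality_effect_fraction <= 1,
            cfg$modality_log2fc_range[1] <= cfg$modality_log2fc_range[2],
            cfg$nb_dispersion > 0, cfg$n_donors >= 1, cfg$donor_effect_sd >= 0,
            cfg$type_var_lognorm_sd >= 0, cfg$type_factor_dim >= 1,
            cfg$modality_type_sd >= 0,
            cfg$n_markers_per_type * nrow(cfg$cell_types) <= cfg$n_genes)
  if (sum(cfg$cell_types$n_cell) + sum(cfg$cell_types$n_nucleus) == 0) {
    stop("degenerate config: no cells in either modality")
  }
  class(cfg) <- "synthetic_config"
  cfg
}

#' Generate a paired scRNA-seq / snRNA-seq dataset with known truth
#'
#' Counts are drawn gene-wise from a negative binomial with mean
#' `library_factor * donor_factor * base_mean(type, gene) *
#' modality_effect(gene)^[nucleus]` and shared dispersion. The same seed
#' always yields bit-identical output.
#'
#' @param config A [synthetic_config()].
#' @return A list with `sc` and `sn` (`labeled_counts`) and `truth`, a
#'   `synthetic_truth` list carrying the per-gene modality multipliers,
#'   per-type marker sets, per-donor effect matrix, and the types x genes
#'   base-mean matrix.
#' @export
generate_paired <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed, {
    G <- config$n_genes
    genes <- sprintf("g%05d", seq_len(G))
    types <- config$cell_types$name

    base <- stats::rlnorm(G, config$base_mean_lognorm[1], config$base_mean_lognorm[2])
    base_mean <- matrix(rep(base, each = length(types)), nrow = length(types),
                        dimnames = list(types, genes))
    if (config$type_var_lognorm_sd > 0) {
      ## fingerprint = shared low-rank module part + gene-specific residual,
      ## each carrying half the configured log-variance
      d <- config$type_factor_dim
      s2 <- config$type_var_lognorm_sd^2 / 2
      Fm <- matrix(stats::rnorm(length(types) * d), length(types), d)
      Wm <- matrix(stats::rnorm(d * G, 0, sqrt(s2 / d)), d, G)
      resid <- matrix(stats::rnorm(length(base_mean), 0, sqrt(s2)),
                      nrow = length(types))
      base_mean <- base_mean * exp(Fm %*% Wm + resid)
    }
    ## disjoint round-robin marker assignment
    marker_sets <- list()
    idx <- seq_len(config$n_markers_per_type * length(types))
    for (k in seq_along(types)) {
      mk <- idx[(idx - 1) %% length(types) + 1 == k]
      marker_sets[[types[k]]] <- genes[mk]
      base_mean[k, mk] <- base_mean[k, mk] * 2^config$marker_log2fc
    }

    n_eff <- round(config$modality_effect_fraction * G)
    effect <- rep(1, G); names(effect) <- genes
    effect_by_type <- matrix(1, length(types), G,
                             dimnames = list(types, genes))
    if (n_eff > 0) {
      prob <- if (isTRUE(config$modality_effect_weighted)) base else NULL
      eff_idx <- sample.int(G, n_eff, prob = prob)
      lfc <- stats::runif(n_eff, config$modality_log2fc_range[1],
                          config$modality_log2fc_range[2])
      lfc <- switch(config$modality_effect_sign,
                    depletion = -lfc,
                    enrichment = lfc,
                    both = lfc * sample(c(-1, 1), n_eff, replace = TRUE))
      effect[eff_idx] <- 2^lfc
      ## per-type realization of each gene's shift around its central value
      lfc_t <- matrix(rep(lfc, each = length(types)), length(types)) +
        matrix(stats::rnorm(length(types) * n_eff, 0,
                            config$modality_type_sd), length(types))
      effect_by_type[, eff_idx] <- 2^lfc_t
    }

    donors <- sprintf("donor%02d", seq_len(config$n_donors))
    donor_eff <- matrix(stats::rlnorm(config$n_donors * G, 0, config$donor_effect_sd),
                        nrow = config$n_donors, dimnames = list(donors, genes))

    draw_modality <- function(n_per_type, modality) {
      keep <- n_per_type > 0
      if (!any(keep)) return(NULL)
      n_cells <- sum(n_per_type)
      ct <- rep(types[keep], n_per_type[keep])
      dn <- sample(donors, n_cells, replace = TRUE)
      lib <- stats::rlnorm(n_cells, config$library_size_lognorm[1],
                           config$library_size_lognorm[2])
      mu <- base_mean[ct, , drop = FALSE] * donor_eff[dn, , drop = FALSE] * lib
      if (modality == "nucleus") mu <- mu * effect_by_type[ct, , drop = FALSE]
      vals <- matrix(stats::rnbinom(length(mu), mu = mu, size = config$nb_dispersion),
                     nrow = n_cells)
      labeled_counts(vals, cell_type = ct, modality = rep(modality, n_cells),
                     donor = dn, gene_ids = genes,
                     cell_ids = sprintf("%s_%05d", substr(modality, 1, 3),
                                        seq_len(n_cells)),
                     dataset_tag = "synthetic")
    }

    sc <- draw_modality(config$cell_types$n_cell, "cell")
    sn <- draw_modality(config$cell_types$n_nucleus, "nucleus")
    if (is.null(sc) && is.null(sn)) stop("degenerate config: no cells generated")

    truth <- structure(list(modality_effect = effect,
                            modality_effect_by_type = effect_by_type,
                            marker_sets = marker_sets,
                            donor_effects = donor_eff,
                            base_mean = base_mean,
                            config = config),
                       class = "synthetic_truth")
    list(sc = sc, sn = sn, truth = truth)
  })
}

#' Simulate a bulk RNA-seq cohort from known cell-type programs
#'
#' Each bulk sample is the proportion-weighted combination of the whole-cell
#' base-mean programs, scaled to a common library size, with multiplicative
#' lognormal noise.
#'
#' @param truth A `synthetic_truth` from [generate_paired()].
#' @param n_samples Number of bulk samples.
#' @param proportion_scheme `"random"` (flat Dirichlet) or a fixed numeric
#'   matrix (`n_samples` x types, rows summing to 1).
#' @param noise_sd sdlog of entry-wise lognormal noise (0 = none).
#' @param target_library Common per-sample total after scaling.
#' @param seed Integer seed.
#' @return List with `bulk` (a `bulk_matrix`) and `proportions`.
#' @export
generate_bulk_cohort <- function(truth, n_samples, proportion_scheme = "random",
                                 noise_sd = 0.1, target_library = 1e6,
                                 seed = 1L) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (n_samples <= 0) stop("n_samples must be positive")
  with_seed(seed, {
    types <- rownames(truth$base_mean)
    if (is.matrix(proportion_scheme)) {
      P <- proportion_scheme
      stopifnot(nrow(P) == n_samples, ncol(P) == length(types))
    } else {
      P <- matrix(stats::rgamma(n_samples * length(types), shape = 1),
                  nrow = n_samples)
      P <- P / rowSums(P)
    }
    colnames(P) <- types
    M <- P %*% truth$base_mean
    M <- cpm_rows(M, target_library)
    if (noise_sd > 0) {
      M <- M * matrix(stats::rlnorm(length(M), 0, noise_sd), nrow = n_samples)
    }
    bulk <- bulk_matrix(M, sample_ids = sprintf("bulk%04d", seq_len(n_samples)),
                        gene_ids = colnames(truth$base_mean))
    list(bulk = bulk, proportions = P)
  })
}

#' Serialize synthetic ground truth as plain text
#'
#' Writes the modality-effect multipliers and marker sets as TSV plus a JSON
#' manifest of the generating configuration.
#'
#' @param truth A `synthetic_truth`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_truth <- function(truth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(
    data.frame(gene = names(truth$modality_effect),
               modality_effect = unname(truth$modality_effect)),
    file.path(dir, "modality_effect.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  marker_tab <- data.frame(
    cell_type = rep(names(truth$marker_sets), lengths(truth$marker_sets)),
    gene = unlist(truth$marker_sets, use.names = FALSE))
  utils::write.table(marker_tab, file.path(dir, "marker_genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- truth$config
  cfg$cell_types <- as.list(cfg$cell_types)
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
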