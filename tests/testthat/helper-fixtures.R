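# Small in-code fixtures shared across test files.

# tiny labeled_counts with explicit values
tiny_lc <- function(values, types, modality = "cell", donors = NULL,
                    genes = NULL) {
  n <- nrow(values)
  if (length(modality) == 1) modality <- rep(modality, n)
  if (is.null(donors)) donors <- rep("d1", n)
  if (is.null(genes)) genes <- paste0("g", seq_len(ncol(values)))
  labeled_counts(values, cell_type = types, modality = modality,
                 donor = donors, gene_ids = genes)
}

# random integer labeled_counts
random_lc <- function(n_cells, n_genes, types = c("A", "B"),
                      modality = "cell", seed = 1, lambda = 5) {
  with_seed(seed, {
    vals <- matrix(rpois(n_cells * n_genes, lambda), n_cells)
    tiny_lc(vals, types = sample(types, n_cells, replace = TRUE),
            modality = modality,
            donors = sample(c("d1", "d2"), n_cells, replace = TRUE))
  })
}

# a small paired synthetic world (shared by several files; cheap to build)
small_world <- function(seed = 7, n_genes = 400,
                        cell_types = c(A = 90, B = 70, C = 60)) {
  generate_paired(synthetic_config(
    n_genes = n_genes, cell_types = cell_types, n_markers_per_type = 20,
    seed = seed))
}

# direct NB aggregate sampler for DE-engine calibration tests: two groups of
# replicate libraries drawn from gene-wise NB means
nb_aggregates <- function(n_per_side, n_genes, mean_range = c(5, 200),
                          theta = 50, lfc = NULL, seed = 1) {
  with_seed(seed, {
    mu <- exp(runif(n_genes, log(mean_range[1]), log(mean_range[2])))
    mu2 <- mu
    if (!is.null(lfc)) mu2 <- mu * 2^lfc
    vals <- rbind(
      matrix(rnbinom(n_per_side * n_genes, mu = rep(mu, each = n_per_side),
                     size = theta), n_per_side),
      matrix(rnbinom(n_per_side * n_genes, mu = rep(mu2, each = n_per_side),
                     size = theta), n_per_side))
    colnames(vals) <- paste0("g", seq_len(n_genes))
    structure(list(values = vals,
                   cell_type = rep("T", 2 * n_per_side),
                   modality = rep(c("cell", "nucleus"), each = n_per_side),
                   replicate = rep(seq_len(n_per_side), 2),
                   membership = NULL, gene_ids = colnames(vals),
                   group_size = 10, low_replicate = character()),
              class = "aggregate_matrix")
  })
}
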