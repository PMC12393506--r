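#' Draw a cell-type proportion vector and its integer cell allocation
#'
#' Two schemes are provided. `random` draws from a flat Dirichlet (equal
#' concentration parameters of 1). `realistic` jitters an empirical base
#' proportion vector with Gaussian noise (sd `prop_noise_sd`) and
#' renormalizes. The proportion vector is converted to integer counts of
#' `total_cells` cells by floor allocation with largest-remainder top-up; if
#' any type receives zero cells the draw is repeated.
#'
#' @param scheme `"random"` or `"realistic"`.
#' @param cell_types Character vector of type names.
#' @param total_cells Cells per pseudobulk (default 1000).
#' @param base Empirical base proportions (required for `realistic`).
#' @param prop_noise_sd Gaussian sd of the realistic-scheme jitter
#'   (default 0.01).
#' @param max_retries Resampling cap before erroring.
#' @return List with `proportions` (= counts / total_cells) and `counts`.
#' @export
sample_proportions <- function(scheme = c("random", "realistic"), cell_types,
                               total_cells = 1000, base = NULL,
                               prop_noise_sd = 0.01, max_retries = 1000) {
  scheme <- match.arg(scheme)
  k <- length(cell_types)
  if (total_cells < k) stop("total_cells < number of cell types: every type needs a cell")
  if (scheme == "realistic") {
    if (is.null(base)) stop("realistic scheme requires empirical base proportions")
    if (any(base < 0) || sum(base) <= 0) stop("base proportions not normalizable")
    base <- base / sum(base)
  }
  for (try in seq_len(max_retries)) {
    p <- if (scheme == "random") {
      g <- stats::rgamma(k, shape = 1)
      g / sum(g)
    } else {
      v <- pmax(base + stats::rnorm(k, 0, prop_noise_sd), 0)
      if (sum(v) == 0) next
      v / sum(v)
    }
    counts <- allocate_counts(p, total_cells)
    if (all(counts > 0)) {
      names(counts) <- cell_types
      return(list(proportions = counts / total_cells, counts = counts))
    }
  }
  stop("failed to draw an allocation with every cell type represented")
}

## floor then largest-remainder top-up; counts always sum to total
allocate_counts <- function(p, total) {
  raw <- p * total
  counts <- floor(raw)
  rem <- total - sum(counts)
  if (rem > 0) {
    frac <- raw - counts
    top <- order(frac, decreasing = TRUE)[seq_len(rem)]
    counts[top] <- counts[top] + 1
  }
  as.integer(counts)
}

#' Build pseudobulks of known proportions from single-cell data
#'
#' For each pseudobulk, a proportion vector is drawn ([sample_proportions()]),
#' the required number of cells per type is sampled from the source (without
#' replacement when enough cells are available, with replacement otherwise),
#' their expression profiles are summed, entry-wise Gaussian noise is added,
#' and negative values are clipped to zero. The default 500 + 500 samples per
#' scheme yield 1000 pseudobulks. The sampled cell indices are kept as a
#' manifest so any pseudobulk can be audited or rebuilt.
#'
#' @param source A single-modality `labeled_counts`.
#' @param n_random,n_realistic Pseudobulks per proportion scheme.
#' @param total_cells Cells per pseudobulk.
#' @param noise_sd Gaussian noise sd on the summed count scale (default 0.05).
#' @param prop_noise_sd Realistic-scheme proportion jitter sd.
#' @param seed Integer seed.
#' @return A `pseudobulk_set`: `bulk` (`bulk_matrix`), `proportions`,
#'   `cell_counts`, `scheme`, `manifest` (list of per-type cell index
#'   vectors), and the generating parameters.
#' @export
build_pseudobulks <- function(source, n_random = 500, n_realistic = 500,
                              total_cells = 1000, noise_sd = 0.05,
                              prop_noise_sd = 0.01, seed = 1L) {
  stopifnot(inherits(source, "labeled_counts"))
  if (length(unique(source$modality)) != 1L) {
    stop("pseudobulk source must use a single modality")
  }
  types <- sort(unique(source$cell_type))
  idx_by_type <- split(seq_along(source$cell_type), source$cell_type)[types]
  emp <- lengths(idx_by_type) / length(source$cell_type)
  vals <- as_dense(source$values)
  n_pb <- n_random + n_realistic
  schemes <- rep(c("random", "realistic"), c(n_random, n_realistic))

  with_seed(seed, {
    P <- matrix(0, n_pb, length(types), dimnames = list(NULL, types))
    K <- matrix(0L, n_pb, length(types), dimnames = list(NULL, types))
    B <- matrix(0, n_pb, ncol(vals))
    manifest <- vector("list", n_pb)
    for (i in seq_len(n_pb)) {
      draw <- sample_proportions(schemes[i], types, total_cells,
                                 base = if (schemes[i] == "realistic") emp,
                                 prop_noise_sd = prop_noise_sd)
      K[i, ] <- draw$counts
      P[i, ] <- draw$proportions
      picked <- lapply(types, function(ty) {
        pool <- idx_by_type[[ty]]
        k <- draw$counts[[ty]]
        sample(pool, k, replace = k > length(pool))
      })
      names(picked) <- types
      manifest[[i]] <- picked
      B[i, ] <- colSums(vals[unlist(picked), , drop = FALSE])
    }
    if (noise_sd > 0) {
      B <- B + matrix(stats::rnorm(length(B), 0, noise_sd), nrow = n_pb)
      B[B < 0] <- 0
    }
    bulk <- bulk_matrix(B, sample_ids = sprintf("pb%04d", seq_len(n_pb)),
                        gene_ids = source$gene_ids)
    structure(list(bulk = bulk, proportions = P, cell_counts = K,
                   scheme = schemes, manifest = manifest,
                   total_cells = total_cells, noise_sd = noise_sd,
                   seed = seed),
              class = "pseudobulk_set")
  })
}

#' @export
print.pseudobulk_set <- function(x, ...) {
  cat(sprintf("<pseudobulk_set> %d samples (%d random, %d realistic), %d types, %d genes\n",
              nrow(x$proportions), sum(x$scheme == "random"),
              sum(x$scheme == "realistic"), ncol(x$proportions),
              ncol(x$bulk$values)))
  invisible(x)
}

#' Rebuild pseudobulk profiles from the sampling manifest
#'
#' Re-sums the recorded member cells of each pseudobulk; with `noise_sd = 0`
#' this reproduces the stored bulk matrix bit-exactly.
#'
#' @param pb A `pseudobulk_set`.
#' @param source The `labeled_counts` it was built from.
#' @return A numeric matrix of re-summed profiles.
#' @export
rebuild_from_manifest <- function(pb, source) {
  vals <- as_dense(source$values)
  t(vapply(pb$manifest,
           function(picked) colSums(vals[unlist(picked), , drop = FALSE]),
           numeric(ncol(vals))))
}

#' Serialize a pseudobulk set
#'
#' Writes the bulk TSV, the ground-truth proportions CSV, and a JSON manifest
#' of sampled cell ids and parameters.
#'
#' @param pb A `pseudobulk_set`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_pseudobulks <- function(pb, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_bulk(pb$bulk, file.path(dir, "pseudobulk.tsv"))
  ptab <- cbind(data.frame(sample_id = pb$bulk$sample_ids, scheme = pb$scheme),
                as.data.frame(pb$proportions))
  utils::write.csv(ptab, file.path(dir, "proportions.csv"), row.names = FALSE)
  jsonlite::write_json(list(total_cells = pb$total_cells, noise_sd = pb$noise_sd,
                            seed = pb$seed, manifest = pb$manifest),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
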