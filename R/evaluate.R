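#' Pearson and RMSE of one sample's proportion estimate
#'
#' The three evaluation scenarios are: `all` (every cell type in the
#' pseudobulk), `non_removed` (the held-out type is dropped from both
#' vectors before scoring), and `removed_only` (handled by
#' [score_removed()], which pools the held-out type's proportion across
#' samples, since a per-sample correlation over one value is undefined).
#'
#' @param true_p,est_p Named proportion vectors aligned on the same types.
#' @param scenario `"all"` or `"non_removed"`.
#' @param held_out Held-out type (needed for `non_removed`).
#' @return Named vector `c(pearson, rmse)`; Pearson is `NA` (with a message)
#'   when either subvector is constant.
#' @export
score_sample <- function(true_p, est_p, scenario = c("all", "non_removed"),
                         held_out = NULL) {
  scenario <- match.arg(scenario)
  stopifnot(length(true_p) == length(est_p))
  if (!is.null(names(true_p)) && !is.null(names(est_p))) {
    stopifnot(identical(names(true_p), names(est_p)))
  }
  if (scenario == "non_removed") {
    if (is.null(held_out)) stop("non_removed scenario needs the held-out type")
    keep <- names(true_p) != held_out
    true_p <- true_p[keep]; est_p <- est_p[keep]
  }
  pearson_rmse(true_p, est_p)
}

#' @rdname score_sample
#' @param true_col,est_col The held-out type's true and estimated proportion
#'   across all samples.
#' @export
score_removed <- function(true_col, est_col) {
  pearson_rmse(true_col, est_col)
}

pearson_rmse <- function(a, b) {
  r <- if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    message("constant vector: Pearson undefined, returning NA")
    NA_real_
  } else stats::cor(a, b)
  c(pearson = r, rmse = sqrt(mean((a - b)^2)))
}

#' Per-sample evaluation records for one deconvolution run
#'
#' Builds the tidy evaluation table: one row per sample for the `all` and
#' `non_removed` scenarios and one pooled row (`sample_id = "pooled"`) for
#' `removed_only`.
#'
#' @param truth True proportion matrix (samples x types).
#' @param result A `deconvolution_result` on the same samples.
#' @param transform Transform label for the records.
#' @param dataset Dataset label.
#' @param held_out Held-out type, or `NULL` (controls: only `all` records).
#' @return Data frame with columns `dataset`, `transform`, `held_out`,
#'   `scenario`, `sample_id`, `pearson`, `rmse`.
#' @export
evaluate_deconvolution <- function(truth, result, transform, dataset = "synthetic",
                                   held_out = NULL) {
  est <- result$proportions
  types <- colnames(truth)
  stopifnot(!is.null(types))
  est_full <- matrix(0, nrow(est), length(types),
                     dimnames = list(rownames(est), types))
  shared <- intersect(colnames(est), types)
  est_full[, shared] <- est[, shared]
  rec <- list()
  for (i in seq_len(nrow(truth))) {
    s <- suppressMessages(score_sample(truth[i, ], est_full[i, ], "all"))
    rec[[length(rec) + 1L]] <- data.frame(
      dataset = dataset, transform = transform,
      held_out = held_out %||% NA_character_, scenario = "all",
      sample_id = rownames(est)[i] %||% as.character(i),
      pearson = s[["pearson"]], rmse = s[["rmse"]])
    if (!is.null(held_out)) {
      s2 <- suppressMessages(score_sample(truth[i, ], est_full[i, ],
                                          "non_removed", held_out))
      rec[[length(rec) + 1L]] <- data.frame(
        dataset = dataset, transform = transform, held_out = held_out,
        scenario = "non_removed",
        sample_id = rownames(est)[i] %||% as.character(i),
        pearson = s2[["pearson"]], rmse = s2[["rmse"]])
    }
  }
  if (!is.null(held_out) && held_out %in% types) {
    s3 <- suppressMessages(score_removed(truth[, held_out], est_full[, held_out]))
    rec[[length(rec) + 1L]] <- data.frame(
      dataset = dataset, transform = transform, held_out = held_out,
      scenario = "removed_only", sample_id = "pooled",
      pearson = s3[["pearson"]], rmse = s3[["rmse"]])
  }
  do.call(rbind, rec)
}

#' Percentile bootstrap confidence interval of the mean
#'
#' @param values Numeric vector (NAs dropped).
#' @param n_boot Bootstrap resamples (default 1000).
#' @param level Confidence level (default 0.95).
#' @param seed Integer seed.
#' @return Named vector `c(mean, lo, hi)`.
#' @export
bootstrap_mean_ci <- function(values, n_boot = 1000, level = 0.95, seed = 1L) {
  values <- values[is.finite(values)]
  if (length(values) == 0) stop("no finite values to bootstrap")
  with_seed(seed, {
    means <- vapply(seq_len(n_boot),
                    function(i) mean(sample(values, replace = TRUE)),
                    numeric(1))
    qs <- stats::quantile(means, c((1 - level) / 2, 1 - (1 - level) / 2),
                          names = FALSE)
    c(mean = mean(values), lo = qs[1], hi = qs[2])
  })
}

#' Two-sample pooled-variance t-test
#'
#' Equal-variance two-tailed t-test; missing values are dropped pairwise.
#' When the pooled variance is zero with equal means the statistic is
#' defined as 0 with p = 1.
#'
#' @param a,b Numeric samples (each n >= 2 after NA removal).
#' @return Named vector `c(t, p)`.
#' @export
t_test_equal_var <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2 || length(b) < 2) stop("both samples need n >= 2")
  sp <- ((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) /
    (length(a) + length(b) - 2)
  if (sp == 0) {
    if (mean(a) == mean(b)) return(c(t = 0, p = 1))
  }
  ht <- stats::t.test(a, b, var.equal = TRUE)
  c(t = unname(ht$statistic), p = ht$p.value)
}

#' Cosine similarity of aggregated cell-type expression profiles
#'
#' Samples `n_cells` cells of the type from each side (with replacement,
#' logged, if fewer are available), sums them into one profile, scales to
#' counts per million, log1p-transforms, and returns the cosine similarity.
#'
#' @param a,b Gene-aligned `labeled_counts`.
#' @param cell_type Type to compare.
#' @param n_cells Cells sampled per side (default 50).
#' @param seed Integer seed.
#' @return Cosine similarity in `[-1, 1]`.
#' @export
cosine_profiles <- function(a, b, cell_type, n_cells = 50, seed = 1L) {
  stopifnot(identical(a$gene_ids, b$gene_ids))
  profile_of <- function(lc, tag) {
    pool <- which(lc$cell_type == cell_type)
    if (length(pool) == 0) stop("cell type absent from ", tag)
    if (length(pool) < n_cells) {
      message(sprintf("%s has %d < %d cells of type %s; sampling with replacement",
                      tag, length(pool), n_cells, cell_type))
    }
    # both sides draw under the same seed, so identical inputs give cosine 1
    idx <- with_seed(seed, sample(pool, n_cells,
                                  replace = length(pool) < n_cells))
    v <- colSums(as_dense(lc$values)[idx, , drop = FALSE])
    log1p(v / sum(v) * 1e6)
  }
  cosine_vec(profile_of(a, "a"), profile_of(b, "b"))
}

#' Cosine similarity between two sets of predicted proportions
#'
#' Both proportion matrices are flattened row-major into long vectors and
#' compared by cosine similarity.
#'
#' @param resA,resB `deconvolution_result`s over the same samples and types.
#' @return Cosine similarity.
#' @export
cosine_proportions <- function(resA, resB) {
  A <- resA$proportions; B <- resB$proportions
  if (!all(dim(A) == dim(B))) stop("proportion matrices differ in shape")
  if (!is.null(colnames(A)) && !is.null(colnames(B)) &&
      !identical(colnames(A), colnames(B))) {
    stop("proportion matrices differ in type order")
  }
  cosine_vec(as.numeric(t(A)), as.numeric(t(B)))
}

#' Inter-transform and inter-donor robustness tables
#'
#' @param by_transform Named list of `deconvolution_result`s, one per
#'   transform (same bulks).
#' @param by_donor Named list (per transform) of named lists of
#'   `deconvolution_result`s, one per donor.
#' @return A `robustness_table`: `transform_pair` (symmetric cosine matrix)
#'   and `donor_pair` (per-transform donor x donor cosine matrices).
#' @export
robustness_tables <- function(by_transform, by_donor = NULL) {
  nm <- names(by_transform)
  M <- matrix(1, length(nm), length(nm), dimnames = list(nm, nm))
  if (length(nm) > 1) {
    for (i in seq_along(nm)) for (j in seq_along(nm)) {
      if (i < j) {
        M[i, j] <- M[j, i] <- cosine_proportions(by_transform[[i]],
                                                 by_transform[[j]])
      }
    }
  }
  donor <- NULL
  if (!is.null(by_donor)) {
    donor <- lapply(by_donor, function(runs) {
      dn <- names(runs)
      D <- matrix(1, length(dn), length(dn), dimnames = list(dn, dn))
      for (i in seq_along(dn)) for (j in seq_along(dn)) {
        if (i < j) D[i, j] <- D[j, i] <- cosine_proportions(runs[[i]], runs[[j]])
      }
      D
    })
  }
  structure(list(transform_pair = M, donor_pair = donor),
            class = "robustness_table")
}

minmax <- function(x) {
  rng <- range(x, na.rm = TRUE)
  if (diff(rng) == 0) {
    message("degenerate min-max scaling (all values equal): returning zeros")
    return(rep(0, length(x)))
  }
  (x - rng[1]) / diff(rng)
}

#' Composite accuracy and robustness scores per transform
#'
#' Accuracy: within each dataset, per-sample Pearson values and inverted
#' RMSE values (dataset maximum minus value) are min-max scaled to `[0, 1]`
#' across all of that dataset's records, averaged per transform within the
#' dataset, then averaged across datasets; the accuracy score is the mean of
#' the two resulting normalized metrics. Robustness: the pooled off-diagonal
#' transform-pair cosines and the pooled donor-pair cosines are each min-max
#' scaled over their own pooled list and averaged per transform; the
#' robustness score is the mean of the two components.
#'
#' @param records Evaluation table from [evaluate_deconvolution()] (rows of
#'   the scenario you want scored, typically `all`).
#' @param robustness A `robustness_table`, or `NULL` for accuracy only.
#' @return A `composite_scores` data frame: one row per transform with
#'   `accuracy_score`, `robustness_score` and their components.
#' @export
composite_scores <- function(records, robustness = NULL) {
  stopifnot(all(c("dataset", "transform", "pearson", "rmse") %in% names(records)))
  transforms <- unique(records$transform)
  if (length(transforms) < 2) stop("composite scores need >= 2 transforms")
  per_dataset <- lapply(split(records, records$dataset), function(d) {
    ok <- is.finite(d$pearson) & is.finite(d$rmse)
    if (!all(ok)) message(sprintf("excluding %d record(s) with missing metrics",
                                  sum(!ok)))
    d <- d[ok, , drop = FALSE]
    np <- minmax(d$pearson)
    nr <- minmax(max(d$rmse) - d$rmse)
    data.frame(transform = d$transform, norm_pearson = np, norm_rmse = nr)
  })
  agg <- do.call(rbind, lapply(names(per_dataset), function(ds) {
    d <- per_dataset[[ds]]
    out <- aggregate(cbind(norm_pearson, norm_rmse) ~ transform, d, mean)
    out$dataset <- ds
    out
  }))
  acc <- aggregate(cbind(norm_pearson, norm_rmse) ~ transform, agg, mean)
  missing_tr <- setdiff(transforms, acc$transform)
  if (length(missing_tr)) {
    warning("transform(s) absent from some dataset: ",
            paste(missing_tr, collapse = ", "))
  }
  acc$accuracy_score <- (acc$norm_pearson + acc$norm_rmse) / 2

  if (!is.null(robustness)) {
    M <- robustness$transform_pair
    off <- M[upper.tri(M) | lower.tri(M)]
    scaledM <- M
    scaledM[upper.tri(M) | lower.tri(M)] <- minmax(off)
    per_transform <- vapply(rownames(M), function(tr) {
      mean(scaledM[tr, setdiff(colnames(M), tr)])
    }, numeric(1))
    per_donor <- rep(NA_real_, nrow(M)); names(per_donor) <- rownames(M)
    if (!is.null(robustness$donor_pair)) {
      pooled <- unlist(lapply(robustness$donor_pair,
                              function(D) D[upper.tri(D)]))
      rng <- range(pooled)
      scale_fun <- if (diff(rng) == 0) {
        message("degenerate min-max scaling (all values equal): returning zeros")
        function(x) rep(0, length(x))
      } else function(x) (x - rng[1]) / diff(rng)
      for (tr in names(robustness$donor_pair)) {
        D <- robustness$donor_pair[[tr]]
        per_donor[tr] <- mean(scale_fun(D[upper.tri(D)]))
      }
    }
    rb <- data.frame(transform = rownames(M), per_transform_score = per_transform,
                     per_donor_score = per_donor)
    rb$robustness_score <- rowMeans(rb[, c("per_transform_score",
                                           "per_donor_score")], na.rm = TRUE)
    acc <- merge(acc, rb, by = "transform", all.x = TRUE)
  }
  class(acc) <- c("composite_scores", "data.frame")
  acc
}
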