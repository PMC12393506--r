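#' Build and validate a pipeline run configuration
#'
#' A run configuration bundles every knob of the end-to-end benchmark:
#' synthetic-world parameters, pseudobulk counts and noise, DE-test
#' aggregation and threshold, transform parameters, the reference variants
#' to benchmark, the master seed, and the output directory. Values can also
#' be loaded from a YAML file with [read_run_config()]; explicit arguments
#' override file keys.
#'
#' @param out_dir Output directory for stage artifacts.
#' @param seed Master seed (mandatory); every stage derives its own stream
#'   from it.
#' @param synthetic List of [synthetic_config()] overrides.
#' @param n_random,n_realistic,total_cells,noise_sd Pseudobulk parameters.
#' @param group_size,alpha DE aggregation size and adjusted-p threshold.
#' @param variants Character vector of reference-variant codes to run.
#' @param var_threshold,k PCA-shift parameters.
#' @param vae List of [fit_vae()] overrides (epochs, hidden width, ...).
#' @return A validated `run_config`.
#' @export
run_config <- function(out_dir, seed, synthetic = list(),
                       n_random = 500, n_realistic = 500, total_cells = 1000,
                       noise_sd = 0.05, group_size = 10, alpha = 0.01,
                       variants = c("pos_ctrl", "neg_ctrl", "sn_raw",
                                    "sn_minus_deg", "pca"),
                       var_threshold = 0.75, k = 10, vae = list()) {
  if (missing(seed) || is.null(seed)) stop("a master seed is mandatory")
  bad <- setdiff(variants, transform_variants()$code)
  if (length(bad)) stop("unknown variant(s): ", paste(bad, collapse = ", "))
  stopifnot(n_random >= 0, n_realistic >= 0, total_cells >= 1,
            noise_sd >= 0, group_size >= 1, alpha > 0, alpha < 1,
            var_threshold > 0, var_threshold <= 1, k >= 1)
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 synthetic = synthetic, n_random = n_random,
                 n_realistic = n_realistic, total_cells = total_cells,
                 noise_sd = noise_sd, group_size = group_size, alpha = alpha,
                 variants = variants, var_threshold = var_threshold, k = k,
                 vae = vae),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML file of configuration keys.
#' @param ... Overrides passed on to [run_config()].
#' @export
read_run_config <- function(path, ...) {
  keys <- yaml::read_yaml(path)
  over <- list(...)
  keys[names(over)] <- over
  do.call(run_config, keys)
}

stage_dir <- function(config, stage) file.path(config$out_dir, stage)

write_manifest <- function(config, stage, params, inputs = character()) {
  hashes <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  jsonlite::write_json(
    list(stage = stage, seed = config$seed, params = params,
         input_hashes = hashes,
         package_version = as.character(utils::packageVersion("refblend"))),
    file.path(stage_dir(config, stage), "manifest.json"),
    auto_unbox = TRUE, digits = NA)
}

need_stage <- function(config, stage) {
  f <- file.path(stage_dir(config, stage), "state.rds")
  if (!file.exists(f)) {
    stop(sprintf("missing artifacts of stage '%s'; run run_stage(\"%s\", config) first",
                 stage, stage))
  }
  readRDS(f)
}

#' Run one pipeline stage
#'
#' Stages: `simulate` (paired synthetic data), `pseudobulk`, `deg`
#' (aggregates + modality DE + gene-set catalog), `train` (PCA/VAE models per
#' held-out type), `transform` (reference panels), `deconvolve`, `evaluate`,
#' `report`. Each stage writes its text artifacts plus a `manifest.json`
#' (seed, parameters, input hashes, package version) and an R-level
#' `state.rds` cache under `out_dir/<stage>/`. Rerunning a stage with
#' identical inputs and seed reproduces its outputs.
#'
#' @param stage Stage name.
#' @param config A `run_config`.
#' @return The stage's main artifact, invisibly.
#' @export
run_stage <- function(stage = c("simulate", "pseudobulk", "deg", "train",
                                "transform", "deconvolve", "evaluate",
                                "report"),
                      config) {
  stage <- match.arg(stage)
  stopifnot(inherits(config, "run_config"))
  dir.create(stage_dir(config, stage), recursive = TRUE, showWarnings = FALSE)
  out <- switch(stage,
    simulate = stage_simulate(config),
    pseudobulk = stage_pseudobulk(config),
    deg = stage_deg(config),
    train = stage_train(config),
    transform = stage_transform(config),
    deconvolve = stage_deconvolve(config),
    evaluate = stage_evaluate(config),
    report = stage_report(config))
  invisible(out)
}

#' @rdname run_stage
#' @export
run_pipeline <- function(config) {
  for (s in c("simulate", "pseudobulk", "deg", "transform", "deconvolve",
              "evaluate", "report")) {
    run_stage(s, config)
  }
  invisible(config$out_dir)
}

stage_simulate <- function(config) {
  sd <- stage_dir(config, "simulate")
  cfg <- do.call(synthetic_config,
                 c(config$synthetic,
                   list(seed = derive_seed(config$seed, "simulate"))[
                     !"seed" %in% names(config$synthetic)]))
  world <- generate_paired(cfg)
  write_counts(world$sc, file.path(sd, "sc"), "mtx")
  write_counts(world$sn, file.path(sd, "sn"), "mtx")
  write_truth(world$truth, file.path(sd, "truth"))
  saveRDS(world, file.path(sd, "state.rds"))
  write_manifest(config, "simulate", unclass(cfg)["n_genes"])
  world
}

stage_pseudobulk <- function(config) {
  world <- need_stage(config, "simulate")
  sd <- stage_dir(config, "pseudobulk")
  ## pseudobulks come from donors disjoint from the reference pool
  donors <- sort(unique(world$sc$donor))
  pb_donors <- donors[seq_len(max(1, length(donors) %/% 2))]
  src <- subset_cells(world$sc, world$sc$donor %in% pb_donors)
  pb <- build_pseudobulks(src, n_random = config$n_random,
                          n_realistic = config$n_realistic,
                          total_cells = config$total_cells,
                          noise_sd = config$noise_sd,
                          seed = derive_seed(config$seed, "pseudobulk"))
  write_pseudobulks(pb, sd)
  saveRDS(list(pb = pb, pb_donors = pb_donors), file.path(sd, "state.rds"))
  write_manifest(config, "pseudobulk",
                 list(n_random = config$n_random,
                      n_realistic = config$n_realistic,
                      total_cells = config$total_cells,
                      noise_sd = config$noise_sd),
                 file.path(stage_dir(config, "simulate"), "state.rds"))
  pb
}

## reference pool: donors not used for pseudobulks
reference_pool <- function(config) {
  world <- need_stage(config, "simulate")
  pbs <- need_stage(config, "pseudobulk")
  ref_donors <- setdiff(sort(unique(world$sc$donor)), pbs$pb_donors)
  if (!length(ref_donors)) ref_donors <- sort(unique(world$sc$donor))
  sc_ref <- subset_cells(world$sc, world$sc$donor %in% ref_donors)
  list(sc = sc_ref, sn = world$sn)
}

stage_deg <- function(config) {
  pool <- reference_pool(config)
  sd <- stage_dir(config, "deg")
  both <- bind_cells(pool$sc, pool$sn)
  agg <- make_aggregates(both, group_size = config$group_size,
                         seed = derive_seed(config$seed, "deg"))
  shared <- intersect(unique(pool$sc$cell_type), unique(pool$sn$cell_type))
  de <- lapply(shared, function(ty) de_test(agg, ty))
  names(de) <- shared
  catalog <- build_catalog(list(synthetic = de), alpha = config$alpha,
                           random_seed = derive_seed(config$seed, "deg_random"))
  for (ty in shared) {
    utils::write.csv(de[[ty]], file.path(sd, paste0("de_", ty, ".csv")),
                     row.names = FALSE)
  }
  write_catalog(catalog, sd)
  saveRDS(list(de = de, catalog = catalog), file.path(sd, "state.rds"))
  write_manifest(config, "deg",
                 list(group_size = config$group_size, alpha = config$alpha),
                 file.path(stage_dir(config, "simulate"), "state.rds"))
  catalog
}

held_out_types <- function(config) {
  pool <- reference_pool(config)
  sort(intersect(unique(pool$sc$cell_type), unique(pool$sn$cell_type)))
}

stage_train <- function(config) {
  pool <- reference_pool(config)
  sd <- stage_dir(config, "train")
  needs_vae <- any(grepl("^vae", config$variants))
  needs_pca <- any(grepl("^pca", config$variants))
  models <- list()
  for (h in held_out_types(config)) {
    sc_tr <- subset_cells(pool$sc, pool$sc$cell_type != h)
    sn_ov <- subset_cells(pool$sn, pool$sn$cell_type != h)
    entry <- list()
    if (needs_pca) {
      entry$pca <- fit_pca_shift(sc_tr, sn_ov,
                                 var_threshold = config$var_threshold,
                                 k = config$k)
    }
    if (any(c("vae_ls", "vae_ls_minus_deg") %in% config$variants)) {
      entry$vae <- do.call(fit_vae, c(
        list(train = bind_cells(sc_tr, sn_ov), conditional = FALSE,
             held_out = h, seed = derive_seed(config$seed, "train", h)),
        config$vae))
    }
    if (any(c("vae_cond", "vae_cond_minus_deg") %in% config$variants)) {
      entry$vae_cond <- do.call(fit_vae, c(
        list(train = bind_cells(sc_tr, sn_ov), conditional = TRUE,
             held_out = h, seed = derive_seed(config$seed, "train_cond", h)),
        config$vae))
    }
    models[[h]] <- entry
  }
  saveRDS(models, file.path(sd, "state.rds"))
  write_manifest(config, "train",
                 list(var_threshold = config$var_threshold, k = config$k,
                      vae = config$vae, pca = needs_pca, vae_used = needs_vae))
  models
}

stage_transform <- function(config) {
  pool <- reference_pool(config)
  sd <- stage_dir(config, "transform")
  catalog <- NULL
  specs_need_catalog <- any(transform_variants()$needs_catalog[
    match(config$variants, transform_variants()$code)])
  if (specs_need_catalog) {
    catalog <- need_stage(config, "deg")$catalog
  }
  models_by_type <- if (file.exists(file.path(stage_dir(config, "train"),
                                              "state.rds"))) {
    readRDS(file.path(stage_dir(config, "train"), "state.rds"))
  } else list()
  al <- align_genes(sc = pool$sc, sn = pool$sn)
  panels <- list()
  for (v in config$variants) {
    row <- transform_variants()[transform_variants()$code == v, ]
    hs <- if (row$needs_held_out) held_out_types(config) else list(NULL)
    for (h in hs) {
      spec <- transform_spec(v, held_out = h)
      key <- if (is.null(h)) v else paste(v, h, sep = ":")
      panels[[key]] <- assemble_reference(
        spec, al$sc, al$sn, catalog = catalog, dataset = "synthetic",
        models = if (is.null(h)) NULL else models_by_type[[h]],
        vae_args = config$vae,
        seed = derive_seed(config$seed, "transform", key))
    }
  }
  saveRDS(panels, file.path(sd, "state.rds"))
  writeLines(names(panels), file.path(sd, "panels.txt"))
  write_manifest(config, "transform", list(variants = config$variants))
  panels
}

stage_deconvolve <- function(config) {
  pbs <- need_stage(config, "pseudobulk")
  panels <- need_stage(config, "transform")
  sd <- stage_dir(config, "deconvolve")
  results <- lapply(panels, function(p) deconvolve(pbs$pb$bulk, p))
  for (key in names(results)) {
    write_proportions(results[[key]],
                      file.path(sd, paste0("proportions_",
                                           gsub("[^A-Za-z0-9_]", "_", key),
                                           ".csv")))
  }
  saveRDS(results, file.path(sd, "state.rds"))
  write_manifest(config, "deconvolve", list(backend = "nnls"))
  results
}

stage_evaluate <- function(config) {
  pbs <- need_stage(config, "pseudobulk")
  panels <- need_stage(config, "transform")
  results <- need_stage(config, "deconvolve")
  sd <- stage_dir(config, "evaluate")
  records <- do.call(rbind, lapply(names(results), function(key) {
    evaluate_deconvolution(pbs$pb$proportions, results[[key]],
                           transform = panels[[key]]$spec$label,
                           dataset = "synthetic",
                           held_out = panels[[key]]$held_out)
  }))
  utils::write.csv(records, file.path(sd, "records.csv"), row.names = FALSE)
  saveRDS(records, file.path(sd, "state.rds"))
  write_manifest(config, "evaluate", list())
  records
}

stage_report <- function(config) {
  records <- need_stage(config, "evaluate")
  results <- need_stage(config, "deconvolve")
  panels <- need_stage(config, "transform")
  sd <- stage_dir(config, "report")
  summarize <- function(d, i) {
    ci <- bootstrap_mean_ci(d$pearson[i],
                            seed = derive_seed(config$seed, "report"))
    rci <- bootstrap_mean_ci(d$rmse[i],
                             seed = derive_seed(config$seed, "report_rmse"))
    data.frame(pearson_mean = ci[["mean"]], pearson_lo = ci[["lo"]],
               pearson_hi = ci[["hi"]], rmse_mean = rci[["mean"]],
               rmse_lo = rci[["lo"]], rmse_hi = rci[["hi"]])
  }
  summary_tab <- do.call(rbind, lapply(
    split(records, list(records$transform, records$scenario), drop = TRUE),
    function(d) cbind(data.frame(transform = d$transform[1],
                                 scenario = d$scenario[1]),
                      summarize(d, is.finite(d$pearson)))))
  utils::write.csv(summary_tab, file.path(sd, "summary_by_transform.csv"),
                   row.names = FALSE)
  ## inter-transform robustness on the shared pseudobulks (one run per
  ## variant; held-out runs of the same variant averaged through pooling)
  labels <- vapply(panels, function(p) p$spec$label, "")
  one_per_label <- results[!duplicated(labels)]
  names(one_per_label) <- labels[!duplicated(labels)]
  shapes <- vapply(one_per_label, function(r) ncol(r$proportions), 0L)
  comparable <- one_per_label[shapes == max(shapes)]
  rob <- if (length(comparable) > 1) robustness_tables(comparable) else NULL
  if (!is.null(rob)) {
    utils::write.csv(rob$transform_pair,
                     file.path(sd, "transform_cosine.csv"))
  }
  scores <- tryCatch(
    composite_scores(records[records$scenario == "all", ], rob),
    error = function(e) NULL)
  if (!is.null(scores)) {
    utils::write.csv(scores, file.path(sd, "composite_scores.csv"),
                     row.names = FALSE)
  }
  saveRDS(list(summary = summary_tab, robustness = rob, scores = scores),
          file.path(sd, "state.rds"))
  write_manifest(config, "report", list())
  list(summary = summary_tab, robustness = rob, scores = scores)
}
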