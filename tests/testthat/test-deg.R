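test_that("aggregates are exact sums of disjoint member groups", {
  lc <- random_lc(55, 20, types = "T", seed = 3)
  # 55 cells in one (type, modality) stratum -> 5 aggregates, 5 discarded
  agg <- make_aggregates(lc, group_size = 10, seed = 1)
  expect_equal(nrow(agg$values), 5)
  all_members <- unlist(agg$membership)
  expect_equal(length(all_members), 50)
  expect_false(any(duplicated(all_members)))
  # re-sum oracle from the recorded membership
  vals <- as.matrix(lc$values)
  for (i in seq_along(agg$membership)) {
    expect_equal(agg$values[i, ],
                 colSums(vals[agg$membership[[i]], , drop = FALSE]))
  }
})

test_that("group_size 1 returns the cells themselves, permuted", {
  lc <- random_lc(12, 6, types = "T", seed = 9)
  agg <- make_aggregates(lc, group_size = 1, seed = 2)
  expect_equal(nrow(agg$values), 12)
  perm <- unlist(agg$membership)
  expect_equal(unname(agg$values), unname(as.matrix(lc$values))[perm, ])
  expect_error(make_aggregates(tiny_lc(matrix(0.5, 2, 2), c("A", "A")),
                               seed = 1), "integer")
})

test_that("strata are split by type and modality; small strata flagged", {
  lc <- tiny_lc(matrix(1L, 70, 3), rep(c("A", "B"), c(40, 30)),
                modality = rep(c("cell", "nucleus", "cell"), c(30, 10, 30)))
  agg <- make_aggregates(lc, group_size = 10, seed = 1)
  key <- paste(agg$cell_type, agg$modality)
  expect_equal(sort(unique(key)), c("A cell", "A nucleus", "B cell"))
  expect_true("A nucleus" %in% agg$low_replicate)  # only 1 aggregate
})

test_that("adjusted p-values follow the BH step-up rule", {
  agg <- nb_aggregates(4, 3, seed = 1)
  # plant known raw p by checking the relationship padj vs pvalue instead of
  # recomputing the engine: the contract is BH over tested genes
  de <- de_test(agg, "T")
  ok <- !is.na(de$pvalue)
  expect_equal(de$padj[ok], p.adjust(de$pvalue[ok], "BH"))
  # frozen example: raw (0.01, 0.02, 0.03) -> (0.03, 0.03, 0.03)
  expect_equal(p.adjust(c(0.01, 0.02, 0.03), "BH"), rep(0.03, 3))
  # monotone non-decreasing in raw-p rank order, padj >= p
  expect_true(all(de$padj[ok] >= de$pvalue[ok]))
  o <- order(de$pvalue[ok])
  expect_true(all(diff(de$padj[ok][o]) >= -1e-12))
})

test_that("the NB Wald engine is calibrated under the null", {
  rates <- vapply(1:4, function(seed) {
    agg <- nb_aggregates(20, 800, theta = 30, seed = seed)
    de <- de_test(agg, "T")
    mean(de$padj < 0.01, na.rm = TRUE)
  }, numeric(1))
  expect_lte(mean(rates), 0.02)
})

test_that("the NB Wald engine detects a 4-fold shift", {
  lfc <- c(rep(2, 40), rep(0, 360))  # 40 spiked genes among 400
  agg <- nb_aggregates(20, 400, theta = 30, lfc = lfc, seed = 5)
  de <- de_test(agg, "T")
  spiked <- de$padj[1:40]
  expect_gte(mean(spiked < 0.01, na.rm = TRUE), 0.8)
  # effect direction: nucleus is the second group, so log2fc ~ +2
  expect_gt(median(de$log2fc[1:40], na.rm = TRUE), 1.5)
})

test_that("all-zero genes are excluded and returned with missing p", {
  agg <- nb_aggregates(4, 10, seed = 2)
  agg$values[, 3] <- 0L
  de <- de_test(agg, "T")
  expect_true(is.na(de$pvalue[3]) && is.na(de$padj[3]))
  expect_error(de_test(agg, "missing_type"), "not present")
  agg_one <- agg
  agg_one$modality <- rep("cell", length(agg_one$modality))
  expect_error(de_test(agg_one, "T"), "both modalities")
})

test_that("the default engine agrees with DESeq2 on strong effects", {
  skip_if_not_installed("DESeq2")
  lfc <- c(rep(2, 30), rep(0, 270))
  agg <- nb_aggregates(15, 300, theta = 20, lfc = lfc, seed = 8)
  de <- de_test(agg, "T")
  dds <- suppressMessages(DESeq2::DESeqDataSetFromMatrix(
    countData = t(agg$values),
    colData = data.frame(modality = factor(agg$modality,
                                           levels = c("cell", "nucleus"))),
    design = ~modality))
  dds <- suppressMessages(DESeq2::DESeq(dds, quiet = TRUE))
  res <- DESeq2::results(dds)
  mine <- de$gene[!is.na(de$padj) & de$padj < 0.01]
  theirs <- rownames(res)[!is.na(res$padj) & res$padj < 0.01]
  jac <- length(intersect(mine, theirs)) / length(union(mine, theirs))
  expect_gte(jac, 0.8)
  # log fold changes agree on the spiked genes
  expect_equal(de$log2fc[1:30], res$log2FoldChange[1:30], tolerance = 0.3)
})

test_that("catalog set algebra matches brute-force enumeration", {
  fake_de <- function(genes_sig, universe) {
    data.frame(gene = universe,
               base_mean = 1, log2fc = 0,
               pvalue = ifelse(universe %in% genes_sig, 1e-6, 0.5),
               padj = ifelse(universe %in% genes_sig, 1e-6, 0.9))
  }
  uni <- paste0("g", 1:10)
  de <- list(
    dsA = list(t1 = fake_de(c("g1", "g2"), uni),
               t2 = fake_de(c("g2", "g3"), uni)),
    dsB = list(t1 = fake_de(c("g2", "g4"), uni)))
  cat_ <- build_catalog(de, alpha = 0.01, random_seed = 1)
  expect_equal(cat_$all_type_union$dsA, c("g1", "g2", "g3"))
  expect_equal(cat_$all_type_union$dsB, c("g2", "g4"))
  expect_equal(cat_$intersection, "g2")
  expect_equal(cat_$other_union$dsA, c("g2", "g4"))
  expect_equal(cat_$other_union$dsB, c("g1", "g2", "g3"))
  # intersection is contained in every per-dataset union
  for (d in names(cat_$all_type_union)) {
    expect_true(all(cat_$intersection %in% cat_$all_type_union[[d]]))
  }
  # held-out exclusion: dropping the only significant type empties the union
  cat_h <- build_catalog(de["dsB"], held_out = "t1", random_seed = 1)
  expect_equal(cat_h$per_dataset_union$dsB, character(0))
  # random matched set has the reference size, for any seed
  for (s in 1:3) {
    cs <- build_catalog(de, random_seed = s)
    expect_equal(length(cs$random_matched), length(cs$per_dataset_union$dsA))
    expect_true(all(cs$random_matched %in% cs$universe))
  }
})

test_that("catalog export writes one-column gene files and a manifest", {
  w <- small_world(seed = 4, n_genes = 200, cell_types = c(A = 60, B = 60))
  agg <- make_aggregates(bind_cells(w$sc, w$sn), seed = 1)
  de <- list(synthetic = list(A = de_test(agg, "A"), B = de_test(agg, "B")))
  cat_ <- build_catalog(de, random_seed = 3)
  dir <- withr::local_tempdir()
  write_catalog(cat_, dir)
  expect_true(file.exists(file.path(dir, "deg_union_synthetic.txt")))
  genes <- readLines(file.path(dir, "deg_union_synthetic.txt"))
  expect_equal(genes, cat_$per_dataset_union$synthetic)
})
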