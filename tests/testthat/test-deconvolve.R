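test_that("signatures are per-type means of CPM profiles", {
  lc <- tiny_lc(rbind(c(10, 30, 60), c(20, 30, 50), c(80, 10, 10)),
                c("A", "A", "B"))
  sig <- build_signature(lc)
  cpm <- refblend:::cpm_rows(as.matrix(lc$values))
  expect_equal(sig["A", ], colMeans(cpm[1:2, ]))
  expect_equal(sig["B", ], cpm[3, ])
  # duplicating every cell leaves the signature unchanged
  dup <- bind_cells(lc, lc)
  expect_equal(build_signature(dup), sig)
  # brute-force oracle on a random panel
  rp <- random_lc(40, 12, types = c("A", "B", "C"), seed = 6)
  sig_r <- build_signature(rp)
  cpm_r <- refblend:::cpm_rows(as.matrix(rp$values))
  for (ty in rownames(sig_r)) {
    expect_equal(sig_r[ty, ], colMeans(cpm_r[rp$cell_type == ty, , drop = FALSE]))
  }
  zero <- tiny_lc(rbind(c(1, 1), c(0, 0)), c("A", "B"))
  expect_error(build_signature(zero), "zero total")
})

test_that("noiseless mixtures are recovered to machine precision", {
  # well-conditioned signature, p = (0.2, 0.3, 0.5)
  set.seed(13)
  sig <- matrix(rexp(3 * 60, 1 / 100), 3, dimnames = list(c("A", "B", "C"),
                                                          paste0("g", 1:60)))
  sig <- sig / rowSums(sig) * 1e6
  p <- c(0.2, 0.3, 0.5)
  bulkv <- rbind(as.numeric(p %*% sig))
  bulk <- bulk_matrix(bulkv, "s1", colnames(sig))
  cells <- tiny_lc(sig, c("A", "B", "C"), genes = colnames(sig))
  panel <- structure(list(cells = cells, genes = colnames(sig),
                          spec = list(label = "toy"), held_out = NULL),
                     class = "reference_panel")
  res <- deconvolve(bulk, panel)
  expect_equal(unname(res$proportions[1, ]), p, tolerance = 1e-6)
  # independent oracle: interior solution equals the unconstrained LS fit
  cpm_bulk <- bulkv / sum(bulkv) * 1e6
  ols <- solve(crossprod(t(sig)), sig %*% as.numeric(cpm_bulk))
  expect_equal(unname(res$proportions[1, ]),
               unname(as.numeric(ols / sum(ols))), tolerance = 1e-6)
  # a pure single-type bulk assigns proportion 1 to that type
  bulk1 <- bulk_matrix(rbind(sig["B", ]), "s1", colnames(sig))
  res1 <- deconvolve(bulk1, panel)
  expect_equal(unname(res1$proportions[1, "B"]), 1, tolerance = 1e-9)
})

test_that("results are scale and cell-order invariant with valid simplex rows", {
  rp <- random_lc(60, 30, types = c("A", "B", "C"), seed = 7, lambda = 8)
  panel <- structure(list(cells = rp, genes = rp$gene_ids,
                          spec = list(label = "toy"), held_out = NULL),
                     class = "reference_panel")
  bulkm <- with_seed(8, matrix(rexp(5 * 30, 1 / 50), 5))
  colnames(bulkm) <- rp$gene_ids
  bulk <- bulk_matrix(bulkm, paste0("s", 1:5), rp$gene_ids)
  res <- deconvolve(bulk, panel)
  expect_true(all(res$proportions >= 0))
  expect_true(all(abs(rowSums(res$proportions) - 1) < 1e-9))
  # scaling one bulk sample by a positive constant changes nothing
  bulk2 <- bulk_matrix(bulkm * 37.5, paste0("s", 1:5), rp$gene_ids)
  expect_equal(deconvolve(bulk2, panel)$proportions, res$proportions,
               tolerance = 1e-9)
  # permuting reference cells changes nothing
  perm <- with_seed(9, sample(60))
  panel_p <- structure(list(cells = subset_cells(rp, perm),
                            genes = rp$gene_ids, spec = list(label = "toy"),
                            held_out = NULL), class = "reference_panel")
  expect_equal(deconvolve(bulk, panel_p)$proportions, res$proportions,
               tolerance = 1e-9)
})

test_that("degenerate all-zero solutions fall back to uniform with a warning", {
  sig <- rbind(A = c(100, 0, 0), B = c(0, 100, 0))
  cells <- tiny_lc(sig, c("A", "B"), genes = paste0("g", 1:3))
  panel <- structure(list(cells = cells, genes = cells$gene_ids,
                          spec = list(label = "toy"), held_out = NULL),
                     class = "reference_panel")
  # bulk supported only on the gene neither type expresses
  bulk <- bulk_matrix(rbind(c(0, 0, 50)), "s1", cells$gene_ids)
  expect_warning(res <- deconvolve(bulk, panel), "uniform")
  expect_equal(unname(res$proportions[1, ]), c(0.5, 0.5))
})

test_that("solver adequacy: matched panels give high accuracy at zero noise", {
  lc <- random_lc(300, 100, types = c("A", "B", "C", "D"), seed = 10,
                  lambda = 6)
  pb <- build_pseudobulks(lc, n_random = 30, n_realistic = 0,
                          total_cells = 200, noise_sd = 0, seed = 3)
  panel <- structure(list(cells = lc, genes = lc$gene_ids,
                          spec = list(label = "matched"), held_out = NULL),
                     class = "reference_panel")
  res <- deconvolve(pb$bulk, panel)
  r <- vapply(seq_len(30), function(i)
    cor(pb$proportions[i, ], res$proportions[i, colnames(pb$proportions)]),
    numeric(1))
  expect_gte(mean(r), 0.9)
})

test_that("the adapter exchange format round-trips proportions", {
  rp <- random_lc(20, 10, types = c("A", "B"), seed = 3)
  panel <- structure(list(cells = rp, genes = rp$gene_ids,
                          spec = list(label = "toy"), held_out = NULL),
                     class = "reference_panel")
  bulk <- bulk_matrix(matrix(rexp(20, 1 / 10), 2, 10,
                             dimnames = list(NULL, rp$gene_ids)),
                      c("s1", "s2"), rp$gene_ids)
  dir <- withr::local_tempdir()
  write_adapter_inputs(panel, bulk, dir, n_iter = 123)
  expect_true(all(file.exists(file.path(dir, c("reference.csv", "bulks.csv",
                                               "cell_types.csv",
                                               "config.json")))))
  cfg <- jsonlite::read_json(file.path(dir, "config.json"))
  expect_equal(cfg$n_iter, 123)
  # a well-formed external output parses; a malformed one errors
  out <- data.frame(sample_id = c("s1", "s2"), A = c(0.3, 0.6),
                    B = c(0.7, 0.4))
  f <- file.path(dir, "proportions.csv")
  write.csv(out, f, row.names = FALSE)
  res <- read_adapter_output(f)
  expect_equal(unname(res$proportions[1, ]), c(0.3, 0.7))
  bad <- data.frame(sample_id = "s1", A = -0.2, B = 1.2)
  write.csv(bad, f, row.names = FALSE)
  expect_error(read_adapter_output(f), "malformed")
})
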