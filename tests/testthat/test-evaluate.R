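test_that("metric formulas match textbook oracles", {
  expect_equal(unname(score_sample(c(0.5, 0.5), c(0.5, 0.5))["rmse"]), 0)
  expect_equal(unname(score_removed(c(0.5, 0.5), c(0.4, 0.6))["rmse"]), 0.1)
  x <- c(0.1, 0.5, 0.4)
  expect_equal(unname(score_sample(x, x)["pearson"]), 1)
  for (seed in 1:4) {
    tr <- with_seed(seed, {
      a <- runif(6); a / sum(a)
    })
    es <- with_seed(seed + 50, {
      b <- runif(6); b / sum(b)
    })
    s <- score_sample(tr, es)
    n <- 6
    r_hand <- sum((tr - mean(tr)) * (es - mean(es))) /
      sqrt(sum((tr - mean(tr))^2) * sum((es - mean(es))^2))
    expect_equal(unname(s["pearson"]), r_hand, tolerance = 1e-12)
    expect_equal(unname(s["rmse"]), sqrt(sum((tr - es)^2) / n),
                 tolerance = 1e-12)
  }
})

test_that("non_removed drops the held-out entry; constants give missing r", {
  tr <- c(A = 0.2, B = 0.3, C = 0.5)
  es <- c(A = 0.9, B = 0.05, C = 0.05)
  s <- score_sample(tr, es, "non_removed", held_out = "A")
  expect_equal(unname(s["rmse"]),
               sqrt(mean((c(0.3, 0.5) - c(0.05, 0.05))^2)))
  expect_message(s2 <- score_sample(c(0.5, 0.5), c(0.3, 0.7)), "constant")
  expect_true(is.na(s2["pearson"]))
  expect_error(score_sample(tr, es, "non_removed"), "held-out")
})

test_that("bootstrap CI is percentile-based, seeded, and covers the mean", {
  const <- rep(3.2, 10)
  ci <- bootstrap_mean_ci(const, seed = 1)
  expect_equal(unname(ci), c(3.2, 3.2, 3.2))
  x <- with_seed(4, rnorm(40))
  ci1 <- bootstrap_mean_ci(x, seed = 9)
  ci2 <- bootstrap_mean_ci(x, seed = 9)
  expect_identical(ci1, ci2)
  expect_true(ci1["lo"] <= mean(x) && mean(x) <= ci1["hi"])
  expect_error(bootstrap_mean_ci(numeric()), "no finite values")
  # coverage of the true mean for i.i.d. normal samples
  hits <- with_seed(17, vapply(seq_len(200), function(i) {
    y <- rnorm(100)
    ci <- bootstrap_mean_ci(y, n_boot = 300, seed = i)
    ci[["lo"]] <= 0 && 0 <= ci[["hi"]]
  }, logical(1)))
  expect_gt(mean(hits), 0.91)
  expect_lt(mean(hits), 0.99)
})

test_that("the pooled t-test matches a hand computation and is antisymmetric", {
  a <- c(1, 2, 3); b <- c(2, 3, 4)
  out <- t_test_equal_var(a, b)
  sp <- sqrt(((2) * var(a) + (2) * var(b)) / 4)
  t_hand <- (mean(a) - mean(b)) / (sp * sqrt(1 / 3 + 1 / 3))
  expect_equal(unname(out["t"]), t_hand, tolerance = 1e-12)
  expect_equal(unname(out["p"]),
               2 * pt(-abs(t_hand), df = 4), tolerance = 1e-12)
  swapped <- t_test_equal_var(b, a)
  expect_equal(unname(swapped["t"]), -unname(out["t"]))
  expect_equal(unname(swapped["p"]), unname(out["p"]))
  expect_equal(unname(t_test_equal_var(a, a)), c(0, 1))
  expect_equal(unname(t_test_equal_var(c(2, 2), c(2, 2))), c(0, 1))
  expect_error(t_test_equal_var(1, c(1, 2)), "n >= 2")
})

test_that("profile cosine follows the CPM/log pipeline and its bounds", {
  lc <- random_lc(120, 40, types = "T", seed = 5, lambda = 10)
  expect_equal(cosine_profiles(lc, lc, "T", seed = 3), 1.0)
  # orthogonal supports -> 0
  a <- tiny_lc(cbind(matrix(5L, 60, 20), matrix(0L, 60, 20)), rep("T", 60))
  b <- tiny_lc(cbind(matrix(0L, 60, 20), matrix(5L, 60, 20)), rep("T", 60))
  expect_equal(cosine_profiles(a, b, "T", seed = 1), 0)
  # direct-formula oracle with the same sampled cells
  other <- random_lc(120, 40, types = "T", seed = 6, lambda = 4)
  got <- cosine_profiles(lc, other, "T", n_cells = 50, seed = 11)
  oracle <- {
    # each side draws under the same seed (the identity-input contract)
    ia <- with_seed(11, sample(120, 50))
    ib <- with_seed(11, sample(120, 50))
    va <- colSums(as.matrix(lc$values)[ia, ])
    vb <- colSums(as.matrix(other$values)[ib, ])
    va <- log1p(va / sum(va) * 1e6); vb <- log1p(vb / sum(vb) * 1e6)
    sum(va * vb) / sqrt(sum(va^2) * sum(vb^2))
  }
  expect_equal(got, oracle, tolerance = 1e-12)
  expect_true(got >= -1 && got <= 1)
  small <- subset_cells(lc, 1:10)
  expect_message(cosine_profiles(small, lc, "T", seed = 2), "replacement")
})

test_that("proportion cosine flattens row-major and ignores positive scaling", {
  P1 <- matrix(c(0.2, 0.8, 0.5, 0.5), 2, byrow = TRUE,
               dimnames = list(NULL, c("A", "B")))
  r1 <- structure(list(proportions = P1), class = "deconvolution_result")
  expect_equal(cosine_proportions(r1, r1), 1.0)
  r2 <- structure(list(proportions = P1 * 4), class = "deconvolution_result")
  expect_equal(cosine_proportions(r1, r2), 1.0)
  P3 <- with_seed(2, matrix(runif(4), 2, dimnames = list(NULL, c("A", "B"))))
  r3 <- structure(list(proportions = P3), class = "deconvolution_result")
  expect_equal(cosine_proportions(r1, r3),
               sum(P1 * P3) / sqrt(sum(P1^2) * sum(P3^2)))
  r4 <- structure(list(proportions = P1[, 1, drop = FALSE]),
                  class = "deconvolution_result")
  expect_error(cosine_proportions(r1, r4), "shape")
})

test_that("min-max scaling matches the frozen example and degenerates to 0", {
  expect_equal(refblend:::minmax(c(2, 4, 6)), c(0, 0.5, 1))
  expect_message(z <- refblend:::minmax(c(3, 3, 3)), "degenerate")
  expect_equal(z, c(0, 0, 0))
})

test_that("composite scores reproduce a hand-computed two-transform toy", {
  # dataset ds1: transform T1 per-sample (pearson, rmse) = (0.9,0.1), (0.7,0.3)
  #              transform T2 = (0.5,0.5), (0.3,0.7)
  rec <- data.frame(
    dataset = "ds1", transform = rep(c("T1", "T2"), each = 2),
    held_out = "x", scenario = "all", sample_id = as.character(1:4),
    pearson = c(0.9, 0.7, 0.5, 0.3), rmse = c(0.1, 0.3, 0.5, 0.7))
  # hand: pearson minmax over {.9,.7,.5,.3} -> {1, 2/3, 1/3, 0}
  #       inverted rmse = .7-{.1,.3,.5,.7} = {.6,.4,.2,0} -> {1, 2/3, 1/3, 0}
  # per transform: T1 = mean(1, 2/3) = 5/6 (both metrics), T2 = mean(1/3, 0) = 1/6
  # accuracy = mean of the two metrics = 5/6 and 1/6
  rob <- structure(list(
    transform_pair = matrix(c(1, 0.8, 0.8, 1), 2,
                            dimnames = list(c("T1", "T2"), c("T1", "T2"))),
    donor_pair = list(
      T1 = matrix(c(1, .9, .9, 1), 2, dimnames = list(1:2, 1:2)),
      T2 = matrix(c(1, .5, .5, 1), 2, dimnames = list(1:2, 1:2)))),
    class = "robustness_table")
  # transform-pair off-diagonals are all 0.8 -> degenerate minmax -> 0 both
  # donor pools {.9, .5} -> minmax -> T1 = 1, T2 = 0
  # robustness = mean(per_transform, per_donor) = (0.5, 0)
  suppressMessages(cs <- composite_scores(rec, rob))
  cs <- cs[order(cs$transform), ]
  expect_equal(cs$accuracy_score, c(5 / 6, 1 / 6), tolerance = 1e-12)
  expect_equal(cs$robustness_score, c(0.5, 0), tolerance = 1e-12)
  expect_true(all(cs$accuracy_score >= 0 & cs$accuracy_score <= 1))
  # invariant to record ordering
  suppressMessages(cs2 <- composite_scores(rec[sample(4), ], rob))
  expect_equal(cs2[order(cs2$transform), ]$accuracy_score, cs$accuracy_score)
  # a strictly dominant transform is the argmax of the accuracy score
  expect_equal(cs$transform[which.max(cs$accuracy_score)], "T1")
  expect_error(composite_scores(rec[rec$transform == "T1", ], NULL),
               ">= 2 transforms")
})

test_that("evaluation records carry all three scenarios with pooled removed", {
  truth <- matrix(c(0.2, 0.3, 0.5, 0.4, 0.4, 0.2), 2, byrow = TRUE,
                  dimnames = list(c("s1", "s2"), c("A", "B", "C")))
  est <- truth + 0.05 * matrix(c(1, -1, 0, -1, 1, 0), 2, byrow = TRUE)
  res <- structure(list(proportions = est), class = "deconvolution_result")
  rec <- evaluate_deconvolution(truth, res, "toy", held_out = "B")
  expect_setequal(unique(rec$scenario), c("all", "non_removed", "removed_only"))
  expect_equal(sum(rec$scenario == "removed_only"), 1)
  expect_equal(rec$sample_id[rec$scenario == "removed_only"], "pooled")
  pooled <- rec[rec$scenario == "removed_only", ]
  expect_equal(pooled$rmse, sqrt(mean((truth[, "B"] - est[, "B"])^2)))
  # a reference without the held-out type scores it as zero estimates
  res2 <- structure(list(proportions = est[, c("A", "C")]),
                    class = "deconvolution_result")
  rec2 <- evaluate_deconvolution(truth, res2, "toy", held_out = "B")
  pooled2 <- rec2[rec2$scenario == "removed_only", ]
  expect_equal(pooled2$rmse, sqrt(mean(truth[, "B"]^2)))
})

test_that("robustness tables are symmetric cosine matrices", {
  mk <- function(seed) {
    P <- with_seed(seed, matrix(runif(6), 3, dimnames = list(NULL, c("A", "B"))))
    structure(list(proportions = P / rowSums(P)),
              class = "deconvolution_result")
  }
  rt <- robustness_tables(list(t1 = mk(1), t2 = mk(2), t3 = mk(3)),
                          by_donor = list(t1 = list(d1 = mk(4), d2 = mk(5))))
  M <- rt$transform_pair
  expect_equal(M, t(M))
  expect_true(all(diag(M) == 1))
  expect_true(all(M >= -1 & M <= 1))
  expect_equal(M["t1", "t2"], cosine_proportions(mk(1), mk(2)))
  expect_equal(rt$donor_pair$t1["d1", "d2"], cosine_proportions(mk(4), mk(5)))
})
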