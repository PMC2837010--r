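log2_matrix <- function(nr, nc, seed = 1, mean = 8, sd = 0.25) {
  set.seed(seed)
  m <- matrix(2^rnorm(nr * nc, mean, sd), nr,
              dimnames = list(sprintf("F%04d", seq_len(nr)),
                              sprintf("s%02d", seq_len(nc))))
  m
}

test_that("row-wise t and F statistics match stats::t.test and stats::aov", {
  m <- log2_matrix(20, 9, seed = 10)
  lx <- log2(m)
  res <- pairwise_differential(m, 1:4, 5:9)
  for (i in c(1, 7, 20)) {
    ref <- t.test(lx[i, 5:9], lx[i, 1:4], var.equal = TRUE)
    expect_equal(res$p_value[i], ref$p.value, tolerance = 1e-12)
  }
  resw <- pairwise_differential(m, 1:4, 5:9, pipeline_config(welch = TRUE))
  refw <- t.test(lx[3, 5:9], lx[3, 1:4])
  expect_equal(resw$p_value[3], refw$p.value, tolerance = 1e-12)

  resa <- anova_transformation_test(m, list(1:3, 4:6), 7:9)
  for (i in c(2, 11)) {
    g <- factor(rep(1:3, each = 3))
    ref <- summary(aov(lx[i, ] ~ g))[[1]][["Pr(>F)"]][1]
    expect_equal(resa$p_value[i], ref, tolerance = 1e-12)
  }
})

test_that("pairwise calls apply the two-fold rule and significance threshold jointly", {
  # identical constant groups: fold change 1, no call
  m <- matrix(2^8, 10, 6, dimnames = list(paste0("F", 1:10), paste0("s", 1:6)))
  res <- pairwise_differential(m, 1:3, 4:6)
  expect_true(all(res$fold_change == 1))
  expect_true(all(res$p_value == 1))
  expect_false(any(res$passes))

  # planted 4-fold with modest noise: called, direction up
  set.seed(11)
  m2 <- log2_matrix(200, 6, seed = 11, sd = 0.05)
  m2[1, 4:6] <- m2[1, 4:6] * 4
  res2 <- pairwise_differential(m2, 1:3, 4:6)
  expect_true(res2$passes[1])
  expect_equal(res2$direction[1], "up")

  # significant but sub-two-fold: excluded by the fold-change rule
  m3 <- log2_matrix(50, 6, seed = 12, sd = 0.01)
  m3[2, 4:6] <- m3[2, 4:6] * 1.5
  res3 <- pairwise_differential(m3, 1:3, 4:6)
  expect_lt(res3$p_value[2], 0.05)
  expect_false(res3$passes[2])

  # swapping group labels flips direction, keeps p and pass status
  fwd <- pairwise_differential(m2, 1:3, 4:6)
  rev <- pairwise_differential(m2, 4:6, 1:3)
  expect_equal(fwd$p_value, rev$p_value)
  expect_equal(fwd$passes, rev$passes)
  flip <- c(up = "down", down = "up", none = "none")
  expect_equal(unname(flip[fwd$direction]), rev$direction)
})

test_that("the ANOVA regime requires a transformation-specific contrast", {
  base <- log2_matrix(30, 9, seed = 13, sd = 0.05)
  # equal in both controls, 4-fold higher in the test group
  up <- base; up[1, 7:9] <- up[1, 7:9] * 4
  res <- anova_transformation_test(up, list(1:3, 4:6), 7:9)
  expect_true(res$passes[1])
  expect_equal(res$direction[1], "up")

  # constant feature: no call
  flat <- base; flat[2, ] <- 2^8
  expect_false(anova_transformation_test(flat, list(1:3, 4:6), 7:9)$passes[2])

  # 4-fold apart controls with the test group at their geometric mean:
  # significant ANOVA but no test-specific contrast -> direction none, fails
  cc <- base
  cc[3, 1:3] <- 2^10; cc[3, 4:6] <- 2^8; cc[3, 7:9] <- 2^9
  res3 <- anova_transformation_test(cc, list(1:3, 4:6), 7:9)
  expect_lt(res3$p_value[3], 0.01)
  expect_gte(res3$fold_change[3], 2)
  expect_equal(res3$direction[3], "none")
  expect_false(res3$passes[3])

  expect_error(anova_transformation_test(base, list(1:3), 7:9), "two groups")
})

test_that("permutation FDR is near 1 under the complete null and near 0 under strong signal", {
  # complete null, p-only rule (fold threshold 1), 5 vs 5
  sim0 <- simulate_microarray_experiment(two_group_config(
    n_probesets = 2000, replicates_per_condition = 5, n_planted_up = 0,
    n_planted_down = 0, redundancy_fraction = 0, probes_per_set = 1,
    seed = 21))
  v0 <- sim0$probe_matrix$intensities
  f0 <- estimate_permutation_fdr(v0, list(a = 1:5, b = 6:10), "pairwise",
                                 pipeline_config(fc_threshold = 1,
                                                 n_permutations = 200,
                                                 seed = 2))
  expect_gt(f0$fdr_estimate, 0.7)
  expect_lt(f0$fdr_estimate, 1.3)

  # strong signal: 200 of 2000 features planted at fold change 8
  sim1 <- simulate_microarray_experiment(two_group_config(
    n_probesets = 2000, n_planted_up = 100, n_planted_down = 100,
    fold_change_range = c(7.99, 8.01), redundancy_fraction = 0,
    probes_per_set = 1, seed = 22))
  v1 <- sim1$probe_matrix$intensities
  f1 <- estimate_permutation_fdr(v1, list(a = 1:3, b = 4:6), "pairwise",
                                 pipeline_config(n_permutations = 200,
                                                 seed = 3))
  expect_gt(f1$observed_count, 150)
  expect_lt(f1$fdr_estimate, 0.03)

  # zero observed calls: FDR 0 by convention, with a warning
  flat <- matrix(2^rnorm(200 * 6, 8, 0.01), 200,
                 dimnames = list(sprintf("F%03d", 1:200), paste0("s", 1:6)))
  expect_warning(
    fz <- estimate_permutation_fdr(flat, list(1:3, 4:6), "pairwise",
                                   pipeline_config(n_permutations = 20,
                                                   seed = 4)),
    "no observed calls")
  expect_equal(fz$fdr_estimate, 0)
})

test_that("permutation FDR is reproducible and invariant to feature order", {
  sim <- simulate_microarray_experiment(two_group_config(
    n_probesets = 300, n_planted_up = 30, n_planted_down = 30,
    redundancy_fraction = 0, probes_per_set = 1, seed = 23))
  v <- sim$probe_matrix$intensities
  cfg <- pipeline_config(n_permutations = 50, seed = 9)
  f1 <- estimate_permutation_fdr(v, list(1:3, 4:6), "pairwise", cfg)
  f2 <- estimate_permutation_fdr(v, list(1:3, 4:6), "pairwise", cfg)
  expect_identical(f1, f2)
  f3 <- estimate_permutation_fdr(v[rev(seq_len(nrow(v))), ],
                                 list(1:3, 4:6), "pairwise", cfg)
  expect_equal(f1$fdr_estimate, f3$fdr_estimate)

  # tiny designs are enumerated exhaustively
  expect_warning(
    fe <- estimate_permutation_fdr(v[, 1:4], list(1:2, 3:4), "pairwise",
                                   pipeline_config(n_permutations = 20,
                                                   fc_threshold = 1,
                                                   seed = 5)),
    "enumerating")
  expect_lte(length(fe$null_counts), 2)  # 3 splits minus the observed one
})

test_that("temperature filtering removes genes whose temperature response dominates", {
  ts_set <- gene_set("CEF_ts", c("g1", "g2", "g3"), "up",
                     fold_change = c(4, 4, 4))
  temp_res <- data.frame(feature_id = c("g1", "g3"),
                         log2_ratio = c(2.0, 0.5),
                         p_value = 0.01, passes = TRUE,
                         stringsAsFactors = FALSE)
  wt_res <- data.frame(feature_id = c("g1", "g3"),
                       log2_ratio = c(1.0, 2.0),
                       p_value = 0.01, passes = TRUE,
                       stringsAsFactors = FALSE)
  out <- filter_temperature_confounded(ts_set, temp_res, wt_res)
  # g1: temperature 2.0 >= transformation 1.0 -> removed
  # g2: not temperature-regulated -> retained
  # g3: temperature 0.5 < transformation 2.0 -> retained
  expect_equal(out$removed$members$gene_id, "g1")
  expect_setequal(out$retained$members$gene_id, c("g2", "g3"))

  # absent from the wild-type comparison => fold change 1 => removed
  wt_none <- wt_res[wt_res$feature_id == "g3", , drop = FALSE]
  out2 <- filter_temperature_confounded(ts_set, temp_res, wt_none)
  expect_true("g1" %in% out2$removed$members$gene_id)
})

test_that("set algebra produces a disjoint CSR union with carried directions", {
  tr <- gene_set("TR", c("a", "b", "c"), c("up", "down", "up"))
  cef <- gene_set("CEF_ts", c("a", "b", "d", "e"),
                  c("up", "down", "up", "down"))
  cnr <- gene_set("CNR_ts", c("a", "d", "f"), c("up", "up", "down"))
  fam <- build_gene_sets(tr, cef, cnr)
  expect_setequal(set_ids(fam$common_all3), "a")
  expect_setequal(set_ids(fam$ts_only), "d")
  expect_setequal(set_ids(fam$CSR), c("a", "d"))
  expect_setequal(set_ids(fam$TR_CEF_ts), c("a", "b"))
  expect_equal(length(fam$CSR),
               length(fam$common_all3) + length(fam$ts_only))
  expect_length(intersect(set_ids(fam$common_all3), set_ids(fam$ts_only)), 0)

  # disjoint inputs: all derived sets empty
  fam0 <- build_gene_sets(gene_set("TR", "x", "up"),
                          gene_set("CEF_ts", "y", "up"),
                          gene_set("CNR_ts", "z", "up"))
  expect_length(fam0$CSR, 0)

  # direction conflict resolved toward TR, and reported
  tr2 <- gene_set("TR", "a", "down")
  expect_message(fam2 <- build_gene_sets(tr2, cef, cnr), "conflict")
  expect_equal(attr(fam2, "direction_conflicts"), "a")
  expect_equal(fam2$common_all3$members$direction, "down")
})

test_that("platform concordance returns exact values on constructed pairs", {
  x <- c(-2, -1, 0.5, 1, 2, 3)
  cc <- platform_concordance(x, x)
  expect_equal(cc$spearman_rho, 1)
  expect_equal(cc$ols_slope, 1)
  cc2 <- platform_concordance(x, 0.5 * x)
  expect_equal(cc2$spearman_rho, 1)
  expect_equal(cc2$ols_slope, 0.5)
  expect_error(platform_concordance(x, rep(1, 6)), "constant")
  expect_error(platform_concordance(1:2, 1:2), "pairs")
})
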