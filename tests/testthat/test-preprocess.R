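make_probe_matrix <- function(m, probes_per_set = 1) {
  n_sets <- nrow(m) / probes_per_set
  probes <- data.frame(
    probeset_id = rep(pad_ids_test("PS", n_sets), each = probes_per_set),
    probe_index = rep(seq_len(probes_per_set), n_sets))
  samples <- data.frame(array_id = colnames(m),
                        condition = "c", temperature = "41.5",
                        replicate = seq_len(ncol(m)))
  structure(list(intensities = m, probes = probes, samples = samples),
            class = "probe_matrix")
}
pad_ids_test <- function(p, n) sprintf(paste0(p, "%04d"), seq_len(n))

test_that("median scaling hits the target exactly and preserves within-array ratios", {
  set.seed(1)
  m <- matrix(rlnorm(2000, 5, 1), ncol = 2,
              dimnames = list(NULL, c("a1", "a2")))
  pmx <- make_probe_matrix(m)
  out <- scale_to_common_median(pmx, 150)
  expect_equal(unname(apply(out$intensities, 2, median)), c(150, 150))
  expect_equal(out$intensities[5, "a1"] / out$intensities[17, "a1"],
               m[5, "a1"] / m[17, "a1"])

  # already at target: unchanged; "auto" = mean of medians
  m2 <- m * 150 / median(m[, 1])
  pm2 <- make_probe_matrix(m2)
  expect_equal(scale_to_common_median(pm2, median(m2[, 1]))$intensities[, 1],
               m2[, 1])
  auto <- scale_to_common_median(pmx, "auto")
  expect_equal(unname(apply(auto$intensities, 2, median)),
               rep(mean(apply(m, 2, median)), 2))
  expect_error(scale_to_common_median(make_probe_matrix(m * 0)), "zero")
})

test_that("invariant-probe selection keeps stable probes and rejects planted rank shifts", {
  set.seed(2)
  base <- sort(rlnorm(5000, 6, 1))
  # identical arrays: every probe survives
  expect_equal(select_invariant_probes(base, base), seq_along(base))
  # a global scale change leaves ranks untouched
  expect_equal(select_invariant_probes(2 * base, base), seq_along(base))
  # perturb 10% of probes with large rank-shifting factors
  idx <- sample(5000, 500)
  target <- base
  target[idx] <- target[idx] * ifelse(runif(500) < 0.5, 20, 1 / 20)
  inv <- select_invariant_probes(target, base)
  expect_gt(length(inv), 0)
  expect_gte(mean(!idx %in% inv), 0.95)
  expect_error(select_invariant_probes(base, base[-1]), "length")
})

test_that("normalization inverts a global monotone distortion and preserves rank order", {
  set.seed(3)
  base <- rlnorm(4000, 6, 1)
  # identity
  inv <- select_invariant_probes(base, base)
  expect_equal(normalize_to_baseline(base, base, inv), base,
               tolerance = 1e-8)
  # 2x distortion, all probes invariant: recovered within 1% inside range
  target <- 2 * base
  norm <- normalize_to_baseline(target, base, seq_along(base))
  inside <- base > quantile(base, 0.05) & base < quantile(base, 0.95)
  expect_lt(max(abs(norm[inside] / base[inside] - 1)), 0.01)
  # monotonicity over the full output
  o <- order(target)
  expect_true(all(diff(norm[o]) >= 0))
  # tiny invariant sets fall back to median-ratio scaling, with a warning
  expect_warning(fallback <- normalize_to_baseline(target, base, 1:5),
                 "median-ratio")
  expect_equal(fallback, base, tolerance = 1e-8)
})

test_that("repeated normalization against the same baseline is idempotent", {
  set.seed(4)
  base <- rlnorm(3000, 6, 1)
  target <- base * exp(rnorm(3000, 0.3, 0.1))
  inv <- select_invariant_probes(target, base, rank_threshold = 0.05)
  once <- normalize_to_baseline(target, base, inv)
  inv2 <- select_invariant_probes(once, base, rank_threshold = 0.05)
  twice <- normalize_to_baseline(once, base, inv2)
  expect_lt(stats::median(abs(twice - once) / once), 0.001)
})

test_that("MBEI factorization is exact on rank-1 input and robust to mild noise", {
  set.seed(5)
  phi <- runif(11, 0.3, 2); phi <- phi / mean(phi)
  theta <- c(80, 120, 400, 90, 260, 150)
  Y <- outer(phi, theta)
  colnames(Y) <- paste0("a", 1:6)
  ex <- compute_mbei(make_probe_matrix(Y, probes_per_set = 11))
  expect_equal(unname(ex$values[1, ]), theta, tolerance = 1e-6)

  # additive noise at 1% of signal: recovered within 5% per array
  Yn <- Y + matrix(rnorm(length(Y), 0, 0.01 * mean(Y)), nrow(Y))
  exn <- compute_mbei(make_probe_matrix(abs(Yn), probes_per_set = 11))
  expect_true(all(abs(exn$values[1, ] / theta - 1) < 0.05))

  # single-probe probe sets pass intensities through
  single <- matrix(c(3, 9, 27, 5, 10, 20), nrow = 2, byrow = TRUE,
                   dimnames = list(NULL, paste0("a", 1:3)))
  exs <- compute_mbei(make_probe_matrix(single, probes_per_set = 1))
  expect_equal(unname(exs$values), unname(single))
})

test_that("MBEI is scale-equivariant", {
  set.seed(6)
  Y <- outer(runif(11, 0.5, 1.5), c(100, 300, 200, 150)) *
    exp(matrix(rnorm(44, 0, 0.1), 11))
  colnames(Y) <- paste0("a", 1:4)
  e1 <- compute_mbei(make_probe_matrix(Y, probes_per_set = 11))
  e2 <- compute_mbei(make_probe_matrix(7 * Y, probes_per_set = 11))
  expect_equal(unname(e2$values), unname(7 * e1$values), tolerance = 1e-6)
})

test_that("probe-set collapse keeps the lowest p-value with a deterministic tie-break", {
  ann <- data.frame(probeset_id = c("PS1", "PS2", "PS3", "PS4"),
                    gene_id = c("gA", "gA", "gB", "gA"))
  res <- data.frame(feature_id = c("PS1", "PS2", "PS3", "PS4"),
                    fold_change = c(2, 3, 4, 3),
                    p_value = c(0.020, 0.004, 0.010, 0.004),
                    passes = TRUE, stringsAsFactors = FALSE)
  out <- collapse_to_genes(res, ann)
  expect_equal(nrow(out), 2)
  # gA: PS2 and PS4 tie at p = 0.004; PS2 wins lexicographically
  expect_equal(out$probeset_id[out$feature_id == "gA"], "PS2")
  expect_equal(out$probeset_id[out$feature_id == "gB"], "PS3")

  # all-unique annotation: size preserved
  ann1 <- data.frame(probeset_id = res$feature_id,
                     gene_id = paste0("u", 1:4))
  expect_equal(nrow(collapse_to_genes(res, ann1)), 4)
  expect_error(collapse_to_genes(res, ann[1:2, ]), "unannotated")
})

test_that("expression matrices collapse to the retained probe set's row", {
  v <- matrix(1:8, nrow = 4,
              dimnames = list(c("PS1", "PS2", "PS3", "PS4"), c("s1", "s2")))
  ex <- structure(list(values = v, samples = NULL), class = "expr_matrix")
  ann <- data.frame(probeset_id = rownames(v),
                    gene_id = c("gA", "gA", "gB", "gB"))
  out <- collapse_to_genes(ex, ann, retain = c(gA = "PS2", gB = "PS3"))
  expect_equal(rownames(out$values), c("gA", "gB"))
  expect_equal(unname(out$values["gA", ]), unname(v["PS2", ]))
})

test_that("the full preprocessing chain preserves planted fold-change ordering", {
  sim <- simulate_microarray_experiment(array_sim_config(
    n_probesets = 800, n_planted_up = 60, n_planted_down = 60, seed = 9))
  pmx <- scale_to_common_median(sim$probe_matrix, "auto")
  pmx <- normalize_group(pmx)
  ex <- compute_mbei(pmx)
  tra <- ex$samples$condition %in% sim$truth$transformed_conditions
  l2fc <- rowMeans(log2(ex$values[, tra])) - rowMeans(log2(ex$values[, !tra]))
  map <- sim$truth$probeset_to_gene
  truth <- rbind(
    transform(sim$truth$planted_up, l2 = log2(fold_change)),
    transform(sim$truth$planted_down, l2 = -log2(fold_change)))
  ps <- map$probeset_id[match(truth$gene_id, map$gene_id)]
  expect_gte(cor(l2fc[ps], truth$l2, method = "spearman"), 0.95)
})
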