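# End-to-end orchestration: discovery (preprocessing -> differential calls
# -> permutation FDR -> gene collapse -> temperature filter -> set algebra)
# and signature derivation/evaluation (ortholog mapping -> clustering ->
# poor-cluster candidates -> intersection -> upper-quartile survival
# split), each returning a run manifest.

default_discovery_conditions <- function() {
  list(
    # three-virus group plus a temperature-control condition
    cef_viruses = data.frame(
      condition = c("RCASBP", "NY315", "SRA", "RCASBP_perm"),
      temperature = c("41.5", "41.5", "41.5", "37.5"),
      transformed = c(FALSE, FALSE, TRUE, FALSE),
      stringsAsFactors = FALSE),
    # ts-kinase groups: transformed at the permissive temperature
    cef_ts = data.frame(
      condition = c("NY72-4_41.5", "NY72-4_37.5"),
      temperature = c("41.5", "37.5"),
      transformed = c(FALSE, TRUE),
      stringsAsFactors = FALSE),
    cnr_ts = data.frame(
      condition = c("CNR_NY72-4_41.5", "CNR_NY72-4_37.5"),
      temperature = c("41.5", "37.5"),
      transformed = c(FALSE, TRUE),
      stringsAsFactors = FALSE))
}

#' Simulate the three discovery experiments with a shared planted program
#'
#' Builds the three experimental groups of the discovery design — a
#' three-virus comparison (plus a temperature-control condition in the same
#' group) and two temperature-sensitive-kinase comparisons in fibroblasts
#' and neuroretinal cells — over a common gene universe, with one planted
#' transformation program shared by all three systems and one shared set of
#' temperature-responsive genes.
#'
#' @param seed Integer seed.
#' @param n_probesets,n_planted_up,n_planted_down,fold_change_range,noise_sd,redundancy_fraction,n_temperature_genes,probes_per_set
#'   Passed to [array_sim_config()].
#' @return List with `experiments` (named list of `probe_matrix`),
#'   `annotation` (probeset/gene/symbol data.frame) and `truth`
#'   (shared planted program and temperature genes).
#' @export
simulate_discovery_experiments <- function(seed = 1, n_probesets = 2000,
                                           n_planted_up = 100,
                                           n_planted_down = 100,
                                           fold_change_range = c(2, 8),
                                           noise_sd = 0.25,
                                           redundancy_fraction = 0.1,
                                           n_temperature_genes = 40,
                                           probes_per_set = 11) {
  conds <- default_discovery_conditions()
  base_cfg <- function(conditions, seed_offset, ...) {
    array_sim_config(n_probesets = n_probesets,
                     probes_per_set = probes_per_set,
                     conditions = conditions,
                     fold_change_range = fold_change_range,
                     noise_sd = noise_sd,
                     redundancy_fraction = redundancy_fraction,
                     seed = seed + seed_offset, ...)
  }
  # draw the shared program once, from the first experiment's truth
  cfg1 <- base_cfg(conds$cef_viruses, 0L,
                   n_planted_up = n_planted_up,
                   n_planted_down = n_planted_down,
                   n_temperature_genes = n_temperature_genes)
  sim1 <- simulate_microarray_experiment(cfg1)
  shared <- sim1$truth
  cfg2 <- base_cfg(conds$cef_ts, 1L,
                   planted_up = shared$planted_up,
                   planted_down = shared$planted_down,
                   temperature_genes = shared$temperature_genes)
  cfg3 <- base_cfg(conds$cnr_ts, 2L,
                   planted_up = shared$planted_up,
                   planted_down = shared$planted_down,
                   temperature_genes = shared$temperature_genes)
  sim2 <- simulate_microarray_experiment(cfg2)
  sim3 <- simulate_microarray_experiment(cfg3)
  annotation <- data.frame(probeset_id = shared$probeset_to_gene$probeset_id,
                           gene_id = shared$probeset_to_gene$gene_id,
                           symbol = shared$probeset_to_gene$gene_id,
                           stringsAsFactors = FALSE)
  list(experiments = list(cef_viruses = sim1$probe_matrix,
                          cef_ts = sim2$probe_matrix,
                          cnr_ts = sim3$probe_matrix),
       annotation = annotation, truth = shared)
}

result_to_gene_set <- function(res, name, provenance) {
  r <- res[res$passes, , drop = FALSE]
  gene_set(name, r$feature_id, r$direction, fold_change = r$fold_change,
           provenance = provenance)
}

#' Run the full discovery pipeline
#'
#' Executes preprocessing (median scaling across experiments, invariant-set
#' normalization within each experimental group, PM-only model-based
#' expression indices), the differential calls (ANOVA regime for the
#' three-virus experiment, pairwise regime for the two ts experiments),
#' permutation FDR per regime, probe-set-to-gene collapse, the
#' temperature-confound filter, and the closing set algebra.
#'
#' @param config A [pipeline_config()].
#' @param bundle Experiments to analyse: the result of
#'   [simulate_discovery_experiments()] (or an equivalent list with
#'   `experiments`, `annotation` and optionally `truth`). `NULL` simulates
#'   a default bundle with `sim_args`.
#' @param sim_args Named list of overrides for
#'   [simulate_discovery_experiments()] when `bundle` is `NULL`.
#' @param out_dir Optional directory: gene sets are written as GMT (plus
#'   member TSVs) and listed in the manifest.
#' @param estimate_fdr Set `FALSE` to skip the permutation FDR stage.
#' @return List of class `discovery_run`: `sets` (the gene-set family),
#'   `results` (per-regime differential tables, gene level), `fdr`
#'   (per-regime permutation estimates), `temperature_filter` (removed
#'   sets), `recovery` (planted-truth scoring when truth is available) and
#'   `manifest`.
#' @export
run_discovery <- function(config = pipeline_config(), bundle = NULL,
                          sim_args = list(), out_dir = NULL,
                          estimate_fdr = TRUE) {
  if (is.null(bundle)) {
    sim_args$seed <- sim_args$seed %||% config$seed
    bundle <- do.call(simulate_discovery_experiments, sim_args)
  }
  exps <- bundle$experiments
  ann <- bundle$annotation

  exps <- scale_to_common_median(exps, "auto")
  exps <- lapply(exps, normalize_group)
  expr <- lapply(exps, compute_mbei)

  s1 <- expr$cef_viruses$samples
  grp <- function(s, cond) s$array_id[s$condition == cond]
  anova_groups <- list(ctrl1 = grp(s1, "RCASBP"), ctrl2 = grp(s1, "NY315"),
                       test = grp(s1, "SRA"))
  tr_res <- anova_transformation_test(expr$cef_viruses, anova_groups[1:2],
                                      anova_groups$test, config)
  wt_res <- pairwise_differential(expr$cef_viruses, grp(s1, "RCASBP"),
                                  grp(s1, "SRA"), config)
  temp_res <- pairwise_differential(expr$cef_viruses, grp(s1, "RCASBP"),
                                    grp(s1, "RCASBP_perm"), config)

  s2 <- expr$cef_ts$samples
  cef_res <- pairwise_differential(expr$cef_ts, grp(s2, "NY72-4_41.5"),
                                   grp(s2, "NY72-4_37.5"), config)
  s3 <- expr$cnr_ts$samples
  cnr_res <- pairwise_differential(expr$cnr_ts, grp(s3, "CNR_NY72-4_41.5"),
                                   grp(s3, "CNR_NY72-4_37.5"), config)

  fdr <- NULL
  if (estimate_fdr) {
    fdr <- list(
      tr = estimate_permutation_fdr(expr$cef_viruses, anova_groups, "anova",
                                    config),
      cef_ts = estimate_permutation_fdr(
        expr$cef_ts, list(grp(s2, "NY72-4_41.5"), grp(s2, "NY72-4_37.5")),
        "pairwise", config),
      cnr_ts = estimate_permutation_fdr(
        expr$cnr_ts, list(grp(s3, "CNR_NY72-4_41.5"),
                          grp(s3, "CNR_NY72-4_37.5")),
        "pairwise", config))
  }

  collapse <- function(res) collapse_to_genes(res, ann)
  tr_g <- collapse(tr_res); cef_g <- collapse(cef_res)
  cnr_g <- collapse(cnr_res); wt_g <- collapse(wt_res)
  temp_g <- collapse(temp_res)

  tr_set <- result_to_gene_set(tr_g, "TR", "three-virus ANOVA regime")
  cef_set <- result_to_gene_set(cef_g, "CEF_ts", "ts fibroblast pairwise regime")
  cnr_set <- result_to_gene_set(cnr_g, "CNR_ts", "ts neuroretinal pairwise regime")

  cef_f <- filter_temperature_confounded(cef_set, temp_g, wt_g)
  cnr_f <- filter_temperature_confounded(cnr_set, temp_g, wt_g)

  sets <- build_gene_sets(tr_set, cef_f$retained, cnr_f$retained)

  recovery <- NULL
  truth <- bundle$truth
  if (!is.null(truth)) {
    planted <- c(truth$planted_up$gene_id, truth$planted_down$gene_id)
    csr <- set_ids(sets$CSR)
    benign <- c(planted, truth$temperature_genes$gene_id)
    recovery <- list(
      sensitivity = length(intersect(csr, planted)) / length(planted),
      false_discoveries = length(setdiff(csr, benign)),
      realized_fdp = if (length(csr)) length(setdiff(csr, benign)) /
        length(csr) else 0)
  }

  files <- character()
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    gmt <- file.path(out_dir, "discovery_sets.gmt")
    write_gene_sets_gmt(sets[c("TR", "CEF_ts", "CNR_ts", "common_all3",
                               "ts_only", "CSR", "TR_CEF_ts")], gmt)
    files <- c(gmt, paste0(gmt, ".members.tsv"))
  }
  manifest <- build_manifest(
    config, seeds = list(pipeline = config$seed),
    files = files,
    summaries = list(set_cardinalities = attr(sets, "summary"),
                     fdr = lapply(fdr, `[`, c("fdr_estimate",
                                              "observed_count")),
                     temperature_removed = c(
                       cef = length(cef_f$removed$members$gene_id),
                       cnr = length(cnr_f$removed$members$gene_id)),
                     recovery = recovery))
  structure(list(sets = sets,
                 results = list(tr = tr_g, cef_ts = cef_g, cnr_ts = cnr_g,
                                wt = wt_g, temperature = temp_g),
                 fdr = fdr,
                 temperature_filter = list(cef = cef_f$removed,
                                           cnr = cnr_f$removed),
                 recovery = recovery, manifest = manifest),
            class = "discovery_run")
}

#' @export
print.discovery_run <- function(x, ...) {
  cat("discovery_run\n")
  print(attr(x$sets, "summary"))
  if (!is.null(x$recovery)) {
    cat(sprintf("  planted-program sensitivity: %.2f; realized FDP: %.3f\n",
                x$recovery$sensitivity, x$recovery$realized_fdp))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Average-linkage outliers can come off the tree as clusters too small for
# survival comparison; reassign each tumor of an undersized cluster to the
# cluster whose members it correlates with best (over the centered
# clustering features).
merge_small_clusters <- function(labels, cohort, features, min_size = 2) {
  x <- cohort$expression[intersect(features, rownames(cohort$expression)), ,
                         drop = FALSE]
  x <- x - rowMeans(x)
  repeat {
    sizes <- table(labels)
    small <- names(sizes)[sizes < min_size]
    if (!length(small) || length(sizes) <= 2L) break
    cl <- small[1]
    members <- names(labels)[labels == cl]
    others <- setdiff(names(sizes), cl)
    cors <- stats::cor(x)
    for (tumor in members) {
      avg <- vapply(others, function(o) {
        mean(cors[tumor, names(labels)[labels == o & names(labels) != tumor]])
      }, numeric(1))
      labels[tumor] <- as.integer(others[which.max(avg)])
    }
    message(sprintf("cluster %s (< %d tumors) merged into nearest cluster(s)",
                    cl, min_size))
  }
  labels
}

#' Simulate a two-training-one-test signature study
#'
#' Three independent tumor cohorts sharing one planted aggressive program:
#' two training cohorts (for clustering-based signature derivation) and one
#' test cohort (for upper-quartile survival evaluation). The up-regulated
#' feature pool handed to clustering contains the planted program plus
#' survival-neutral decoy genes, emulating an up-regulated discovery set
#' that is only partly prognostic.
#'
#' @param seed Integer seed.
#' @param n_signature_genes Planted aggressive-program genes.
#' @param n_decoy_up Up-regulated discovery genes with no survival effect.
#' @param n_tumors,n_background_genes,hazard_ratio,expression_shift,censoring_rate,aggressive_fraction
#'   Cohort parameters (see [cohort_sim_config()]); `hazard_ratio` applies
#'   to all three cohorts unless `test_hazard_ratio` overrides the test
#'   cohort.
#' @param test_hazard_ratio Hazard ratio of the test cohort.
#' @return List with `train_a`, `train_b`, `test` (each a
#'   `tumor_cohort`), `csr_up` (`gene_set` of clustering features) and
#'   `truth` (planted signature genes and per-cohort aggressive tumors).
#' @export
simulate_signature_study <- function(seed = 1, n_signature_genes = 30,
                                     n_decoy_up = 50, n_tumors = 200,
                                     n_background_genes = 300,
                                     hazard_ratio = 3, expression_shift = 2,
                                     censoring_rate = 0.3,
                                     aggressive_fraction = 0.25,
                                     test_hazard_ratio = hazard_ratio) {
  sig <- pad_ids("SIG", n_signature_genes)
  mk <- function(s, hr, endpoint) {
    simulate_tumor_cohort(cohort_sim_config(
      n_tumors = n_tumors, n_background_genes = n_background_genes,
      signature_genes = sig, aggressive_fraction = aggressive_fraction,
      expression_shift = expression_shift, hazard_ratio = hr,
      censoring_rate = censoring_rate, endpoint = endpoint, seed = s))
  }
  a <- mk(seed, hazard_ratio, "disease-free")
  b <- mk(seed + 1000L, hazard_ratio, "disease-free")
  test <- mk(seed + 2000L, test_hazard_ratio, "disease-free")
  decoys <- pad_ids("BG", n_background_genes)[seq_len(n_decoy_up)]
  csr_up <- gene_set("CSR_up", c(sig, decoys), "up",
                     provenance = "planted program + survival-neutral decoys")
  list(train_a = a$cohort, train_b = b$cohort, test = test$cohort,
       csr_up = csr_up,
       truth = list(signature_genes = sig,
                    aggressive_tumors = list(a = a$truth$aggressive_tumors,
                                             b = b$truth$aggressive_tumors,
                                             test = test$truth$aggressive_tumors)))
}

#' Derive and evaluate an aggressive signature
#'
#' Maps the up-regulated discovery set onto the tumor platform, clusters
#' each training cohort (Pearson distance, average linkage, k clusters),
#' selects each poor-prognosis cluster by restricted mean survival, takes
#' per-cluster one-tailed candidate genes, intersects the two candidate
#' lists into the signature, and evaluates it on every test cohort via the
#' upper-quartile score split.
#'
#' @param csr_up `gene_set` of up-regulated discovery genes (or a character
#'   vector of features already on the tumor platform).
#' @param train_a,train_b Training `tumor_cohort`s with survival.
#' @param test_cohorts A `tumor_cohort` or (named) list of them.
#' @param config A [pipeline_config()] (`n_clusters`, `alpha_signature`,
#'   `quartile`).
#' @param ortholog_map Data frame (`source_id`, `target_id`); default maps
#'   each discovery id to itself.
#' @param out_dir Optional directory: signature GMT and a JSON report are
#'   written and listed in the manifest.
#' @return List of class `signature_run`: `signature`
#'   (`signature_result`), `training` (per-cohort cluster labels,
#'   poor-cluster diagnostics, candidates), `evaluations` (per test
#'   cohort), `manifest`.
#' @export
run_signature <- function(csr_up, train_a, train_b, test_cohorts,
                          config = pipeline_config(),
                          ortholog_map = NULL, out_dir = NULL) {
  features <- if (inherits(csr_up, "gene_set")) {
    map <- ortholog_map %||% identity_ortholog_map(set_ids(csr_up))
    map_orthologs(csr_up, map, direction_filter = "up")
  } else {
    as.character(csr_up)
  }
  if (inherits(test_cohorts, "tumor_cohort")) {
    test_cohorts <- list(test = test_cohorts)
  }
  train_one <- function(cohort) {
    labels <- cluster_samples(cohort, features, k = config$n_clusters)
    labels <- merge_small_clusters(labels, cohort, features, min_size = 2)
    poor <- select_poor_cluster(labels, cohort)
    cands <- candidate_genes_from_cluster(cohort, labels, poor$poor_cluster,
                                          alpha = config$alpha_signature,
                                          features = features)
    list(labels = labels, poor = poor, candidates = cands)
  }
  ta <- train_one(train_a)
  tb <- train_one(train_b)
  signature <- derive_aggressive_signature(ta$candidates, tb$candidates)
  if (!length(signature$genes)) {
    stopf("empty signature: candidate counts were %d and %d",
          length(signature$candidates$a), length(signature$candidates$b))
  }
  evaluations <- lapply(test_cohorts, evaluate_signature,
                        signature = signature, quartile = config$quartile)
  files <- character()
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    gmt <- file.path(out_dir, "aggressive_signature.gmt")
    write_gene_sets_gmt(gene_set("aggressive_signature", signature$genes,
                                 "up", provenance = "training intersection"),
                        gmt)
    rep_path <- file.path(out_dir, "signature_report.json")
    jsonlite::write_json(list(
      signature = signature$genes, concordance = signature$concordance,
      candidate_counts = lengths(signature$candidates),
      evaluations = lapply(evaluations, function(e) list(
        groups = as.list(e$groups),
        restricted_means = as.list(e$restricted_means),
        time_unit = e$time_unit, logrank_chisq = e$logrank_chisq,
        logrank_p = e$logrank_p))),
      rep_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    files <- c(gmt, paste0(gmt, ".members.tsv"), rep_path)
  }
  manifest <- build_manifest(
    config, seeds = list(pipeline = config$seed), files = files,
    summaries = list(
      cluster_sizes = list(a = as.vector(table(ta$labels)),
                           b = as.vector(table(tb$labels))),
      poor_clusters = c(a = ta$poor$poor_cluster, b = tb$poor$poor_cluster),
      candidate_counts = c(a = length(ta$candidates),
                           b = length(tb$candidates)),
      signature_size = length(signature$genes),
      concordance = signature$concordance,
      logrank_p = vapply(evaluations, `[[`, numeric(1), "logrank_p")))
  structure(list(signature = signature,
                 training = list(a = ta, b = tb),
                 evaluations = evaluations, manifest = manifest),
            class = "signature_run")
}

#' @export
print.signature_run <- function(x, ...) {
  cat(sprintf("signature_run: %d-gene signature (concordance %.2f)\n",
              length(x$signature$genes), x$signature$concordance))
  for (nm in names(x$evaluations)) {
    e <- x$evaluations[[nm]]
    cat(sprintf("  %s: log-rank p = %.3g; RMS high %.3g vs rest %.3g %s\n",
                nm, e$logrank_p, e$restricted_means[["high"]],
                e$restricted_means[["rest"]], e$time_unit))
  }
  invisible(x)
}
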