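#' Configuration for a synthetic probe-level microarray experiment
#'
#' Describes one experimental group of an oligonucleotide-array infection
#' study: a set of viral conditions (each with a culture temperature and a
#' flag saying whether cells are transformed under it), at least three
#' biological replicates per condition, planted differentially expressed
#' genes, optional temperature-responsive genes, and redundant probe sets
#' (two probe sets interrogating the same gene, as happens when annotation
#' collapses probe sets by shared gene IDs).
#'
#' The generative model works on perfect-match (PM) intensities:
#' \deqn{PM_{ij} = \phi_i \, 2^{x_g(c_j) + \epsilon_{ij}}, \qquad
#'       \epsilon_{ij} \sim N(0, \sigma^2)}
#' where \eqn{\phi_i} are probe affinities (log-normal, geometric mean 1
#' within each probe set, so probe-set summaries are unbiased),
#' \eqn{x_g(c)} is the true log2 expression of gene \eqn{g} under condition
#' \eqn{c}, and \eqn{\sigma} is `noise_sd`. Planted genes have
#' \eqn{x_g} shifted by \eqn{\pm\log_2(\mathrm{FC})} in transformed
#' conditions; temperature genes are shifted between the two temperature
#' labels regardless of transformation status.
#'
#' @param n_probesets Number of probe sets on the array.
#' @param probes_per_set PM probes per probe set (Affymetrix-style default 11).
#' @param conditions Data frame with columns `condition`, `temperature`
#'   (character labels) and `transformed` (logical). The default emulates a
#'   three-virus comparison: an empty-vector virus and a
#'   transformation-deficient mutant as controls, plus a wild-type
#'   transforming virus, all at 41.5 degrees C.
#' @param replicates_per_condition Biological replicates per condition
#'   (minimum 3).
#' @param n_planted_up,n_planted_down Numbers of genes planted up-/
#'   down-regulated in transformed conditions. Ignored when explicit
#'   `planted_up`/`planted_down` tables are supplied.
#' @param planted_up,planted_down Optional data.frames
#'   (`gene_id`, `fold_change`) pinning the planted program to specific gene
#'   IDs — used to share one transcriptional program across experiments.
#' @param fold_change_range Linear fold-change range (both > 1) from which
#'   planted effects are drawn uniformly.
#' @param n_temperature_genes Number of genes responding to temperature
#'   rather than transformation (requires two temperature labels).
#' @param temperature_genes Optional data.frame (`gene_id`, `fold_change`,
#'   `direction`) pinning temperature-responsive genes.
#' @param temperature_fc_range Linear fold-change range for temperature
#'   effects.
#' @param noise_sd SD of the additive Gaussian noise on the log2 scale
#'   (log-normal multiplicative on intensities).
#' @param redundancy_fraction Fraction of genes represented by two probe
#'   sets.
#' @param affinity_sd SD of log2 probe affinities.
#' @param baseline_log2_mean,baseline_log2_sd Mean/SD of baseline log2 gene
#'   expression.
#' @param seed Integer seed; identical configs with identical seeds produce
#'   bit-identical output.
#' @return A validated list of class `array_sim_config`.
#' @seealso [simulate_microarray_experiment()]
#' @export
array_sim_config <- function(n_probesets = 2000,
                             probes_per_set = 11,
                             conditions = data.frame(
                               condition = c("RCASBP", "NY315", "SRA"),
                               temperature = "41.5",
                               transformed = c(FALSE, FALSE, TRUE),
                               stringsAsFactors = FALSE),
                             replicates_per_condition = 3,
                             n_planted_up = 100,
                             n_planted_down = 100,
                             planted_up = NULL,
                             planted_down = NULL,
                             fold_change_range = c(2, 8),
                             n_temperature_genes = 0,
                             temperature_genes = NULL,
                             temperature_fc_range = c(2, 6),
                             noise_sd = 0.25,
                             redundancy_fraction = 0.1,
                             affinity_sd = 0.5,
                             baseline_log2_mean = 8,
                             baseline_log2_sd = 1,
                             seed = 1) {
  cfg <- list(n_probesets = n_probesets, probes_per_set = probes_per_set,
              conditions = conditions,
              replicates_per_condition = replicates_per_condition,
              n_planted_up = n_planted_up, n_planted_down = n_planted_down,
              planted_up = planted_up, planted_down = planted_down,
              fold_change_range = fold_change_range,
              n_temperature_genes = n_temperature_genes,
              temperature_genes = temperature_genes,
              temperature_fc_range = temperature_fc_range,
              noise_sd = noise_sd,
              redundancy_fraction = redundancy_fraction,
              affinity_sd = affinity_sd,
              baseline_log2_mean = baseline_log2_mean,
              baseline_log2_sd = baseline_log2_sd,
              seed = seed)
  validate_array_sim_config(cfg)
  structure(cfg, class = "array_sim_config")
}

validate_array_sim_config <- function(cfg) {
  if (!is_count(cfg$n_probesets, min = 1) ||
      !is_count(cfg$probes_per_set, min = 1)) {
    stopf("configuration error: n_probesets and probes_per_set must be positive integers")
  }
  cond <- cfg$conditions
  if (!is.data.frame(cond) ||
      !all(c("condition", "temperature", "transformed") %in% names(cond)) ||
      nrow(cond) < 2L) {
    stopf("configuration error: conditions must be a data.frame with columns condition/temperature/transformed and >= 2 rows")
  }
  if (anyDuplicated(cond$condition)) {
    stopf("configuration error: duplicated condition labels")
  }
  if (!is_count(cfg$replicates_per_condition) ||
      cfg$replicates_per_condition < 3) {
    stopf("configuration error: replicates_per_condition must be >= 3")
  }
  n_up <- if (is.null(cfg$planted_up)) cfg$n_planted_up else nrow(cfg$planted_up)
  n_dn <- if (is.null(cfg$planted_down)) cfg$n_planted_down else nrow(cfg$planted_down)
  if (!is_count(n_up) || !is_count(n_dn)) {
    stopf("configuration error: planted counts must be nonnegative integers")
  }
  if (n_up + n_dn > cfg$n_probesets) {
    stopf("configuration error: planted counts (%d) exceed n_probesets (%d)",
          n_up + n_dn, cfg$n_probesets)
  }
  if (any(cfg$fold_change_range <= 1)) {
    stopf("configuration error: fold_change_range lower bound must exceed 1")
  }
  if (cfg$noise_sd < 0) stopf("configuration error: noise_sd must be >= 0")
  if (cfg$redundancy_fraction < 0 || cfg$redundancy_fraction > 1) {
    stopf("configuration error: redundancy_fraction must lie in [0, 1]")
  }
  n_temp <- if (is.null(cfg$temperature_genes)) cfg$n_temperature_genes
            else nrow(cfg$temperature_genes)
  if (n_temp > 0 && length(unique(cond$temperature)) < 2L) {
    stopf("configuration error: temperature genes require two temperature labels")
  }
  invisible(cfg)
}

#' Simulate a probe-level microarray infection experiment
#'
#' Generates perfect-match probe intensities for every array of an
#' experimental group, together with a ground-truth record sufficient to
#' score any downstream caller (planted fold changes, temperature genes,
#' probe-set-to-gene redundancy map).
#'
#' Genes outnumber probe sets by the redundancy fraction:
#' `n_genes = round(n_probesets / (1 + redundancy_fraction))`, and the
#' first `n_probesets - n_genes` genes are interrogated by a second probe
#' set with independent probe affinities but identical true expression.
#' Temperature effects apply to arrays whose temperature label equals the
#' second of the two sorted temperature labels (the shift is between the
#' labels, with random sign unless pinned).
#'
#' @param config An [array_sim_config()].
#' @return A list with components `probe_matrix` (class `probe_matrix`:
#'   `intensities` probe-by-array matrix, `probes` probe annotation,
#'   `samples` array metadata) and `truth` (class `ground_truth`).
#' @examples
#' sim <- simulate_microarray_experiment(array_sim_config(
#'   n_probesets = 50, noise_sd = 0, n_planted_up = 5, n_planted_down = 5,
#'   seed = 7))
#' dim(sim$probe_matrix$intensities)
#' head(sim$truth$planted_up)
#' @export
simulate_microarray_experiment <- function(config) {
  validate_array_sim_config(config)
  with_rng_seed(config$seed, {
    cond <- config$conditions
    n_red <- round(config$n_probesets * config$redundancy_fraction /
                     (1 + config$redundancy_fraction))
    n_genes <- config$n_probesets - n_red
    genes <- pad_ids("G", n_genes)
    ps_gene <- c(genes, genes[seq_len(n_red)])
    probeset_id <- pad_ids("PS", config$n_probesets)
    probeset_to_gene <- data.frame(probeset_id = probeset_id,
                                   gene_id = ps_gene,
                                   stringsAsFactors = FALSE)

    baseline <- stats::rnorm(n_genes, config$baseline_log2_mean,
                             config$baseline_log2_sd)
    names(baseline) <- genes

    # planted transformation program
    pick <- function(tbl, n, pool, fc_range) {
      if (!is.null(tbl)) {
        bad <- setdiff(tbl$gene_id, genes)
        if (length(bad)) stopf("planted gene ids not in universe: %s", bad[1])
        return(tbl)
      }
      ids <- sample(pool, n)
      data.frame(gene_id = ids,
                 fold_change = stats::runif(n, fc_range[1], fc_range[2]),
                 stringsAsFactors = FALSE)
    }
    pool <- genes
    up <- pick(config$planted_up, config$n_planted_up, pool,
               config$fold_change_range)
    pool <- setdiff(pool, up$gene_id)
    down <- pick(config$planted_down, config$n_planted_down, pool,
                 config$fold_change_range)
    pool <- setdiff(pool, down$gene_id)

    temps <- sort(unique(cond$temperature))
    temp_tbl <- config$temperature_genes
    n_temp <- if (is.null(temp_tbl)) config$n_temperature_genes else nrow(temp_tbl)
    if (is.null(temp_tbl) && n_temp > 0) {
      ids <- sample(pool, n_temp)
      temp_tbl <- data.frame(
        gene_id = ids,
        fold_change = stats::runif(n_temp, config$temperature_fc_range[1],
                                   config$temperature_fc_range[2]),
        direction = sample(c("up", "down"), n_temp, replace = TRUE),
        stringsAsFactors = FALSE)
    }
    if (is.null(temp_tbl)) {
      temp_tbl <- data.frame(gene_id = character(), fold_change = numeric(),
                             direction = character(), stringsAsFactors = FALSE)
    }

    # true log2 expression per gene x condition
    x <- matrix(baseline, nrow = n_genes, ncol = nrow(cond),
                dimnames = list(genes, cond$condition))
    transformed <- cond$transformed
    x[up$gene_id, transformed] <- x[up$gene_id, transformed, drop = FALSE] +
      log2(up$fold_change)
    x[down$gene_id, transformed] <- x[down$gene_id, transformed, drop = FALSE] -
      log2(down$fold_change)
    if (nrow(temp_tbl)) {
      hot <- cond$temperature == temps[length(temps)]
      sgn <- ifelse(temp_tbl$direction == "up", 1, -1)
      x[temp_tbl$gene_id, hot] <- x[temp_tbl$gene_id, hot, drop = FALSE] +
        sgn * log2(temp_tbl$fold_change)
    }

    # probe affinities: log-normal, geometric mean 1 within each probe set
    n_probes <- config$n_probesets * config$probes_per_set
    lphi <- stats::rnorm(n_probes, 0, config$affinity_sd)
    set_of_probe <- rep(seq_len(config$n_probesets),
                        each = config$probes_per_set)
    lphi <- lphi - ave(lphi, set_of_probe)

    samples <- data.frame(
      array_id = paste0(rep(cond$condition, each = config$replicates_per_condition),
                        "_r", seq_len(config$replicates_per_condition)),
      condition = rep(cond$condition, each = config$replicates_per_condition),
      temperature = rep(cond$temperature, each = config$replicates_per_condition),
      replicate = rep(seq_len(config$replicates_per_condition), nrow(cond)),
      stringsAsFactors = FALSE)

    gene_of_probe <- ps_gene[set_of_probe]
    cond_of_array <- match(samples$condition, cond$condition)
    # log2 PM = log2(phi) + x_g(cond) + noise
    true_log2 <- x[cbind(rep(match(gene_of_probe, genes), nrow(samples)),
                         rep(cond_of_array, each = n_probes))]
    eps <- if (config$noise_sd > 0) {
      stats::rnorm(n_probes * nrow(samples), 0, config$noise_sd)
    } else 0
    pm <- matrix(2^(lphi + true_log2 + eps), nrow = n_probes,
                 dimnames = list(
                   paste0(probeset_id[set_of_probe], "_p",
                          rep(seq_len(config$probes_per_set),
                              config$n_probesets)),
                   samples$array_id))

    probes <- data.frame(probeset_id = probeset_id[set_of_probe],
                         probe_index = rep(seq_len(config$probes_per_set),
                                           config$n_probesets),
                         stringsAsFactors = FALSE)
    pmx <- structure(list(intensities = pm, probes = probes,
                          samples = samples), class = "probe_matrix")
    truth <- structure(list(
      planted_up = up, planted_down = down, temperature_genes = temp_tbl,
      probeset_to_gene = probeset_to_gene,
      transformed_conditions = cond$condition[cond$transformed],
      temperature_levels = temps,
      gene_universe = genes), class = "ground_truth")
    list(probe_matrix = pmx, truth = truth)
  })
}

#' @export
print.probe_matrix <- function(x, ...) {
  cat(sprintf("probe_matrix: %d probes (%d probe sets) x %d arrays\n",
              nrow(x$intensities), length(unique(x$probes$probeset_id)),
              ncol(x$intensities)))
  cat("  conditions:", paste(unique(x$samples$condition), collapse = ", "),
      "\n")
  invisible(x)
}

#' Configuration for a synthetic survival-annotated tumor cohort
#'
#' Emulates a tumor expression cohort with clinical follow-up: a fraction of
#' tumors carry an "aggressive" transcriptional program (signature genes
#' shifted up on the log2 scale) and experience events at a proportionally
#' higher hazard. Survival times are exponential with hazard
#' `baseline_hazard * hazard_ratio^is_aggressive`; censoring times are
#' independent exponentials whose rate is solved numerically so the expected
#' censoring proportion equals `censoring_rate`.
#'
#' @param n_tumors Number of tumors.
#' @param n_background_genes Genes unrelated to the aggressive program.
#' @param n_signature_genes Genes shifted in aggressive tumors. Ignored if
#'   `signature_genes` supplies explicit ids.
#' @param signature_genes Optional character vector of signature gene ids
#'   (shared across cohorts to emulate a common program).
#' @param aggressive_fraction Fraction of tumors in the aggressive subgroup,
#'   in (0, 1).
#' @param expression_shift Log2 units added to signature genes in aggressive
#'   tumors.
#' @param hazard_ratio Hazard ratio of aggressive vs other tumors (> 0).
#' @param baseline_hazard Event hazard of non-aggressive tumors (> 0), in
#'   1/`time_unit`.
#' @param censoring_rate Expected fraction of censored observations, in
#'   [0, 1).
#' @param noise_sd SD of log2 expression around each gene's mean.
#' @param time_unit `"years"` or `"months"`; recorded, never converted.
#' @param endpoint Endpoint label carried into the cohort.
#' @param seed Integer seed.
#' @return A validated list of class `cohort_sim_config`.
#' @seealso [simulate_tumor_cohort()]
#' @export
cohort_sim_config <- function(n_tumors = 200,
                              n_background_genes = 1000,
                              n_signature_genes = 30,
                              signature_genes = NULL,
                              aggressive_fraction = 0.25,
                              expression_shift = 2,
                              hazard_ratio = 3,
                              baseline_hazard = 0.08,
                              censoring_rate = 0.3,
                              noise_sd = 1,
                              time_unit = "years",
                              endpoint = "disease-free",
                              seed = 1) {
  cfg <- list(n_tumors = n_tumors, n_background_genes = n_background_genes,
              n_signature_genes = n_signature_genes,
              signature_genes = signature_genes,
              aggressive_fraction = aggressive_fraction,
              expression_shift = expression_shift,
              hazard_ratio = hazard_ratio, baseline_hazard = baseline_hazard,
              censoring_rate = censoring_rate, noise_sd = noise_sd,
              time_unit = time_unit, endpoint = endpoint, seed = seed)
  if (!is_count(cfg$n_tumors, min = 4)) {
    stopf("configuration error: n_tumors must be an integer >= 4")
  }
  if (cfg$aggressive_fraction <= 0 || cfg$aggressive_fraction >= 1) {
    stopf("configuration error: aggressive_fraction must lie in (0, 1)")
  }
  if (cfg$hazard_ratio <= 0) {
    stopf("configuration error: hazard_ratio must be > 0")
  }
  if (cfg$baseline_hazard <= 0) {
    stopf("configuration error: baseline_hazard must be > 0")
  }
  if (cfg$censoring_rate < 0 || cfg$censoring_rate >= 1) {
    stopf("configuration error: censoring_rate must lie in [0, 1)")
  }
  structure(cfg, class = "cohort_sim_config")
}

# Exponential censoring rate c with P(censor) = q for a two-hazard mixture:
# q(c) = p * c/(c + h1) + (1 - p) * c/(c + h0), increasing in c.
solve_censoring_rate <- function(q, p, h1, h0) {
  if (q == 0) return(0)
  f <- function(cc) p * cc / (cc + h1) + (1 - p) * cc / (cc + h0) - q
  stats::uniroot(f, lower = 1e-12, upper = 1e12, tol = 1e-12)$root
}

#' Simulate a tumor cohort with proportional-hazards survival
#'
#' @param config A [cohort_sim_config()].
#' @return A list with `cohort` (class `tumor_cohort`: log2 `expression`
#'   gene-by-tumor matrix, `survival` data.frame with `tumor_id`, `time`,
#'   `event`, plus `time_unit` and `endpoint` labels) and `truth` (class
#'   `ground_truth`: `aggressive_tumors`, `signature_genes`,
#'   `true_hazard_ratio`).
#' @examples
#' sim <- simulate_tumor_cohort(cohort_sim_config(
#'   n_tumors = 40, n_background_genes = 50, censoring_rate = 0, seed = 3))
#' all(sim$cohort$survival$event == 1)
#' @export
simulate_tumor_cohort <- function(config) {
  if (!inherits(config, "cohort_sim_config")) {
    config <- do.call(cohort_sim_config, config)
  }
  with_rng_seed(config$seed, {
    sig <- config$signature_genes
    if (is.null(sig)) sig <- pad_ids("SIG", config$n_signature_genes)
    bg <- pad_ids("BG", config$n_background_genes)
    genes <- c(sig, bg)
    n <- config$n_tumors
    tumor_id <- pad_ids("T", n)

    n_agg <- max(1L, round(n * config$aggressive_fraction))
    aggressive <- sort(sample(n, n_agg))
    is_agg <- seq_len(n) %in% aggressive

    gene_mean <- stats::rnorm(length(genes), 8, 1)
    expr <- matrix(stats::rnorm(length(genes) * n, gene_mean,
                                config$noise_sd),
                   nrow = length(genes),
                   dimnames = list(genes, tumor_id))
    expr[sig, is_agg] <- expr[sig, is_agg, drop = FALSE] +
      config$expression_shift

    h <- config$baseline_hazard * config$hazard_ratio^is_agg
    t_event <- stats::rexp(n, rate = h)
    c_rate <- solve_censoring_rate(config$censoring_rate,
                                   config$aggressive_fraction,
                                   config$baseline_hazard * config$hazard_ratio,
                                   config$baseline_hazard)
    t_cens <- if (c_rate > 0) stats::rexp(n, rate = c_rate) else rep(Inf, n)
    time <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)

    cohort <- structure(list(
      expression = expr,
      survival = data.frame(tumor_id = tumor_id, time = time, event = event,
                            stringsAsFactors = FALSE),
      time_unit = config$time_unit, endpoint = config$endpoint),
      class = "tumor_cohort")
    truth <- structure(list(
      aggressive_tumors = tumor_id[is_agg],
      signature_genes = sig,
      true_hazard_ratio = config$hazard_ratio), class = "ground_truth")
    list(cohort = cohort, truth = truth)
  })
}

#' @export
print.tumor_cohort <- function(x, ...) {
  cat(sprintf("tumor_cohort: %d genes x %d tumors; %d events / %d censored (%s, %s)\n",
              nrow(x$expression), ncol(x$expression),
              sum(x$survival$event), sum(1 - x$survival$event),
              x$endpoint, x$time_unit))
  invisible(x)
}

#' Generate discovery gene lists with a configurable overlap structure
#'
#' Builds the three discovery-stage gene sets — transformation-regulated
#' (TR), temperature-sensitive fibroblast (CEF ts) and temperature-sensitive
#' neuroretinal (CNR ts) — from synthetic gene IDs, with every overlap
#' region and per-region up/down split configurable. The CNR list is also
#' returned at probe-set level with a configurable number of redundant
#' probe sets (two probe sets per gene), so the probe-set-to-gene collapse
#' can be exercised.
#'
#' The defaults reproduce the cardinality structure of a three-system v-Src
#' discovery analysis: 953 TR genes (418 up / 535 down), 477 CEF ts genes
#' (261 up / 216 down), 947 CNR ts genes (444 up / 503 down) carried by
#' 1062 probe sets, a 145-gene TR-and-CEF overlap (61 up / 84 down), an
#' 84-gene three-way common set and a 91-gene ts-only set, which combine
#' into a 175-gene common v-Src-regulated (CSR) set containing 80
#' up-regulated genes.
#'
#' @param n_common_all3 Genes in all three sets.
#' @param n_tr_cef_only Genes in TR and CEF ts but not CNR ts.
#' @param n_ts_only Genes in both ts sets but not TR.
#' @param n_tr_only,n_cef_only,n_cnr_only Genes private to each set.
#' @param up_common_all3,up_tr_cef_only,up_ts_only,up_tr_only,up_cef_only,up_cnr_only
#'   Up-regulated counts within each region (the remainder is down).
#' @param n_cnr_redundant CNR genes carried by two probe sets.
#' @param seed Seed for the synthetic p-values attached to the CNR
#'   probe-set table (used by the lowest-p collapse rule).
#' @return A list with `gene_set` objects `tr`, `cef_ts`, `cnr_ts`
#'   (gene level), a `cnr_probesets` data.frame (`probeset_id`, `gene_id`,
#'   `direction`, `fold_change`, `p_value`) and the matching `annotation`
#'   data.frame.
#' @export
simulate_set_structure <- function(n_common_all3 = 84, n_tr_cef_only = 61,
                                   n_ts_only = 91, n_tr_only = 808,
                                   n_cef_only = 241, n_cnr_only = 772,
                                   up_common_all3 = 33, up_tr_cef_only = 28,
                                   up_ts_only = 47, up_tr_only = 357,
                                   up_cef_only = 153, up_cnr_only = 364,
                                   n_cnr_redundant = 115, seed = 1) {
  counts <- c(n_common_all3, n_tr_cef_only, n_ts_only, n_tr_only,
              n_cef_only, n_cnr_only)
  ups <- c(up_common_all3, up_tr_cef_only, up_ts_only, up_tr_only,
           up_cef_only, up_cnr_only)
  stopifnot(all(ups <= counts), all(counts >= 0))
  total <- sum(counts)
  ids <- pad_ids("G", total)
  region <- rep(c("common3", "trcef", "tsonly", "tr_only", "cef_only",
                  "cnr_only"), counts)
  dirs <- unlist(mapply(function(n, u) rep(c("up", "down"), c(u, n - u)),
                        counts, ups, SIMPLIFY = FALSE))
  univ <- data.frame(gene_id = ids, region = region, direction = dirs,
                     stringsAsFactors = FALSE)

  take <- function(regions, name, prov) {
    m <- univ[univ$region %in% regions, ]
    gene_set(name, m$gene_id, m$direction, provenance = prov)
  }
  tr <- take(c("common3", "trcef", "tr_only"), "TR",
             "three-virus ANOVA regime")
  cef <- take(c("common3", "trcef", "tsonly", "cef_only"), "CEF_ts",
              "ts fibroblast pairwise regime")
  cnr_members <- univ[univ$region %in% c("common3", "tsonly", "cnr_only"), ]
  cnr <- gene_set("CNR_ts", cnr_members$gene_id, cnr_members$direction,
                  provenance = "ts neuroretinal pairwise regime")

  if (n_cnr_redundant > nrow(cnr_members)) {
    stopf("n_cnr_redundant exceeds the number of CNR genes")
  }
  ps <- with_rng_seed(seed, {
    dup <- cnr_members$gene_id[seq_len(n_cnr_redundant)]
    tab <- rbind(cnr_members[, c("gene_id", "direction")],
                 cnr_members[cnr_members$gene_id %in% dup,
                             c("gene_id", "direction")])
    tab <- tab[order(tab$gene_id), ]
    tab$probeset_id <- pad_ids("CNRPS", nrow(tab))
    tab$fold_change <- stats::runif(nrow(tab), 2, 8)
    tab$p_value <- stats::runif(nrow(tab), 1e-6, 0.05)
    rownames(tab) <- NULL
    tab[, c("probeset_id", "gene_id", "direction", "fold_change", "p_value")]
  })
  annotation <- data.frame(probeset_id = ps$probeset_id,
                           gene_id = ps$gene_id,
                           symbol = ps$gene_id, stringsAsFactors = FALSE)
  list(tr = tr, cef_ts = cef, cnr_ts = cnr, cnr_probesets = ps,
       annotation = annotation)
}
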