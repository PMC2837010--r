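# Differential-expression calling and set algebra.
#
# Calls follow a two-fold rule on log2 expression plus a significance
# threshold: p <= 0.05 for pairwise t-tests and p <= 0.01 for the one-way
# ANOVA transformation regime. Statistics are computed row-wise over the
# whole matrix (closed-form pooled t and one-way F), which keeps the
# label-permutation FDR loop fast; they agree with stats::t.test/aov
# to machine precision (verified in the test suite).

#' Pipeline thresholds and tuning parameters
#'
#' @param fc_threshold Linear fold-change threshold (default 2).
#' @param alpha_pairwise p-value threshold for pairwise t-tests (0.05).
#' @param alpha_anova p-value threshold for the ANOVA regime (0.01).
#' @param n_permutations Label permutations for FDR estimation. 10,000 for
#'   a full analysis; 200 is a practical desk-scale default.
#' @param alpha_signature One-tailed threshold for poor-cluster candidate
#'   genes (0.05).
#' @param n_clusters Tumor clusters cut from the training dendrogram (4).
#' @param quartile Upper fraction of tumors labeled signature-high (0.25).
#' @param welch Use Welch (unequal-variance) t-tests instead of pooled.
#' @param seed Seed for permutation draws.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(fc_threshold = 2, alpha_pairwise = 0.05,
                            alpha_anova = 0.01, n_permutations = 200,
                            alpha_signature = 0.05, n_clusters = 4,
                            quartile = 0.25, welch = FALSE, seed = 1) {
  stopifnot(fc_threshold >= 1, alpha_pairwise > 0, alpha_pairwise <= 1,
            alpha_anova > 0, alpha_anova <= 1, n_permutations >= 20,
            n_clusters >= 2, quartile > 0, quartile < 1)
  structure(list(fc_threshold = fc_threshold,
                 alpha_pairwise = alpha_pairwise, alpha_anova = alpha_anova,
                 n_permutations = n_permutations,
                 alpha_signature = alpha_signature, n_clusters = n_clusters,
                 quartile = quartile, welch = welch, seed = seed),
            class = "pipeline_config")
}

# Row-wise two-sample t-test on a log2 matrix. Returns t, df, p.
row_t_test <- function(lx, ia, ib, welch = FALSE) {
  na <- length(ia); nb <- length(ib)
  ma <- rowMeans(lx[, ia, drop = FALSE])
  mb <- rowMeans(lx[, ib, drop = FALSE])
  va <- rowSums((lx[, ia, drop = FALSE] - ma)^2) / (na - 1)
  vb <- rowSums((lx[, ib, drop = FALSE] - mb)^2) / (nb - 1)
  if (welch) {
    se2 <- va / na + vb / nb
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  } else {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se2 <- sp2 * (1 / na + 1 / nb)
    df <- rep(na + nb - 2, length(ma))
  }
  tt <- (mb - ma) / sqrt(se2)
  p <- 2 * stats::pt(-abs(tt), df)
  # degenerate rows: zero variance in both groups
  zero <- se2 == 0
  p[zero & mb == ma] <- 1
  p[zero & mb != ma] <- 0
  list(t = tt, p = p, mean_a = ma, mean_b = mb)
}

# Row-wise one-way fixed-effects ANOVA on a log2 matrix.
row_anova <- function(lx, groups) {
  k <- length(groups)
  n <- sum(lengths(groups))
  gm <- rowMeans(lx[, unlist(groups), drop = FALSE])
  ssb <- 0; ssw <- 0
  means <- matrix(0, nrow(lx), k)
  for (g in seq_len(k)) {
    xg <- lx[, groups[[g]], drop = FALSE]
    mg <- rowMeans(xg)
    means[, g] <- mg
    ssb <- ssb + length(groups[[g]]) * (mg - gm)^2
    ssw <- ssw + rowSums((xg - mg)^2)
  }
  df1 <- k - 1; df2 <- n - k
  msb <- ssb / df1; msw <- ssw / df2
  f <- msb / msw
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  p[msw == 0 & msb == 0] <- 1
  p[msw == 0 & msb > 0] <- 0
  list(f = f, p = p, group_means = means)
}

#' Pairwise differential-expression call
#'
#' Per feature: linear fold change as the ratio of group geometric means
#' (group B over group A), p-value from an unpaired two-tailed t-test on
#' log2 values (pooled variance by default). A feature passes when its fold
#' change is at least `fc_threshold` in either direction and
#' `p <= alpha_pairwise`.
#'
#' @param expr An `expr_matrix` (linear scale) or a positive numeric matrix.
#' @param group_a,group_b Sample ids or column indices (>= 2 each).
#' @param config A [pipeline_config()].
#' @return A data.frame (`feature_id`, `fold_change` (linear, >= 1),
#'   `log2_ratio` (signed, B vs A), `direction`, `p_value`, `passes`,
#'   `test_kind`).
#' @export
pairwise_differential <- function(expr, group_a, group_b,
                                  config = pipeline_config()) {
  v <- expr_values(expr)
  ia <- resolve_cols(v, group_a); ib <- resolve_cols(v, group_b)
  if (length(ia) < 2L || length(ib) < 2L) {
    stopf("each group needs at least 2 samples")
  }
  lx <- log2(v)
  tt <- row_t_test(lx, ia, ib, welch = config$welch)
  l2r <- tt$mean_b - tt$mean_a
  fc <- 2^abs(l2r)
  direction <- ifelse(l2r > 0, "up", ifelse(l2r < 0, "down", "none"))
  passes <- fc >= config$fc_threshold & tt$p <= config$alpha_pairwise &
    direction != "none"
  data.frame(feature_id = rownames(v), fold_change = fc, log2_ratio = l2r,
             direction = direction, p_value = tt$p, passes = passes,
             test_kind = "ttest", stringsAsFactors = FALSE, row.names = NULL)
}

#' Transformation-dependence call by one-way ANOVA
#'
#' The three-virus regime: two control conditions (empty-vector and
#' transformation-deficient virus) and one transforming test condition. A
#' feature passes when (i) the one-way ANOVA across the three groups on
#' log2 values gives `p <= alpha_anova`, (ii) the largest pairwise ratio of
#' group geometric means is at least `fc_threshold`, and (iii) the test
#' group differs from the pooled controls by at least `fc_threshold`.
#' Features whose only two-fold contrast is control-vs-control are not
#' transformation-dependent: they get direction `"none"` and fail.
#'
#' @param expr An `expr_matrix` or positive matrix.
#' @param control_groups List of two sample-id/index vectors.
#' @param test_group Sample ids/indices of the transforming condition.
#' @param config A [pipeline_config()].
#' @return A data.frame as in [pairwise_differential()], where
#'   `fold_change` is the maximum pairwise group ratio and `log2_ratio` the
#'   test-vs-pooled-controls contrast; `test_kind = "anova"`.
#' @export
anova_transformation_test <- function(expr, control_groups, test_group,
                                      config = pipeline_config()) {
  v <- expr_values(expr)
  if (length(control_groups) != 2L) {
    stopf("control_groups must list exactly two groups")
  }
  groups <- c(lapply(control_groups, resolve_cols, v = v),
              list(resolve_cols(v, test_group)))
  if (any(lengths(groups) < 2L)) stopf("each group needs >= 2 samples")
  lx <- log2(v)
  an <- row_anova(lx, groups)
  gm <- an$group_means                       # columns: ctrl1, ctrl2, test
  max_pair_l2 <- pmax(abs(gm[, 1] - gm[, 2]), abs(gm[, 1] - gm[, 3]),
                      abs(gm[, 2] - gm[, 3]))
  pooled_ctrl <- rowMeans(lx[, c(groups[[1]], groups[[2]]), drop = FALSE])
  contrast <- rowMeans(lx[, groups[[3]], drop = FALSE]) - pooled_ctrl
  lfc <- log2(config$fc_threshold)
  test_specific <- abs(contrast) >= lfc
  direction <- ifelse(test_specific, ifelse(contrast > 0, "up", "down"),
                      "none")
  passes <- an$p <= config$alpha_anova & max_pair_l2 >= lfc & test_specific
  data.frame(feature_id = rownames(v), fold_change = 2^max_pair_l2,
             log2_ratio = contrast, direction = direction, p_value = an$p,
             passes = passes, test_kind = "anova", stringsAsFactors = FALSE,
             row.names = NULL)
}

n_label_arrangements <- function(sizes) {
  exp(lgamma(sum(sizes) + 1) - sum(lgamma(sizes + 1)))
}

#' Permutation-based false discovery rate
#'
#' Permutes sample-to-group labels (within the experimental group), re-runs
#' the identical call rule, and estimates
#' `FDR = mean(null pass count) / observed pass count`. Arrangements
#' equivalent to the observed grouping (up to the call rule's symmetries:
#' group swap for the pairwise rule, control-group swap for the ANOVA rule)
#' are excluded from the null — they would reproduce the observed calls
#' verbatim, which with few samples per group badly inflates the estimate.
#' With fewer than 20 distinct label arrangements the permutation
#' distribution is enumerated exhaustively instead (with a warning). Zero
#' observed calls give an FDR of 0 with a warning.
#'
#' @param expr An `expr_matrix` or positive matrix.
#' @param groups Named list of sample-id/index vectors defining the
#'   comparison (2 groups for the pairwise regime, 3 with the test group
#'   last for the ANOVA regime).
#' @param call_rule `"pairwise"`, `"anova"`, or a function
#'   `(expr, groups, config) -> logical pass vector`.
#' @param config A [pipeline_config()]; `n_permutations` and `seed` drive
#'   the permutation draw.
#' @return List with `fdr_estimate`, `observed_count`, `mean_null_count`
#'   and the vector `null_counts`.
#' @export
estimate_permutation_fdr <- function(expr, groups, call_rule,
                                     config = pipeline_config()) {
  v <- expr_values(expr)
  groups <- lapply(groups, resolve_cols, v = v)
  rule <- if (is.function(call_rule)) {
    call_rule
  } else if (identical(call_rule, "pairwise")) {
    function(expr, groups, config) {
      pairwise_differential(expr, groups[[1]], groups[[2]], config)$passes
    }
  } else if (identical(call_rule, "anova")) {
    function(expr, groups, config) {
      anova_transformation_test(expr, groups[1:2], groups[[3]], config)$passes
    }
  } else {
    stopf("call_rule must be 'pairwise', 'anova' or a function")
  }
  observed <- sum(rule(v, groups, config))
  all_cols <- unlist(groups)
  sizes <- lengths(groups)
  n_arr <- n_label_arrangements(sizes)
  relabel <- function(perm) {
    split(perm, rep(seq_along(groups), sizes))
  }
  # canonical key of an arrangement, modulo the call rule's symmetries
  rule_kind <- if (is.character(call_rule)) call_rule else "generic"
  arr_key <- function(gs) {
    parts <- vapply(gs, function(g) paste(sort(g), collapse = ","),
                    character(1))
    sym <- switch(rule_kind,
                  pairwise = seq_along(parts),          # fully symmetric
                  anova = seq_len(2),                   # controls swap
                  integer(0))
    if (length(sym)) parts[sym] <- sort(parts[sym])
    paste(parts, collapse = "|")
  }
  observed_key <- arr_key(groups)
  null_counts <- if (n_arr < 20) {
    warnf("only %.0f distinct label arrangements; enumerating exhaustively",
          n_arr)
    perms <- all_permutations(all_cols)
    keys <- vapply(perms, function(p) arr_key(relabel(p)), character(1))
    perms <- perms[!duplicated(keys) & keys != observed_key]
    vapply(perms, function(p) sum(rule(v, relabel(p), config)), numeric(1))
  } else {
    with_rng_seed(config$seed, {
      vapply(seq_len(config$n_permutations), function(i) {
        for (try in 1:100) {
          p <- sample(all_cols)
          if (arr_key(relabel(p)) != observed_key) break
        }
        sum(rule(v, relabel(p), config))
      }, numeric(1))
    })
  }
  mean_null <- mean(null_counts)
  fdr <- if (observed == 0) {
    warnf("no observed calls; permutation FDR reported as 0")
    0
  } else {
    mean_null / observed
  }
  list(fdr_estimate = fdr, observed_count = observed,
       mean_null_count = mean_null, null_counts = null_counts)
}

all_permutations <- function(x) {
  if (length(x) == 1L) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in all_permutations(x[-i])) out[[length(out) + 1L]] <- c(x[i], rest)
  }
  out
}

#' Remove temperature-confounded genes from a ts-regime gene set
#'
#' In a temperature-sensitive (ts) kinase experiment the permissive vs
#' non-permissive comparison confounds transformation with temperature. A
#' gene called in the ts regime is attributed to temperature — and removed —
#' when it is also called in the temperature-control comparison
#' (uninfected-control cells at the two temperatures) with a magnitude at
#' least as large as its transformation response in the wild-type regime at
#' the non-permissive temperature. Genes absent from the wild-type
#' comparison are treated as unchanged there (fold change 1), the
#' conservative choice that removes the gene.
#'
#' @param ts_set A `gene_set` with fold changes (ts-regime calls, gene
#'   level).
#' @param temperature_result Gene-level differential result of the
#'   temperature-control comparison (`passes` marks temperature-regulated
#'   genes).
#' @param wt_result_at_41 Gene-level differential result of the wild-type
#'   transformation comparison at the non-permissive temperature.
#' @return List with `retained` and `removed` `gene_set`s; the removed
#'   set's members carry `temp_log2fc` and `wt_log2fc` columns.
#' @export
filter_temperature_confounded <- function(ts_set, temperature_result,
                                          wt_result_at_41) {
  m <- ts_set$members
  temp <- temperature_result[temperature_result$passes, , drop = FALSE]
  t_idx <- match(m$gene_id, temp$feature_id)
  w_idx <- match(m$gene_id, wt_result_at_41$feature_id)
  temp_l2 <- abs(temp$log2_ratio[t_idx])          # NA if not temp-regulated
  wt_l2 <- abs(wt_result_at_41$log2_ratio[w_idx])
  wt_l2[is.na(wt_l2)] <- 0                        # absent => fold change 1
  remove <- !is.na(t_idx) & temp_l2 >= wt_l2
  removed <- m[remove, , drop = FALSE]
  removed$temp_log2fc <- temp_l2[remove]
  removed$wt_log2fc <- wt_l2[remove]
  ret <- gene_set(ts_set$name, m$gene_id[!remove], m$direction[!remove],
                  fold_change = m$fold_change[!remove],
                  provenance = paste0(ts_set$provenance,
                                      "; temperature-filtered"))
  rem <- structure(list(name = paste0(ts_set$name, "_temperature_confounded"),
                        members = removed, provenance = ts_set$provenance),
                   class = "gene_set")
  list(retained = ret, removed = rem)
}

merge_directions <- function(ids, primary, secondary) {
  d <- primary$direction[match(ids, primary$gene_id)]
  miss <- is.na(d)
  d[miss] <- secondary$direction[match(ids[miss], secondary$gene_id)]
  d
}

#' Set algebra over the three discovery gene sets
#'
#' From the transformation-regulated (TR) set and the two
#' temperature-sensitive sets (fibroblast `cef_ts`, neuroretinal `cnr_ts`),
#' all at gene level, derives:
#' \itemize{
#'   \item `common_all3` — genes in all three sets;
#'   \item `ts_only` — genes in both ts sets but not in TR;
#'   \item `CSR` — the common v-Src-regulated set,
#'     `common_all3` + `ts_only` (a disjoint union);
#'   \item `TR_CEF_ts` — genes in both TR and the fibroblast ts set.
#' }
#' Directions are carried through; on conflict between input sets, the TR
#' direction wins (then `cef_ts`), and the conflict is reported in the
#' `direction_conflicts` attribute.
#'
#' @param tr,cef_ts,cnr_ts `gene_set` objects at gene level.
#' @return Named list of `gene_set`s (`TR`, `CEF_ts`, `CNR_ts`,
#'   `common_all3`, `ts_only`, `CSR`, `TR_CEF_ts`) with a `summary`
#'   data.frame of cardinalities and up/down breakdowns.
#' @export
build_gene_sets <- function(tr, cef_ts, cnr_ts) {
  all_members <- rbind(
    cbind(tr$members[c("gene_id", "direction")], src = "tr"),
    cbind(cef_ts$members[c("gene_id", "direction")], src = "cef"),
    cbind(cnr_ts$members[c("gene_id", "direction")], src = "cnr"))
  conf <- tapply(all_members$direction, all_members$gene_id,
                 function(d) length(unique(d)) > 1)
  conflicts <- names(conf)[conf]
  if (length(conflicts)) {
    message(sprintf("direction conflict for %d gene(s); using TR (then CEF_ts) direction",
                    length(conflicts)))
  }
  ids_tr <- set_ids(tr); ids_cef <- set_ids(cef_ts); ids_cnr <- set_ids(cnr_ts)
  mk <- function(name, ids, prov) {
    dirs <- merge_directions(ids, tr$members, cef_ts$members)
    miss <- is.na(dirs)
    dirs[miss] <- cnr_ts$members$direction[match(ids[miss],
                                                 cnr_ts$members$gene_id)]
    gene_set(name, ids, dirs, provenance = prov)
  }
  common3 <- mk("common_all3", intersect(intersect(ids_tr, ids_cef), ids_cnr),
                "TR & CEF_ts & CNR_ts")
  ts_only <- mk("ts_only", setdiff(intersect(ids_cef, ids_cnr), ids_tr),
                "(CEF_ts & CNR_ts) \\ TR")
  csr <- mk("CSR", c(set_ids(common3), set_ids(ts_only)),
            "common_all3 + ts_only")
  tr_cef <- mk("TR_CEF_ts", intersect(ids_tr, ids_cef), "TR & CEF_ts")
  fam <- list(TR = tr, CEF_ts = cef_ts, CNR_ts = cnr_ts,
              common_all3 = common3, ts_only = ts_only, CSR = csr,
              TR_CEF_ts = tr_cef)
  summary <- do.call(rbind, lapply(names(fam), function(nm) {
    ud <- up_down_counts(fam[[nm]])
    data.frame(set = nm, n = length(fam[[nm]]), up = ud["up"],
               down = ud["down"], row.names = NULL)
  }))
  attr(fam, "summary") <- summary
  attr(fam, "direction_conflicts") <- conflicts
  fam
}

#' Cross-platform concordance of paired expression estimates
#'
#' Spearman rank correlation and ordinary-least-squares slope of paired
#' log-ratio estimates of the same genes from two measurement platforms
#' (e.g. northern blot densitometry vs microarray).
#'
#' @param x,y Numeric vectors of paired log ratios (length >= 3), or a
#'   two-column data.frame/matrix as `x`.
#' @return List with `spearman_rho`, `spearman_p` and `ols_slope`.
#' @export
platform_concordance <- function(x, y = NULL) {
  if (is.null(y)) {
    stopifnot(ncol(x) >= 2L)
    y <- x[[2]]; x <- x[[1]]
  }
  if (length(x) != length(y) || length(x) < 3L) {
    stopf("need >= 3 complete pairs")
  }
  if (!all(is.finite(x)) || !all(is.finite(y))) stopf("non-finite values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stopf("correlation undefined for constant input")
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  slope <- unname(stats::coef(stats::lm(y ~ x))[2])
  list(spearman_rho = unname(ct$estimate), spearman_p = ct$p.value,
       ols_slope = slope)
}

# --- shared small helpers -------------------------------------------------

expr_values <- function(expr) {
  v <- if (inherits(expr, "expr_matrix")) expr$values else expr
  if (!is.matrix(v)) stopf("expected an expr_matrix or numeric matrix")
  if (is.null(rownames(v))) rownames(v) <- pad_ids("F", nrow(v))
  v
}

resolve_cols <- function(v, idx) {
  if (is.character(idx)) {
    m <- match(idx, colnames(v))
    if (anyNA(m)) stopf("unknown sample ids: %s",
                        paste(idx[is.na(m)], collapse = ", "))
    m
  } else {
    as.integer(idx)
  }
}
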