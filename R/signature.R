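# Aggressive-signature derivation: cluster training tumors on the
# up-regulated CSR orthologs, find the poor-prognosis cluster, select genes
# over-expressed there, and intersect candidates across training sets.

#' Map an up-regulated gene set onto a target platform via orthologs
#'
#' Keeps only up-direction members, expands each through the ortholog map
#' to all of its target-platform probe sets (many-to-many kept), drops
#' genes without any ortholog entry, and returns the de-duplicated,
#' order-stable target feature list.
#'
#' @param gene_set A `gene_set`.
#' @param ortholog_map Data frame with columns `source_id`, `target_id`.
#' @param direction_filter Direction to keep (default `"up"`).
#' @return Character vector of target features; dropped source genes are in
#'   attribute `"dropped"`.
#' @export
map_orthologs <- function(gene_set, ortholog_map, direction_filter = "up") {
  stopifnot(all(c("source_id", "target_id") %in% names(ortholog_map)))
  keep <- gene_set$members[gene_set$members$direction == direction_filter, ]
  hits <- ortholog_map[ortholog_map$source_id %in% keep$gene_id, ]
  dropped <- setdiff(keep$gene_id, hits$source_id)
  if (length(dropped)) {
    message(sprintf("%d gene(s) without ortholog entries dropped (e.g. %s)",
                    length(dropped), dropped[1]))
  }
  # order-stable: follow the input member order, then map order
  hits <- hits[order(match(hits$source_id, keep$gene_id)), ]
  out <- hits$target_id[!duplicated(hits$target_id)]
  if (!length(out)) stopf("no orthologous features to cluster on")
  attr(out, "dropped") <- dropped
  out
}

#' Identity ortholog map for a feature universe
#'
#' Convenience constructor mapping each id to itself — used when discovery
#' and tumor platforms share identifiers (as in the synthetic pipeline).
#'
#' @param ids Character vector of feature ids.
#' @return Data frame with `source_id`, `target_id`.
#' @export
identity_ortholog_map <- function(ids) {
  data.frame(source_id = ids, target_id = ids, stringsAsFactors = FALSE)
}

#' Cluster tumors by Pearson correlation distance
#'
#' Agglomerative hierarchical clustering of tumors over a feature subset:
#' feature rows are mean-centered, pairwise tumor distance is
#' `1 - Pearson correlation`, linkage is average (UPGMA), and the tree is
#' cut into exactly `k` clusters. Deterministic for fixed input.
#'
#' @param cohort A `tumor_cohort`.
#' @param features Feature ids to cluster on (default: all). Features
#'   absent from the cohort are dropped with a message.
#' @param k Number of clusters (>= 2).
#' @param center Mean-center feature rows first (default TRUE).
#' @return Integer cluster labels (1..k) named by tumor id, with the
#'   `hclust` tree in attribute `"tree"`.
#' @export
cluster_samples <- function(cohort, features = NULL, k = 4, center = TRUE) {
  expr <- cohort$expression
  if (is.null(features)) features <- rownames(expr)
  miss <- setdiff(features, rownames(expr))
  if (length(miss)) {
    message(sprintf("%d feature(s) absent from cohort dropped", length(miss)))
    features <- setdiff(features, miss)
  }
  if (!length(features)) stopf("no clustering features present in cohort")
  if (k < 2) stopf("k must be >= 2")
  if (ncol(expr) < k) stopf("fewer tumors than clusters")
  x <- expr[features, , drop = FALSE]
  sds <- apply(x, 2, stats::sd)       # raw profile variance per tumor
  if (center) x <- x - rowMeans(x)
  if (any(sds == 0)) {
    stopf("tumor(s) with zero variance over the clustering features: %s",
          paste(colnames(x)[sds == 0], collapse = ", "))
  }
  d <- stats::as.dist(1 - stats::cor(x))
  tree <- stats::hclust(d, method = "average")
  labels <- stats::cutree(tree, k = k)
  attr(labels, "tree") <- tree
  labels
}

#' Select the poor-prognosis tumor cluster
#'
#' Computes the Kaplan-Meier curve and restricted mean survival (truncated
#' at the largest observed time in the cohort) for every cluster and
#' returns the cluster with the smallest restricted mean, together with the
#' k-group log-rank test across clusters. Ties are broken toward the
#' smallest cluster index, with a warning.
#'
#' @param labels Cluster labels named by tumor id (from
#'   [cluster_samples()]).
#' @param cohort A `tumor_cohort`.
#' @return List with `poor_cluster`, `restricted_means` (named by cluster),
#'   `tau`, `logrank_chisq`, `logrank_p`.
#' @export
select_poor_cluster <- function(labels, cohort) {
  surv <- cohort$survival
  labels <- labels[match(surv$tumor_id, names(labels))]
  if (anyNA(labels)) stopf("cluster labels missing for some tumors")
  sizes <- table(labels)
  if (length(sizes) < 2L) stopf("need at least 2 clusters")
  if (any(sizes < 2L)) stopf("every cluster needs >= 2 tumors")
  tau <- max(surv$time)
  rms <- vapply(sort(unique(labels)), function(cl) {
    i <- labels == cl
    restricted_mean_survival(km_estimate(surv$time[i], surv$event[i]), tau,
                             warn_beyond = FALSE)
  }, numeric(1))
  names(rms) <- sort(unique(labels))
  lr <- logrank_test(surv$time, surv$event, labels)
  best <- rms == min(rms)
  if (sum(best) > 1L) {
    warnf("restricted-mean tie between clusters %s; choosing the smallest index",
          paste(names(rms)[best], collapse = ", "))
  }
  list(poor_cluster = as.integer(names(rms)[which(best)[1]]),
       restricted_means = rms, tau = tau,
       logrank_chisq = lr$chisq, logrank_p = lr$p)
}

#' Candidate signature genes from the poor-prognosis cluster
#'
#' Per feature, a one-tailed (greater in the poor cluster) unpaired
#' pooled-variance t-test of poor-cluster tumors against all other tumors
#' pooled; features with `p < alpha` become candidates. Features with zero
#' variance in both groups are excluded with a message.
#'
#' @param cohort A `tumor_cohort` (log2 expression).
#' @param labels Cluster labels named by tumor id.
#' @param poor_id The poor-prognosis cluster id.
#' @param alpha One-tailed significance threshold (default 0.05).
#' @param features Optional feature subset to test (default: every cohort
#'   feature); typically the up-regulated discovery features used for
#'   clustering.
#' @return A `gene_set` of candidates (direction `"up"`), with the full
#'   per-feature table in attribute `"table"`.
#' @export
candidate_genes_from_cluster <- function(cohort, labels, poor_id,
                                         alpha = 0.05, features = NULL) {
  expr <- cohort$expression
  if (!is.null(features)) {
    features <- intersect(features, rownames(expr))
    if (!length(features)) stopf("no requested features present in cohort")
    expr <- expr[features, , drop = FALSE]
  }
  labels <- labels[match(colnames(expr), names(labels))]
  ip <- which(labels == poor_id)
  io <- which(labels != poor_id)
  if (length(ip) < 2L || length(io) < 2L) {
    stopf("poor cluster and complement each need >= 2 tumors")
  }
  tt <- row_t_test(expr, io, ip)            # mean_b = poor cluster
  # one-tailed p for 'greater in poor cluster'
  df <- length(ip) + length(io) - 2
  p1 <- stats::pt(tt$t, df, lower.tail = FALSE)
  degenerate <- is.na(tt$t)
  if (any(degenerate)) {
    message(sprintf("%d zero-variance feature(s) excluded", sum(degenerate)))
  }
  sel <- !degenerate & p1 < alpha
  tab <- data.frame(feature_id = rownames(expr), delta = tt$mean_b - tt$mean_a,
                    p_value = p1, selected = sel, stringsAsFactors = FALSE)
  gs <- gene_set(sprintf("poor_cluster_%s_candidates", poor_id),
                 rownames(expr)[sel], "up",
                 provenance = sprintf("one-tailed t-test p < %g vs pooled complement",
                                      alpha))
  attr(gs, "table") <- tab
  gs
}

#' Derive the aggressive signature from two training candidate lists
#'
#' The signature is the intersection of the two training sets' candidate
#' gene lists; concordance is the fraction of the smaller candidate list
#' recovered in the intersection.
#'
#' @param candidates_a,candidates_b `gene_set`s of per-training-set
#'   candidates (gene level).
#' @return An object of class `signature_result`: list with `genes`,
#'   `candidates` (both input id vectors), `concordance`.
#' @export
derive_aggressive_signature <- function(candidates_a, candidates_b) {
  a <- set_ids(candidates_a); b <- set_ids(candidates_b)
  genes <- intersect(a, b)
  conc <- if (min(length(a), length(b)) == 0) 0 else
    length(genes) / min(length(a), length(b))
  structure(list(genes = genes,
                 candidates = list(a = a, b = b),
                 concordance = conc), class = "signature_result")
}

#' @export
print.signature_result <- function(x, ...) {
  cat(sprintf("signature_result: %d genes (candidates %d and %d; concordance %.2f)\n",
              length(x$genes), length(x$candidates$a), length(x$candidates$b),
              x$concordance))
  invisible(x)
}
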