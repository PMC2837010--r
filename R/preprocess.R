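# Array normalization and probe-set summarization.
#
# The pipeline mirrors dChip-style preprocessing: arrays are median-scaled
# across experiments, normalized within each experimental group against the
# group's median-intensity array through an invariant probe set, and
# summarized to expression indices by a perfect-match-only multiplicative
# model fit by alternating least squares.

#' Scale arrays to a common median intensity
#'
#' Each array (column) is rescaled multiplicatively so that its median
#' intensity equals `target_median`. Within-array intensity ratios are
#' unchanged. Used to put separate experiments on a comparable intensity
#' scale before within-group normalization.
#'
#' @param matrices A `probe_matrix`, or a list of them (one per experiment).
#' @param target_median Positive number, or `"auto"`: the mean of all input
#'   array medians.
#' @return Input object(s) with scaled intensities.
#' @export
scale_to_common_median <- function(matrices, target_median = "auto") {
  single <- inherits(matrices, "probe_matrix")
  if (single) matrices <- list(matrices)
  if (!length(matrices)) stopf("no matrices supplied")
  meds <- lapply(matrices, function(m) apply(m$intensities, 2, stats::median))
  if (any(unlist(meds) == 0)) {
    stopf("array with zero median intensity cannot be scaled")
  }
  target <- if (identical(target_median, "auto")) mean(unlist(meds))
            else as.numeric(target_median)
  if (!is_scalar_num(target) || target <= 0) {
    stopf("target_median must be a positive number or 'auto'")
  }
  out <- mapply(function(m, md) {
    m$intensities <- sweep(m$intensities, 2, target / md, `*`)
    m
  }, matrices, meds, SIMPLIFY = FALSE)
  if (single) out[[1]] else out
}

#' Select rank-invariant probes between two arrays
#'
#' Iteratively retains probes whose normalized rank difference between the
#' target and baseline arrays is below `rank_threshold`, recomputing ranks
#' within the retained set, until the set changes by less than 1% or
#' `max_iter` is reached. Probes whose ranks are stable across arrays are
#' presumed non-differentially expressed and anchor the normalization
#' curve.
#'
#' @param target_array,baseline_array Numeric intensity vectors of equal
#'   length (>= 10).
#' @param rank_threshold Maximum |rank difference| / (current set size).
#' @param max_iter Iteration cap.
#' @return Integer vector of probe indices (into the input vectors). Never
#'   empty: if iteration empties the set, the N/10 probes with the smallest
#'   initial rank differences are returned instead.
#' @export
select_invariant_probes <- function(target_array, baseline_array,
                                    rank_threshold = 0.005, max_iter = 30) {
  n <- length(target_array)
  if (length(baseline_array) != n) {
    stopf("target and baseline arrays differ in length (%d vs %d)",
          n, length(baseline_array))
  }
  if (n < 10) stopf("need at least 10 probes")
  keep <- seq_len(n)
  rd0 <- abs(rank(target_array) - rank(baseline_array)) / n
  for (i in seq_len(max_iter)) {
    rt <- rank(target_array[keep])
    rb <- rank(baseline_array[keep])
    ok <- abs(rt - rb) / length(keep) < rank_threshold
    if (!any(ok)) {
      keep <- order(rd0)[seq_len(max(1L, n %/% 10L))]
      break
    }
    new_keep <- keep[ok]
    done <- (length(keep) - length(new_keep)) < 0.01 * length(keep)
    keep <- new_keep
    if (done) break
  }
  sort(keep)
}

#' Normalize a target array against a baseline through invariant probes
#'
#' Fits a monotone normalization curve — a running median of baseline
#' intensity as a function of target intensity over the invariant probe set
#' (window = 10% of the invariant probes) — and maps every target intensity
#' through it by piecewise-linear interpolation, with linear extrapolation
#' beyond the invariant range. The curve is fit on the log2 scale, where
#' array noise is approximately homoscedastic, and is forced
#' non-decreasing, so the map preserves within-array rank order.
#'
#' Rank differences saturate at the extremes of the intensity range (the
#' brightest probes of two arrays have nearly equal ranks whatever their
#' values), so the outermost invariant pairs carry no real evidence of the
#' array-to-array transfer curve; the `trim` fraction of pairs at each end
#' is therefore dropped before fitting, and intensities beyond the fitted
#' range are mapped with unit log-scale slope (fold differences relative to
#' the nearest calibrated intensity are preserved).
#'
#' @param target_array,baseline_array Numeric intensity vectors.
#' @param invariant_set Integer probe indices from
#'   [select_invariant_probes()]. Fewer than 10 probes triggers a warning
#'   and a fallback to median-ratio scaling.
#' @param trim Fraction of invariant pairs dropped at each intensity
#'   extreme before the curve fit.
#' @return Normalized target intensity vector.
#' @export
normalize_to_baseline <- function(target_array, baseline_array,
                                  invariant_set, trim = 0.1) {
  n <- length(target_array)
  if (length(baseline_array) != n) stopf("array length mismatch")
  if (!length(invariant_set)) stopf("invariant set is empty")
  if (length(invariant_set) < 10) {
    warnf("invariant set has %d (< 10) probes; falling back to median-ratio scaling",
          length(invariant_set))
    return(target_array * stats::median(baseline_array) /
             stats::median(target_array))
  }
  lt <- log2(target_array)
  xt <- lt[invariant_set]
  yb <- log2(baseline_array)[invariant_set]
  if (trim > 0 && length(xt) * (1 - 2 * trim) >= 10) {
    qs <- stats::quantile(xt, c(trim, 1 - trim))
    keep <- xt >= qs[1] & xt <= qs[2]
    xt <- xt[keep]; yb <- yb[keep]
  }
  o <- order(xt)
  xt <- xt[o]; yb <- yb[o]
  k <- max(3L, round(0.1 * length(xt)))
  if (k %% 2L == 0L) k <- k + 1L
  k <- min(k, length(xt) - (1 - length(xt) %% 2L))
  ys <- stats::runmed(yb, k, endrule = "median")
  if (length(xt) > 4L) {
    # the outermost points use Tukey's end-point extrapolation; drop them
    idx <- 2:(length(xt) - 1L)
    xt <- xt[idx]; ys <- ys[idx]
  }
  ys <- cummax(ys)                       # enforce a monotone curve
  # collapse ties in x (approx() requires increasing x)
  ux <- !duplicated(xt)
  xs <- xt[ux]
  ys <- vapply(split(ys, cumsum(ux)), max, numeric(1))
  if (length(xs) < 2L) {
    return(target_array * stats::median(baseline_array) /
             stats::median(target_array))
  }
  out <- stats::approx(xs, ys, xout = lt, rule = 2)$y
  # beyond the invariant range extrapolate with unit slope on the log
  # scale: fold differences relative to the nearest calibrated intensity
  # are preserved (a fitted tail slope would rest on too few probes)
  m <- length(xs)
  lo <- lt < xs[1]
  hi <- lt > xs[m]
  out[lo] <- ys[1] + (lt[lo] - xs[1])
  out[hi] <- ys[m] + (lt[hi] - xs[m])
  2^out
}

#' Normalize every array of an experimental group to its median array
#'
#' Convenience wrapper applying [select_invariant_probes()] and
#' [normalize_to_baseline()] to each non-baseline array of a
#' `probe_matrix`. The baseline is the array whose median intensity is the
#' median of the per-array medians within the group.
#'
#' @param probe_matrix A `probe_matrix`.
#' @param rank_threshold,max_iter Passed to [select_invariant_probes()].
#' @param trim Passed to [normalize_to_baseline()].
#' @return The `probe_matrix` with normalized intensities; the chosen
#'   baseline array id is recorded in attribute `"baseline_array"`.
#' @export
normalize_group <- function(probe_matrix, rank_threshold = 0.005,
                            max_iter = 30, trim = 0.1) {
  pm <- probe_matrix$intensities
  meds <- apply(pm, 2, stats::median)
  base_j <- which.min(abs(meds - stats::median(meds)))
  base <- pm[, base_j]
  for (j in seq_len(ncol(pm))) {
    if (j == base_j) next
    inv <- select_invariant_probes(pm[, j], base, rank_threshold, max_iter)
    pm[, j] <- normalize_to_baseline(pm[, j], base, inv, trim = trim)
  }
  probe_matrix$intensities <- pm
  attr(probe_matrix, "baseline_array") <- colnames(pm)[base_j]
  probe_matrix
}

# Alternating-least-squares fit of PM(i,j) = phi_i * theta_j on (a subset
# of) observed entries. `mask` is a logical matrix of entries to use.
als_fit <- function(Y, mask = NULL, tol = 1e-10, max_iter = 100) {
  if (is.null(mask)) mask <- matrix(TRUE, nrow(Y), ncol(Y))
  W <- mask * 1
  Yw <- Y * W
  theta <- colSums(Yw) / pmax(colSums(W), 1)
  for (it in seq_len(max_iter)) {
    denom <- W %*% theta^2
    phi <- as.vector((Yw %*% theta) / ifelse(denom > 0, denom, 1))
    mphi <- mean(phi)
    if (mphi == 0) mphi <- 1
    phi <- phi / mphi
    denom2 <- crossprod(W, phi^2)
    theta_new <- as.vector(crossprod(Yw, phi) / ifelse(denom2 > 0, denom2, 1)) *
      1  # identifiability: mean(phi) = 1 absorbed into theta via rescale above
    delta <- max(abs(theta_new - theta)) / max(max(abs(theta)), 1e-12)
    theta <- theta_new
    if (delta < tol) break
  }
  list(phi = phi, theta = theta)
}

#' Model-based expression index from perfect-match probes
#'
#' Summarizes probe-level intensities to one expression value per probe set
#' and array by fitting the multiplicative model
#' \deqn{PM_{ij} = \phi_i \theta_j + \epsilon_{ij}}
#' per probe set by alternating least squares under the identifiability
#' constraint \eqn{\mathrm{mean}(\phi) = 1}. One outlier pass masks
#' residuals exceeding 3 residual SDs and refits. \eqn{\theta_j} is
#' reported as the expression value, floored at `1e-6 * median(theta)`
#' (keeping values positive for downstream log transforms). Probe sets with
#' a single probe return that probe's intensities unchanged.
#'
#' @param probe_matrix A `probe_matrix` with >= 2 arrays.
#' @return An `expr_matrix`: list with `values` (probe-set by array matrix,
#'   linear scale) and `samples` (array metadata).
#' @export
compute_mbei <- function(probe_matrix) {
  pm <- probe_matrix$intensities
  if (ncol(pm) < 2L) stopf("MBEI requires at least 2 arrays")
  sets <- probe_matrix$probes$probeset_id
  uset <- unique(sets)
  idx <- split(seq_along(sets), factor(sets, levels = uset))
  vals <- matrix(0, length(uset), ncol(pm),
                 dimnames = list(uset, colnames(pm)))
  for (s in seq_along(uset)) {
    Y <- pm[idx[[s]], , drop = FALSE]
    if (nrow(Y) == 1L) {
      vals[s, ] <- Y[1, ]
      next
    }
    if (all(Y == 0)) {
      warnf("probe set %s has all-zero intensities; expression floored at 0",
            uset[s])
      next
    }
    fit <- als_fit(Y)
    resid <- Y - outer(fit$phi, fit$theta)
    s_r <- stats::sd(resid)
    if (is.finite(s_r) && s_r > 0) {
      mask <- abs(resid) <= 3 * s_r
      # keep at least one observation per row/column
      bad_row <- rowSums(mask) == 0
      bad_col <- colSums(mask) == 0
      mask[bad_row, ] <- TRUE
      mask[, bad_col] <- TRUE
      if (!all(mask)) fit <- als_fit(Y, mask)
    }
    vals[s, ] <- fit$theta
  }
  med <- stats::median(vals[vals > 0])
  floor_at <- 1e-6 * if (is.finite(med) && med > 0) med else 1
  vals[vals < floor_at] <- floor_at
  structure(list(values = vals, samples = probe_matrix$samples),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d features x %d samples\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Collapse probe sets to unique genes
#'
#' Redundant probe sets (identical gene IDs in the annotation) are
#' collapsed so every output feature is a unique gene. For a differential
#' result, the probe set with the smallest p-value is retained (ties broken
#' by lexicographically smallest probe-set id). For an expression matrix, a
#' `retain` map (gene id -> probe-set id, e.g. taken from a collapsed
#' differential result's `probeset_id` column) selects the surviving row;
#' without one, the probe set with the largest median intensity is kept.
#'
#' @param x A differential result data.frame (columns `feature_id`,
#'   `p_value`, ...) or an `expr_matrix`.
#' @param annotation Data frame with columns `probeset_id`, `gene_id` (and
#'   optionally `symbol`) covering every feature of `x`.
#' @param retain Optional named character vector (names = gene ids,
#'   values = probeset ids) for expression matrices.
#' @return Same type as `x`, at gene level. Differential results gain a
#'   `probeset_id` column recording the retained probe set.
#' @export
collapse_to_genes <- function(x, annotation, retain = NULL) {
  UseMethod("collapse_to_genes")
}

map_genes <- function(features, annotation) {
  m <- match(features, annotation$probeset_id)
  if (anyNA(m)) {
    stopf("unannotated features: %s",
          paste(utils::head(features[is.na(m)], 5), collapse = ", "))
  }
  annotation$gene_id[m]
}

#' @export
collapse_to_genes.data.frame <- function(x, annotation, retain = NULL) {
  stopifnot(all(c("feature_id", "p_value") %in% names(x)))
  gene <- map_genes(x$feature_id, annotation)
  # order by gene, then p, then probeset id: first row per gene wins
  o <- order(gene, x$p_value, x$feature_id)
  xo <- x[o, , drop = FALSE]
  keep <- !duplicated(gene[o])
  out <- xo[keep, , drop = FALSE]
  out$probeset_id <- out$feature_id
  out$feature_id <- gene[o][keep]
  rownames(out) <- NULL
  out
}

#' @export
collapse_to_genes.expr_matrix <- function(x, annotation, retain = NULL) {
  gene <- map_genes(rownames(x$values), annotation)
  if (is.null(retain)) {
    med <- apply(x$values, 1, stats::median)
    o <- order(gene, -med, rownames(x$values))
  } else {
    chosen <- rownames(x$values) == unname(retain[gene])
    chosen[is.na(chosen)] <- FALSE
    o <- order(gene, !chosen, rownames(x$values))
  }
  keep <- !duplicated(gene[o])
  v <- x$values[o, , drop = FALSE][keep, , drop = FALSE]
  rownames(v) <- gene[o][keep]
  x$values <- v
  x
}
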