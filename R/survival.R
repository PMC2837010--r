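# Signature scoring and survival comparison.
#
# Kaplan-Meier estimation and the log-rank test are delegated to the
# survival package (survfit / survdiff); restricted-mean integration, the
# mean-centered signature score and the upper-quartile split are
# implemented here.

#' Kaplan-Meier product-limit estimate
#'
#' Right-continuous step estimate of the survival function, with the
#' standard tie convention (events precede censorings at equal times).
#'
#' @param times Positive follow-up times.
#' @param events 0/1 event indicators (1 = event, 0 = censored).
#' @return An object of class `km_curve`: list with `time` (distinct event
#'   times, ascending), `n_risk`, `n_event`, `surv` (S(t) just after each
#'   event time), `n` and `max_time` (largest observed time, event or
#'   censoring).
#' @examples
#' km <- km_estimate(c(1, 2, 3, 4), c(1, 1, 0, 1))
#' km$surv  # 0.75, 0.50, 0.00
#' @export
km_estimate <- function(times, events) {
  if (!length(times)) stopf("empty input")
  if (length(events) != length(times)) stopf("times/events length mismatch")
  if (any(times <= 0)) stopf("times must be positive")
  if (!all(events %in% c(0, 1))) stopf("events must be 0/1")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1,
                           conf.type = "log")
  keep <- fit$n.event > 0
  structure(list(time = fit$time[keep], n_risk = fit$n.risk[keep],
                 n_event = fit$n.event[keep], surv = fit$surv[keep],
                 lower = fit$lower[keep], upper = fit$upper[keep],
                 n = length(times), max_time = max(times)),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("km_curve: n = %d, %d distinct event times, final S = %.3f\n",
              x$n, length(x$time),
              if (length(x$surv)) x$surv[length(x$surv)] else 1))
  invisible(x)
}

#' Restricted mean survival time
#'
#' Area under the Kaplan-Meier step function on `[0, tau]`. Beyond the last
#' observed time the curve is held at its last value (with a warning), the
#' usual convention when `tau` exceeds follow-up.
#'
#' @param curve A `km_curve`.
#' @param tau Truncation time (> 0).
#' @param warn_beyond Warn when `tau` exceeds the curve's last observed
#'   time (set `FALSE` when truncating per-group curves at a cohort-wide
#'   time, where running past a group's follow-up is expected).
#' @return The restricted mean, in the time unit of the input.
#' @examples
#' km <- km_estimate(c(1, 2, 3, 4), c(1, 1, 0, 1))
#' restricted_mean_survival(km, 4)  # 2.75
#' @export
restricted_mean_survival <- function(curve, tau, warn_beyond = TRUE) {
  stopifnot(inherits(curve, "km_curve"))
  if (!is_scalar_num(tau) || tau <= 0) stopf("tau must be positive")
  if (warn_beyond && tau > curve$max_time) {
    warnf("tau (%g) exceeds the last observed time (%g); S held at its last value",
          tau, curve$max_time)
  }
  knots <- c(0, curve$time[curve$time < tau], tau)
  heights <- c(1, curve$surv[curve$time < tau])
  sum(diff(knots) * heights)
}

#' Log-rank test
#'
#' Standard (unweighted) log-rank test over the distinct event times, using
#' hypergeometric means and variances; the k-group version uses the
#' quadratic form with a chi-square reference on k-1 degrees of freedom.
#'
#' @param times Positive follow-up times.
#' @param events 0/1 event indicators.
#' @param group_labels Group membership (>= 2 non-empty groups).
#' @return List with `chisq`, `df`, `p`, and per-group `observed` /
#'   `expected` event counts.
#' @examples
#' logrank_test(c(1, 2, 3, 4), c(1, 1, 1, 1), c("a", "a", "b", "b"))$chisq
#' @export
logrank_test <- function(times, events, group_labels) {
  g <- droplevels(as.factor(group_labels))
  if (nlevels(g) < 2L) {
    stopf("all subjects in one group; need >= 2 non-empty groups")
  }
  fit <- tryCatch(survival::survdiff(survival::Surv(times, events) ~ g),
                  error = function(e) NULL)
  if (!is.null(fit)) {
    df <- length(fit$n) - 1
    return(list(chisq = unname(fit$chisq), df = df,
                p = stats::pchisq(fit$chisq, df, lower.tail = FALSE),
                observed = fit$obs, expected = fit$exp))
  }
  # survdiff refuses singular variance matrices (e.g. every subject failing
  # at a single time); compute the quadratic form with a pseudo-inverse,
  # where directions without variance carry no information.
  logrank_quadratic(times, events, g)
}

logrank_quadratic <- function(times, events, g) {
  k <- nlevels(g)
  O <- E <- numeric(k)
  V <- matrix(0, k, k)
  for (t in sort(unique(times[events == 1]))) {
    at <- times >= t
    n <- sum(at)
    n_g <- tabulate(g[at], k)
    d <- sum(times == t & events == 1)
    d_g <- tabulate(g[times == t & events == 1], k)
    O <- O + d_g
    E <- E + d * n_g / n
    if (n > 1) {
      frac <- n_g / n
      V <- V + d * (n - d) / (n - 1) * (diag(frac, k) - tcrossprod(frac))
    }
  }
  u <- (O - E)[-k]
  Vk <- V[-k, -k, drop = FALSE]
  sv <- svd(Vk)
  pos <- sv$d > max(sv$d[1], 0) * 1e-10
  chisq <- if (!any(pos)) 0 else {
    ginv <- sv$v[, pos, drop = FALSE] %*%
      (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
    drop(t(u) %*% ginv %*% u)
  }
  df <- k - 1
  list(chisq = chisq, df = df,
       p = stats::pchisq(chisq, df, lower.tail = FALSE),
       observed = O, expected = E)
}

#' Aggressive-signature score per tumor
#'
#' Every signature feature row is mean-centered across tumors; a tumor's
#' score is the mean of its centered values over the signature features
#' present in the cohort. Scores therefore sum to zero across tumors and
#' are invariant to adding per-gene constants.
#'
#' @param cohort A `tumor_cohort` (log2 expression).
#' @param signature Character vector of signature feature ids, or a
#'   `signature_result`.
#' @return Data frame (`tumor_id`, `score`), ordered as the cohort; the
#'   features actually used are in attribute `"features_used"`.
#' @export
aggressive_score <- function(cohort, signature) {
  if (inherits(signature, "signature_result")) signature <- signature$genes
  present <- intersect(signature, rownames(cohort$expression))
  missing <- setdiff(signature, present)
  if (length(missing)) {
    message(sprintf("%d signature feature(s) absent from cohort dropped",
                    length(missing)))
  }
  if (!length(present)) stopf("no signature features present in the cohort")
  x <- cohort$expression[present, , drop = FALSE]
  x <- x - rowMeans(x)
  out <- data.frame(tumor_id = colnames(cohort$expression),
                    score = colMeans(x), stringsAsFactors = FALSE,
                    row.names = NULL)
  attr(out, "features_used") <- present
  out
}

#' Split tumors at the upper quartile of the signature score
#'
#' The `ceiling(n * quartile)` tumors with the largest scores are labeled
#' `"high"`, the rest `"rest"`. Boundary ties are broken by stable
#' (lexicographic) tumor-id order, so the split is deterministic.
#'
#' @param scores Data frame from [aggressive_score()] (`tumor_id`,
#'   `score`).
#' @param quartile Upper fraction labeled high (default 0.25).
#' @return Character vector of labels named by tumor id, in input order.
#' @export
upper_quartile_split <- function(scores, quartile = 0.25) {
  n <- nrow(scores)
  if (n < 4L) stopf("need at least 4 tumors to split")
  stopifnot(quartile > 0, quartile < 1)
  n_high <- ceiling(n * quartile)
  o <- order(-scores$score, scores$tumor_id)
  labels <- rep("rest", n)
  labels[o[seq_len(n_high)]] <- "high"
  names(labels) <- scores$tumor_id
  labels
}

#' Evaluate a signature against a cohort's survival outcomes
#'
#' Composes [aggressive_score()], [upper_quartile_split()],
#' [km_estimate()] per group, [restricted_mean_survival()] (truncated at
#' the largest observed time) and [logrank_test()].
#'
#' @param cohort A `tumor_cohort`.
#' @param signature Feature ids or a `signature_result`.
#' @param quartile Upper fraction labeled high.
#' @return Object of class `signature_evaluation`: list with `groups`
#'   (sizes), `labels`, `scores`, `curves` (named list of `km_curve`),
#'   `restricted_means`, `tau`, `time_unit`, `endpoint`, `logrank_chisq`,
#'   `logrank_p`.
#' @export
evaluate_signature <- function(cohort, signature, quartile = 0.25) {
  scores <- aggressive_score(cohort, signature)
  labels <- upper_quartile_split(scores, quartile)
  surv <- cohort$survival
  lab <- labels[match(surv$tumor_id, names(labels))]
  tau <- max(surv$time)
  curves <- lapply(c(high = "high", rest = "rest"), function(gr) {
    i <- lab == gr
    km_estimate(surv$time[i], surv$event[i])
  })
  rms <- vapply(curves, restricted_mean_survival, numeric(1), tau = tau,
                warn_beyond = FALSE)
  lr <- logrank_test(surv$time, surv$event, lab)
  structure(list(groups = table(lab), labels = labels, scores = scores,
                 curves = curves, restricted_means = rms, tau = tau,
                 time_unit = cohort$time_unit, endpoint = cohort$endpoint,
                 logrank_chisq = lr$chisq, logrank_p = lr$p),
            class = "signature_evaluation")
}

#' @export
print.signature_evaluation <- function(x, ...) {
  cat(sprintf("signature_evaluation (%s, %s)\n", x$endpoint, x$time_unit))
  cat(sprintf("  groups: high = %d, rest = %d\n",
              x$groups[["high"]], x$groups[["rest"]]))
  cat(sprintf("  restricted mean survival (tau = %.3g): high = %.3g, rest = %.3g %s\n",
              x$tau, x$restricted_means[["high"]],
              x$restricted_means[["rest"]], x$time_unit))
  cat(sprintf("  log-rank: chi-square = %.3f, p = %.3g\n",
              x$logrank_chisq, x$logrank_p))
  invisible(x)
}

#' Per-group KM curve table for plotting or export
#'
#' @param evaluation A `signature_evaluation`.
#' @return Data frame with columns `group`, `time`, `n_risk`, `n_event`,
#'   `survival`.
#' @export
km_curve_table <- function(evaluation) {
  do.call(rbind, lapply(names(evaluation$curves), function(gr) {
    cv <- evaluation$curves[[gr]]
    data.frame(group = gr, time = cv$time, n_risk = cv$n_risk,
               n_event = cv$n_event, survival = cv$surv,
               stringsAsFactors = FALSE)
  }))
}
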