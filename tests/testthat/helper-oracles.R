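# Independent oracles and small fixture builders shared across test files.
# Everything here is deliberately naive (loops, first-principles formulas)
# so it stays independent of the package implementation it checks.

# Two-group log-rank statistic from first principles: loop over distinct
# event times, hypergeometric mean/variance per time, chi-square = (O-E)^2/V.
brute_force_logrank <- function(times, events, in_group1) {
  ts <- sort(unique(times[events == 1]))
  O1 <- 0; E1 <- 0; V <- 0
  for (t in ts) {
    at_risk <- times >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & in_group1)
    d <- sum(times == t & events == 1)
    d1 <- sum(times == t & events == 1 & in_group1)
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  if (V == 0) return(0)
  (O1 - E1)^2 / V
}

# Product-limit estimate by direct recursion over distinct event times.
brute_force_km <- function(times, events, at) {
  ts <- sort(unique(times[events == 1]))
  s <- 1
  for (t in ts[ts <= at]) {
    n <- sum(times >= t)
    d <- sum(times == t & events == 1)
    s <- s * (1 - d / n)
  }
  s
}

# Adjusted Rand index between two partitions.
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  expected <- sum_a * sum_b / n
  maximum <- (sum_a + sum_b) / 2
  if (maximum == expected) return(1)
  (sum_ij - expected) / (maximum - expected)
}

# Minimal tumor_cohort builder for tests that only need expression and/or
# survival, bypassing the simulator.
make_cohort <- function(expression, time, event, time_unit = "years",
                        endpoint = "disease-free") {
  structure(list(
    expression = expression,
    survival = data.frame(tumor_id = colnames(expression), time = time,
                          event = event, stringsAsFactors = FALSE),
    time_unit = time_unit, endpoint = endpoint), class = "tumor_cohort")
}

# KM median survival time (first time S drops to <= 0.5), Inf if never.
km_median <- function(curve) {
  i <- which(curve$surv <= 0.5)
  if (!length(i)) Inf else curve$time[i[1]]
}

# Two-condition array config used by several differential tests.
two_group_config <- function(...) {
  array_sim_config(conditions = data.frame(
    condition = c("ctrl", "test"), temperature = "41.5",
    transformed = c(FALSE, TRUE), stringsAsFactors = FALSE), ...)
}
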