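test_that("product-limit estimates match hand computation and the no-censoring ECDF oracle", {
  km <- km_estimate(c(1, 2, 3, 4), c(1, 1, 0, 1))
  expect_equal(km$time, c(1, 2, 4))
  expect_equal(km$surv, c(0.75, 0.50, 0))
  expect_equal(km$n_risk, c(4, 3, 1))

  # all censored: survival stays at 1
  kc <- km_estimate(c(2, 5, 9), c(0, 0, 0))
  expect_length(kc$time, 0)
  expect_equal(restricted_mean_survival(kc, 9), 9)

  # single subject with an event: S drops 1 -> 0
  k1 <- km_estimate(3, 1)
  expect_equal(k1$surv, 0)

  # without censoring, S(t) = 1 - ECDF at every event time
  set.seed(30)
  tms <- round(rexp(40, 0.2), 1) + 0.1
  kme <- km_estimate(tms, rep(1, 40))
  for (j in seq_along(kme$time)) {
    expect_equal(kme$surv[j], mean(tms > kme$time[j]))
    expect_equal(kme$surv[j], brute_force_km(tms, rep(1, 40), kme$time[j]))
  }

  expect_error(km_estimate(numeric(), numeric()), "empty")
  expect_error(km_estimate(c(1, -1), c(1, 1)), "positive")
})

test_that("restricted mean survival integrates the step function and approaches 1/rate", {
  km <- km_estimate(c(1, 2, 3, 4), c(1, 1, 0, 1))
  expect_equal(restricted_mean_survival(km, 4), 2.75)  # 1 + 0.75 + 0.5*2
  expect_equal(restricted_mean_survival(km, 1.5), 1 + 0.75 * 0.5)
  expect_warning(restricted_mean_survival(km, 10), "exceeds")

  set.seed(31)
  tms <- rexp(10000, rate = 2) + 1e-9
  kme <- km_estimate(tms, rep(1, 10000))
  expect_equal(restricted_mean_survival(kme, max(tms)), 0.5,
               tolerance = 0.05)
})

test_that("log-rank matches the hand-computed toy and a brute-force oracle on random instances", {
  lr <- logrank_test(c(1, 2, 3, 4), c(1, 1, 1, 1), c(1, 1, 2, 2))
  expect_equal(lr$chisq, 49 / 17, tolerance = 1e-12)
  expect_equal(lr$p, pchisq(49 / 17, 1, lower.tail = FALSE))

  # identical groups: chi-square 0, p 1
  lr0 <- logrank_test(rep(c(1, 2, 5), 2), rep(c(1, 0, 1), 2),
                      rep(1:2, each = 3))
  expect_equal(lr0$chisq, 0, tolerance = 1e-12)
  expect_equal(lr0$p, 1, tolerance = 1e-12)

  set.seed(32)
  for (case in seq_len(1000)) {
    n <- sample(4:12, 1)
    tms <- sample(1:6, n, replace = TRUE)          # heavy ties on purpose
    evs <- rbinom(n, 1, 0.7)
    grp <- c(1, 2, sample(1:2, n - 2, replace = TRUE))  # both groups present
    if (sum(evs) == 0) evs[1] <- 1
    got <- logrank_test(tms, evs, grp)$chisq
    want <- brute_force_logrank(tms, evs, grp == 1)
    expect_equal(got, want, tolerance = 1e-8)
  }

  expect_error(logrank_test(1:4, rep(1, 4), rep(1, 4)), "one group")
})

test_that("signature scores are centered averages with exact hand values", {
  expr <- matrix(c(1, 2, 3, 4,
                   0, 0, 0, 4), nrow = 2, byrow = TRUE,
                 dimnames = list(c("g1", "g2"), paste0("T", 1:4)))
  cohort <- make_cohort(expr, time = 1:4, event = rep(1, 4))
  sc <- aggressive_score(cohort, c("g1", "g2"))
  expect_equal(sc$score, c(-1.25, -0.75, -0.25, 2.25))
  expect_equal(sum(sc$score), 0)

  # constant genes give all-zero scores; per-gene constants do not matter
  flat <- make_cohort(matrix(5, 2, 4, dimnames = dimnames(expr)),
                      time = 1:4, event = rep(1, 4))
  expect_true(all(aggressive_score(flat, c("g1", "g2"))$score == 0))
  shifted <- cohort
  shifted$expression <- cohort$expression + c(100, -7)
  expect_equal(aggressive_score(shifted, c("g1", "g2"))$score, sc$score)

  # absent features are dropped with a message; none present is an error
  expect_message(aggressive_score(cohort, c("g1", "g2", "gX")), "absent")
  expect_error(suppressMessages(aggressive_score(cohort, "gX")),
               "no signature features")
})

test_that("the upper-quartile split takes ceil(n/4) tumors with stable tie-breaking", {
  sc8 <- data.frame(tumor_id = sprintf("T%02d", 1:8), score = 8:1 / 10)
  expect_equal(sum(upper_quartile_split(sc8) == "high"), 2)
  sc10 <- data.frame(tumor_id = sprintf("T%02d", 1:10), score = 10:1 / 10)
  expect_equal(sum(upper_quartile_split(sc10) == "high"), 3)  # ceil(2.5)

  # boundary tie: lexicographically smaller tumor id enters the high group
  sct <- data.frame(tumor_id = c("T04", "T01", "T03", "T02"),
                    score = c(0.9, 0.5, 0.5, 0.1))
  lab <- upper_quartile_split(sct, 0.5)
  expect_equal(names(lab)[lab == "high"], c("T04", "T01"))
  expect_identical(lab, upper_quartile_split(sct[c(2, 1, 4, 3), ], 0.5)[
    names(lab)])

  expect_error(upper_quartile_split(sc8[1:3, ]), "at least 4")
})

test_that("signature evaluation separates survival under a strong planted hazard", {
  hits <- 0
  for (s in seq_len(100)) {
    sim <- simulate_tumor_cohort(cohort_sim_config(
      n_tumors = 200, n_background_genes = 50, n_signature_genes = 10,
      hazard_ratio = 3, expression_shift = 2, seed = 500 + s))
    ev <- evaluate_signature(sim$cohort, sim$truth$signature_genes)
    if (ev$logrank_p < 0.001) hits <- hits + 1
  }
  expect_gte(hits, 90)

  # under the strong hazard the high group also has the smaller restricted mean
  sim <- simulate_tumor_cohort(cohort_sim_config(
    n_tumors = 2000, n_background_genes = 20, n_signature_genes = 10,
    hazard_ratio = 3, expression_shift = 2, seed = 77))
  ev <- evaluate_signature(sim$cohort, sim$truth$signature_genes)
  expect_lt(ev$restricted_means[["high"]], ev$restricted_means[["rest"]])
})

test_that("evaluation p-values are uniform under the null hazard", {
  ps <- vapply(seq_len(500), function(s) {
    sim <- simulate_tumor_cohort(cohort_sim_config(
      n_tumors = 200, n_background_genes = 20, n_signature_genes = 5,
      hazard_ratio = 1, expression_shift = 2, seed = 3000 + s))
    evaluate_signature(sim$cohort, sim$truth$signature_genes)$logrank_p
  }, numeric(1))
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("signature evaluation is invariant to tumor column order", {
  sim <- simulate_tumor_cohort(cohort_sim_config(
    n_tumors = 60, n_background_genes = 30, n_signature_genes = 8,
    seed = 41))
  cohort <- sim$cohort
  set.seed(42)
  perm <- sample(ncol(cohort$expression))
  shuffled <- cohort
  shuffled$expression <- cohort$expression[, perm]
  shuffled$survival <- cohort$survival[perm, ]
  e1 <- evaluate_signature(cohort, sim$truth$signature_genes)
  e2 <- evaluate_signature(shuffled, sim$truth$signature_genes)
  expect_equal(e1$logrank_chisq, e2$logrank_chisq)
  expect_equal(e1$restricted_means, e2$restricted_means)
  expect_equal(sort(names(e1$labels[e1$labels == "high"])),
               sort(names(e2$labels[e2$labels == "high"])))
})
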