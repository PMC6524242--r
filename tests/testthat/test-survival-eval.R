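test_that("time-dependent ROC handles uninformative and perfect markers", {
  time <- c(0.5, 0.8, 1.5, 2, 3, 4, 5, 6)
  event <- rep(1, 8)
  # constant score: AUC exactly 0.5 (all ties)
  roc0 <- time_dependent_roc(rep(1, 8), time, event, horizon = 2.5)
  expect_equal(roc0$auc, 0.5)
  # every death-by-horizon outranks every survivor: AUC 1
  rs <- c(10, 9, 8, 7, 1, 2, 3, 4)
  roc1 <- time_dependent_roc(rs, time, event, horizon = 2.5)
  expect_equal(roc1$auc, 1)
  expect_equal(roc1$n_cases, 4)
  expect_error(time_dependent_roc(rs, time, event, horizon = 10), "controls")
  expect_error(time_dependent_roc(rs, time, event, horizon = 0.1), "cases")
})

test_that("uncensored td-ROC equals exhaustive Mann-Whitney pair counting", {
  withr::with_seed(3, {
    for (i in 1:5) {
      n <- sample(8:20, 1)
      time <- rexp(n) + 0.05
      event <- rep(1, n)
      rs <- round(-time + rnorm(n, 0, 0.5), 1)  # rounding induces ties
      h <- median(time)
      got <- time_dependent_roc(rs, time, event, h)
      expect_equal(got$auc, oracle_mw_auc(rs, time <= h), tolerance = 1e-12)
    }
  })
})

test_that("td-ROC AUC is invariant under strictly monotone score transforms", {
  withr::with_seed(4, {
    n <- 60
    time <- rexp(n, 0.3)
    event <- rbinom(n, 1, 0.7)
    rs <- rnorm(n)
    h <- quantile(time, 0.5)
    a <- time_dependent_roc(rs, time, event, h)
    b <- time_dependent_roc(exp(2 * rs) + 5, time, event, h)
    expect_equal(a$auc, b$auc, tolerance = 1e-12)
  })
})

test_that("the Youden cutoff attains the maximum of sens + spec - 1", {
  withr::with_seed(5, {
    time <- rexp(40, 0.4); event <- rbinom(40, 1, 0.8); rs <- rnorm(40)
    roc <- time_dependent_roc(rs, time, event, quantile(time, 0.6))
    j <- roc$curve$sensitivity + roc$curve$specificity - 1
    expect_equal(roc$youden, max(j), tolerance = 1e-12)
    expect_equal(roc$cutoff, roc$curve$cutoff[which.max(j)])
  })
})

test_that("log-rank matches a hand-computed observed-minus-expected statistic", {
  # 6 patients, two groups, no censoring
  time <- c(1, 2, 3, 4, 5, 6)
  event <- rep(1, 6)
  group <- c("a", "b", "a", "b", "a", "b")
  km <- km_logrank(factor(group), time, event)
  # independent oracle: classic log-rank computation
  o_minus_e <- 0; v <- 0
  for (t in time) {
    at_risk <- time >= t
    d <- sum(time == t)
    n <- sum(at_risk)
    n_a <- sum(at_risk & group == "a")
    d_a <- sum(time == t & group == "a")
    e_a <- d * n_a / n
    o_minus_e <- o_minus_e + (d_a - e_a)
    if (n > 1) v <- v + d * (n_a / n) * (1 - n_a / n) * (n - d) / (n - 1)
  }
  expect_equal(km$chisq, o_minus_e^2 / v, tolerance = 1e-10)
  expect_equal(km$p, pchisq(o_minus_e^2 / v, 1, lower.tail = FALSE),
               tolerance = 1e-10)

  # identical event-time multisets: statistic 0, p = 1
  km0 <- km_logrank(factor(rep(c("a", "b"), each = 3)),
                    c(1, 2, 3, 1, 2, 3), rep(1, 6))
  expect_equal(km0$chisq, 0, tolerance = 1e-12)
  expect_equal(km0$p, 1, tolerance = 1e-12)
  expect_error(km_logrank(factor(rep("a", 6)), time, event), "two nonempty")
  expect_error(km_logrank(rnorm(6), time, event), "cutoff")
})

test_that("a strong planted signature separates risk groups decisively", {
  sim <- suppressMessages(simulate_cohort(cohort_truth(), 690, seed = 61))
  sig <- gene_signature(sim$beta_effective, name = "planted")
  rs <- apply_signature(sig, sim$cohort)
  roc <- time_dependent_roc(rs$risk_score, rs$time, rs$event, 5)
  km <- km_logrank(rs$risk_score, rs$time, rs$event, cutoff = roc$cutoff)
  expect_lt(km$p, 1e-4)
  expect_gt(roc$auc, 0.8)
})

test_that("random-signature null reports both counting conventions", {
  sim_l <- suppressMessages(simulate_cohort(cohort_truth(n_genes = 60), 60, seed = 71))
  sim_v <- suppressMessages(simulate_cohort(cohort_truth(n_genes = 60), 60, seed = 72))
  obs <- gene_signature(sim_l$truth$signature)
  nd <- suppressMessages(random_signature_null(
    sim_l$cohort, sim_v$cohort, obs, k = 3, B = 25, seed = 5))
  expect_length(nd$null_aucs, 25)
  n_ge <- sum(nd$null_aucs >= nd$observed_auc)
  expect_equal(nd$p_value, n_ge / 25)
  expect_equal(nd$p_value_add_one, (1 + n_ge) / 26)
  expect_error(random_signature_null(sim_l$cohort, sim_v$cohort, obs,
                                     k = 1000, B = 2, seed = 1), "universe")
})

test_that("full-fraction robustness replicates equal the full-cohort AUC", {
  sim <- suppressMessages(simulate_cohort(cohort_truth(), 200, seed = 81))
  sig_true <- gene_signature(sim$beta_effective, name = "planted")
  withr::with_seed(9, {
    random_sig <- gene_signature(
      setNames(rnorm(12), sample(rownames(sim$cohort$expression), 12)),
      name = "random")
  })
  rb <- suppressMessages(robustness_subsample(
    sim$cohort, list(planted = sig_true, random = random_sig),
    fraction = 1, B = 2, horizons = c(3), seed = 3))
  rs <- apply_signature(sig_true, sim$cohort)
  full_auc <- time_dependent_roc(rs$risk_score, rs$time, rs$event, 3)$auc
  a <- rb$aucs$auc[rb$aucs$signature == "planted"]
  expect_equal(a, rep(full_auc, 2), tolerance = 1e-12)

  # planted vs random: one-tailed Wilcoxon strongly favors the planted score
  rb2 <- suppressMessages(robustness_subsample(
    sim$cohort, list(planted = sig_true, random = random_sig),
    fraction = 0.5, B = 40, horizons = c(3), seed = 4))
  expect_lt(rb2$tests$p, 0.01)
  expect_equal(nrow(rb2$aucs), 2 * 40)
})

test_that("paired bootstrap AUC comparison splits ties and detects superiority", {
  withr::with_seed(11, {
    n <- 120
    time <- rexp(n, 0.4); event <- rep(1, n)
    perfect <- -time
    noise <- rnorm(n)
    h <- quantile(time, 0.6)
    same <- compare_auc_bootstrap(perfect, perfect, time, event, h, B = 50, seed = 2)
    expect_equal(same$p, 0.5)
    sup <- compare_auc_bootstrap(perfect, noise, time, event, h, B = 200, seed = 3)
    expect_lt(sup$p, 0.01)
    expect_gt(sup$auc_a, sup$auc_b)
  })
})

test_that("multivariate Cox recovers a planted age effect with clean encodings", {
  sim <- suppressMessages(simulate_cohort(cohort_truth(), 690, seed = 91))
  sig <- gene_signature(sim$beta_effective, name = "planted")
  out <- suppressMessages(multivariate_cox(sim$cohort, list(signature1 = sig)))
  expect_setequal(unique(out$analysis), c("univariate", "multivariate"))
  age_multi <- out[out$variable == "age_ge60" & out$analysis == "multivariate", ]
  expect_gt(age_multi$hr, 1.6); expect_lt(age_multi$hr, 2.3)
  sig_multi <- out[out$variable == "signature1" & out$analysis == "multivariate", ]
  expect_lt(sig_multi$p, 1e-4)

  # single-level variable errors
  ch <- sim$cohort
  ch$clinical$gender <- "Male"
  expect_error(suppressMessages(multivariate_cox(ch, list())), "single level")
})

test_that("stratified KM reduces to the unstratified analysis for one stratum", {
  sim <- suppressMessages(simulate_cohort(cohort_truth(), 400, seed = 101))
  sig <- gene_signature(sim$beta_effective, name = "planted")
  rs <- apply_signature(sig, sim$cohort)
  ch1 <- sim$cohort
  ch1$clinical$grade <- "high"
  one <- suppressMessages(suppressWarnings(
    stratified_km(ch1, rs, "grade", cutoff_horizon = 5)))
  expect_equal(nrow(one), 1)
  roc <- time_dependent_roc(rs$risk_score, rs$time, rs$event, 5)
  km <- km_logrank(rs$risk_score, rs$time, rs$event, cutoff = roc$cutoff)
  expect_equal(one$p, km$p, tolerance = 1e-12)
  expect_equal(one$cutoff, roc$cutoff)

  # signature effect present in both grade strata
  both <- suppressMessages(suppressWarnings(
    stratified_km(sim$cohort, rs, "grade", cutoff_horizon = 5)))
  expect_equal(nrow(both), 2)
  expect_true(all(both$p < 0.01))
  # age stratifier splits at 60; therapy stratifiers drop unknowns
  by_age <- suppressMessages(suppressWarnings(
    stratified_km(sim$cohort, rs, "age")))
  expect_setequal(by_age$stratum, c("age<=60", "age>60"))
  by_rt <- suppressMessages(suppressWarnings(
    stratified_km(sim$cohort, rs, "radiotherapy")))
  expect_true(all(by_rt$stratum %in% c("yes", "no")))
})

test_that("drug-response surrogate labels follow survival status at the horizon", {
  sim <- suppressMessages(simulate_cohort(cohort_truth(), 690, seed = 111))
  sig <- gene_signature(sim$beta_effective, name = "planted")
  rs <- apply_signature(sig, sim$cohort)
  dr <- suppressMessages(drug_response_classification(sim$cohort, rs,
                                                      horizon_years = 3))
  cl <- sim$cohort$clinical
  ther <- cl[cl$targeted_therapy == "yes", ]
  lab <- dr$labels
  joined <- merge(lab, ther, by = "patient_id")
  expect_true(all(joined$label[joined$time <= 3 & joined$event == 1] == "resistant"))
  expect_true(all(joined$label[joined$time > 3] == "sensitive"))
  expect_gt(dr$auc, 0.75)
  expect_lt(dr$km$p, 0.01)

  # all patients alive at the horizon: single-class labels error
  ch <- sim$cohort
  ch$clinical$time <- ch$clinical$time + 50
  expect_error(suppressMessages(
    drug_response_classification(ch, rs, horizon_years = 3)), "single-class")
})

test_that("pairwise risk-score group tests cover every pair and detect shifts", {
  expect_equal(riskscore_group_comparison(
    c(5, 5, 5, 5, 5, 5), rep(c("a", "b"), each = 3))$p, 1)
  withr::with_seed(12, {
    rs <- c(rnorm(50), rnorm(50, 2))
    ann <- rep(c("mut", "wt"), each = 50)
    expect_lt(riskscore_group_comparison(rs, ann)$p, 1e-6)
    rs4 <- rnorm(120)
    ann4 <- sample(c("classical", "mesenchymal", "neural", "proneural"),
                   120, TRUE)
    out <- riskscore_group_comparison(rs4, ann4)
    expect_equal(nrow(out), 6)
  })
  expect_error(riskscore_group_comparison(rnorm(10), rep("only", 10)),
               "at least two")
})
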