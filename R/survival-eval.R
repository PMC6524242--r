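#' Kaplan-Meier curves and two-sided log-rank test
#'
#' Splits patients into groups — either by thresholding a risk score at a
#' cutoff (`rs > cutoff` is high risk) or by a supplied grouping vector —
#' estimates product-limit survival curves per group, and tests the
#' difference with the two-sided log-rank test.
#'
#' @param scores Numeric risk scores, or a character/factor group label per
#'   patient.
#' @param time,event Follow-up and event indicator.
#' @param cutoff Risk-score cutoff (required when `scores` is numeric);
#'   usually the Youden cutoff from [time_dependent_roc()].
#' @return A list of class `km_logrank`: `curves` (tidy tibble: `group`,
#'   `time`, `surv`, `n_risk`, `n_event`), `chisq`, `df`, `p`,
#'   `group_sizes`.
#' @export
km_logrank <- function(scores, time, event, cutoff = NULL) {
  if (is.numeric(scores)) {
    if (is.null(cutoff)) abort("km_logrank: a cutoff is required for numeric scores")
    group <- ifelse(scores > cutoff, "high", "low")
  } else {
    group <- as.character(scores)
  }
  sizes <- table(group)
  if (length(sizes) < 2 || any(sizes == 0)) {
    abort("km_logrank: need two nonempty groups")
  }
  surv <- survival::Surv(time, event)
  fit <- survival::survfit(surv ~ group)
  strata_names <- sub("^group=", "", rep(names(fit$strata), fit$strata))
  curves <- tibble::tibble(
    group = strata_names, time = fit$time, surv = fit$surv,
    n_risk = fit$n.risk, n_event = fit$n.event
  )
  sd <- survival::survdiff(surv ~ group)
  df <- length(sd$n) - 1
  p <- pchisq(sd$chisq, df, lower.tail = FALSE)
  structure(
    list(curves = curves, chisq = unname(sd$chisq), df = df, p = p,
         group_sizes = sizes),
    class = "km_logrank"
  )
}

#' @export
print.km_logrank <- function(x, ...) {
  cat(sprintf("<km_logrank> chisq = %.3f (df %d), p = %.3g; groups: %s\n",
              x$chisq, x$df, x$p,
              paste(names(x$group_sizes), unname(x$group_sizes),
                    sep = "=", collapse = ", ")))
  invisible(x)
}

#' @method glance km_logrank
#' @export
glance.km_logrank <- function(x, ...) {
  tibble::tibble(chisq = x$chisq, df = x$df, p = x$p)
}

#' Random-signature bootstrap null for prognostic accuracy
#'
#' Draws `B` random gene sets of size `k` from the shared gene universe,
#' fits each as an unpenalized multivariate Cox signature on the learning
#' cohort, scores the validation cohort, and records the time-dependent ROC
#' AUC at the evaluation horizon. The observed signature's AUC is compared
#' against this null; the empirical p-value is reported under both the
#' plug-in convention `#{AUC_null >= AUC_obs} / B` and the add-one
#' convention `(1 + #) / (B + 1)`. Draws whose Cox fit fails are resampled
#' (logged, capped at `2B` attempts).
#'
#' @param learning,validation [cohort()]s sharing a gene universe.
#' @param observed_sig The [gene_signature()] under test.
#' @param k Genes per random signature.
#' @param B Number of draws.
#' @param seed Integer seed.
#' @param horizon Evaluation horizon in years; default is the 75th
#'   percentile of validation follow-up (the "overall survival" convention).
#' @param gene_universe Optional symbol vector to draw from (default: all
#'   genes shared by both cohorts).
#' @return An object of class `null_distribution`: `observed_auc`,
#'   `null_aucs` (length `B`), `p_value`, `p_value_add_one`, `B`, `k`,
#'   `horizon`, `seed`.
#' @export
random_signature_null <- function(learning, validation, observed_sig, k = 12,
                                  B = 1000, seed = 1, horizon = NULL,
                                  gene_universe = NULL) {
  stopifnot(inherits(learning, "cohort"), inherits(validation, "cohort"))
  universe <- gene_universe %||%
    intersect(rownames(learning$expression), rownames(validation$expression))
  if (length(universe) < k) abort("random_signature_null: gene universe smaller than k")
  horizon <- horizon %||% overall_survival_horizon(validation$clinical$time)
  h <- horizon_in_unit(horizon, validation$time_unit)

  rs_obs <- apply_signature(observed_sig, validation)
  observed_auc <- time_dependent_roc(rs_obs$risk_score, rs_obs$time,
                                     rs_obs$event, h)$auc

  null_aucs <- with_preserved_seed(seed, {
    out <- numeric(0)
    attempts <- 0
    n_failed <- 0
    while (length(out) < B && attempts < 2 * B) {
      attempts <- attempts + 1
      genes <- sample(universe, k)
      auc <- tryCatch({
        sig <- refit_signature(learning, genes, name = "random")
        rs <- apply_signature(sig, validation)
        time_dependent_roc(rs$risk_score, rs$time, rs$event, h)$auc
      }, error = function(e) NA_real_)
      if (is.na(auc)) n_failed <- n_failed + 1 else out <- c(out, auc)
    }
    if (n_failed > 0) mcg_log("random_signature_null: resampled ", n_failed,
                              " failed draw(s)")
    if (length(out) < B) abort("random_signature_null: too many failed draws")
    out
  })
  n_ge <- sum(null_aucs >= observed_auc)
  structure(
    list(observed_auc = observed_auc, null_aucs = null_aucs,
         p_value = n_ge / B, p_value_add_one = (1 + n_ge) / (B + 1),
         B = B, k = k, horizon = horizon, seed = seed),
    class = "null_distribution"
  )
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf(
    "<null_distribution> observed AUC %.3f vs %d random %d-gene signatures: p = %.4g (add-one %.4g)\n",
    x$observed_auc, x$B, x$k, x$p_value, x$p_value_add_one))
  invisible(x)
}

#' Subsample robustness comparison of competing signatures
#'
#' Draws `B` random subsamples (a fraction of the validation patients,
#' without replacement), scores every signature on the same subsample, and
#' records each signature's time-dependent AUC at each horizon. Signature
#' AUC distributions are compared against the first (reference) signature
#' with one-tailed Wilcoxon rank-sum tests (alternative: reference is
#' greater). Replicates in which some horizon has no cases or no controls
#' are redrawn (logged).
#'
#' @param validation A [cohort()].
#' @param signatures Named list of [gene_signature()]s; the first is the
#'   reference.
#' @param fraction Fraction of patients per subsample (default 0.5; a 0.6
#'   variant is also in published use).
#' @param B Number of subsamples.
#' @param horizons Horizons in years; `NA` entries mean the overall-survival
#'   horizon (75th percentile of follow-up).
#' @param seed Integer seed.
#' @return An object of class `robustness_result`: `aucs` (tibble
#'   `replicate`, `signature`, `horizon`, `auc`), `tests` (tibble
#'   `signature`, `horizon`, `p` one-tailed vs reference), `fraction`, `B`.
#' @export
robustness_subsample <- function(validation, signatures, fraction = 0.5,
                                 B = 100, horizons = c(NA, 3, 5), seed = 1) {
  stopifnot(inherits(validation, "cohort"), length(signatures) >= 2)
  if (is.null(names(signatures)) || any(names(signatures) == "")) {
    abort("robustness_subsample: signatures must be a named list")
  }
  n <- n_patients(validation)
  m <- max(2, round(fraction * n))
  if (m < 20) abort("robustness_subsample: subsample too small (< 20 patients)")

  os_h <- overall_survival_horizon(validation$clinical$time)
  horizon_years <- ifelse(is.na(horizons), os_h, horizons)
  horizon_label <- ifelse(is.na(horizons), "overall",
                          paste0(horizons, "y"))
  h_unit <- horizon_in_unit(horizon_years, validation$time_unit)

  scores <- lapply(signatures, function(s) apply_signature(s, validation)$risk_score)
  time <- validation$clinical$time
  event <- validation$clinical$event

  aucs <- with_preserved_seed(seed, {
    rows <- list()
    b <- 0
    attempts <- 0
    n_redrawn <- 0
    while (b < B && attempts < 10 * B) {
      attempts <- attempts + 1
      idx <- sample.int(n, m)
      rep_rows <- tryCatch({
        purrr::map_dfr(seq_along(signatures), function(si) {
          purrr::map_dfr(seq_along(h_unit), function(hi) {
            roc <- time_dependent_roc(scores[[si]][idx], time[idx],
                                      event[idx], h_unit[hi])
            tibble::tibble(signature = names(signatures)[si],
                           horizon = horizon_label[hi], auc = roc$auc)
          })
        })
      }, error = function(e) NULL)
      if (is.null(rep_rows)) { n_redrawn <- n_redrawn + 1; next }
      b <- b + 1
      rep_rows$replicate <- b
      rows[[b]] <- rep_rows
    }
    if (n_redrawn > 0) mcg_log("robustness_subsample: redrew ", n_redrawn,
                               " degenerate replicate(s)")
    if (b < B) abort("robustness_subsample: too many degenerate replicates")
    dplyr::bind_rows(rows)
  })

  ref <- names(signatures)[1]
  tests <- purrr::map_dfr(setdiff(names(signatures), ref), function(sg) {
    purrr::map_dfr(unique(aucs$horizon), function(hl) {
      a_ref <- aucs$auc[aucs$signature == ref & aucs$horizon == hl]
      a_cmp <- aucs$auc[aucs$signature == sg & aucs$horizon == hl]
      p <- suppressWarnings(wilcox.test(a_ref, a_cmp, alternative = "greater")$p.value)
      tibble::tibble(signature = sg, horizon = hl, p = p)
    })
  })
  structure(
    list(aucs = aucs, tests = tests, fraction = fraction, B = B,
         reference = ref),
    class = "robustness_result"
  )
}

#' Paired bootstrap comparison of two risk scores' AUCs
#'
#' Resamples patients with replacement `B` times, computes both scores'
#' time-dependent AUCs on each resample, and reports the one-sided
#' empirical p-value that score A is superior: the fraction of resamples
#' with `AUC_a <= AUC_b`, ties counted half.
#'
#' @param rs_a,rs_b Risk scores over the same patients.
#' @param time,event Follow-up and event indicator.
#' @param horizon Horizon (same unit as `time`).
#' @param B Bootstrap resamples.
#' @param seed Integer seed.
#' @return A list with `p`, `auc_a`, `auc_b` (full-sample AUCs) and `B`.
#' @export
compare_auc_bootstrap <- function(rs_a, rs_b, time, event, horizon, B = 1000,
                                  seed = 1) {
  stopifnot(length(rs_a) == length(rs_b))
  auc_a <- time_dependent_roc(rs_a, time, event, horizon)$auc
  auc_b <- time_dependent_roc(rs_b, time, event, horizon)$auc
  n <- length(rs_a)
  stat <- with_preserved_seed(seed, {
    wins_b <- 0
    b <- 0
    attempts <- 0
    while (b < B && attempts < 10 * B) {
      attempts <- attempts + 1
      idx <- sample.int(n, n, replace = TRUE)
      res <- tryCatch({
        aa <- time_dependent_roc(rs_a[idx], time[idx], event[idx], horizon)$auc
        ab <- time_dependent_roc(rs_b[idx], time[idx], event[idx], horizon)$auc
        c(aa, ab)
      }, error = function(e) NULL)
      if (is.null(res)) next
      b <- b + 1
      wins_b <- wins_b + (res[1] < res[2]) + 0.5 * (res[1] == res[2])
    }
    if (b < B) abort("compare_auc_bootstrap: too many degenerate resamples")
    wins_b / B
  })
  list(p = stat, auc_a = auc_a, auc_b = auc_b, B = B)
}

#' Univariate and multivariate Cox models over covariates and signatures
#'
#' Encodes the standard clinicopathologic contrasts — age >= 60 versus
#' < 60, male versus female, high versus low grade — together with any
#' supplied signature risk scores, fits one univariate Cox model per
#' variable and one joint multivariate model, and reports hazard ratios
#' with 95% confidence intervals and Wald p-values. Patients with missing
#' values are dropped listwise (logged). Collinear variables raise an
#' error naming the offending variable.
#'
#' @param ch A [cohort()].
#' @param signatures Named list of [gene_signature()]s scored on the cohort
#'   and entered as continuous risk scores (may be empty).
#' @param horizon_years Optional horizon: follow-up is truncated at the
#'   horizon (events after it become censored) to study horizon-restricted
#'   survival; `NULL` uses overall survival.
#' @return A tibble with `variable`, `analysis` ("univariate" or
#'   "multivariate"), `beta`, `hr`, `ci_low`, `ci_high`, `p`, `estimable`.
#' @export
multivariate_cox <- function(ch, signatures = list(), horizon_years = NULL) {
  stopifnot(inherits(ch, "cohort"))
  cl <- ch$clinical
  time <- cl$time
  event <- cl$event
  if (!is.null(horizon_years)) {
    h <- horizon_in_unit(horizon_years, ch$time_unit)
    event <- ifelse(time > h, 0L, event)
    time <- pmin(time, h)
  }
  vars <- list()
  if ("age" %in% names(cl)) vars$age_ge60 <- as.numeric(cl$age >= 60)
  if ("gender" %in% names(cl)) vars$male <- as.numeric(cl$gender == "Male")
  if ("grade" %in% names(cl)) vars$high_grade <- as.numeric(cl$grade == "high")
  for (nm in names(signatures)) {
    vars[[nm]] <- apply_signature(signatures[[nm]], ch)$risk_score
  }
  if (length(vars) == 0) abort("multivariate_cox: no variables to fit")
  df <- tibble::as_tibble(vars)
  keep <- complete.cases(df) & is.finite(time)
  if (any(!keep)) {
    mcg_log("multivariate_cox: dropping ", sum(!keep),
            " patients with missing values (listwise)")
  }
  df <- df[keep, ]; time <- time[keep]; event <- event[keep]
  const <- names(df)[vapply(df, function(v) length(unique(v)) < 2, logical(1))]
  if (length(const) > 0) {
    abort(paste0("multivariate_cox: variable(s) with a single level: ",
                 paste(const, collapse = ", ")))
  }
  y <- survival::Surv(time, event)

  uni <- purrr::map_dfr(names(df), function(v) {
    fit <- suppressWarnings(survival::coxph(y ~ ., data = df[, v, drop = FALSE]))
    out <- cox_effect_row(v, fit, v)
    out$analysis <- "univariate"
    out
  })
  mfit <- suppressWarnings(survival::coxph(y ~ ., data = df))
  bad <- names(stats::coef(mfit))[!is.finite(stats::coef(mfit))]
  if (length(bad) > 0) {
    abort(paste0("multivariate_cox: collinear variable(s): ",
                 paste(bad, collapse = ", ")))
  }
  multi <- purrr::map_dfr(names(df), function(v) {
    out <- cox_effect_row(v, mfit, v)
    out$analysis <- "multivariate"
    out
  })
  dplyr::bind_rows(uni, multi)[, c("variable", "analysis", "beta", "hr",
                                   "ci_low", "ci_high", "p", "estimable")]
}

#' Risk-score Kaplan-Meier analysis within clinical strata
#'
#' Within each level of a stratifying variable (e.g. age group, grade,
#' pharmaceutical therapy, radiotherapy), finds the stratum's own Youden
#' cutoff from the time-dependent ROC at `cutoff_horizon`, splits the
#' stratum into high- and low-risk groups, and runs the Kaplan-Meier /
#' log-rank comparison. Patients with an `"unknown"` or missing stratifier
#' value are dropped (logged); strata where either risk group is empty are
#' skipped (logged). Small strata produce a warning.
#'
#' @param ch A [cohort()].
#' @param rs Output of [apply_signature()] (or a numeric score vector in
#'   patient order).
#' @param stratifier Clinical column to stratify on; `"age"` is split at 60
#'   years.
#' @param cutoff_horizon Horizon in years for the per-stratum Youden cutoff.
#' @return A tibble with one row per analyzed stratum: `stratum`, `n`,
#'   `cutoff`, `chisq`, `p`, `n_high`, `n_low`, and a `km` list column of
#'   [km_logrank()] results.
#' @export
stratified_km <- function(ch, rs, stratifier, cutoff_horizon = 5) {
  stopifnot(inherits(ch, "cohort"))
  if (is.data.frame(rs)) rs <- rs$risk_score
  cl <- ch$clinical
  if (!stratifier %in% c(names(cl))) {
    abort(paste0("stratified_km: unknown stratifier '", stratifier, "'"))
  }
  strat <- if (stratifier == "age") {
    ifelse(cl$age <= 60, "age<=60", "age>60")
  } else {
    as.character(cl[[stratifier]])
  }
  drop <- is.na(strat) | strat == "unknown"
  if (any(drop)) {
    mcg_log("stratified_km: dropping ", sum(drop),
            " patients with unknown '", stratifier, "'")
  }
  h <- horizon_in_unit(cutoff_horizon, ch$time_unit)
  purrr::map_dfr(sort(unique(strat[!drop])), function(lev) {
    idx <- which(!drop & strat == lev)
    res <- tryCatch({
      roc <- time_dependent_roc(rs[idx], cl$time[idx], cl$event[idx], h)
      km <- km_logrank(rs[idx], cl$time[idx], cl$event[idx], cutoff = roc$cutoff)
      if (any(km$group_sizes < 10)) {
        warn(paste0("stratified_km: stratum '", lev,
                    "' has a risk group smaller than 10"))
      }
      tibble::tibble(stratum = lev, n = length(idx), cutoff = roc$cutoff,
                     chisq = km$chisq, p = km$p,
                     n_high = sum(rs[idx] > roc$cutoff),
                     n_low = sum(rs[idx] <= roc$cutoff),
                     km = list(km))
    }, error = function(e) {
      mcg_log("stratified_km: skipping stratum '", lev, "': ",
              conditionMessage(e))
      NULL
    })
    res
  })
}

#' Surrogate drug-response classification from survival status
#'
#' For patients who received targeted therapy, the observed survival status
#' at a horizon substitutes for the latent response label: alive at the
#' horizon = sensitive, dead by the horizon = resistant; patients censored
#' before the horizon carry no label and are excluded (logged). Patients are
#' predicted sensitive (low risk) or resistant (high risk) by the Youden
#' cutoff of the horizon's time-dependent ROC, the predicted groups are
#' compared with Kaplan-Meier / log-rank over the full therapy subset, and
#' the risk score's accuracy against the surrogate labels is reported as a
#' binary ROC AUC.
#'
#' @param ch A [cohort()] (restricted internally to
#'   `targeted_therapy == "yes"` when that column is present).
#' @param rs [apply_signature()] output or numeric scores in patient order.
#' @param horizon_years Horizon defining the surrogate labels (3 or 5).
#' @return A list of class `drug_response`: `labels` (tibble `patient_id`,
#'   `risk_score`, `label`, `predicted`), `cutoff`, `auc`, `km`
#'   ([km_logrank()] of predicted groups), `n_excluded`.
#' @export
drug_response_classification <- function(ch, rs, horizon_years = 3) {
  stopifnot(inherits(ch, "cohort"))
  if (is.data.frame(rs)) rs <- rs$risk_score
  cl <- ch$clinical
  sel <- if ("targeted_therapy" %in% names(cl)) cl$targeted_therapy == "yes"
         else rep(TRUE, nrow(cl))
  if (!any(sel)) abort("drug_response_classification: no targeted-therapy patients")
  rs <- rs[sel]; cl <- cl[sel, ]
  h <- horizon_in_unit(horizon_years, ch$time_unit)

  dead <- cl$time <= h & cl$event == 1
  alive <- cl$time > h
  excl <- !dead & !alive
  if (sum(dead) == 0 || sum(alive) == 0) {
    abort("drug_response_classification: surrogate labels are single-class at this horizon")
  }
  if (any(excl)) {
    mcg_log("drug_response_classification: excluding ", sum(excl),
            " patients censored before the horizon")
  }
  roc <- time_dependent_roc(rs, cl$time, cl$event, h)
  predicted <- ifelse(rs > roc$cutoff, "resistant", "sensitive")
  km <- km_logrank(factor(predicted), cl$time, cl$event)
  lab <- tibble::tibble(
    patient_id = cl$patient_id[!excl],
    risk_score = rs[!excl],
    label = ifelse(dead[!excl], "resistant", "sensitive"),
    predicted = predicted[!excl]
  )
  auc <- auc_binary(lab$risk_score, lab$label == "resistant")
  structure(
    list(labels = lab, cutoff = roc$cutoff, auc = auc, km = km,
         n_excluded = sum(excl), horizon_years = horizon_years),
    class = "drug_response"
  )
}

#' Pairwise risk-score comparison across annotation groups
#'
#' Two-sided Wilcoxon rank-sum test of the risk score between every pair of
#' annotation levels (e.g. mutation status or molecular subtype). Levels
#' with fewer than 3 patients and `"unknown"`/missing values are dropped
#' with a log message; fewer than two remaining levels is an error.
#'
#' @param rs [apply_signature()] output or numeric scores.
#' @param annotation Character/factor annotation per patient.
#' @return A tibble with `group_a`, `group_b`, `n_a`, `n_b`, `p`.
#' @export
riskscore_group_comparison <- function(rs, annotation) {
  if (is.data.frame(rs)) rs <- rs$risk_score
  annotation <- as.character(annotation)
  keep <- !is.na(annotation) & annotation != "unknown" & is.finite(rs)
  rs <- rs[keep]; annotation <- annotation[keep]
  sizes <- table(annotation)
  small <- names(sizes)[sizes < 3]
  if (length(small) > 0) {
    mcg_log("riskscore_group_comparison: dropping small group(s): ",
            paste(small, collapse = ", "))
  }
  levels_ok <- names(sizes)[sizes >= 3]
  if (length(levels_ok) < 2) {
    abort("riskscore_group_comparison: need at least two groups with >= 3 patients")
  }
  pairs <- utils::combn(sort(levels_ok), 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    xa <- rs[annotation == a]; xb <- rs[annotation == b]
    p <- suppressWarnings(wilcox.test(xa, xb, alternative = "two.sided")$p.value)
    if (is.nan(p)) p <- 1  # fully tied samples carry no evidence
    tibble::tibble(group_a = a, group_b = b,
                   n_a = length(xa), n_b = length(xb), p = p)
  })
}
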