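cohort_design <- function(ch, genes, log_transform = FALSE) {
  missing_genes <- setdiff(genes, rownames(ch$expression))
  if (length(missing_genes) > 0) {
    abort(paste0("candidate gene(s) missing from cohort expression: ",
                 paste(missing_genes, collapse = ", ")))
  }
  x <- t(ch$expression[genes, , drop = FALSE])
  if (log_transform) x <- log2(x + 1)
  x
}

# event-stratified fold assignment so every fold sees deaths
stratified_foldid <- function(event, nfolds) {
  foldid <- integer(length(event))
  for (lev in unique(event)) {
    idx <- which(event == lev)
    foldid[idx] <- sample(rep_len(seq_len(nfolds), length(idx)))
  }
  foldid
}

#' Differential-network-constrained LASSO Cox signature learning
#'
#' Fits an L1-penalized Cox proportional-hazards model over the candidate
#' genes along a lambda grid (100 values, descending from the smallest
#' lambda that zeroes every coefficient down by a factor of 1000), selects
#' the penalty minimizing the mean cross-validated partial-likelihood
#' deviance (ties resolved to the larger lambda), and returns the nonzero
#' coefficients at that penalty directly as the risk signature — no
#' post-selection refit. Cross-validation folds are stratified by event
#' status and drawn from `seed`.
#'
#' @param ch Learning [cohort()].
#' @param candidates Candidate gene symbols (all must be present in the
#'   cohort expression; typically [candidate_gene_list()] output).
#' @param cfg An [analysis_config()] (supplies `cv_folds`).
#' @param seed Integer seed for the fold assignment.
#' @param log_transform Use `log2(x + 1)` expression in the design matrix.
#' @param name Name for the returned signature.
#' @return A list with `fit` (class `lasso_cox_fit`: candidates, the glmnet
#'   cross-validation object, `lambda`, `log_lambda`, the CV curve tibble,
#'   and the selected terms) and `signature` (a [gene_signature()], or
#'   `NULL` when every coefficient is zero at the optimum).
#' @export
fit_lasso_cox <- function(ch, candidates, cfg = analysis_config(), seed = 1,
                          log_transform = FALSE, name = "lasso_cox") {
  stopifnot(inherits(ch, "cohort"))
  if (length(candidates) == 0) abort("fit_lasso_cox: no candidate genes")
  candidates <- normalize_symbols(candidates)
  x <- cohort_design(ch, candidates, log_transform)
  n_events <- sum(ch$clinical$event)
  if (n_events == 0) abort("fit_lasso_cox: cohort has zero events")
  if (n_events < 10 * cfg$cv_folds) {
    warn(paste0("fit_lasso_cox: only ", n_events, " events for ",
                cfg$cv_folds, "-fold CV; estimates may be unstable"))
  }
  sds <- apply(x, 2, sd)
  if (all(sds == 0)) {
    fit <- structure(
      list(candidates = candidates, cv = NULL, lambda = NA_real_,
           log_lambda = NA_real_,
           cv_curve = tibble::tibble(lambda = numeric(), mean_deviance = numeric(),
                                     se = numeric()),
           selected = tibble::tibble(gene = character(), beta = numeric()),
           seed = seed),
      class = "lasso_cox_fit"
    )
    return(list(fit = fit, signature = NULL))
  }
  y <- survival::Surv(ch$clinical$time, ch$clinical$event)
  cvfit <- with_preserved_seed(seed, {
    foldid <- stratified_foldid(ch$clinical$event, cfg$cv_folds)
    glmnet::cv.glmnet(x, y, family = "cox", foldid = foldid,
                      nlambda = 100, lambda.min.ratio = 1e-3)
  })
  lambda <- cvfit$lambda.min
  beta <- as.numeric(stats::coef(cvfit, s = "lambda.min"))
  names(beta) <- rownames(stats::coef(cvfit, s = "lambda.min"))
  nz <- beta[beta != 0]
  selected <- tibble::tibble(gene = names(nz), beta = unname(nz))
  fit <- structure(
    list(candidates = candidates, cv = cvfit, lambda = lambda,
         log_lambda = log(lambda),
         cv_curve = tibble::tibble(lambda = cvfit$lambda,
                                   mean_deviance = cvfit$cvm, se = cvfit$cvsd),
         selected = selected, seed = seed),
    class = "lasso_cox_fit"
  )
  signature <- if (nrow(selected) > 0) {
    gene_signature(selected, name = name, lambda = lambda,
                   learning_set = "learning_cohort")
  } else NULL
  list(fit = fit, signature = signature)
}

#' @export
print.lasso_cox_fit <- function(x, ...) {
  cat(sprintf("<lasso_cox_fit> %d candidates, %d selected at lambda = %.6g (ln lambda = %.5g)\n",
              length(x$candidates), nrow(x$selected), x$lambda, x$log_lambda))
  invisible(x)
}

#' @method tidy lasso_cox_fit
#' @export
#' @rdname fit_lasso_cox
#' @param x A `lasso_cox_fit`.
#' @param ... Unused.
tidy.lasso_cox_fit <- function(x, ...) x$selected

#' @method glance lasso_cox_fit
#' @export
#' @rdname fit_lasso_cox
glance.lasso_cox_fit <- function(x, ...) {
  tibble::tibble(lambda = x$lambda, log_lambda = x$log_lambda,
                 n_candidates = length(x$candidates),
                 n_selected = nrow(x$selected))
}

cox_effect_row <- function(variable, fit, term) {
  s <- summary(fit)
  i <- match(term, rownames(s$coefficients))
  beta <- s$coefficients[i, "coef"]
  tibble::tibble(
    variable = variable,
    beta = beta,
    hr = exp(beta),
    ci_low = s$conf.int[i, "lower .95"],
    ci_high = s$conf.int[i, "upper .95"],
    p = s$coefficients[i, "Pr(>|z|)"],
    estimable = is.finite(beta)
  )
}

#' Univariate Cox regression per gene
#'
#' One single-covariate Cox proportional-hazards fit per gene; hazard
#' ratios are per unit of (optionally log2) expression. Genes on which the
#' fit fails or is non-estimable (e.g. constant expression) are returned as
#' flagged rows rather than raising an error.
#'
#' @inheritParams fit_lasso_cox
#' @param genes Gene symbols to test.
#' @return A tibble with `variable`, `beta`, `hr`, `ci_low`, `ci_high`, `p`,
#'   `estimable`.
#' @export
univariate_cox_per_gene <- function(ch, genes, log_transform = FALSE) {
  x <- cohort_design(ch, normalize_symbols(genes), log_transform)
  y <- survival::Surv(ch$clinical$time, ch$clinical$event)
  purrr::map_dfr(colnames(x), function(g) {
    fit <- tryCatch(
      suppressWarnings(survival::coxph(y ~ xg, data = data.frame(xg = x[, g]))),
      error = function(e) NULL
    )
    if (is.null(fit) || !is.finite(stats::coef(fit)[1])) {
      return(tibble::tibble(variable = g, beta = NA_real_, hr = NA_real_,
                            ci_low = NA_real_, ci_high = NA_real_,
                            p = NA_real_, estimable = FALSE))
    }
    cox_effect_row(g, fit, "xg")
  })
}

#' Apply a gene signature to a cohort: per-patient risk scores
#'
#' The risk score is the linear predictor `sum(beta_g * expression_g)` on
#' the raw expression scale by default. Signature genes absent from the
#' cohort contribute zero and are reported; if no signature gene is present
#' the call errors.
#'
#' @param sig A [gene_signature()].
#' @param ch A [cohort()].
#' @param log_transform Use `log2(x + 1)` expression values.
#' @return A tibble with `patient_id`, `risk_score`, `time`, `event`;
#'   attribute `missing_genes` lists absent signature genes.
#' @export
#' @examples
#' sim <- simulate_cohort(cohort_truth(n_genes = 100), n_patients = 40, seed = 2)
#' rs <- apply_signature(signature_macrophage(), sim$cohort)
#' head(rs, 3)
apply_signature <- function(sig, ch, log_transform = FALSE) {
  stopifnot(inherits(sig, "gene_signature"), inherits(ch, "cohort"))
  present <- sig$terms$gene %in% rownames(ch$expression)
  if (!any(present)) abort("apply_signature: no signature gene present in cohort")
  missing_genes <- sig$terms$gene[!present]
  if (length(missing_genes) > 0) {
    mcg_log("apply_signature: ", length(missing_genes),
            " signature gene(s) absent, contributing 0: ",
            paste(missing_genes, collapse = ", "))
  }
  terms <- sig$terms[present, ]
  x <- cohort_design(ch, terms$gene, log_transform)
  rs <- as.vector(x %*% terms$beta)
  out <- tibble::tibble(
    patient_id = ch$clinical$patient_id,
    risk_score = rs,
    time = ch$clinical$time,
    event = ch$clinical$event
  )
  attr(out, "missing_genes") <- missing_genes
  attr(out, "signature") <- sig$name
  out
}

#' Combined clinical + signature risk score
#'
#' The published combined signature: `CS = 0.008974621 * Age +
#' 1.617859481 * Grade + 0.940077644 * Signature_1 + 0.006408624 *
#' Signature_3`, with Grade coded 1 for lower-grade and 2 for high-grade
#' disease.
#'
#' @param age Age in years.
#' @param grade_code Integer grade code, 1 (lower grade) or 2 (high grade).
#' @param rs_sig1 Macrophage-signature risk score.
#' @param rs_sig3 Immune-related (Cheng) signature risk score.
#' @return Numeric combined score, vectorized over the inputs.
#' @export
#' @examples
#' combined_signature(0, 1, 0, 0)
combined_signature <- function(age, grade_code, rs_sig1, rs_sig3) {
  if (!all(grade_code %in% c(1, 2))) {
    abort("combined_signature: grade_code must be 1 (lower grade) or 2 (high grade)")
  }
  0.008974621 * age + 1.617859481 * grade_code +
    0.940077644 * rs_sig1 + 0.006408624 * rs_sig3
}

#' Refit a gene list as an unpenalized Cox signature
#'
#' Convention for published gene lists shipped without coefficients: a
#' multivariate (unpenalized) Cox proportional-hazards fit on the learning
#' cohort supplies the coefficients.
#'
#' @inheritParams fit_lasso_cox
#' @param genes Gene symbols (must be present in the cohort expression;
#'   genes absent are dropped with a log message).
#' @param name Signature name.
#' @return A [gene_signature()].
#' @export
refit_signature <- function(ch, genes, name = "refit", log_transform = FALSE) {
  genes <- normalize_symbols(genes)
  present <- genes %in% rownames(ch$expression)
  if (!any(present)) abort("refit_signature: no gene present in cohort")
  if (any(!present)) {
    mcg_log("refit_signature: dropping ", sum(!present),
            " gene(s) absent from cohort")
  }
  x <- cohort_design(ch, genes[present], log_transform)
  y <- survival::Surv(ch$clinical$time, ch$clinical$event)
  fit <- suppressWarnings(survival::coxph(y ~ x))
  beta <- stats::coef(fit)
  names(beta) <- colnames(x)
  beta <- beta[is.finite(beta)]
  if (length(beta) == 0) abort("refit_signature: no estimable coefficient")
  gene_signature(beta, name = name, learning_set = "learning_cohort")
}

#' LASSO Cox baseline over the full DEG list
#'
#' Comparison baseline: the same penalized fit as [fit_lasso_cox()] but with
#' every DEG (mapped to cohort symbols) as a candidate, skipping the
#' differential-network constraint.
#'
#' @inheritParams fit_lasso_cox
#' @param all_deg_genes Full DEG symbol list.
#' @return As [fit_lasso_cox()].
#' @export
baseline_lasso_all_degs <- function(ch, all_deg_genes, cfg = analysis_config(),
                                    seed = 1, log_transform = FALSE) {
  if (length(all_deg_genes) == 0) abort("baseline_lasso_all_degs: empty DEG list")
  genes <- intersect(normalize_symbols(all_deg_genes), rownames(ch$expression))
  if (length(genes) == 0) abort("baseline_lasso_all_degs: no DEG present in cohort")
  fit_lasso_cox(ch, genes, cfg, seed = seed, log_transform = log_transform,
                name = "lasso_all_degs")
}

#' Correlation-network node-strength baseline signature
#'
#' Comparison baseline without perturbation analysis: a weighted correlation
#' network over the full sample set (vehicle, endpoint and rebound animals
#' together), where each DEG node's strength is the sum of |PCC| with every
#' other DEG node (both compartments, no threshold). The top `k` genes by
#' node strength (ties broken lexicographically by node id; a symbol
#' counted once) define a gene set whose coefficients come from an
#' unpenalized Cox refit on the learning cohort.
#'
#' @param exp_norm A (vehicle-normalized) [compartment_experiment()].
#' @param node_genes Named list (`TC`, `TAM`) of DEG symbols.
#' @param ch Learning [cohort()].
#' @param k Genes to select.
#' @param log_transform Passed to [refit_signature()].
#' @return A list with `signature` (a [gene_signature()]) and `strengths`
#'   (tibble `id`, `gene`, `compartment`, `strength`, ranked).
#' @export
baseline_node_strength_signature <- function(exp_norm, node_genes, ch, k = 12,
                                             log_transform = FALSE) {
  animals <- sort(unique(exp_norm$samples$pair_id))
  dat <- node_data_matrix(exp_norm, node_genes, animals)
  if (k > nrow(dat)) abort("baseline_node_strength_signature: k exceeds node count")
  cmat <- suppressWarnings(cor(t(dat)))
  diag(cmat) <- 0
  strength <- unname(rowSums(abs(cmat), na.rm = TRUE))
  ranked <- tibble::tibble(
    id = rownames(dat),
    gene = sub("\\|(TC|TAM)$", "", rownames(dat)),
    compartment = sub("^.*\\|", "", rownames(dat)),
    strength = strength
  )
  ranked <- ranked[order(-ranked$strength, ranked$id), ]
  uniq <- unique(normalize_symbols(ranked$gene))
  top_genes <- uniq[seq_len(min(k, length(uniq)))]
  sig <- refit_signature(ch, intersect(top_genes, rownames(ch$expression)),
                         name = "node_strength", log_transform = log_transform)
  list(signature = sig, strengths = ranked)
}
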