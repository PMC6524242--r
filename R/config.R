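#' Analysis configuration
#'
#' Collects every tunable cutoff of the pipeline in one validated object.
#' Defaults are the thresholds used throughout the multicellular-network
#' workflow: differential expression calls at |FC| > 1.5 with BH-adjusted
#' p < 0.05, the top 50 DEGs per compartment as network nodes, network edges
#' at |PCC| > 0.95 with correlation-test p < 0.05, differential edges at
#' |dPCC| > 0.05 supported by at least 3 perturbation networks, tenfold
#' cross-validation for the penalized Cox fit, 1000 random 12-gene signatures
#' for the bootstrap null, and 100 half-cohort subsamples for the robustness
#' comparison. All threshold comparisons in the pipeline are strict.
#'
#' @param deg_abs_fc_threshold Fold-change cutoff on the ratio scale; a gene is
#'   a DEG only if FC > threshold or FC < 1/threshold (strict).
#' @param deg_adj_p_threshold BH-adjusted p-value cutoff for DEG calls.
#' @param top_k_per_compartment Number of largest-|log2 FC| DEGs kept per
#'   compartment as network nodes.
#' @param edge_abs_pcc_threshold Absolute Pearson correlation an edge must
#'   exceed.
#' @param edge_p_threshold Correlation-test p-value an edge must stay below.
#' @param delta_pcc_threshold Minimum |dPCC| for a perturbation to count as
#'   differential for a gene pair.
#' @param min_perturbations Number of perturbation networks that must exceed
#'   `delta_pcc_threshold` (with consistent sign) for a robust edge.
#' @param cv_folds Folds for cross-validated LASSO Cox.
#' @param n_random_signatures Draws for the random-signature null.
#' @param random_signature_size Genes per random signature.
#' @param robustness_fraction Fraction of patients per robustness subsample,
#'   in (0, 1].
#' @param robustness_reps Number of robustness subsamples.
#' @param roc_horizons Evaluation horizons, in years.
#' @param log_epsilon Pseudo-value added before log2 in the DEG t-test.
#' @param rng_seed Optional integer seed recorded with the configuration.
#'
#' @return A list of class `mcg_config`.
#' @export
#' @examples
#' cfg <- analysis_config(delta_pcc_threshold = 0.1)
#' cfg$delta_pcc_threshold
analysis_config <- function(deg_abs_fc_threshold = 1.5,
                            deg_adj_p_threshold = 0.05,
                            top_k_per_compartment = 50,
                            edge_abs_pcc_threshold = 0.95,
                            edge_p_threshold = 0.05,
                            delta_pcc_threshold = 0.05,
                            min_perturbations = 3,
                            cv_folds = 10,
                            n_random_signatures = 1000,
                            random_signature_size = 12,
                            robustness_fraction = 0.5,
                            robustness_reps = 100,
                            roc_horizons = c(3, 5),
                            log_epsilon = 0.01,
                            rng_seed = NULL) {
  cfg <- list(
    deg_abs_fc_threshold = deg_abs_fc_threshold,
    deg_adj_p_threshold = deg_adj_p_threshold,
    top_k_per_compartment = top_k_per_compartment,
    edge_abs_pcc_threshold = edge_abs_pcc_threshold,
    edge_p_threshold = edge_p_threshold,
    delta_pcc_threshold = delta_pcc_threshold,
    min_perturbations = min_perturbations,
    cv_folds = cv_folds,
    n_random_signatures = n_random_signatures,
    random_signature_size = random_signature_size,
    robustness_fraction = robustness_fraction,
    robustness_reps = robustness_reps,
    roc_horizons = roc_horizons,
    log_epsilon = log_epsilon,
    rng_seed = rng_seed
  )
  thresholds <- cfg[c(
    "deg_abs_fc_threshold", "deg_adj_p_threshold", "top_k_per_compartment",
    "edge_abs_pcc_threshold", "edge_p_threshold", "delta_pcc_threshold",
    "min_perturbations", "cv_folds", "n_random_signatures",
    "random_signature_size", "robustness_reps", "log_epsilon"
  )]
  bad <- names(thresholds)[!vapply(
    thresholds, function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x > 0,
    logical(1)
  )]
  if (length(bad) > 0) {
    abort(paste0("analysis_config: these fields must be positive scalars: ",
                 paste(bad, collapse = ", ")))
  }
  if (!is.numeric(robustness_fraction) || robustness_fraction <= 0 ||
      robustness_fraction > 1) {
    abort("analysis_config: robustness_fraction must lie in (0, 1]")
  }
  if (!is.numeric(roc_horizons) || length(roc_horizons) < 1 ||
      any(roc_horizons <= 0)) {
    abort("analysis_config: roc_horizons must be positive")
  }
  structure(cfg, class = "mcg_config")
}

#' @export
print.mcg_config <- function(x, ...) {
  cat("<mcg_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-24s %s\n", nm,
                paste(format(x[[nm]]), collapse = ", ")))
  }
  invisible(x)
}
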