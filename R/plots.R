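#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_step geom_point
#'   geom_histogram geom_vline geom_abline geom_boxplot labs theme_minimal
NULL

#' @export
ggplot2::autoplot

#' ROC curve of a time-dependent ROC result
#'
#' @param object A `td_roc` from [time_dependent_roc()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot td_roc
#' @export
autoplot.td_roc <- function(object, ...) {
  d <- object$curve
  ggplot(d, aes(x = 1 - .data$specificity, y = .data$sensitivity)) +
    geom_step(color = "#c0392b") +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed", color = "grey60") +
    labs(x = "1 - specificity", y = "sensitivity",
         title = sprintf("Time-dependent ROC at horizon %g (AUC %.3f)",
                         object$horizon, object$auc)) +
    theme_minimal()
}

#' Kaplan-Meier curves of a log-rank comparison
#'
#' @param object A `km_logrank` from [km_logrank()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot km_logrank
#' @export
autoplot.km_logrank <- function(object, ...) {
  ggplot(object$curves, aes(x = .data$time, y = .data$surv,
                            color = .data$group)) +
    geom_step() +
    labs(x = "time", y = "survival probability",
         title = sprintf("Kaplan-Meier (log-rank p = %.3g)", object$p)) +
    theme_minimal()
}

#' Null AUC distribution with the observed signature's AUC
#'
#' @param object A `null_distribution` from [random_signature_null()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot null_distribution
#' @export
autoplot.null_distribution <- function(object, ...) {
  ggplot(tibble::tibble(auc = object$null_aucs), aes(x = .data$auc)) +
    geom_histogram(bins = 40, fill = "#2980b9", alpha = 0.7) +
    geom_vline(xintercept = object$observed_auc, color = "#c0392b") +
    labs(x = "null AUC", y = "count",
         title = sprintf("Random %d-gene signatures: P(AUC >= %.3f) = %.4g",
                         object$k, object$observed_auc, object$p_value)) +
    theme_minimal()
}

#' Cross-validation deviance curve of a penalized Cox fit
#'
#' @param object A `lasso_cox_fit` from [fit_lasso_cox()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot lasso_cox_fit
#' @export
autoplot.lasso_cox_fit <- function(object, ...) {
  d <- object$cv_curve
  ggplot(d, aes(x = log(.data$lambda), y = .data$mean_deviance)) +
    geom_point(size = 0.8) +
    geom_line(alpha = 0.5) +
    geom_vline(xintercept = object$log_lambda, linetype = "dashed") +
    labs(x = "ln(lambda)", y = "mean CV partial-likelihood deviance",
         title = sprintf("Optimal lambda = %.6g (ln = %.4f)",
                         object$lambda, object$log_lambda)) +
    theme_minimal()
}

#' Subsample AUC distributions of competing signatures
#'
#' @param object A `robustness_result` from [robustness_subsample()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot robustness_result
#' @export
autoplot.robustness_result <- function(object, ...) {
  ggplot(object$aucs, aes(x = .data$signature, y = .data$auc,
                          fill = .data$signature)) +
    geom_boxplot(show.legend = FALSE) +
    ggplot2::facet_wrap(~horizon) +
    labs(x = NULL, y = "subsample AUC",
         title = sprintf("Robustness over %d subsamples (fraction %.2f)",
                         object$B, object$fraction)) +
    theme_minimal()
}
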