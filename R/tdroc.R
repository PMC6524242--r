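# Kaplan-Meier estimate of the censoring survivor function G(t) = P(C > t),
# as a left-continuous-evaluable step function. Returns a function g(t, minus)
# where minus = TRUE evaluates G(t^-).
censoring_km <- function(time, event) {
  fit <- survival::survfit(survival::Surv(time, 1 - event) ~ 1)
  steps_t <- fit$time
  steps_s <- fit$surv
  function(t, minus = FALSE) {
    s <- vapply(t, function(ti) {
      if (minus) idx <- which(steps_t < ti) else idx <- which(steps_t <= ti)
      if (length(idx) == 0) 1 else steps_s[max(idx)]
    }, numeric(1))
    # guard against zero mass in the tail (would give infinite weights)
    pos <- steps_s[steps_s > 0]
    floor_s <- if (length(pos) > 0) min(pos) else 1
    pmax(s, floor_s)
  }
}

# weighted Mann-Whitney AUC of scores for cases (positive) vs controls,
# with half credit for ties; equals the trapezoidal area under the weighted
# empirical ROC curve
weighted_auc <- function(score_case, w_case, score_control, w_control) {
  tot <- sum(w_case) * sum(w_control)
  if (tot == 0) return(NA_real_)
  s <- sort(unique(c(score_case, score_control)))
  wc <- vapply(s, function(v) sum(w_control[score_control == v]), numeric(1))
  cum_below <- cumsum(c(0, wc))[seq_along(s)]
  conc <- vapply(seq_along(s), function(i) cum_below[i] + 0.5 * wc[i], numeric(1))
  idx <- match(score_case, s)
  sum(w_case * conc[idx]) / tot
}

#' Time-dependent ROC with Kaplan-Meier censoring weights
#'
#' Cumulative-cases / dynamic-controls ROC at a fixed horizon: patients who
#' died by the horizon are cases, patients still at risk beyond it are
#' controls, and patients censored before the horizon are excluded with
#' their probability mass redistributed through inverse-probability-of-
#' censoring weights from the Kaplan-Meier estimate of the censoring
#' distribution (cases weighted by `1/G(T-)`, controls by `1/G(horizon)`).
#' The AUC is the area under the weighted empirical ROC (equivalently the
#' weighted Mann-Whitney statistic with ties split); the optimal cutoff
#' maximizes the Youden index `sensitivity + specificity - 1`. With no
#' censoring this reduces exactly to the binary ROC of status-at-horizon.
#'
#' @param rs Numeric risk scores (higher = higher risk).
#' @param time,event Follow-up time and event indicator (1 = death).
#' @param horizon Evaluation horizon, same unit as `time`.
#' @return An object of class `td_roc`: list with `horizon`, `auc`,
#'   `cutoff`, `youden`, `curve` (tibble `cutoff`, `sensitivity`,
#'   `specificity`), `n_cases`, `n_controls`, `n_excluded`.
#' @export
#' @examples
#' set.seed(1)
#' t <- rexp(50); s <- -t + rnorm(50, 0, 0.3)
#' time_dependent_roc(s, t, rep(1, 50), horizon = median(t))$auc
time_dependent_roc <- function(rs, time, event, horizon) {
  stopifnot(length(rs) == length(time), length(time) == length(event))
  ok <- is.finite(rs) & is.finite(time)
  rs <- rs[ok]; time <- time[ok]; event <- event[ok]
  is_case <- time <= horizon & event == 1
  is_control <- time > horizon
  excluded <- !is_case & !is_control
  if (sum(is_case) == 0 || sum(is_control) == 0) {
    abort(paste0("time_dependent_roc: no ",
                 if (sum(is_case) == 0) "cases" else "controls",
                 " at horizon ", format(horizon)))
  }
  g <- censoring_km(time, event)
  w_case <- 1 / g(time[is_case], minus = TRUE)
  w_control <- rep(1 / g(horizon)[1], sum(is_control))

  sc <- rs[is_case]; sk <- rs[is_control]
  auc <- weighted_auc(sc, w_case, sk, w_control)

  cuts <- sort(unique(rs))
  sens <- vapply(cuts, function(cv) sum(w_case[sc > cv]) / sum(w_case), numeric(1))
  spec <- vapply(cuts, function(cv) sum(w_control[sk <= cv]) / sum(w_control),
                 numeric(1))
  j <- sens + spec - 1
  best <- which.max(j)
  structure(
    list(horizon = horizon, auc = auc, cutoff = cuts[best], youden = j[best],
         curve = tibble::tibble(cutoff = cuts, sensitivity = sens,
                                specificity = spec),
         n_cases = sum(is_case), n_controls = sum(is_control),
         n_excluded = sum(excluded)),
    class = "td_roc"
  )
}

#' @export
print.td_roc <- function(x, ...) {
  cat(sprintf(
    "<td_roc> horizon %g: AUC %.3f, Youden cutoff %.4g (%d cases / %d controls / %d censored excluded)\n",
    x$horizon, x$auc, x$cutoff, x$n_cases, x$n_controls, x$n_excluded))
  invisible(x)
}

#' @method tidy td_roc
#' @export
#' @rdname time_dependent_roc
#' @param x A `td_roc`.
#' @param ... Unused.
tidy.td_roc <- function(x, ...) x$curve

#' @method glance td_roc
#' @export
#' @rdname time_dependent_roc
glance.td_roc <- function(x, ...) {
  tibble::tibble(horizon = x$horizon, auc = x$auc, cutoff = x$cutoff,
                 youden = x$youden, n_cases = x$n_cases,
                 n_controls = x$n_controls, n_excluded = x$n_excluded)
}

# plain binary ROC AUC (Mann-Whitney with ties split)
auc_binary <- function(score, label) {
  weighted_auc(score[label], rep(1, sum(label)),
               score[!label], rep(1, sum(!label)))
}

# default horizon for "overall survival" accuracy: upper quartile of follow-up
overall_survival_horizon <- function(time) unname(quantile(time, 0.75))
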