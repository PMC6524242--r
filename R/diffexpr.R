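#' Normalize expression to the vehicle-group mean
#'
#' Divides every endpoint/rebound sample value of each gene by that gene's
#' mean over the vehicle samples of the same compartment, so downstream fold
#' changes and correlations are expressed relative to the untreated state.
#' Genes whose vehicle mean is zero in a compartment cannot be normalized
#' and are dropped (logged); the vehicle columns themselves are retained
#' (normalized to their own mean) so the full-sample correlation baseline
#' remains computable.
#'
#' @param exp A [compartment_experiment()] (raw scale).
#' @return A [compartment_experiment()] with `normalized = TRUE`.
#' @export
vehicle_normalize <- function(exp) {
  stopifnot(inherits(exp, "compartment_experiment"))
  if (isTRUE(exp$normalized)) abort("vehicle_normalize: already normalized")
  s <- exp$samples
  if (!any(s$group == "Veh")) abort("vehicle_normalize: no vehicle samples")
  mat <- exp$expression
  out <- mat
  drop_gene <- rep(FALSE, nrow(mat))
  for (comp in c("TC", "TAM")) {
    cols <- s$sample_id[s$compartment == comp]
    veh <- s$sample_id[s$compartment == comp & s$group == "Veh"]
    if (length(veh) == 0) abort(paste0("vehicle_normalize: no vehicle samples in ", comp))
    vmean <- rowMeans(mat[, veh, drop = FALSE])
    drop_gene <- drop_gene | vmean == 0
    out[, cols] <- mat[, cols, drop = FALSE] / vmean
  }
  if (any(drop_gene)) {
    mcg_log("vehicle_normalize: dropping ", sum(drop_gene),
            " gene(s) with zero vehicle mean")
    out <- out[!drop_gene, , drop = FALSE]
  }
  compartment_experiment(out, s, normalized = TRUE)
}

# vectorized two-sided Welch t-test on the rows of two matrices
welch_rows <- function(a, b) {
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- apply(a, 1, var); vb <- apply(b, 1, var)
  se2 <- va / na + vb / nb
  tstat <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * pt(-abs(tstat), df)
  # degenerate variance in both groups: identical values are untestable
  # (p := 1); zero-noise separation of the means is certain (p := 0)
  degen <- se2 == 0
  p[degen & ma == mb] <- 1
  p[degen & ma != mb] <- 0
  if (any(degen)) mcg_log("select_degs: ", sum(degen),
                          " gene(s) with zero variance in both groups")
  list(t = tstat, p = p)
}

#' Rebound-vs-endpoint differential expression
#'
#' Per compartment, computes each gene's fold change (ratio of rebound to
#' endpoint group means of vehicle-normalized expression) and a two-sided
#' Welch t-test on `log2(normalized value + epsilon)`, with Benjamini-
#' Hochberg adjustment within compartment. A gene is a DEG when
#' `FC > threshold` or `FC < 1/threshold` (strictly) and its adjusted p is
#' strictly below the cutoff.
#'
#' @param exp_norm A vehicle-normalized [compartment_experiment()].
#' @param cfg An [analysis_config()].
#' @return A tibble with one row per gene per compartment: `gene`,
#'   `compartment`, `fc`, `log2_fc`, `p`, `adj_p`, `is_deg`, `abs_fc_rank`
#'   (rank of |log2 FC| within compartment, 1 = largest), sorted by
#'   |log2 FC| descending within compartment.
#' @export
select_degs <- function(exp_norm, cfg = analysis_config()) {
  stopifnot(inherits(exp_norm, "compartment_experiment"))
  if (!isTRUE(exp_norm$normalized)) {
    abort("select_degs: expression must be vehicle-normalized first")
  }
  s <- exp_norm$samples
  eps <- cfg$log_epsilon
  res <- purrr::map_dfr(c("TC", "TAM"), function(comp) {
    reb <- s$sample_id[s$compartment == comp & s$group == "Reb"]
    ep <- s$sample_id[s$compartment == comp & s$group == "Ep"]
    if (length(reb) < 2 || length(ep) < 2) {
      abort(paste0("select_degs: need >= 2 Reb and >= 2 Ep samples in ", comp))
    }
    m_reb <- exp_norm$expression[, reb, drop = FALSE]
    m_ep <- exp_norm$expression[, ep, drop = FALSE]
    fc <- rowMeans(m_reb) / rowMeans(m_ep)
    tt <- welch_rows(log2(m_reb + eps), log2(m_ep + eps))
    tibble::tibble(
      gene = rownames(m_reb), compartment = comp,
      fc = unname(fc), log2_fc = unname(log2(fc)), p = unname(tt$p)
    )
  })
  res <- res |>
    dplyr::group_by(.data$compartment) |>
    dplyr::mutate(
      adj_p = p.adjust(.data$p, method = "BH"),
      is_deg = (.data$fc > cfg$deg_abs_fc_threshold |
                  .data$fc < 1 / cfg$deg_abs_fc_threshold) &
        .data$adj_p < cfg$deg_adj_p_threshold,
      abs_fc_rank = rank(-abs(.data$log2_fc), ties.method = "min")
    ) |>
    dplyr::arrange(dplyr::desc(abs(.data$log2_fc)), .by_group = TRUE) |>
    dplyr::ungroup()
  res
}

#' Top-k DEGs per compartment by absolute fold change
#'
#' Keeps the `k` DEGs of largest |log2 FC| in each compartment; ties are
#' broken by smaller adjusted p, then lexicographic gene symbol. If a
#' compartment has fewer than `k` DEGs, all of them are returned with a
#' log message.
#'
#' @param records Output of [select_degs()].
#' @param k Genes to keep per compartment.
#' @return Named list with elements `TC` and `TAM`, each a character vector
#'   of gene symbols.
#' @export
top_k_degs <- function(records, k = 50) {
  if (!is.numeric(k) || k <= 0) abort("top_k_degs: k must be positive")
  degs <- dplyr::filter(records, .data$is_deg)
  out <- lapply(c(TC = "TC", TAM = "TAM"), function(comp) {
    d <- degs[degs$compartment == comp, ]
    d <- d[order(-abs(d$log2_fc), d$adj_p, d$gene), ]
    if (nrow(d) < k) {
      mcg_log("top_k_degs: only ", nrow(d), " DEGs in ", comp,
              " (requested ", k, ")")
    }
    head(d$gene, k)
  })
  out
}
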