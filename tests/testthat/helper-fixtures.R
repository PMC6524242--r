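# small fixtures built in code, shared across test files

# hand-sized paired experiment: `values` is a genes x animals matrix applied
# to both compartments unless tam_values is given
toy_experiment <- function(values, groups, tam_values = NULL) {
  n_animals <- ncol(values)
  animals <- sprintf("A%02d", seq_len(n_animals))
  tam <- tam_values %||% values
  expr <- cbind(values, tam)
  colnames(expr) <- c(paste0(animals, "_TC"), paste0(animals, "_TAM"))
  if (is.null(rownames(expr))) {
    rownames(expr) <- sprintf("G%03d", seq_len(nrow(expr)))
  }
  samples <- tibble::tibble(
    sample_id = colnames(expr),
    compartment = rep(c("TC", "TAM"), each = n_animals),
    group = rep(groups, 2),
    pair_id = rep(animals, 2)
  )
  compartment_experiment(expr, samples)
}

`%||%` <- rlang::`%||%`

# independent textbook Pearson r and p (the oracle against pearson_edge and
# the matrix path in build_network)
oracle_pearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  if (abs(r) >= 1) return(list(r = r, p = 0))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(t), n - 2))
}

# exhaustive Mann-Whitney AUC by pair counting (oracle for the ROC code)
oracle_mw_auc <- function(score, positive) {
  sp <- score[positive]
  sn <- score[!positive]
  tot <- 0
  for (a in sp) for (b in sn) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

# small survival cohort with a single planted gene effect, built directly
toy_surv_cohort <- function(n = 60, beta = 1, seed = 1, censor = 0.2) {
  withr::with_seed(seed, {
    x <- stats::rlnorm(n, 0, 0.5)
    expr <- rbind(GENE1 = x, GENE2 = stats::rlnorm(n, 0, 0.5))
    t_event <- stats::rexp(n, rate = 0.2 * exp(beta * (x - mean(x))))
    c_time <- if (censor > 0) stats::rexp(n, rate = 0.2 * censor / (1 - censor)) else Inf
    clinical <- tibble::tibble(
      patient_id = sprintf("P%03d", seq_len(n)),
      time = pmin(t_event, c_time),
      event = as.integer(t_event <= c_time),
      age = round(stats::runif(n, 30, 80)),
      gender = sample(c("Male", "Female"), n, TRUE),
      grade = sample(c("low", "high"), n, TRUE)
    )
    colnames(expr) <- clinical$patient_id
    suppressMessages(cohort(expr, clinical))
  })
}

# a reproducible arbitrary 12-gene signature over a cohort's universe
with_seed_signature <- function(ch, seed, k = 12) {
  withr::with_seed(seed + 90000, {
    genes <- sample(rownames(ch$expression), k)
    gene_signature(stats::setNames(stats::rnorm(k), genes), name = "arbitrary")
  })
}
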