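# run code with a private, restorable RNG stream; a seed is mandatory for
# every generator so outputs are bit-reproducible
with_preserved_seed <- function(seed, code) {
  if (is.null(seed) || is.na(seed)) abort("a seed is required for simulation")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Ground truth for a simulated paired-compartment mouse experiment
#'
#' Describes what [simulate_mouse_experiment()] plants: per-compartment
#' differentially expressed genes with true rebound-vs-endpoint fold changes,
#' and "gained" gene pairs engineered so that each drug-resistant (Reb)
#' sample is a coherent high-leverage point for the pair — uncorrelated (or
#' weakly correlated) across the endpoint samples, but displaced along a
#' shared direction in every rebound sample, so that adding any single Reb
#' sample to the endpoint reference raises the pair's Pearson correlation.
#'
#' Default sizes mirror the emulated preclinical design: 5 vehicle, 6
#' endpoint and 4 rebound animals, each contributing one tumor-cell and one
#' macrophage profile, over a universe of 1000 genes per compartment.
#' Correlation is planted through shared latent factors (loading
#' `sqrt(rho)`), never through explicit covariance matrices, so any number
#' of pairs stays positive definite.
#'
#' @param n_genes Genes per compartment.
#' @param n_veh,n_ep,n_reb Animals per treatment group. `n_ep` must be at
#'   least 3 (a Pearson correlation over fewer endpoint samples is not
#'   testable).
#' @param noise_sd Within-group biological noise, SD of log2 expression.
#'   The default (0.5) keeps ordinary DEG shifts at ~2.4 noise SDs, large
#'   enough for the t-test yet small enough that un-engineered DEG pairs do
#'   not cross the stringent |PCC| edge threshold from a single added
#'   sample.
#' @param n_deg_per_compartment Planted DEGs per compartment (beyond the
#'   genes used by planted pairs).
#' @param deg_log2fc Absolute log2 fold change of planted DEGs; signs
#'   alternate.
#' @param n_gained_pairs Number of planted intercellular gained pairs (TC
#'   gene paired with TAM gene).
#' @param rho_ep Latent-factor correlation of planted pairs across endpoint
#'   samples (default 0: uncorrelated when sensitive).
#' @param rho_reb Latent-factor correlation of planted pairs across rebound
#'   samples.
#' @param reb_shift Shared log2 displacement of both pair genes in every
#'   rebound sample; this is what makes a Reb sample a leverage point. In
#'   units of log2 expression (the default is `10 * noise_sd` when left
#'   `NULL`, an essentially certain leverage gain).
#' @param reb_shift_mode `"constant"`: every rebound sample displaces every
#'   pair in the same (positive) direction — coherent resistance rewiring,
#'   under which pairs of genes from different planted pairs also gain
#'   correlation, as dense all-gained differential networks show in real
#'   resistant tumors. `"random"`: each pair draws an independent
#'   Rademacher sign per rebound sample (still shared by the two genes of
#'   the pair), modelling independently rewired pairs; cross-pair
#'   correlation changes then flip sign across perturbations and are
#'   rejected by the sign-consistency rule, which is the appropriate
#'   regime for measuring false-call rates.
#' @param baseline_log2_range Range of per-gene baseline log2 abundance.
#'
#' @return A list of class `mouse_truth` with elements `deg` (tibble: gene,
#'   compartment, fc), `gained_pairs` (tibble: gene_a/comp_a, gene_b/comp_b,
#'   rho_ep, rho_reb, reb_shift), group sizes and noise scale.
#' @export
mouse_truth <- function(n_genes = 1000,
                        n_veh = 5, n_ep = 6, n_reb = 4,
                        noise_sd = 0.5,
                        n_deg_per_compartment = 40,
                        deg_log2fc = 1.2,
                        n_gained_pairs = 10,
                        rho_ep = 0,
                        rho_reb = 0.9,
                        reb_shift = NULL,
                        reb_shift_mode = c("constant", "random"),
                        baseline_log2_range = c(2, 8)) {
  reb_shift_mode <- match.arg(reb_shift_mode)
  if (n_ep < 3) abort("mouse_truth: n_ep must be >= 3 (correlation undefined below)")
  if (n_veh < 1 || n_reb < 1) abort("mouse_truth: all groups must be nonempty")
  if (abs(rho_ep) > 1 || abs(rho_reb) > 1) abort("mouse_truth: |rho| must be <= 1")
  reb_shift <- reb_shift %||% (10 * noise_sd)
  n_pair_genes <- n_gained_pairs
  if (n_deg_per_compartment + n_pair_genes > n_genes) {
    abort("mouse_truth: gene universe too small for the planted sets")
  }
  genes <- sprintf("G%04d", seq_len(n_genes))

  # pair genes come first; their rebound displacement (reb_shift) makes them
  # de facto strong DEGs under the constant mode, so they survive top-k DEG
  # selection and become network nodes. They are not listed in `deg`, whose
  # rows promise an exact planted mean ratio.
  pair_genes_tc <- genes[seq_len(n_pair_genes)]
  pair_genes_tam <- genes[seq_len(n_pair_genes)]
  mk_deg <- function(comp) {
    if (n_deg_per_compartment == 0) return(NULL)
    idx <- n_pair_genes + seq_len(n_deg_per_compartment)
    tibble::tibble(
      gene = genes[idx], compartment = comp,
      fc = 2^(deg_log2fc * rep_len(c(1, -1), n_deg_per_compartment))
    )
  }
  deg <- dplyr::bind_rows(
    tibble::tibble(gene = character(), compartment = character(), fc = numeric()),
    mk_deg("TC"), mk_deg("TAM")
  )

  gained_pairs <- if (n_gained_pairs > 0) {
    tibble::tibble(
      gene_a = pair_genes_tc, comp_a = "TC",
      gene_b = pair_genes_tam, comp_b = "TAM",
      rho_ep = rho_ep, rho_reb = rho_reb, reb_shift = reb_shift,
      sign_mode = reb_shift_mode
    )
  } else {
    tibble::tibble(gene_a = character(), comp_a = character(),
                   gene_b = character(), comp_b = character(),
                   rho_ep = numeric(), rho_reb = numeric(),
                   reb_shift = numeric(), sign_mode = character())
  }
  if (nrow(gained_pairs) > 0 &&
      (!all(gained_pairs$gene_a %in% genes) || !all(gained_pairs$gene_b %in% genes))) {
    abort("mouse_truth: planted pairs must reference generated genes")
  }

  structure(
    list(genes = genes, n_veh = n_veh, n_ep = n_ep, n_reb = n_reb,
         noise_sd = noise_sd, deg = deg, gained_pairs = gained_pairs,
         baseline_log2_range = baseline_log2_range),
    class = "mouse_truth"
  )
}

#' Simulate a paired TC/TAM mouse experiment with known ground truth
#'
#' Draws an FPKM-like expression matrix (log-normal noise around per-gene,
#' per-compartment baselines) for `n_veh + n_ep + n_reb` animals, each with
#' one tumor-cell and one macrophage profile. Planted DEGs receive a mean
#' log2 shift in the rebound group equal to `log2(fc)`; planted gained pairs
#' receive shared latent factors (correlation `rho_ep` across endpoint
#' samples, `rho_reb` across rebound samples) plus the shared `reb_shift`
#' displacement in rebound samples.
#'
#' @param truth A [mouse_truth()].
#' @param seed Integer seed (required; identical seed and truth give
#'   bit-identical output).
#' @return A list with `experiment` (a [compartment_experiment()]) and
#'   `truth` (the input, unchanged).
#' @export
#' @examples
#' sim <- simulate_mouse_experiment(mouse_truth(n_genes = 50), seed = 1)
#' sim$experiment
simulate_mouse_experiment <- function(truth, seed) {
  stopifnot(inherits(truth, "mouse_truth"))
  if (missing(seed)) abort("simulate_mouse_experiment: seed is required")
  with_preserved_seed(seed, {
    n_animals <- truth$n_veh + truth$n_ep + truth$n_reb
    animals <- sprintf("A%02d", seq_len(n_animals))
    group <- rep(c("Veh", "Ep", "Reb"), c(truth$n_veh, truth$n_ep, truth$n_reb))
    ep_cols <- which(group == "Ep")
    reb_cols <- which(group == "Reb")
    genes <- truth$genes
    n_genes <- length(genes)

    # shared latent factors per planted pair, drawn once so both compartments
    # see the same factor realization
    pair_f_ep <- pair_f_reb <- pair_sign <- NULL
    n_pairs <- nrow(truth$gained_pairs)
    if (n_pairs > 0) {
      pair_f_ep <- matrix(rnorm(n_pairs * truth$n_ep), nrow = n_pairs)
      pair_f_reb <- matrix(rnorm(n_pairs * truth$n_reb), nrow = n_pairs)
      pair_sign <- matrix(1, nrow = n_pairs, ncol = truth$n_reb)
      rnd <- truth$gained_pairs$sign_mode == "random"
      if (any(rnd)) {
        pair_sign[rnd, ] <- sample(c(-1, 1), sum(rnd) * truth$n_reb,
                                   replace = TRUE)
      }
    }

    one_compartment <- function(comp) {
      mu <- runif(n_genes, truth$baseline_log2_range[1], truth$baseline_log2_range[2])
      log2x <- mu + matrix(rnorm(n_genes * n_animals, 0, truth$noise_sd),
                           nrow = n_genes)
      dimnames(log2x) <- list(genes, animals)

      d <- truth$deg[truth$deg$compartment == comp, ]
      if (nrow(d) > 0) {
        log2x[d$gene, reb_cols] <- log2x[d$gene, reb_cols] + log2(d$fc)
      }

      gp <- truth$gained_pairs
      if (nrow(gp) > 0) {
        for (i in seq_len(nrow(gp))) {
          g <- if (gp$comp_a[i] == comp) gp$gene_a[i]
               else if (gp$comp_b[i] == comp) gp$gene_b[i]
               else next
          # rebuild this gene's Ep/Reb noise as latent factor + private noise
          if (gp$rho_ep[i] != 0) {
            log2x[g, ep_cols] <- mu[match(g, genes)] + truth$noise_sd *
              (sqrt(gp$rho_ep[i]) * pair_f_ep[i, ] +
                 sqrt(1 - gp$rho_ep[i]) * rnorm(truth$n_ep))
          }
          if (gp$rho_reb[i] != 0) {
            shift_already <- if (any(truth$deg$gene == g & truth$deg$compartment == comp)) {
              log2(truth$deg$fc[truth$deg$gene == g & truth$deg$compartment == comp][1])
            } else 0
            log2x[g, reb_cols] <- mu[match(g, genes)] + shift_already +
              truth$noise_sd * (sqrt(gp$rho_reb[i]) * pair_f_reb[i, ] +
                                  sqrt(1 - gp$rho_reb[i]) * rnorm(truth$n_reb))
          }
          # displacement shared by both pair genes per rebound sample: the
          # single-sample leverage that the perturbation analysis detects
          log2x[g, reb_cols] <- log2x[g, reb_cols] + gp$reb_shift[i] * pair_sign[i, ]
        }
      }
      log2x
    }

    tc <- one_compartment("TC")
    tam <- one_compartment("TAM")
    expr <- cbind(2^tc, 2^tam)
    colnames(expr) <- c(paste0(animals, "_TC"), paste0(animals, "_TAM"))
    samples <- tibble::tibble(
      sample_id = colnames(expr),
      compartment = rep(c("TC", "TAM"), each = n_animals),
      group = rep(group, 2),
      pair_id = rep(animals, 2)
    )
    list(experiment = compartment_experiment(expr, samples), truth = truth)
  })
}
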