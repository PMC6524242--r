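# mcgnet

Multicellular gene-network perturbation analysis and network-constrained
survival signatures.

## The problem

When a tumor escapes a targeted therapy, the interactions between tumor
cells (TCs) and tumor-associated macrophages (TAMs) rewire. With paired
TC/TAM expression profiles from only a handful of animals per treatment
group, ordinary differential co-expression analysis is hopeless — but the
*single-sample perturbation* trick is not: build a reference co-expression
network from the drug-sensitive (endpoint) animals alone, then rebuild it
after adding **one** drug-resistant (rebound) animal at a time, and ask
which gene pairs change correlation consistently across those
perturbations. `mcgnet` implements that analysis end to end, together with
the survival modelling that turns the resulting differential network into a
patient-level prognostic signature, and seeded synthetic-data generators so
every stage is testable with known ground truth.

## The method in brief

- Nodes are (gene, compartment) pairs from the top-50 |fold change| DEGs
  per compartment (rebound vs endpoint, vehicle-normalized, Welch t-test,
  BH-adjusted, `|FC| > 1.5` and `p_adj < 0.05`, strict).
- Edges require `|PCC| > 0.95` and `p < 0.05` across paired animals;
  TC–TAM edges are intercellular, within-compartment edges intracellular.
- For each pair, `dPCC_i = PCC(Ep + Reb_i) − PCC(Ep)`; a robust
  differential edge has `|dPCC_i| > 0.05` with one consistent sign in at
  least 3 of the 4 perturbation networks (gained if positive, lost if
  negative).
- Genes of the differential network are candidates for an L1-penalized Cox
  model (`glmnet`, tenfold event-stratified CV, penalty at the deviance
  minimum); the nonzero coefficients define the risk score
  `RS = Σ β_g · x_g`.
- Evaluation: time-dependent ROC with Kaplan–Meier censoring weights,
  Youden-cutoff Kaplan–Meier / log-rank splits, a random-gene-signature
  bootstrap null, subsample robustness with one-tailed Wilcoxon tests,
  paired-bootstrap AUC comparisons, multivariate Cox adjustment,
  survival-status surrogate classification of targeted-therapy response,
  and risk-score comparisons across mutation/subtype strata.

The shipped `signature_macrophage()` object carries the published 12-gene
macrophage-related signature (5 macrophage genes, 7 tumor-cell genes) with
its published coefficients, e.g. `+1.184362541 × FANCA` and
`−0.877296902 × SCN3A`, and the published optimal penalty
(λ = 0.06226413, ln λ = −2.77637). `combined_signature()` implements the
published clinical/molecular combination
`CS = 0.008974621·Age + 1.617859481·Grade + 0.940077644·Sig1 + 0.006408624·Sig3`.

## Worked example

```r
library(mcgnet)

# mouse side: paired 5 vehicle / 6 endpoint / 4 rebound animals
sim   <- simulate_mouse_experiment(mouse_truth(n_genes = 300), seed = 1)
norm  <- vehicle_normalize(sim$experiment)
nodes <- top_k_degs(select_degs(norm), k = 50)
nets  <- build_sensitive_and_perturbation_networks(norm, nodes)
dnet  <- build_differential_network(
           delta_pcc_table(nets$sensitive, nets$perturbations))
dnet
#> <differential_network> 31 nodes, 317 robust edges (99% gained)

# patient side: learn on n = 310, validate on n = 690
learn <- simulate_cohort(cohort_truth(), 310, seed = 2)
valid <- simulate_cohort(cohort_truth(), 690, seed = 3)
fit   <- fit_lasso_cox(learn$cohort, learn$candidates, seed = 2)
glance(fit$fit)
#> # A tibble: 1 × 4
#>   lambda log_lambda n_candidates n_selected
#>    <dbl>      <dbl>        <int>      <int>
#> 1 0.0332      -3.41           29         19

rs   <- apply_signature(fit$signature, valid$cohort)
roc3 <- time_dependent_roc(rs$risk_score, rs$time, rs$event, horizon = 3)
roc3
#> <td_roc> horizon 3: AUC 0.868, Youden cutoff 4.574 (389 cases / 216 controls / 85 censored excluded)
km_logrank(rs$risk_score, rs$time, rs$event, cutoff = roc3$cutoff)
#> <km_logrank> chisq = 251.234 (df 1), p = 1.4e-56; groups: high=416, low=274
```

The dense, almost entirely correlation-gained differential network is the
expected outcome when resistant samples displace interacting gene pairs
coherently; the validation AUC near 0.87 and the decisive log-rank split
reflect the planted signature strength (see the methods vignette in
`vignettes/` for what the generators do and do not emulate). Every result
object has `tidy()`/`glance()` methods and an `autoplot()` for the ROC
curve, KM curves, CV path, null distribution and robustness boxplots.

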