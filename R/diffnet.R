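#' Per-pair delta-PCC table across perturbation networks
#'
#' For every candidate gene pair, recomputes the Pearson correlation from
#' the underlying sample vectors in the sensitive network (endpoint animals)
#' and in each perturbation network (endpoint plus one rebound animal), and
#' tabulates `dPCC_i = PCC_perturbed_i - PCC_sensitive`. A perturbation
#' "exceeds" for a pair when `|dPCC_i|` strictly exceeds the threshold; a
#' pair is robust when at least `min_perturbations` perturbations exceed
#' with one consistent sign (mixed-sign exceedances are never robust).
#'
#' The default pair universe (`"edge-union"`) contains the pairs that pass
#' the edge criterion in the sensitive network or in at least one
#' perturbation network; `"all-pairs"` scores every node pair regardless.
#' Deltas always come from the raw correlations, never from the thresholded
#' edge sets.
#'
#' @param sensitive Sensitive `gene_network` from
#'   [build_sensitive_and_perturbation_networks()].
#' @param perturbations List of perturbation `gene_network`s sharing the
#'   sensitive network's node universe.
#' @param cfg An [analysis_config()].
#' @param pair_universe `"edge-union"` or `"all-pairs"`.
#' @return A tibble with one row per pair: `node_a`, `node_b`,
#'   `pcc_sensitive`, `delta_pcc` (list column, one value per perturbation),
#'   `n_exceed`, `representative_delta` (mean over the consistently signed
#'   exceeding perturbations; 0 when none), `robust`, `edge_class`
#'   (gained/lost/invariant) and `in_sensitive` (pair was an edge of the
#'   sensitive network).
#' @export
delta_pcc_table <- function(sensitive, perturbations, cfg = analysis_config(),
                            pair_universe = c("edge-union", "all-pairs")) {
  pair_universe <- match.arg(pair_universe)
  ids <- rownames(sensitive$data)
  for (p in perturbations) {
    if (!identical(rownames(p$data), ids)) {
      abort("delta_pcc_table: networks have mismatched node universes")
    }
  }
  if (cfg$min_perturbations > length(perturbations)) {
    warn("delta_pcc_table: min_perturbations exceeds the number of perturbation networks; no pair can be robust")
  }

  cor_of <- function(net) suppressWarnings(cor(t(net$data)))
  c_sens <- cor_of(sensitive)
  c_pert <- lapply(perturbations, cor_of)

  ut <- which(upper.tri(c_sens), arr.ind = TRUE)
  if (pair_universe == "edge-union") {
    edge_key <- function(net) paste(net$edges$node_a, net$edges$node_b)
    keys <- unique(unlist(c(list(edge_key(sensitive)), lapply(perturbations, edge_key))))
    pair_keys <- paste(ids[ut[, 1]], ids[ut[, 2]])
    ut <- ut[pair_keys %in% keys, , drop = FALSE]
  }
  if (nrow(ut) == 0) {
    return(tibble::tibble(
      node_a = character(), node_b = character(), pcc_sensitive = numeric(),
      delta_pcc = list(), n_exceed = integer(), representative_delta = numeric(),
      robust = logical(), edge_class = character(), in_sensitive = logical()
    ))
  }

  r_sens <- c_sens[ut]
  deltas <- vapply(c_pert, function(cm) cm[ut] - r_sens,
                   numeric(nrow(ut)))
  if (is.null(dim(deltas))) deltas <- matrix(deltas, nrow = nrow(ut))

  thr <- cfg$delta_pcc_threshold
  per_pair <- function(d) {
    d <- d[is.finite(d)]
    exceed <- d[abs(d) > thr]
    if (length(exceed) == 0) {
      return(list(n_exceed = 0L, rep = 0, class = "invariant", robust = FALSE))
    }
    if (all(exceed > 0) || all(exceed < 0)) {
      n <- length(exceed)
      rep_d <- mean(exceed)
      list(n_exceed = as.integer(n), rep = rep_d,
           class = if (rep_d > 0) "gained" else "lost",
           robust = n >= cfg$min_perturbations)
    } else {
      # contradictory perturbations: differential but uninterpretable
      list(n_exceed = 0L, rep = 0, class = "invariant", robust = FALSE)
    }
  }
  calls <- lapply(seq_len(nrow(ut)), function(i) per_pair(deltas[i, ]))

  sens_keys <- paste(sensitive$edges$node_a, sensitive$edges$node_b)
  tibble::tibble(
    node_a = ids[ut[, 1]],
    node_b = ids[ut[, 2]],
    pcc_sensitive = r_sens,
    delta_pcc = lapply(seq_len(nrow(ut)), function(i) deltas[i, ]),
    n_exceed = vapply(calls, `[[`, integer(1), "n_exceed"),
    representative_delta = vapply(calls, `[[`, numeric(1), "rep"),
    robust = vapply(calls, `[[`, logical(1), "robust"),
    edge_class = vapply(calls, `[[`, character(1), "class"),
    in_sensitive = paste(ids[ut[, 1]], ids[ut[, 2]]) %in% sens_keys
  )
}

#' Build the robust differential network
#'
#' Keeps the robust rows of a [delta_pcc_table()] as differential edges,
#' classed gained (`representative_delta > 0`) or lost (`< 0`). Pairs that
#' were edges of the sensitive network but never exceeded the delta
#' threshold are reported separately as the invariant side table.
#'
#' @param delta_table Output of [delta_pcc_table()].
#' @param cfg An [analysis_config()] (recorded for provenance).
#' @return An object of class `differential_network`: list with `edges`
#'   (robust rows), `invariant_edges` (sensitive-network edges with no
#'   exceedance), `nodes` (edge-incident), `n_nodes`, `n_edges`, and
#'   `fraction_gained`.
#' @export
build_differential_network <- function(delta_table, cfg = analysis_config()) {
  robust <- delta_table[delta_table$robust, , drop = FALSE]
  invariant <- delta_table[delta_table$edge_class == "invariant" &
                             delta_table$in_sensitive, , drop = FALSE]
  ids <- unique(c(robust$node_a, robust$node_b))
  nodes <- tibble::tibble(
    id = ids,
    gene = sub("\\|(TC|TAM)$", "", ids),
    compartment = sub("^.*\\|", "", ids)
  )
  structure(
    list(edges = robust, invariant_edges = invariant, nodes = nodes,
         n_nodes = nrow(nodes), n_edges = nrow(robust),
         fraction_gained = if (nrow(robust) == 0) NA_real_ else
           mean(robust$edge_class == "gained"),
         config = cfg),
    class = "differential_network"
  )
}

#' @export
print.differential_network <- function(x, ...) {
  cat(sprintf("<differential_network> %d nodes, %d robust edges", x$n_nodes, x$n_edges))
  if (x$n_edges > 0) cat(sprintf(" (%.0f%% gained)", 100 * x$fraction_gained))
  cat("\n")
  invisible(x)
}

#' Candidate gene list of a differential network
#'
#' Unique gene symbols among the edge-incident nodes, optionally passed
#' through an ortholog/symbol map (two-column data frame `from`, `to`;
#' matching is case-insensitive). Unmapped symbols are dropped with a log
#' message. A gene present as both a TC node and a TAM node yields one
#' candidate.
#'
#' @param dnet A `differential_network`.
#' @param symbol_map Optional data frame with columns `from` and `to`;
#'   `NULL` means identity mapping.
#' @return Character vector of candidate gene symbols (uppercased).
#' @export
candidate_gene_list <- function(dnet, symbol_map = NULL) {
  stopifnot(inherits(dnet, "differential_network"))
  symbols <- unique(normalize_symbols(dnet$nodes$gene))
  if (is.null(symbol_map)) return(symbols)
  if (!all(c("from", "to") %in% names(symbol_map))) {
    abort("candidate_gene_list: symbol_map needs columns 'from' and 'to'")
  }
  idx <- match(symbols, normalize_symbols(symbol_map$from))
  unmapped <- symbols[is.na(idx)]
  if (length(unmapped) > 0) {
    mcg_log("candidate_gene_list: dropping ", length(unmapped),
            " unmapped symbol(s): ", paste(unmapped, collapse = ", "))
  }
  unique(normalize_symbols(symbol_map$to[idx[!is.na(idx)]]))
}
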