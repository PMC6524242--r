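#' Pearson correlation of one gene pair with a correlation-test p-value
#'
#' Standard Pearson r between two equal-length sample vectors, with the
#' two-sided p-value of the t statistic `r * sqrt((n - 2) / (1 - r^2))` on
#' `n - 2` degrees of freedom. Perfect correlation (|r| = 1) returns p = 0.
#'
#' @param x,y Numeric vectors of equal length `n >= 3` with nonzero variance.
#' @return A list with `pcc` and `p`.
#' @export
#' @examples
#' pearson_edge(c(1, 2, 3, 4), c(1, 2, 3, 4))$pcc
pearson_edge <- function(x, y) {
  n <- length(x)
  if (length(y) != n) abort("pearson_edge: x and y must have equal length")
  if (n < 3) abort("pearson_edge: need at least 3 samples")
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    abort("pearson_edge: values must be finite")
  }
  if (var(x) == 0 || var(y) == 0) {
    abort("pearson_edge: undefined correlation (zero variance)")
  }
  r <- cor(x, y)
  list(pcc = r, p = pcc_pvalue(r, n))
}

pcc_pvalue <- function(r, n) {
  p <- rep(0, length(r))
  inside <- is.finite(r) & abs(r) < 1
  tstat <- r[inside] * sqrt((n - 2) / (1 - r[inside]^2))
  p[inside] <- 2 * pt(-abs(tstat), n - 2)
  p[!is.finite(r)] <- NA_real_
  p
}

node_id <- function(gene, compartment) paste(gene, compartment, sep = "|")

# node-by-animal matrix of (vehicle-normalized) expression for the requested
# node genes, columns ordered by pairing id so TC and TAM values align
node_data_matrix <- function(exp_norm, node_genes, animals) {
  rows <- list()
  for (comp in c("TC", "TAM")) {
    genes <- node_genes[[comp]]
    if (length(genes) == 0) next
    cols <- compartment_columns(exp_norm, comp)
    cols <- cols[match(animals, cols$pair_id), ]
    if (anyNA(cols$sample_id)) {
      abort("build_network: some requested animals lack a paired sample")
    }
    missing_genes <- setdiff(genes, rownames(exp_norm$expression))
    if (length(missing_genes) > 0) {
      abort(paste0("build_network: node gene(s) absent from expression: ",
                   paste(missing_genes, collapse = ", ")))
    }
    m <- exp_norm$expression[genes, cols$sample_id, drop = FALSE]
    rownames(m) <- node_id(genes, comp)
    rows[[comp]] <- m
  }
  out <- do.call(rbind, rows)
  colnames(out) <- animals
  out
}

#' Build a multicellular co-expression network
#'
#' Computes the Pearson correlation of every unordered pair of (gene,
#' compartment) nodes across the selected paired animals — tumor-cell and
#' macrophage values from the same animal are aligned by the pairing ID, so
#' the observation unit is the animal and intercellular (TC-TAM) edges are
#' well defined. An edge is kept iff `|PCC|` strictly exceeds the edge
#' threshold and its p-value is strictly below the p cutoff. Nodes with zero
#' variance across the selected animals cannot form edges and are skipped
#' with a log message. Isolated nodes are not counted in `n_nodes`.
#'
#' @param exp_norm A (normally vehicle-normalized) [compartment_experiment()].
#' @param node_genes Named list with character vectors `TC` and `TAM`: the
#'   genes forming nodes in each compartment (typically [top_k_degs()]).
#' @param animals Pairing IDs of the animals to correlate across (>= 3).
#' @param cfg An [analysis_config()].
#' @param label Network label.
#' @return An object of class `gene_network`: a list with `label`, `animals`,
#'   `nodes` (tibble `gene`, `compartment`, `id`), `edges` (tibble `node_a`,
#'   `node_b`, `pcc`, `p`, `kind`), the node-by-animal `data` matrix the
#'   correlations were computed from, and `topology` (see
#'   [topology_metrics()]).
#' @export
build_network <- function(exp_norm, node_genes, animals, cfg = analysis_config(),
                          label = "network") {
  if (length(animals) < 3) abort("build_network: need at least 3 paired samples")
  dat <- node_data_matrix(exp_norm, node_genes, animals)
  n <- ncol(dat)
  sds <- apply(dat, 1, sd)
  if (any(sds == 0)) {
    mcg_log("build_network [", label, "]: ", sum(sds == 0),
            " zero-variance node(s) skipped for edge calling")
  }
  cmat <- suppressWarnings(cor(t(dat)))
  ut <- which(upper.tri(cmat), arr.ind = TRUE)
  r <- cmat[ut]
  ok <- is.finite(r)
  p <- rep(NA_real_, length(r))
  p[ok] <- pcc_pvalue(r[ok], n)
  keep <- ok & abs(r) > cfg$edge_abs_pcc_threshold & p < cfg$edge_p_threshold
  ids <- rownames(dat)
  edges <- tibble::tibble(
    node_a = ids[ut[keep, 1]],
    node_b = ids[ut[keep, 2]],
    pcc = r[keep],
    p = p[keep]
  )
  split_a <- strsplit(edges$node_a, "|", fixed = TRUE)
  split_b <- strsplit(edges$node_b, "|", fixed = TRUE)
  comp_a <- vapply(split_a, `[`, "", 2)
  comp_b <- vapply(split_b, `[`, "", 2)
  edges$kind <- ifelse(comp_a == comp_b, "intracellular", "intercellular")
  nodes <- tibble::tibble(
    gene = sub("\\|(TC|TAM)$", "", ids),
    compartment = sub("^.*\\|", "", ids),
    id = ids
  )
  net <- structure(
    list(label = label, animals = animals, nodes = nodes, edges = edges,
         data = dat, topology = NULL),
    class = "gene_network"
  )
  net$topology <- topology_metrics(net)
  net
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("<gene_network> '%s': %d candidate nodes, %d edges over %d animals\n",
              x$label, nrow(x$nodes), nrow(x$edges), length(x$animals)))
  t <- x$topology
  cat(sprintf("  connected nodes %d | diameter %g | centralization %.3f | avg neighbors %.3f\n",
              t$n_nodes, t$diameter, t$centralization, t$avg_neighbors))
  invisible(x)
}

#' Sensitive and single-sample perturbation networks
#'
#' Builds the drug-sensitive reference network over the endpoint (Ep)
#' animals only, then one perturbation network per rebound (Reb) animal over
#' the endpoint animals plus that single rebound animal. All networks share
#' the same node universe, so differential comparison is pairwise meaningful.
#'
#' @inheritParams build_network
#' @return A list with `sensitive` (a `gene_network`) and `perturbations`
#'   (a named list of `gene_network`s, one per rebound animal).
#' @export
build_sensitive_and_perturbation_networks <- function(exp_norm, node_genes,
                                                      cfg = analysis_config()) {
  s <- exp_norm$samples
  ep <- sort(unique(s$pair_id[s$group == "Ep"]))
  reb <- sort(unique(s$pair_id[s$group == "Reb"]))
  if (length(ep) == 0) abort("no endpoint animals")
  if (length(reb) == 0) abort("no rebound animals")
  sensitive <- build_network(exp_norm, node_genes, ep, cfg, label = "sensitive")
  perturbations <- lapply(reb, function(r) {
    build_network(exp_norm, node_genes, c(ep, r), cfg,
                  label = paste0("perturbation_", r))
  })
  names(perturbations) <- reb
  list(sensitive = sensitive, perturbations = perturbations)
}

#' Topology metrics of a gene network
#'
#' `n_nodes` counts edge-incident (non-isolated) nodes only; `diameter` is
#' the longest shortest path within the largest connected component (0 for
#' an edgeless network); `centralization` is Freeman degree centralization,
#' `sum(d_max - d_i) / ((n - 1) * (n - 2))` over the non-isolated nodes (0
#' for n < 3); `avg_neighbors` is `2 * E / N` over non-isolated nodes.
#'
#' @param net A `gene_network`, or a tibble of edges with columns `node_a`,
#'   `node_b`.
#' @return A list with `n_nodes`, `n_edges`, `diameter`, `centralization`,
#'   `avg_neighbors`.
#' @export
topology_metrics <- function(net) {
  edges <- if (inherits(net, "gene_network")) net$edges else tibble::as_tibble(net)
  n_edges <- nrow(edges)
  if (n_edges == 0) {
    return(list(n_nodes = 0L, n_edges = 0L, diameter = 0,
                centralization = 0, avg_neighbors = 0))
  }
  g <- igraph::graph_from_data_frame(
    edges[, c("node_a", "node_b")], directed = FALSE
  )
  n <- igraph::vcount(g)
  deg <- igraph::degree(g)
  comps <- igraph::components(g)
  big <- which.max(comps$csize)
  sub <- igraph::induced_subgraph(g, which(comps$membership == big))
  dists <- igraph::distances(sub)
  diam <- max(dists[is.finite(dists)])
  centr <- if (n >= 3) sum(max(deg) - deg) / ((n - 1) * (n - 2)) else 0
  list(n_nodes = as.integer(n), n_edges = as.integer(n_edges),
       diameter = diam, centralization = centr,
       avg_neighbors = 2 * n_edges / n)
}

#' Export a network as an edge-list TSV or GraphML file
#'
#' The edge list carries `node_a`, `node_b`, `comp_a`, `comp_b`, `pcc`, `p`
#' and `kind` (intracellular/intercellular); GraphML output (via igraph)
#' carries the same attributes. An empty network writes a header-only TSV.
#'
#' @param net A `gene_network`.
#' @param path Output file path.
#' @param format `"tsv"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path, format = c("tsv", "graphml")) {
  format <- match.arg(format)
  stopifnot(inherits(net, "gene_network"))
  e <- net$edges
  comp_of <- function(id) sub("^.*\\|", "", id)
  out <- tibble::tibble(
    node_a = e$node_a, node_b = e$node_b,
    comp_a = comp_of(e$node_a), comp_b = comp_of(e$node_b),
    pcc = e$pcc, p = e$p, kind = e$kind
  )
  if (format == "tsv") {
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    g <- igraph::graph_from_data_frame(out, directed = FALSE)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Read an exported edge-list TSV back into an edge tibble
#'
#' @param path Path written by [export_network()] with `format = "tsv"`.
#' @return Edge tibble with the exported columns.
#' @export
read_network_edges <- function(path) {
  read_delim_table(path)
}
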